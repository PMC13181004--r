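#' Read a BED-like interval file
#'
#' Reads BED3 (`chrom start end`), tagged-read BED (BED3 plus a genome
#' tag in column 4), BED6 gene models, or ENCODE narrowPeak.  Files are
#' tab-separated with no header; coordinates are 0-based half-open.
#'
#' @param path file path.
#' @param format one of `"bed3"`, `"tagged"`, `"bed6"`, `"narrowpeak"`.
#' @return tibble in file order.  `bed3`: `chrom,start,end`; `tagged`:
#'   plus `genome_tag`; `bed6`: `chrom,start,end,gene_id,score,strand`
#'   plus derived `tss`; `narrowpeak`: the first 3 columns kept (extra
#'   columns ignored).
#' @export
read_bed <- function(path, format = c("bed3", "tagged", "bed6", "narrowpeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ncol_req <- c(bed3 = 3L, tagged = 4L, bed6 = 6L, narrowpeak = 3L)[[format]]
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(0), start = integer(0), end = integer(0))
    if (format == "tagged") out$genome_tag <- character(0)
    if (format == "bed6") {
      out$gene_id <- character(0); out$score <- numeric(0)
      out$strand <- character(0); out$tss <- integer(0)
    }
    return(out)
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < ncol_req)) {
    bad <- which(nf < ncol_req)[1]
    abort(sprintf("%s line %d: expected >= %d tab-separated fields, found %d",
                  path, bad, ncol_req, nf[bad]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("%s line %d: non-numeric coordinates", path, bad))
  }
  out <- tibble(chrom = col(1), start = start, end = end)
  if (format == "tagged") out$genome_tag <- col(4)
  if (format == "bed6") {
    out$gene_id <- col(4)
    out$score <- suppressWarnings(as.numeric(col(5)))
    out$strand <- col(6)
    if (!all(out$strand %in% c("+", "-"))) {
      abort(sprintf("%s: strand column must be '+' or '-'", path))
    }
  }
  bad <- which(!(out$end > out$start) | out$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval %s:%d-%d (end <= start or start < 0)",
                  path, bad[1], out$chrom[bad[1]], out$start[bad[1]], out$end[bad[1]]))
  }
  if (format == "bed6") {
    if (anyDuplicated(out$gene_id)) {
      abort(sprintf("%s: duplicated gene_id(s)", path))
    }
    out$tss <- ifelse(out$strand == "+", out$start, out$end)
  }
  out
}

#' @rdname read_bed
#' @export
read_bed6 <- function(path) read_bed(path, format = "bed6")

#' Write intervals as BED
#'
#' Tab-separated, no header.  Writes `chrom,start,end`, plus
#' `genome_tag` when present (tagged-read BED), or
#' `gene_id,score,strand` when all three are present (BED6).
#'
#' @param x interval tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED output")
  cols <- c("chrom", "start", "end")
  if ("genome_tag" %in% names(x)) {
    cols <- c(cols, "genome_tag")
  } else if (all(c("gene_id", "score", "strand") %in% names(x))) {
    cols <- c(cols, "gene_id", "score", "strand")
  }
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param x tibble with `chrom,start,end,value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x, "bedGraph output")
  stopifnot("value" %in% names(x))
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' The manifest is a TSV with header columns `sample_id, assay,
#' condition, genotype, cell_line, replicate` and optionally `path`
#' (read file per sample).  `sample_id` must be unique.
#'
#' @param path file path.
#' @return tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "assay", "condition", "genotype", "cell_line", "replicate")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$sample_id)) abort("manifest sample_id values must be unique")
  m
}

#' @rdname read_manifest
#' @param m manifest tibble.
#' @export
write_manifest <- function(m, path) {
  readr::write_tsv(m, path, progress = FALSE)
  invisible(path)
}

#' Read or write a count matrix TSV
#'
#' First column `gene_id` (gene and ERCC row identifiers), remaining
#' columns one per sample, integer counts, with header.
#'
#' @param path file path.
#' @return tibble with `gene_id` first.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene_id") abort("count matrix must have gene_id as first column")
  if (anyDuplicated(x$gene_id)) abort("duplicate row ids in count matrix")
  x
}

#' @rdname read_counts
#' @param x counts tibble.
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
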