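#' Validate a tibble of genomic intervals
#'
#' Intervals everywhere in chiprx are 0-based half-open: `start` is the
#' first base covered, `end` is one past the last.  An interval must have
#' `end > start`, `start >= 0` and a non-empty chromosome name.
#'
#' @param x data frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x` invisibly (as a tibble), or an error describing the first
#'   offending rows.
#' @export
validate_intervals <- function(x, what = "interval set") {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks required column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(x$end > x$start) | x$start < 0 |
                 is.na(x$chrom) | !nzchar(as.character(x$chrom)))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: %d invalid interval(s) (end <= start, start < 0 or empty chrom); first at row %d (%s:%s-%s)",
      what, length(bad), bad[1],
      x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# GRanges from an interval tibble; BED half-open -> IRanges 1-based closed.
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# Interval tibble from a GRanges (back to 0-based half-open).
gr_as_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Overlap query between two interval sets
#'
#' Returns the rows of `subjects` that overlap `query` by at least one
#' base pair, under half-open coordinates: subject `s` overlaps query `q`
#' iff `s$chrom == q$chrom`, `s$start < q$end` and `q$start < s$end`.
#' Abutting intervals (`end == start`) do not overlap.
#'
#' @param query single-row data frame (or any interval tibble; overlap
#'   with any query row counts).
#' @param subjects interval tibble.
#' @return the overlapping subset of `subjects`, in subject order.
#' @export
interval_overlap_query <- function(query, subjects) {
  validate_intervals(query, "query")
  subjects <- as_tibble(subjects)
  if (nrow(subjects) == 0) return(subjects)
  validate_intervals(subjects, "subjects")
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_gr(subjects), as_gr(query),
                                minoverlap = 1L))
  subjects[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Nearest transcription start site for genomic points
#'
#' Assigns each point the gene whose TSS is closest on the same
#' chromosome.  Ties are broken deterministically: the smaller TSS
#' coordinate wins, then the lexicographically smaller `gene_id`.  Points
#' on a chromosome with no annotated gene are dropped with a warning.
#'
#' @param points tibble with `chrom` and `pos` (bp).
#' @param genes gene model tibble from [read_bed6()] or [sim_layout()];
#'   needs `chrom`, `gene_id`, `tss`.
#' @return `points` with `gene_id`, `tss` and `tss_distance` columns
#'   appended; unassignable points removed.
#' @export
nearest_tss <- function(points, genes) {
  points <- as_tibble(points)
  genes <- as_tibble(genes)
  stopifnot(all(c("chrom", "pos") %in% names(points)),
            all(c("chrom", "gene_id", "tss") %in% names(genes)))
  # Deterministic candidate order: by tss then gene_id, so that among
  # equidistant genes the first encountered is the tie-rule winner.
  genes <- arrange(genes, .data$chrom, .data$tss, .data$gene_id)
  by_chrom <- split(genes, genes$chrom)
  orphan <- !(points$chrom %in% names(by_chrom))
  if (any(orphan)) {
    warn(sprintf("%d point(s) on chromosomes without genes were dropped",
                 sum(orphan)))
    points <- points[!orphan, , drop = FALSE]
  }
  if (nrow(points) == 0) {
    return(mutate(points, gene_id = character(0), tss = integer(0),
                  tss_distance = numeric(0)))
  }
  assign_one_chrom <- function(pts, gn) {
    tss <- gn$tss
    # candidates flanking each point in tss order, then the tie rules
    idx_hi <- findInterval(pts$pos, tss) # last tss <= pos (ties: rightmost)
    pick <- integer(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      j <- idx_hi[i]
      cand <- unique(pmin(pmax(c(j - 1L, j, j + 1L, j + 2L), 1L), length(tss)))
      d <- abs(tss[cand] - pts$pos[i])
      best <- cand[d == min(d)]
      # genes sorted by (tss, gene_id): the first best index wins the tie
      pick[i] <- best[1]
    }
    mutate(pts,
           gene_id = gn$gene_id[pick],
           tss = gn$tss[pick],
           tss_distance = abs(gn$tss[pick] - .data$pos))
  }
  points$.row <- seq_len(nrow(points))
  out <- purrr::map_dfr(split(points, points$chrom), function(pts) {
    assign_one_chrom(pts, by_chrom[[pts$chrom[1]]])
  })
  out <- arrange(out, .data$.row)
  out$.row <- NULL
  as_tibble(out)
}

#' Midpoint of an interval
#'
#' `floor((start + end) / 2)`, the anchor used for peak-to-TSS distances.
#'
#' @param x interval tibble.
#' @return integer vector of midpoints.
#' @export
interval_midpoint <- function(x) {
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}
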