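#' Spike-normalized metagene profile
#'
#' Averages per-base read coverage over genes after rescaling every gene
#' body to a common axis: `flank/bin_width` fixed-width upstream bins,
#' `body_bins` bins spanning the gene body (each `length/body_bins` bp),
#' and the same number of fixed-width downstream bins.  Genes on the
#' minus strand are orientation-flipped so bin 1 is always the 5'
#' upstream end.  Per-base coverage is multiplied by the sample's
#' normalizer; profiles of multiple samples are returned per sample and
#' can be averaged downstream (replicates first, then genes are already
#' averaged here).
#'
#' Genes whose body is shorter than `body_bins` bp, or whose extended
#' region leaves the chromosome, are excluded.
#'
#' @param reads retained target reads (`chrom, start, end`, optional
#'   `sample_id`).
#' @param genes gene tibble (`chrom, start, end, gene_id, strand`).
#' @param factors [scaling_factors()] tibble.
#' @param body_bins number of scaled gene-body bins (default 100).
#' @param flank flanking region size in bp (default 10000).
#' @param bin_width flank bin width in bp (default 100).
#' @return tibble `sample_id, bin, segment, value`, `bin` in
#'   `1:(2*flank/bin_width + body_bins)`, `segment` one of
#'   `"upstream", "body", "downstream"`; class `chiprx_metagene`.
#' @export
metagene_profile <- function(reads, genes, factors, body_bins = 100,
                             flank = 10000, bin_width = 100) {
  genes <- as_tibble(genes)
  validate_intervals(genes, "genes")
  stopifnot(all(c("gene_id", "strand") %in% names(genes)))
  n_flank <- as.integer(flank / bin_width)
  eligible <- genes$end - genes$start >= body_bins & genes$start - flank >= 0
  genes <- genes[eligible, , drop = FALSE]
  if (nrow(genes) == 0) abort("no genes eligible for the metagene profile")
  reads <- as_tibble(reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"

  # bin boundaries per gene, 5'->3' in genomic orientation; flipped later
  bins_for_gene <- function(start, end) {
    up <- seq(start - flank, start, length.out = n_flank + 1)
    body <- seq(start, end, length.out = body_bins + 1)
    down <- seq(end, end + flank, length.out = n_flank + 1)
    b <- c(up[-(n_flank + 1)], body[-(body_bins + 1)], down)
    cbind(floor(b[-length(b)]), ceiling(b[-1]))
  }
  n_bins <- 2L * n_flank + body_bins
  bmat <- do.call(rbind, purrr::map2(genes$start, genes$end, bins_for_gene))
  bin_chrom <- rep(genes$chrom, each = n_bins)
  bin_width_bp <- pmax(bmat[, 2] - bmat[, 1], 1)

  samples <- unique(reads$sample_id)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    r <- reads[reads$sample_id == samples[si], , drop = FALSE]
    f <- factors[factors$sample_id == samples[si], , drop = FALSE]
    if (nrow(f) != 1) abort(sprintf("no scaling factors for sample %s", samples[si]))
    vals <- numeric(nrow(bmat))
    for (ch in unique(genes$chrom)) {
      rc <- r[r$chrom == ch, , drop = FALSE]
      sel <- bin_chrom == ch
      if (nrow(rc) == 0) next
      cov <- IRanges::coverage(IRanges::IRanges(start = rc$start + 1L,
                                                end = rc$end))
      maxend <- max(bmat[sel, 2])
      if (length(cov) < maxend) {
        cov <- c(cov, S4Vectors::Rle(0L, maxend - length(cov)))
      }
      v <- IRanges::Views(cov, start = bmat[sel, 1] + 1L, end = bmat[sel, 2])
      vals[sel] <- IRanges::viewSums(v) / bin_width_bp[sel]
    }
    mat <- matrix(vals, ncol = n_bins, byrow = TRUE)
    flip <- genes$strand == "-"
    mat[flip, ] <- mat[flip, rev(seq_len(n_bins)), drop = FALSE]
    prof <- colMeans(mat) * f$normalizer
    out[[si]] <- tibble(
      sample_id = samples[si],
      bin = seq_len(n_bins),
      segment = rep(c("upstream", "body", "downstream"),
                    c(n_flank, body_bins, n_flank)),
      value = prof)
  }
  res <- bind_rows(out)
  class(res) <- c("chiprx_metagene", class(res))
  res
}

#' Average metagene profiles over samples within groups
#'
#' @param profiles [metagene_profile()] output.
#' @param groups tibble mapping `sample_id` to grouping columns (e.g.
#'   the manifest's `condition`).
#' @return tibble with one averaged profile per group.
#' @export
average_profiles <- function(profiles, groups) {
  grp_cols <- setdiff(names(groups), "sample_id")
  profiles |>
    left_join(groups, by = "sample_id") |>
    group_by(across(all_of(c(grp_cols, "bin", "segment")))) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    arrange(across(all_of(grp_cols)), .data$bin)
}

#' @exportS3Method ggplot2::autoplot
autoplot.chiprx_metagene <- function(object, colour = "sample_id", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$value,
                               colour = .data[[colour]])) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = range(object$bin[object$segment == "body"]) + c(-0.5, 0.5),
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "metagene bin (5' flank - body - 3' flank)",
                  y = "spike-normalized coverage") +
    ggplot2::theme_minimal()
}
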