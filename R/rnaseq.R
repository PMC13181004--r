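is_ercc <- function(ids, prefix = "ERCC-") startsWith(ids, prefix)

#' ERCC spike-in size factors
#'
#' Per-sample size factors from the total count over ERCC rows.  With
#' `center = "geometric"` (default), `s_j = E_j / geometric-mean(E)`,
#' which makes the factors scale-free across the experiment.  With
#' `center = "reference"`, `s_j = E_j / k_ref`, a fixed-reference
#' normalizer (counts per `k_ref` ERCC reads) under which rescaling one
#' sample's column cancels exactly.  `method = "median-ratio"` replaces
#' the ERCC totals by the median across ERCC rows of the count ratio to
#' the row geometric mean (a median-of-ratios variant restricted to the
#' spike rows).
#'
#' @param counts count tibble (`gene_id` + sample columns); ERCC rows
#'   recognized by `ercc_prefix`.
#' @param center `"geometric"` or `"reference"`.
#' @param method `"total"` or `"median-ratio"`.
#' @param k_ref reference ERCC count for `center = "reference"`.
#' @param ercc_prefix row-id prefix marking spike rows.
#' @return tibble `sample_id, ercc_total, size_factor`.
#' @export
ercc_size_factors <- function(counts, center = c("geometric", "reference"),
                              method = c("total", "median-ratio"),
                              k_ref = 1e4, ercc_prefix = "ERCC-") {
  center <- match.arg(center)
  method <- match.arg(method)
  samples <- setdiff(names(counts), "gene_id")
  e <- counts[is_ercc(counts$gene_id, ercc_prefix), samples, drop = FALSE]
  if (nrow(e) == 0) abort("no ERCC rows found in the count matrix")
  totals <- vapply(e, sum, numeric(1))
  if (any(totals == 0)) {
    abort(sprintf("zero ERCC total in sample(s): %s",
                  paste(samples[totals == 0], collapse = ", ")))
  }
  base_stat <- if (method == "total") {
    totals
  } else {
    em <- as.matrix(e)
    keep <- rowSums(em > 0) == ncol(em)
    if (!any(keep)) abort("no ERCC row with positive counts in all samples")
    gm <- exp(rowMeans(log(em[keep, , drop = FALSE])))
    apply(em[keep, , drop = FALSE] / gm, 2, median)
  }
  sf <- if (center == "geometric") {
    base_stat / exp(mean(log(base_stat)))
  } else {
    base_stat / k_ref
  }
  tibble(sample_id = samples, ercc_total = unname(totals),
         size_factor = unname(sf))
}

#' Normalize a count matrix by size factors
#'
#' @param counts count tibble.
#' @param size_factors [ercc_size_factors()] tibble.
#' @param drop_ercc drop the spike rows from the result (default TRUE).
#' @param ercc_prefix row-id prefix marking spike rows.
#' @return tibble of normalized counts (`raw / size_factor`).
#' @export
normalize_counts <- function(counts, size_factors, drop_ercc = TRUE,
                             ercc_prefix = "ERCC-") {
  samples <- setdiff(names(counts), "gene_id")
  missing_s <- setdiff(samples, size_factors$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("no size factor for sample(s): %s",
                  paste(missing_s, collapse = ", ")))
  }
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)
  out <- counts
  for (s in samples) out[[s]] <- counts[[s]] / sf[[s]]
  if (drop_ercc) out <- out[!is_ercc(out$gene_id, ercc_prefix), , drop = FALSE]
  out
}

# vectorized Welch two-sample t-test on the rows of two matrices
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  t <- (m1 - m2) / se
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # zero-variance convention: equal constant groups are unremarkable
  degenerate <- se2 == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  list(estimate = m1 - m2, se = se, p = p, df = df)
}

#' Differential expression by Welch's t-test on ERCC-scaled counts
#'
#' A deliberately simple differential-expression procedure: counts are
#' divided by the ERCC size factors, genes with zero counts in every
#' sample are excluded as not detected, and each remaining gene is
#' tested with a Welch two-sample t-test on `log2(normalized + eps)`
#' across replicates; p-values are Benjamini-Hochberg adjusted over the
#' tested genes.  The reported `log2fc` is
#' `log2((mean normalized case + eps) / (mean normalized ref + eps))`.
#' This is not a negative-binomial shrinkage model; it is adequate for
#' the questions asked here (sign balance, knockout ablation, spike-in
#' scaling), which hinge on the normalization rather than on the test.
#'
#' @param counts count tibble (genes + ERCC rows).
#' @param manifest manifest with `sample_id` and `condition` for the RNA
#'   samples present in `counts`.
#' @param contrast `c(case, reference)` condition levels.
#' @param size_factors optional precomputed [ercc_size_factors()].
#' @param pseudocount `eps` (default 0.5).
#' @param ercc_prefix spike row-id prefix.
#' @return tibble `gene_id, base_mean, log2fc, se, p, padj`, one row per
#'   detected gene.
#' @export
de_welch <- function(counts, manifest, contrast = c("hypoxia", "normoxia"),
                     size_factors = NULL, pseudocount = 0.5,
                     ercc_prefix = "ERCC-") {
  samples <- setdiff(names(counts), "gene_id")
  design <- manifest |>
    filter(.data$sample_id %in% samples,
           .data$condition %in% contrast)
  n_per <- table(factor(design$condition, levels = contrast))
  if (any(n_per < 2)) {
    abort(sprintf("need >= 2 replicates per condition; found %s",
                  paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", ")))
  }
  if (is.null(size_factors)) {
    size_factors <- ercc_size_factors(counts[, c("gene_id", design$sample_id)],
                                      ercc_prefix = ercc_prefix)
  }
  norm <- normalize_counts(counts[, c("gene_id", design$sample_id)],
                           size_factors, drop_ercc = TRUE,
                           ercc_prefix = ercc_prefix)
  mat <- as.matrix(norm[, design$sample_id, drop = FALSE])
  detected <- rowSums(mat > 0) > 0
  mat <- mat[detected, , drop = FALSE]
  ids <- norm$gene_id[detected]
  case_cols <- design$sample_id[design$condition == contrast[1]]
  ref_cols <- design$sample_id[design$condition == contrast[2]]
  lm_case <- log2(mat[, case_cols, drop = FALSE] + pseudocount)
  lm_ref <- log2(mat[, ref_cols, drop = FALSE] + pseudocount)
  w <- welch_rows(lm_case, lm_ref)
  tibble(
    gene_id = ids,
    base_mean = rowMeans(mat),
    log2fc = log2((rowMeans(mat[, case_cols, drop = FALSE]) + pseudocount) /
                    (rowMeans(mat[, ref_cols, drop = FALSE]) + pseudocount)),
    se = w$se,
    p = w$p,
    padj = p.adjust(w$p, method = "BH"))
}

#' Count significantly up- and down-regulated genes
#'
#' @param de [de_welch()] result.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return tibble `up, down, n_tested`.
#' @export
updown_summary <- function(de, alpha = 0.05) {
  sig <- de$padj < alpha
  tibble(up = sum(sig & de$log2fc > 0),
         down = sum(sig & de$log2fc < 0),
         n_tested = nrow(de))
}

#' Volcano plot of a differential-expression result
#'
#' @param de [de_welch()] result.
#' @param alpha significance threshold for colouring.
#' @return a ggplot.
#' @export
plot_volcano <- function(de, alpha = 0.05) {
  de <- mutate(de, significant = .data$padj < alpha)
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
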