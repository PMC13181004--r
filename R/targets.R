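#' Reproducible peaks across two replicates
#'
#' Keeps only signal supported by both biological replicates: every
#' rep1/rep2 peak pair overlapping by at least 1 bp contributes, and the
#' retained peaks are union-merged, with chained overlaps merging
#' transitively.  The operation is symmetric in its arguments.
#'
#' @param rep1,rep2 peak tibbles (`chrom, start, end`).
#' @return merged peak tibble sorted by (chrom, start); empty when no
#'   pair overlaps.
#' @export
reproducible_peaks <- function(rep1, rep2) {
  rep1 <- as_tibble(rep1); rep2 <- as_tibble(rep2)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  validate_intervals(rep1, "rep1"); validate_intervals(rep2, "rep2")
  g1 <- as_gr(rep1); g2 <- as_gr(rep2)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(g1, g2, minoverlap = 1L))
  keep <- c(g1[unique(S4Vectors::queryHits(hits))],
            g2[unique(S4Vectors::subjectHits(hits))])
  if (length(keep) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  merged <- GenomicRanges::reduce(GenomicRanges::sort(keep))
  arrange(gr_as_tbl(merged), .data$chrom, .data$start)
}

#' Call composite HIF binding sites
#'
#' A binding site is a locus where a HIF-1β peak overlaps at least one
#' HIF-α peak (HIF-1α or HIF-2α) by >= 1 bp.  Each qualifying β peak
#' yields exactly one site whose interval is the union (hull) of the β
#' peak and every overlapping α peak, with the contributing factors
#' recorded.
#'
#' @param beta,alpha1,alpha2 reproducible peak tibbles for HIF1B, HIF1A,
#'   HIF2A (`alpha2` may be empty/NULL).
#' @return tibble `site_id, chrom, start, end, midpoint, factors`
#'   (`factors` a comma-separated subset of `HIF1B,HIF1A,HIF2A`).
#' @export
call_hif_sites <- function(beta, alpha1, alpha2 = NULL) {
  beta <- as_tibble(beta)
  empty <- tibble(site_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  midpoint = integer(0), factors = character(0))
  if (nrow(beta) == 0) return(empty)
  validate_intervals(beta, "beta peaks")
  alpha <- list(HIF1A = alpha1, HIF2A = alpha2)
  alpha <- purrr::keep(alpha, function(x) !is.null(x) && nrow(as_tibble(x)) > 0)
  if (length(alpha) == 0) return(empty)
  gb <- as_gr(beta)
  hull_start <- beta$start; hull_end <- beta$end
  has <- matrix(FALSE, nrow(beta), length(alpha),
                dimnames = list(NULL, names(alpha)))
  for (nm in names(alpha)) {
    a <- as_tibble(alpha[[nm]])
    validate_intervals(a, paste(nm, "peaks"))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gb, as_gr(a), minoverlap = 1L))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    has[unique(qh), nm] <- TRUE
    if (length(qh) > 0) {
      agg_min <- tapply(a$start[sh], qh, min)
      agg_max <- tapply(a$end[sh], qh, max)
      idx <- as.integer(names(agg_min))
      hull_start[idx] <- pmin(hull_start[idx], agg_min)
      hull_end[idx] <- pmax(hull_end[idx], agg_max)
    }
  }
  keep <- rowSums(has) > 0
  if (!any(keep)) return(empty)
  out <- tibble(
    chrom = beta$chrom[keep],
    start = as.integer(hull_start[keep]),
    end = as.integer(hull_end[keep]),
    factors = vapply(which(keep), function(i) {
      paste(c("HIF1B", colnames(has)[has[i, ]]), collapse = ",")
    }, character(1))) |>
    arrange(.data$chrom, .data$start)
  out |>
    mutate(site_id = sprintf("site_%03d", row_number()),
           midpoint = interval_midpoint(out)) |>
    select("site_id", "chrom", "start", "end", "midpoint", "factors")
}

#' Assign hypoxia-inducible target genes to binding sites
#'
#' Each site is anchored at its midpoint and assigned the nearest TSS on
#' the same chromosome ([nearest_tss()] tie rules).  The assigned gene
#' is retained as a target iff it is inducible in the supplied
#' differential-expression result (`log2fc > 0` and `padj < alpha`);
#' sites whose nearest gene is not inducible yield no target.  A gene
#' nearest to several sites appears once, with its closest site.
#'
#' @param sites [call_hif_sites()] output.
#' @param genes gene tibble with `chrom, gene_id, tss`.
#' @param de [de_welch()] result covering the annotation.
#' @param alpha inducibility threshold on `padj` (default 0.05).
#' @return tibble `gene_id, site_id, tss_distance, log2fc, padj`.
#' @export
assign_hif_targets <- function(sites, genes, de, alpha = 0.05) {
  if (nrow(sites) == 0) {
    return(tibble(gene_id = character(0), site_id = character(0),
                  tss_distance = numeric(0), log2fc = numeric(0),
                  padj = numeric(0)))
  }
  pts <- tibble(chrom = sites$chrom, pos = sites$midpoint,
                site_id = sites$site_id)
  hit <- nearest_tss(pts, genes)
  hit |>
    inner_join(select(de, "gene_id", "log2fc", "padj"), by = "gene_id") |>
    filter(.data$log2fc > 0, .data$padj < alpha) |>
    group_by(.data$gene_id) |>
    slice_min(.data$tss_distance, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("gene_id", "site_id", "tss_distance", "log2fc", "padj") |>
    arrange(.data$gene_id)
}

# distance from every gene TSS to the nearest site midpoint (Inf when no
# site shares the chromosome)
tss_site_distance <- function(genes, sites) {
  d <- rep(Inf, nrow(genes))
  for (ch in unique(sites$chrom)) {
    mid <- sort(sites$midpoint[sites$chrom == ch])
    sel <- which(genes$chrom == ch)
    if (length(sel) == 0) next
    tss <- genes$tss[sel]
    j <- findInterval(tss, mid)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(mid))
    d[sel] <- pmin(abs(tss - mid[lo]), abs(tss - mid[hi]))
  }
  d
}

#' Sample expression-matched, distance-excluded control genes
#'
#' Draws, for each target gene, one control gene matched on expression:
#' targets are binned into deciles of their expression, and a control is
#' sampled without replacement from the eligible pool falling in the
#' same decile.  Eligible genes have their TSS more than `min_dist` bp
#' from every binding-site midpoint, detected expression, and are not
#' targets.  When a decile pool is exhausted, the unused eligible gene
#' with the nearest expression is taken instead.  Fully deterministic
#' for a fixed `seed`.
#'
#' @param targets [assign_hif_targets()] output (`gene_id`).
#' @param genes gene tibble (`chrom, gene_id, tss`).
#' @param sites [call_hif_sites()] output.
#' @param expression tibble `gene_id, expression` (e.g. mean normalized
#'   normoxic counts); genes absent or with `expression <= 0` are not
#'   eligible, and targets missing from it are dropped from matching.
#' @param min_dist exclusion distance in bp (default 5e5).
#' @param n_bins number of expression quantile bins (default 10).
#' @param seed integer seed.
#' @return tibble `gene_id, bin, expression, matched_target, fallback`;
#'   attribute `bins` holds the bin boundaries.
#' @export
sample_matched_controls <- function(targets, genes, sites, expression,
                                    min_dist = 5e5, n_bins = 10, seed = 1) {
  genes <- as_tibble(genes)
  expr <- setNames(expression$expression, expression$gene_id)
  tg <- filter(targets, .data$gene_id %in% names(expr))
  tg_expr <- expr[tg$gene_id]
  d <- tss_site_distance(genes, sites)
  pool <- genes |>
    mutate(site_dist = d) |>
    filter(.data$site_dist > min_dist,
           !(.data$gene_id %in% targets$gene_id),
           .data$gene_id %in% names(expr)) |>
    mutate(expression = unname(expr[.data$gene_id])) |>
    filter(.data$expression > 0)
  if (nrow(pool) < nrow(tg)) {
    abort(sprintf("eligible control pool (%d) smaller than target set (%d)",
                  nrow(pool), nrow(tg)))
  }
  probs <- seq(0, 1, length.out = n_bins + 1)
  brk <- unique(quantile(tg_expr, probs = probs, names = FALSE))
  bin_of <- function(x) {
    b <- findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), length(brk) - 1L)
  }
  tg_bin <- bin_of(tg_expr)
  pool_bin <- bin_of(pool$expression)
  withr::with_seed(seed, {
    used <- rep(FALSE, nrow(pool))
    picks <- integer(nrow(tg))
    fallback <- logical(nrow(tg))
    # deterministic processing order: by target gene_id
    ord <- order(tg$gene_id)
    for (i in ord) {
      cand <- which(!used & pool_bin == tg_bin[i])
      if (length(cand) > 0) {
        picks[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        free <- which(!used)
        gap <- abs(log(pool$expression[free]) - log(tg_expr[i]))
        picks[i] <- free[which.min(gap)]
        fallback[i] <- TRUE
      }
      used[picks[i]] <- TRUE
    }
    out <- tibble(gene_id = pool$gene_id[picks],
                  bin = tg_bin,
                  expression = pool$expression[picks],
                  matched_target = tg$gene_id,
                  fallback = fallback) |>
      arrange(.data$matched_target)
    attr(out, "bins") <- brk
    out
  })
}
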