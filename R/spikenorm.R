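#' Classify tagged reads and apply the blacklist
#'
#' Partitions every read into exactly one of four classes: `spike`
#' (exogenous genome), `ambiguous` (mapped to both genomes, excluded),
#' `blacklisted` (target-genome read overlapping a blacklist interval by
#' at least 1 bp, excluded) and `target` (retained target-genome read).
#'
#' @param reads tibble of tagged reads (`chrom, start, end, genome_tag`,
#'   optionally `sample_id`); `genome_tag` must be one of
#'   `target`, `spike`, `ambiguous`.
#' @param blacklist interval tibble on target-genome coordinates, or
#'   `NULL` for no blacklist.
#' @return `reads` with a `read_class` column added.
#' @export
classify_reads <- function(reads, blacklist = NULL) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    return(mutate(reads, read_class = character(0)))
  }
  validate_intervals(reads, "reads")
  bad <- setdiff(unique(reads$genome_tag), c("target", "spike", "ambiguous"))
  if (length(bad) > 0) {
    abort(sprintf("unknown genome_tag value(s): %s", paste(bad, collapse = ", ")))
  }
  cls <- reads$genome_tag
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    validate_intervals(blacklist, "blacklist")
    is_t <- cls == "target"
    if (any(is_t)) {
      hits <- suppressWarnings(
        GenomicRanges::countOverlaps(as_gr(reads[is_t, ]),
                                     as_gr(blacklist), minoverlap = 1L))
      cls[is_t][hits > 0] <- "blacklisted"
    }
  }
  mutate(reads, read_class = cls)
}

#' Per-sample spike-in scaling factors
#'
#' Summarises classified reads per sample: retained target reads
#' `n_target` (excluding ambiguous and blacklisted), spike reads
#' `n_spike`, the excluded categories, the conventional scaling factor
#' `n_target / n_spike`, and the multiplicative `normalizer` applied to
#' raw region counts.  Two normalizers are exposed:
#' `"spike"` = `k / n_spike` (reads per `k` spike reads — preserves
#' global shifts) and `"depth"` = `k / n_target` (conventional library
#' size normalization, which cancels them).  The two differ only by the
#' sample's `n_target/n_spike` ratio, so spike scaling is exactly the
#' composition of depth scaling with the conventional factor.
#'
#' @param classified output of [classify_reads()]; a `sample_id` column
#'   groups multiple samples.
#' @param normalizer `"spike"` or `"depth"`.
#' @param k reference constant of the normalizer (default 1e4).
#' @return tibble with one row per sample: `sample_id, n_total,
#'   n_target, n_spike, n_ambiguous, n_blacklisted, factor, normalizer`.
#' @export
scaling_factors <- function(classified, normalizer = c("spike", "depth"),
                            k = 1e4) {
  normalizer <- match.arg(normalizer)
  x <- as_tibble(classified)
  if (!"read_class" %in% names(x)) {
    abort("scaling_factors() expects the output of classify_reads()")
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample"
  out <- x |>
    group_by(.data$sample_id) |>
    summarise(n_total = dplyr::n(),
              n_target = sum(.data$read_class == "target"),
              n_spike = sum(.data$read_class == "spike"),
              n_ambiguous = sum(.data$read_class == "ambiguous"),
              n_blacklisted = sum(.data$read_class == "blacklisted"),
              .groups = "drop")
  stopifnot(all(out$n_total ==
                  out$n_target + out$n_spike + out$n_ambiguous + out$n_blacklisted))
  if (any(out$n_spike == 0)) {
    abort(sprintf("sample(s) with zero spike-in reads cannot be normalized: %s",
                  paste(out$sample_id[out$n_spike == 0], collapse = ", ")))
  }
  if (normalizer == "depth" && any(out$n_target == 0)) {
    abort("sample(s) with zero target reads cannot be depth-normalized")
  }
  out$factor <- out$n_target / out$n_spike
  out$normalizer <- if (normalizer == "spike") k / out$n_spike else k / out$n_target
  attr(out, "normalizer_type") <- normalizer
  attr(out, "k") <- k
  out
}

#' Spike-scale raw counts
#'
#' `norm_signal = raw_count * normalizer`.  With the spike normalizer
#' this is reads per `k` exogenous reads, which is invariant to
#' sequencing depth but preserves genuine global differences in target
#' chromatin.
#'
#' @param raw_count numeric vector of raw region counts.
#' @param factors one row of [scaling_factors()] (or a scalar normalizer).
#' @return numeric vector of normalized signals.
#' @export
spike_scale <- function(raw_count, factors) {
  nz <- if (is.numeric(factors)) factors else factors$normalizer
  stopifnot(length(nz) == 1, is.finite(nz), nz > 0)
  raw_count * nz
}

#' Bulk spike-normalized signal per sample
#'
#' The total target read count normalized to spike-in:
#' `n_target / n_spike`.  This single scalar per sample is the
#' "total read count, normalised to spike-in" used as the response in
#' the multi-factor ANOVA of bulk signal.
#'
#' @param factors [scaling_factors()] tibble.
#' @return tibble `sample_id, bulk_signal`.
#' @export
bulk_signal <- function(factors) {
  stopifnot(all(factors$n_spike > 0))
  transmute(factors, sample_id = .data$sample_id,
            bulk_signal = .data$n_target / .data$n_spike)
}

#' Count reads over extended gene bodies
#'
#' Extends each gene body by `flank` bp on both sides (clipped at the
#' chromosome start), then counts, per sample, the reads overlapping the
#' extended region by at least 1 bp.  A read is counted once per gene;
#' when extended regions overlap, one read may count towards several
#' genes.  Strand is ignored.
#'
#' @param reads read tibble (`chrom, start, end`, optional `sample_id`);
#'   pass retained target reads (e.g.
#'   `filter(classified, read_class == "target")`).
#' @param genes gene model tibble (`chrom, start, end, gene_id`).
#' @param flank extension in bp (default 2000).
#' @return tibble `gene_id x sample_id` with `raw_count` (all genes
#'   present for every sample, zeros included).
#' @export
count_gene_reads <- function(reads, genes, flank = 2000) {
  genes <- as_tibble(genes)
  validate_intervals(genes, "genes")
  stopifnot("gene_id" %in% names(genes))
  reads <- as_tibble(reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  if (nrow(reads) == 0) {
    return(tibble(gene_id = genes$gene_id, sample_id = "sample",
                  raw_count = 0L))
  }
  ext <- mutate(genes, start = pmax(.data$start - flank, 0),
                end = .data$end + flank)
  gr_genes <- as_gr(ext)
  samples <- unique(reads$sample_id)
  out <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    r <- reads[reads$sample_id == samples[i], , drop = FALSE]
    cnt <- if (nrow(r) == 0) integer(nrow(genes))
    else suppressWarnings(
      GenomicRanges::countOverlaps(gr_genes, as_gr(r), minoverlap = 1L))
    out[[i]] <- tibble(gene_id = genes$gene_id, sample_id = samples[i],
                       raw_count = as.integer(cnt))
  }
  bind_rows(out)
}

#' Attach normalized signals to gene counts
#'
#' @param counts output of [count_gene_reads()].
#' @param factors [scaling_factors()] tibble covering every sample.
#' @return `counts` with `norm_signal = raw_count * normalizer`.
#' @export
gene_signals <- function(counts, factors) {
  missing_s <- setdiff(unique(counts$sample_id), factors$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("no scaling factors for sample(s): %s",
                  paste(missing_s, collapse = ", ")))
  }
  counts |>
    left_join(select(factors, "sample_id", "normalizer"), by = "sample_id") |>
    mutate(norm_signal = .data$raw_count * .data$normalizer) |>
    select(-"normalizer")
}

#' Per-gene log2 fold-change between conditions
#'
#' For each gene, normalized signals are averaged over replicates on the
#' linear scale within each condition and the ratio is taken with a
#' pseudocount:
#' `log2fc = log2((mean_case + eps) / (mean_ref + eps))`.
#' Genes with zero signal in every sample of both conditions are treated
#' as not detected and excluded.  Setting `per_replicate = TRUE` instead
#' averages per-replicate log2 ratios (replicates paired by number).
#'
#' @param signals output of [gene_signals()] with a `condition` column
#'   (join the manifest first), plus `replicate` when
#'   `per_replicate = TRUE`.
#' @param contrast length-2 character: `c(case, reference)`, default
#'   `c("hypoxia", "normoxia")`.
#' @param pseudocount `eps` (default 0.5).
#' @param per_replicate average log-ratios instead of ratio of averages.
#' @return tibble `gene_id, mean_ref, mean_case, log2fc, rank` sorted by
#'   ascending `log2fc`; `rank` is 1..n with ties broken by `gene_id`.
#' @export
gene_log2fc <- function(signals, contrast = c("hypoxia", "normoxia"),
                        pseudocount = 0.5, per_replicate = FALSE) {
  stopifnot(length(contrast) == 2)
  if (!"condition" %in% names(signals)) {
    abort("signals need a 'condition' column; join the manifest first")
  }
  present <- unique(signals$condition)
  if (!all(contrast %in% present)) {
    abort(sprintf("contrast condition(s) absent: %s",
                  paste(setdiff(contrast, present), collapse = ", ")))
  }
  x <- filter(signals, .data$condition %in% contrast)
  detected <- x |>
    group_by(.data$gene_id) |>
    summarise(any_signal = any(.data$norm_signal > 0), .groups = "drop")
  if (per_replicate) {
    if (!"replicate" %in% names(x)) abort("per_replicate = TRUE needs a 'replicate' column")
    wide <- x |>
      select("gene_id", "condition", "replicate", "norm_signal") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "norm_signal")
    fc <- wide |>
      mutate(l2 = log2((.data[[contrast[1]]] + pseudocount) /
                         (.data[[contrast[2]]] + pseudocount))) |>
      group_by(.data$gene_id) |>
      summarise(log2fc = mean(.data$l2), .groups = "drop")
    means <- x |>
      group_by(.data$gene_id, .data$condition) |>
      summarise(m = mean(.data$norm_signal), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "m")
    fc <- left_join(fc, means, by = "gene_id")
  } else {
    fc <- x |>
      group_by(.data$gene_id, .data$condition) |>
      summarise(m = mean(.data$norm_signal), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "m") |>
      mutate(log2fc = log2((.data[[contrast[1]]] + pseudocount) /
                             (.data[[contrast[2]]] + pseudocount)))
  }
  fc |>
    rename(mean_case = all_of(contrast[1]), mean_ref = all_of(contrast[2])) |>
    left_join(detected, by = "gene_id") |>
    filter(.data$any_signal) |>
    select("gene_id", "mean_ref", "mean_case", "log2fc") |>
    arrange(.data$log2fc, .data$gene_id) |>
    mutate(rank = row_number())
}

#' Signal relative to total histone H3
#'
#' Ratio of the spike-normalized signal of a histone mark to the
#' spike-normalized total-H3 signal over the same regions, with the
#' pseudocount in numerator and denominator.  Samples are matched by
#' gene and by the supplied design columns (condition, genotype,
#' replicate).
#'
#' @param mark_signals,h3_signals [gene_signals()] outputs for the mark
#'   and for total H3, each carrying the design columns in `by`.
#' @param by matching columns (default
#'   `c("gene_id", "condition", "genotype", "replicate")`).
#' @param pseudocount `eps` (default 0.5).
#' @return tibble with the matching columns and `mark_signal,
#'   h3_signal, ratio`.
#' @export
h3_relative <- function(mark_signals, h3_signals,
                        by = c("gene_id", "condition", "genotype", "replicate"),
                        pseudocount = 0.5) {
  by <- intersect(by, intersect(names(mark_signals), names(h3_signals)))
  if (!"gene_id" %in% by) abort("h3_relative() requires matching by gene_id")
  m <- mark_signals |>
    select(all_of(by), mark_signal = "norm_signal")
  h <- h3_signals |>
    select(all_of(by), h3_signal = "norm_signal")
  joined <- inner_join(m, h, by = by)
  unmatched <- anti_join(m, h, by = by)
  if (nrow(unmatched) > 0) {
    abort(sprintf("%d mark observation(s) lack a matching H3 sample",
                  nrow(unmatched)))
  }
  mutate(joined, ratio = (.data$mark_signal + pseudocount) /
           (.data$h3_signal + pseudocount))
}
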