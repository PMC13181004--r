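#' Default end-to-end pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()].
#' Sections: `simulate` (arguments to [sim_params()] plus the manifest
#' design), `normalize` (`k`, `normalizer`), `quantify` (`flank`,
#' `pseudocount`, `profile_assays`, `profile_flank`, `body_bins`,
#' `write_bedgraph`), `de` (`contrast`, `alpha`), `targets`
#' (`min_dist`, `alpha`, `n_bins`) and `report` (`anova_factors`).
#' A YAML file with the same structure can be loaded with
#' [read_config()].
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    simulate = list(params = list(), cell_line = "PC3", n_rep = 2),
    normalize = list(k = 1e4, normalizer = "spike"),
    quantify = list(flank = 2000, pseudocount = 0.5,
                    profile_assays = "H3K4me3", profile_flank = 10000,
                    body_bins = 100, write_bedgraph = FALSE),
    de = list(contrast = c("hypoxia", "normoxia"), alpha = 0.05),
    targets = list(min_dist = 5e5, alpha = 0.05, n_bins = 10),
    report = list(anova_factors = c("condition", "genotype", "assay"))
  )
}

#' @rdname default_config
#' @param path YAML configuration file.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(user)) {
    cfg[[sec]] <- utils::modifyList(cfg[[sec]] %||% list(), user[[sec]])
  }
  cfg
}

write_out <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name), progress = FALSE)
}

#' Run the full spike-in analysis pipeline
#'
#' Simulates a complete study, then runs every analysis stage —
#' read classification and scaling factors, gene-body quantification,
#' per-mark fold-change and rank tables, metagene profiles, ERCC-scaled
#' differential expression, binding-site and target calling, matched
#' control sampling, the target-vs-control chromatin contrast in both
#' genotypes, bulk-signal ANOVA and fold-change correlations — and
#' writes every result as TSV (plus the simulated inputs as BED/TSV)
#' under `out_dir`.  Fully deterministic for a fixed seed.
#'
#' @param out_dir output directory.
#' @param config configuration list, see [default_config()].
#' @param seed integer seed for every stochastic stage.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(out_dir, config = default_config(), seed = 1) {
  cfg <- utils::modifyList(default_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  params <- do.call(sim_params, cfg$simulate$params)
  manifest <- sim_manifest(params, n_rep = cfg$simulate$n_rep,
                           cell_line = cfg$simulate$cell_line)
  sim <- stage("simulate",
               simulate_study(file.path(out_dir, "sim"), params,
                              manifest = manifest, seed = seed))
  layout <- sim$layout
  chip_manifest <- filter(sim$manifest, .data$assay != "RNA")

  classified <- stage("normalize",
                      classify_reads(sim$reads, layout$blacklist))
  sf <- stage("normalize",
              scaling_factors(classified,
                              normalizer = cfg$normalize$normalizer,
                              k = cfg$normalize$k))
  write_out(sf, out_dir, "scaling_factors.tsv")
  bulk <- left_join(bulk_signal(sf), chip_manifest, by = "sample_id")
  write_out(bulk, out_dir, "bulk_signal.tsv")

  target_reads <- filter(classified, .data$read_class == "target")
  counts <- stage("quantify",
                  count_gene_reads(target_reads, layout$genes,
                                   flank = cfg$quantify$flank))
  signals <- gene_signals(counts, sf) |>
    left_join(select(chip_manifest, "sample_id", "assay", "condition",
                     "genotype", "replicate"), by = "sample_id")
  write_out(signals, out_dir, "gene_signals.tsv")

  fc_tables <- list(); rank_summaries <- list()
  for (gt in unique(chip_manifest$genotype)) {
    for (mk in unique(chip_manifest$assay)) {
      sub <- filter(signals, .data$assay == mk, .data$genotype == gt)
      if (length(unique(sub$condition)) < 2) next
      fc <- stage("quantify",
                  gene_log2fc(sub, contrast = cfg$de$contrast,
                              pseudocount = cfg$quantify$pseudocount))
      key <- paste(mk, gt, sep = "_")
      fc_tables[[key]] <- fc
      rt <- rank_table(fc)
      write_out(fc, out_dir, sprintf("chip_log2fc_%s.tsv", key))
      write_out(rt, out_dir, sprintf("chip_rank_%s.tsv", key))
      rank_summaries[[key]] <- mutate(induction_summary(fc),
                                      assay = mk, genotype = gt)
    }
  }
  write_out(bind_rows(rank_summaries), out_dir, "induction_summary.tsv")

  profiles <- NULL
  prof_assays <- intersect(cfg$quantify$profile_assays, chip_manifest$assay)
  if (length(prof_assays) > 0) {
    prof_samples <- filter(chip_manifest, .data$assay %in% prof_assays)
    profiles <- stage("profile", metagene_profile(
      filter(target_reads, .data$sample_id %in% prof_samples$sample_id),
      layout$genes, sf, body_bins = cfg$quantify$body_bins,
      flank = cfg$quantify$profile_flank))
    avg <- average_profiles(profiles,
                            select(prof_samples, "sample_id", "assay",
                                   "condition", "genotype"))
    write_out(avg, out_dir, "metagene_profiles.tsv")
  }

  rna_manifest <- filter(sim$manifest, .data$assay == "RNA")
  de_by_gt <- list()
  for (gt in unique(rna_manifest$genotype)) {
    cols <- c("gene_id", filter(rna_manifest, .data$genotype == gt)$sample_id)
    de_by_gt[[gt]] <- stage("de",
                            de_welch(sim$counts[, cols],
                                     rna_manifest, contrast = cfg$de$contrast))
    write_out(de_by_gt[[gt]], out_dir, sprintf("de_%s.tsv", gt))
    write_out(updown_summary(de_by_gt[[gt]], alpha = cfg$de$alpha),
              out_dir, sprintf("de_summary_%s.tsv", gt))
  }

  rep_peaks <- list()
  for (fac in unique(sim$peaks$factor)) {
    rep_peaks[[fac]] <- stage("targets", reproducible_peaks(
      filter(sim$peaks, .data$factor == fac, .data$replicate == 1),
      filter(sim$peaks, .data$factor == fac, .data$replicate == 2)))
  }
  sites <- stage("targets",
                 call_hif_sites(rep_peaks$HIF1B, rep_peaks$HIF1A,
                                rep_peaks$HIF2A))
  write_out(sites, out_dir, "hif_sites.tsv")
  de_wt <- de_by_gt$WT %||% de_by_gt[[1]]
  targets <- stage("targets",
                   assign_hif_targets(sites, layout$genes, de_wt,
                                      alpha = cfg$targets$alpha))
  write_out(targets, out_dir, "hif_targets.tsv")

  sf_rna <- ercc_size_factors(sim$counts)
  norm_rna <- normalize_counts(sim$counts, sf_rna)
  normox_wt <- filter(rna_manifest, .data$condition == cfg$de$contrast[2],
                      .data$genotype == "WT")
  expression <- tibble(
    gene_id = norm_rna$gene_id,
    expression = rowMeans(as.matrix(norm_rna[, normox_wt$sample_id])))
  controls <- NULL; contrast_tbl <- NULL
  if (nrow(targets) > 0) {
    controls <- stage("targets",
                      sample_matched_controls(targets, layout$genes, sites,
                                              expression,
                                              min_dist = cfg$targets$min_dist,
                                              n_bins = cfg$targets$n_bins,
                                              seed = seed + 7L))
    write_out(controls, out_dir, "matched_controls.tsv")
    contrast_tbl <- purrr::imap_dfr(fc_tables, function(fc, key) {
      mt <- mean(fc$log2fc[fc$gene_id %in% targets$gene_id])
      mc <- mean(fc$log2fc[fc$gene_id %in% controls$gene_id])
      tibble(contrast = key, mean_targets = mt, mean_controls = mc,
             delta = mt - mc)
    })
    write_out(contrast_tbl, out_dir, "target_vs_control.tsv")
  }

  anova_fit <- NULL
  af <- intersect(cfg$report$anova_factors, names(bulk))
  af <- af[vapply(af, function(f) length(unique(bulk[[f]])) > 1, logical(1))]
  if (length(af) >= 1) {
    anova_fit <- stage("report",
                       anova_main_effects(bulk, "bulk_signal", af))
    write_out(tidy(anova_fit), out_dir, "bulk_anova.tsv")
  }

  cors <- list()
  for (key in names(fc_tables)) {
    gt <- sub(".*_", "", key)
    de_gt <- de_by_gt[[gt]]
    if (is.null(de_gt)) next
    ct <- tryCatch(fc_correlation(fc_tables[[key]], de_gt),
                   error = function(e) NULL)
    if (!is.null(ct)) cors[[key]] <- mutate(tidy(ct), contrast = key)
  }
  if (length(cors) > 0) {
    write_out(bind_rows(cors), out_dir, "fc_correlations.tsv")
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(sprintf("chiprx pipeline run, seed %d", seed),
               sprintf("R %s", as.character(getRversion())),
               utils::capture.output(utils::str(cfg, give.attr = FALSE))),
             log_path)

  invisible(list(layout = layout, manifest = sim$manifest, sf = sf,
                 bulk = bulk, signals = signals, fc_tables = fc_tables,
                 profiles = profiles, de = de_by_gt, sites = sites,
                 targets = targets, controls = controls,
                 target_vs_control = contrast_tbl, anova = anova_fit,
                 correlations = if (length(cors)) bind_rows(cors) else NULL,
                 dir = out_dir))
}
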