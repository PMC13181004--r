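#' Parameters of the synthetic spike-in study
#'
#' Builds the parameter list for the synthetic-data generator.  Defaults
#' describe a desk-scale hypoxia experiment: four 25 Mb target
#' chromosomes carrying 2000 genes, one 2 Mb exogenous spike-in
#' chromosome, a constant spike-in chromatin mass added to every sample,
#' a global hypoxic increase in every histone trimethylation mark, and an
#' additional cis increase of the active marks at designated HIF target
#' genes that is present only in the wild-type genotype.
#'
#' The sequencing model is competitive: each sample has a fixed read
#' depth that is split between the human (target) and spike-in chromatin
#' in proportion to their mass.  When the global multiplier raises the
#' human mass in hypoxia, spike reads are crowded out — exactly the
#' mechanism that makes depth normalization erase the global shift while
#' spike normalization preserves it.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_targets number of designated HIF target genes, all placed on
#'   the first two chromosomes so that a distance-eligible background
#'   pool always exists on the other two (default 150).
#' @param depth sequencing depth per ChIP sample (default 2e5 reads).
#' @param spike_mass constant exogenous chromatin mass per sample, in
#'   the same arbitrary units as the per-gene baseline mass (default 250,
#'   about a tenth of the baseline human mass, giving a realistic ~10%
#'   spike read fraction).
#' @param global_mult named per-mark multiplicative increase of human
#'   chromatin mass in hypoxia (both genotypes).
#' @param cis_boost named per-mark additional multiplier at target genes
#'   in hypoxia, wild-type genotype only.
#' @param background_frac fraction of human reads placed uniformly over
#'   the target chromosomes rather than in gene windows (default 0.10).
#' @param ambiguous_frac fraction of reads tagged as mapping to both
#'   genomes (default 5e-6, i.e. 0.0005%).
#' @param baseline_sdlog log-sd of the per-gene baseline mass.
#' @param expr_coupling rank-coupling (0..1) between expression and the
#'   baseline of the active marks (negative sign applied to the
#'   repressive marks).
#' @param nb_dispersion negative-binomial dispersion of RNA counts.
#' @param rna_depth mean RNA library size (default 5e5).
#' @param rna_depth_sdlog log-sd of per-sample RNA depth variation.
#' @param n_rna_rep RNA replicates per condition x genotype (default 4).
#' @param rna_target_fc range of the hypoxic induction fold-change of
#'   target genes in the wild type (default uniform on 2–4).
#' @param n_indep_up,n_indep_down number of HIF-independent genes
#'   regulated up/down in hypoxia in both genotypes (default 100 each).
#' @param indep_fc fold-change range of the HIF-independent set.
#' @param ercc_frac fraction of RNA reads drawn from the ERCC ladder.
#' @param peak_width,peak_jitter,peak_dropout,tss_offset,n_decoys
#'   transcription-factor peak simulation: peak width (bp), per-replicate
#'   coordinate jitter (bp), per-replicate peak dropout probability,
#'   maximum distance of a binding-site centre from its target TSS (bp),
#'   and number of decoy sites of each type.
#' @param n_chrom,chrom_len,spike_len,gene_len_meanlog,gene_len_sdlog,
#'   gene_len_min,gene_len_max,min_gap,n_blacklist,blacklist_width
#'   genome layout controls.
#' @param read_len simulated read length (bp).
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000,
                       n_targets = 150,
                       depth = 2e5,
                       spike_mass = 250,
                       global_mult = c(H3K4me3 = 1.5, H3K36me3 = 1.4,
                                       H3K9me3 = 1.3, H3K27me3 = 1.3,
                                       H3 = 1.05),
                       cis_boost = c(H3K4me3 = 1.4, H3K36me3 = 1.3,
                                     H3K9me3 = 1.0, H3K27me3 = 1.0,
                                     H3 = 1.0),
                       background_frac = 0.10,
                       ambiguous_frac = 5e-6,
                       baseline_sdlog = 0.5,
                       expr_coupling = 0.7,
                       nb_dispersion = 0.05,
                       rna_depth = 5e5,
                       rna_depth_sdlog = 0.2,
                       n_rna_rep = 4,
                       rna_target_fc = c(2, 4),
                       n_indep_up = 100,
                       n_indep_down = 100,
                       indep_fc = c(1.5, 2),
                       ercc_frac = 0.03,
                       peak_width = 400,
                       peak_jitter = 50,
                       peak_dropout = 0.1,
                       tss_offset = 5000,
                       n_decoys = 30,
                       n_chrom = 4,
                       chrom_len = 25e6,
                       spike_len = 2e6,
                       gene_len_meanlog = log(5000),
                       gene_len_sdlog = 0.8,
                       gene_len_min = 1000,
                       gene_len_max = 50000,
                       min_gap = 2000,
                       n_blacklist = 20,
                       blacklist_width = 5000,
                       read_len = 50) {
  p <- as.list(environment())
  stopifnot(all(p$global_mult > 0), all(p$cis_boost > 0),
            p$background_frac >= 0, p$background_frac < 1,
            p$spike_mass > 0, p$n_targets <= p$n_genes)
  structure(p, class = "sim_params")
}

#' Generate the synthetic genome layout
#'
#' Places non-overlapping genes (log-normal lengths, clipped, with a
#' minimum intergenic gap) on the target chromosomes, draws a random
#' blacklist, designates HIF target genes on the first two chromosomes
#' only, and assigns each gene a latent expression level that the ChIP
#' and RNA generators share.
#'
#' @param params [sim_params()] list.
#' @param seed integer seed; the layout is fully deterministic given it.
#' @return a `sim_layout` list with tibbles `genes` (BED6 columns plus
#'   `tss`, `is_target`, `expr_z`, `rel_expr`), `blacklist`, `chroms`,
#'   and the spike chromosome name/length.
#' @export
sim_layout <- function(params = sim_params(), seed = 1) {
  p <- params
  withr::with_seed(seed, {
    chroms <- tibble(chrom = paste0("chr", seq_len(p$n_chrom)),
                     length = as.integer(p$chrom_len))
    # genes per chromosome, as even as possible
    n_per <- diff(round(seq(0, p$n_genes, length.out = p$n_chrom + 1)))
    lens <- pmin(pmax(round(rlnorm(p$n_genes, p$gene_len_meanlog,
                                   p$gene_len_sdlog)),
                      p$gene_len_min), p$gene_len_max)
    edge_margin <- 12000  # keep metagene flanks inside the chromosome
    genes <- vector("list", p$n_chrom)
    k <- 0
    for (ci in seq_len(p$n_chrom)) {
      n_c <- n_per[ci]
      len_c <- lens[k + seq_len(n_c)]
      need <- sum(len_c) + (n_c + 1) * p$min_gap + 2 * edge_margin
      if (need > p$chrom_len) {
        abort(sprintf(
          "layout infeasible: %d genes need %d bp on a %d bp chromosome",
          n_c, need, as.integer(p$chrom_len)))
      }
      free <- p$chrom_len - need
      extra <- rexp(n_c + 1)
      extra <- floor(extra / sum(extra) * free)
      gaps <- p$min_gap + extra
      starts <- edge_margin + cumsum(gaps[seq_len(n_c)]) +
        cumsum(c(0, head(len_c, -1)))
      genes[[ci]] <- tibble(
        chrom = chroms$chrom[ci],
        start = as.integer(starts),
        end = as.integer(starts + len_c),
        gene_id = sprintf("g%04d", k + seq_len(n_c)),
        score = 0,
        strand = sample(c("+", "-"), n_c, replace = TRUE)
      )
      k <- k + n_c
    }
    genes <- bind_rows(genes)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    # latent expression shared by RNA counts and active-mark baselines
    genes$expr_z <- rnorm(p$n_genes)
    genes$rel_expr <- exp(genes$expr_z)
    pool <- genes$gene_id[genes$chrom %in% chroms$chrom[1:2]]
    if (length(pool) < p$n_targets) {
      abort("layout infeasible: fewer genes on chromosomes 1-2 than requested targets")
    }
    genes$is_target <- genes$gene_id %in% sample(pool, p$n_targets)
    blacklist <- tibble(
      chrom = sample(chroms$chrom, p$n_blacklist, replace = TRUE),
      start = as.integer(floor(runif(p$n_blacklist, 0,
                                     p$chrom_len - p$blacklist_width)))
    )
    blacklist$end <- as.integer(blacklist$start + p$blacklist_width)
    blacklist <- arrange(blacklist, .data$chrom, .data$start)
    structure(list(genes = genes, blacklist = blacklist, chroms = chroms,
                   spike_chrom = "spike_2L",
                   spike_len = as.integer(p$spike_len)),
              class = "sim_layout")
  })
}

#' Build a sample manifest for the simulated study
#'
#' @param params [sim_params()] list (supplies the default assay list and
#'   RNA replicate number).
#' @param assays ChIP assays to include (default all marks in
#'   `params$global_mult`).
#' @param conditions,genotypes design levels.
#' @param n_rep ChIP replicates per design cell (default 2).
#' @param cell_line free-text cell line label.
#' @param rna include RNA samples (`params$n_rna_rep` per cell)?
#' @return manifest tibble (`sample_id, assay, condition, genotype,
#'   cell_line, replicate`).
#' @export
sim_manifest <- function(params = sim_params(),
                         assays = names(params$global_mult),
                         conditions = c("normoxia", "hypoxia"),
                         genotypes = c("WT", "KO"),
                         n_rep = 2,
                         cell_line = "PC3",
                         rna = TRUE) {
  chip <- tidyr::expand_grid(assay = assays, genotype = genotypes,
                             condition = conditions,
                             replicate = seq_len(n_rep))
  if (rna) {
    rna_tbl <- tidyr::expand_grid(assay = "RNA", genotype = genotypes,
                                  condition = conditions,
                                  replicate = seq_len(params$n_rna_rep))
    chip <- bind_rows(chip, rna_tbl)
  }
  chip |>
    mutate(cell_line = cell_line,
           sample_id = paste(.data$assay, .data$genotype, .data$condition,
                             paste0("rep", .data$replicate), sep = "_")) |>
    select("sample_id", "assay", "condition", "genotype", "cell_line",
           "replicate")
}

#' Check that a manifest covers a full factorial design
#'
#' Errors with the list of absent design cells when any combination of
#' assay x condition x genotype x replicate is missing.
#'
#' @param manifest manifest tibble.
#' @param assays,conditions,genotypes,replicates expected levels.
#' @return the manifest, invisibly, when complete.
#' @export
check_manifest_design <- function(manifest, assays,
                                  conditions = c("normoxia", "hypoxia"),
                                  genotypes = c("WT", "KO"),
                                  replicates = 1:2) {
  want <- tidyr::expand_grid(assay = assays, condition = conditions,
                             genotype = genotypes, replicate = replicates)
  missing_cells <- anti_join(want, manifest,
                             by = c("assay", "condition", "genotype", "replicate"))
  if (nrow(missing_cells) > 0) {
    cells <- paste(missing_cells$assay, missing_cells$genotype,
                   missing_cells$condition,
                   paste0("rep", missing_cells$replicate),
                   sep = "/", collapse = ", ")
    abort(sprintf("manifest is missing %d design cell(s): %s",
                  nrow(missing_cells), cells))
  }
  invisible(manifest)
}

# per-mark quantification window: promoter-centred for H3K4me3, gene body
# for everything else
mark_windows <- function(genes, assay, chroms, promoter_flank = 1000) {
  if (assay == "H3K4me3") {
    len <- setNames(chroms$length, chroms$chrom)
    tibble(chrom = genes$chrom,
           start = pmax(genes$tss - promoter_flank, 0L),
           end = pmin(genes$tss + promoter_flank, len[genes$chrom]),
           gene_id = genes$gene_id)
  } else {
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           gene_id = genes$gene_id)
  }
}

# per-gene, per-mark baseline chromatin mass; coupled to expression with
# the mark's sign (active marks +, repressive marks -)
mark_baseline <- function(layout, assay, p) {
  s <- if (assay %in% c("H3K4me3", "H3K36me3")) 1
  else if (assay %in% c("H3K9me3", "H3K27me3")) -1
  else 0
  rho <- p$expr_coupling * s
  z <- rho * layout$genes$expr_z +
    sqrt(1 - rho^2) * rnorm(nrow(layout$genes))
  exp(p$baseline_sdlog * z)
}

#' Simulate tagged ChIP read sets
#'
#' Draws, for every ChIP sample in the manifest, an aligned-read set
#' tagged by genome of origin.  Per gene `g`, mark `m` and sample `s`
#' the unnormalized human mass is
#' `w = b[g,m] * G_m^[hypoxia] * H_m^[hypoxia & WT & target]`; the fixed
#' depth is then split between human and spike chromatin by mass, and
#' read counts are independent Poisson draws — spike reads with mean
#' `depth * m0 / (M + m0)`, gene reads with mean
#' `depth * M/(M+m0) * (1-rho) * w/sum(w)`, background reads (total
#' fraction `rho`) uniform over the target chromosomes.  Reads are placed
#' uniformly within the mark window (promoter for H3K4me3, gene body
#' otherwise); a small configurable fraction is tagged `ambiguous`.
#'
#' @param layout [sim_layout()] result.
#' @param params [sim_params()] list.
#' @param manifest manifest tibble; only ChIP rows (assay != "RNA") are
#'   simulated, in manifest order.
#' @param seed integer seed.
#' @return tibble of reads: `sample_id, chrom, start, end, genome_tag`.
#' @export
sim_chip_reads <- function(layout, params = sim_params(),
                           manifest = sim_manifest(params), seed = 1) {
  p <- params
  chip <- filter(manifest, .data$assay != "RNA")
  if (nrow(chip) == 0) abort("manifest contains no ChIP samples")
  unknown <- setdiff(unique(chip$assay), names(p$global_mult))
  if (length(unknown) > 0) {
    abort(sprintf("no global multiplier for assay(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  genes <- layout$genes
  chrom_len <- setNames(layout$chroms$length, layout$chroms$chrom)
  withr::with_seed(seed, {
    baselines <- lapply(setNames(nm = sort(unique(chip$assay))),
                        mark_baseline, layout = layout, p = p)
    out <- vector("list", nrow(chip))
    for (i in seq_len(nrow(chip))) {
      row <- chip[i, ]
      b <- baselines[[row$assay]]
      hyp <- row$condition == "hypoxia"
      mult <- if (hyp) p$global_mult[[row$assay]] else 1
      boost <- if (hyp && row$genotype == "WT") p$cis_boost[[row$assay]] else 1
      w <- b * mult * ifelse(genes$is_target, boost, 1)
      S <- sum(w)
      M <- S / (1 - p$background_frac)
      human_frac <- M / (M + p$spike_mass)
      win <- mark_windows(genes, row$assay, layout$chroms)
      # gene reads
      n_g <- rpois(nrow(genes), p$depth * human_frac *
                     (1 - p$background_frac) * w / S)
      gi <- rep.int(seq_len(nrow(genes)), n_g)
      g_start <- floor(runif(length(gi), win$start[gi],
                             pmax(win$end[gi] - p$read_len, win$start[gi] + 1)))
      g_reads <- tibble(chrom = win$chrom[gi], start = as.integer(g_start))
      # background reads, uniform over target chromosomes by length
      n_bg <- rpois(1, p$depth * human_frac * p$background_frac)
      bg_chrom <- sample(layout$chroms$chrom, n_bg, replace = TRUE,
                         prob = layout$chroms$length)
      bg_start <- floor(runif(n_bg, 0, chrom_len[bg_chrom] - p$read_len))
      bg_reads <- tibble(chrom = bg_chrom, start = as.integer(bg_start))
      # spike reads
      n_sp <- rpois(1, p$depth * p$spike_mass / (M + p$spike_mass))
      sp_reads <- tibble(
        chrom = layout$spike_chrom,
        start = as.integer(floor(runif(n_sp, 0, layout$spike_len - p$read_len))))
      human <- bind_rows(g_reads, bg_reads)
      reads <- bind_rows(
        mutate(human, genome_tag = "target"),
        mutate(sp_reads, genome_tag = "spike"))
      amb <- runif(nrow(reads)) < p$ambiguous_frac
      reads$genome_tag[amb] <- "ambiguous"
      reads$end <- as.integer(reads$start + p$read_len)
      reads$sample_id <- row$sample_id
      out[[i]] <- reads[, c("sample_id", "chrom", "start", "end", "genome_tag")]
    }
    bind_rows(out)
  })
}

# fixed 92-entry ERCC-like concentration ladder (log2-spaced, as in the
# ERCC mixes), identical across samples
ercc_ladder <- function() {
  conc <- 2^seq(-8, 14, length.out = 92)
  tibble(gene_id = sprintf("ERCC-%05d", seq_len(92)), conc = conc / sum(conc))
}

#' Simulate an RNA-seq count matrix with ERCC rows
#'
#' Gene counts are negative binomial with mean proportional to the
#' sample depth and the gene's latent expression; in hypoxia, wild-type
#' target genes are induced by a per-gene fold-change drawn from
#' `rna_target_fc`, a HIF-independent set is regulated up/down in both
#' genotypes, and everything else is unchanged.  The knockout genotype
#' loses the target induction but keeps the HIF-independent response.
#' The 92 ERCC rows are Poisson draws proportional to depth times a
#' fixed concentration ladder shared by all samples.
#'
#' @inheritParams sim_chip_reads
#' @param manifest manifest tibble; only `assay == "RNA"` rows are used.
#' @return counts tibble (`gene_id` + one column per RNA sample), with a
#'   `truth` attribute holding the per-gene true fold-changes
#'   (`gene_id, class, fc_wt, fc_ko`).
#' @export
sim_rna_counts <- function(layout, params = sim_params(),
                           manifest = sim_manifest(params), seed = 1) {
  p <- params
  rna <- filter(manifest, .data$assay == "RNA")
  if (nrow(rna) == 0) abort("manifest contains no RNA samples")
  cells <- count(rna, .data$condition, .data$genotype)
  if (any(cells$n < 2)) {
    abort("RNA manifest needs >= 2 replicates per condition x genotype")
  }
  genes <- layout$genes
  withr::with_seed(seed, {
    n <- nrow(genes)
    truth <- tibble(gene_id = genes$gene_id, class = "stable",
                    fc_wt = 1, fc_ko = 1)
    truth$class[genes$is_target] <- "target"
    truth$fc_wt[genes$is_target] <- runif(sum(genes$is_target),
                                          p$rna_target_fc[1], p$rna_target_fc[2])
    non_target <- which(!genes$is_target)
    n_ind <- p$n_indep_up + p$n_indep_down
    if (n_ind > 0) {
      if (n_ind > length(non_target)) abort("too many HIF-independent genes requested")
      ind <- sample(non_target, n_ind)
      up <- ind[seq_len(p$n_indep_up)]
      down <- setdiff(ind, up)
      fc_up <- runif(length(up), p$indep_fc[1], p$indep_fc[2])
      fc_down <- 1 / runif(length(down), p$indep_fc[1], p$indep_fc[2])
      truth$class[up] <- "indep_up"; truth$class[down] <- "indep_down"
      truth$fc_wt[up] <- fc_up; truth$fc_wt[down] <- fc_down
      truth$fc_ko[up] <- fc_up; truth$fc_ko[down] <- fc_down
    }
    ladder <- ercc_ladder()
    rel <- genes$rel_expr / sum(genes$rel_expr)
    counts <- matrix(0L, nrow = n + nrow(ladder), ncol = nrow(rna))
    depth_fac <- exp(rnorm(nrow(rna), 0, p$rna_depth_sdlog))
    for (j in seq_len(nrow(rna))) {
      depth <- p$rna_depth * depth_fac[j]
      fc <- if (rna$condition[j] == "hypoxia") {
        if (rna$genotype[j] == "WT") truth$fc_wt else truth$fc_ko
      } else rep(1, n)
      mu <- depth * (1 - p$ercc_frac) * rel * fc
      counts[seq_len(n), j] <- rnbinom(n, mu = mu, size = 1 / p$nb_dispersion)
      counts[n + seq_len(nrow(ladder)), j] <-
        rpois(nrow(ladder), depth * p$ercc_frac * ladder$conc)
    }
    colnames(counts) <- rna$sample_id
    out <- bind_cols(tibble(gene_id = c(genes$gene_id, ladder$gene_id)),
                     as_tibble(counts))
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate transcription-factor peak files
#'
#' For every designated target gene a binding-site centre is placed
#' within `tss_offset` bp of the TSS.  A HIF-1β peak is emitted at the
#' centre in each of two replicates subject to a per-replicate dropout
#' probability, together with a HIF-1α peak, a HIF-2α peak, or both.
#' Decoy sites are added: β-only sites, α-only sites, and
#' single-replicate sites, placed uniformly on the first two
#' chromosomes.
#'
#' @inheritParams sim_chip_reads
#' @return tibble of peaks: `factor, replicate, chrom, start, end`,
#'   sorted by (factor, replicate, chrom, start), with a `truth`
#'   attribute recording per-site emission flags for every factor and
#'   replicate.
#' @export
sim_peaks <- function(layout, params = sim_params(), seed = 1) {
  p <- params
  genes <- layout$genes
  tg <- filter(genes, .data$is_target)
  withr::with_seed(seed, {
    centre <- tg$tss + round(runif(nrow(tg), -p$tss_offset, p$tss_offset))
    alpha_choice <- sample(c("a1", "a2", "both"), nrow(tg), replace = TRUE,
                           prob = c(0.4, 0.4, 0.2))
    sites <- tibble(site_id = paste0("site_", tg$gene_id),
                    type = "target", gene_id = tg$gene_id,
                    chrom = tg$chrom, centre = centre,
                    has_beta = TRUE,
                    has_a1 = alpha_choice %in% c("a1", "both"),
                    has_a2 = alpha_choice %in% c("a2", "both"),
                    single_rep = FALSE)
    decoy <- function(type, has_beta, has_a1, has_a2, single_rep) {
      if (p$n_decoys == 0) return(NULL)
      chrom <- sample(layout$chroms$chrom[1:2], p$n_decoys, replace = TRUE)
      tibble(site_id = sprintf("%s_%02d", type, seq_len(p$n_decoys)),
             type = type, gene_id = NA_character_, chrom = chrom,
             centre = round(runif(p$n_decoys, 2e4, p$chrom_len - 2e4)),
             has_beta = has_beta, has_a1 = has_a1, has_a2 = has_a2,
             single_rep = single_rep)
    }
    sites <- bind_rows(
      sites,
      decoy("beta_only", TRUE, FALSE, FALSE, FALSE),
      decoy("alpha_only", FALSE, TRUE, FALSE, FALSE),
      decoy("single_rep", TRUE, TRUE, FALSE, TRUE))
    peaks <- list(); truth_cols <- list()
    for (fac in c("HIF1B", "HIF1A", "HIF2A")) {
      present <- switch(fac, HIF1B = sites$has_beta,
                        HIF1A = sites$has_a1, HIF2A = sites$has_a2)
      for (rep_i in 1:2) {
        emitted <- present & runif(nrow(sites)) >= p$peak_dropout
        emitted <- emitted & !(sites$single_rep & rep_i == 2)
        jit <- round(runif(nrow(sites), -p$peak_jitter, p$peak_jitter))
        st <- pmax(sites$centre + jit - p$peak_width %/% 2, 0)
        peaks[[paste(fac, rep_i)]] <- tibble(
          factor = fac, replicate = rep_i,
          chrom = sites$chrom[emitted],
          start = as.integer(st[emitted]),
          end = as.integer(st[emitted] + p$peak_width))
        truth_cols[[paste0(tolower(fac), "_r", rep_i)]] <- emitted
      }
    }
    out <- bind_rows(peaks) |>
      arrange(.data$factor, .data$replicate, .data$chrom, .data$start)
    attr(out, "truth") <- bind_cols(
      sites[, c("site_id", "type", "gene_id", "chrom", "centre")],
      as_tibble(truth_cols))
    out
  })
}

#' Write a complete simulated study to disk
#'
#' Runs [sim_layout()], [sim_chip_reads()], [sim_rna_counts()] and
#' [sim_peaks()] with sub-seeds derived from `seed` and writes every
#' output in the plain-text formats the analysis functions read: gene
#' models (BED6), blacklist (BED3), one tagged-read BED per ChIP sample,
#' a counts TSV, peak BEDs per factor and replicate, and the manifest
#' (with a `path` column for ChIP samples).
#'
#' @inheritParams sim_chip_reads
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the in-memory objects
#'   (`layout, manifest, reads, counts, peaks`) plus `dir`.
#' @export
simulate_study <- function(dir, params = sim_params(),
                           manifest = NULL, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layout <- sim_layout(params, seed = seed)
  if (is.null(manifest)) manifest <- sim_manifest(params)
  reads <- sim_chip_reads(layout, params, manifest, seed = seed + 1L)
  counts <- sim_rna_counts(layout, params, manifest, seed = seed + 2L)
  peaks <- sim_peaks(layout, params, seed = seed + 3L)
  gcols <- c("chrom", "start", "end", "gene_id", "score", "strand")
  write_bed(layout$genes[, gcols], file.path(dir, "genes.bed"))
  write_bed(layout$blacklist, file.path(dir, "blacklist.bed"))
  chip <- filter(manifest, .data$assay != "RNA")
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    if (manifest$assay[i] == "RNA") { paths[i] <- ""; next }
    f <- paste0(sid, ".reads.bed")
    write_bed(filter(reads, .data$sample_id == sid)[, -1], file.path(dir, f))
    paths[i] <- f
  }
  write_counts(counts, file.path(dir, "rna_counts.tsv"))
  for (fac in unique(peaks$factor)) {
    for (rep_i in unique(peaks$replicate)) {
      pk <- filter(peaks, .data$factor == fac, .data$replicate == rep_i)
      write_bed(pk[, c("chrom", "start", "end")],
                file.path(dir, sprintf("peaks_%s_rep%d.bed", fac, rep_i)))
    }
  }
  m_out <- mutate(manifest, path = paths)
  write_manifest(m_out, file.path(dir, "manifest.tsv"))
  invisible(list(layout = layout, manifest = m_out, reads = reads,
                 counts = counts, peaks = peaks, dir = dir))
}
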