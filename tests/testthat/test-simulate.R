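test_that("layout generation is deterministic and respects its invariants", {
  p <- small_params()
  lay1 <- sim_layout(p, seed = 7)
  lay2 <- sim_layout(p, seed = 7)
  expect_identical(lay1, lay2)

  g <- lay1$genes
  expect_equal(nrow(g), p$n_genes)
  expect_equal(sum(g$is_target), p$n_targets)
  expect_true(all(g$chrom[g$is_target] %in% c("chr1", "chr2")))
  expect_true(all(g$end > g$start))
  # non-overlapping with the minimum intergenic gap, per chromosome
  for (ch in unique(g$chrom)) {
    gc <- dplyr::arrange(dplyr::filter(g, chrom == ch), start)
    if (nrow(gc) > 1) {
      expect_true(all(gc$start[-1] - gc$end[-nrow(gc)] >= p$min_gap))
    }
  }
  expect_true(all(g$tss == ifelse(g$strand == "+", g$start, g$end)))
})

test_that("infeasible gene requests raise a configuration error", {
  p <- sim_params(n_genes = 4000, n_chrom = 1, chrom_len = 1e6)
  expect_error(sim_layout(p, seed = 1), "infeasible")
})

test_that("simulated reads stay on their chromosomes and carry valid tags", {
  p <- small_params()
  lay <- sim_layout(p, seed = 1)
  man <- sim_manifest(p, assays = "H3K36me3", genotypes = "WT", rna = FALSE)
  reads <- sim_chip_reads(lay, p, man, seed = 2)
  expect_setequal(unique(reads$sample_id), man$sample_id)
  expect_true(all(reads$genome_tag %in% c("target", "spike", "ambiguous")))
  sp <- reads$genome_tag == "spike"
  expect_true(all(reads$chrom[sp] == lay$spike_chrom))
  expect_true(all(reads$chrom[!sp] %in% c(lay$chroms$chrom, lay$spike_chrom)))
  lens <- c(stats::setNames(lay$chroms$length, lay$chroms$chrom),
            stats::setNames(lay$spike_len, lay$spike_chrom))
  expect_true(all(reads$start >= 0 & reads$end <= lens[reads$chrom]))
  expect_error(sim_chip_reads(lay, p, man[0, ], seed = 1), "no ChIP samples")
})

test_that("with all multipliers at 1, spike-normalized signal is condition-balanced", {
  p <- small_params(global_mult = c(H3K4me3 = 1), cis_boost = c(H3K4me3 = 1))
  lay <- sim_layout(p, seed = 3)
  man <- sim_manifest(p, assays = "H3K4me3", genotypes = "WT", rna = FALSE)
  reads <- sim_chip_reads(lay, p, man, seed = 4)
  cl <- classify_reads(reads, lay$blacklist)
  sf <- scaling_factors(cl)
  sig <- gene_signals(count_gene_reads(dplyr::filter(cl, read_class == "target"),
                                       lay$genes), sf) |>
    dplyr::left_join(man, by = "sample_id")
  fc <- gene_log2fc(sig)
  expect_lt(abs(median(fc$log2fc)), 0.1)
})

test_that("RNA counts honour the designed truth structure", {
  p <- small_params()
  lay <- sim_layout(p, seed = 5)
  man <- sim_manifest(p)
  counts <- sim_rna_counts(lay, p, man, seed = 6)
  truth <- attr(counts, "truth")
  expect_equal(sum(truth$class == "indep_up"), p$n_indep_up)
  expect_equal(sum(truth$class == "indep_down"), p$n_indep_down)
  # KO loses the target induction but keeps the independent response
  expect_true(all(truth$fc_ko[truth$class == "target"] == 1))
  expect_true(all(truth$fc_wt[truth$class == "target"] > 1))
  expect_identical(truth$fc_ko[truth$class %in% c("indep_up", "indep_down")],
                   truth$fc_wt[truth$class %in% c("indep_up", "indep_down")])
  expect_equal(sum(truth$fc_wt > 1 & startsWith(truth$class, "indep")),
               sum(truth$fc_wt < 1 & startsWith(truth$class, "indep")))
  # 92 ERCC rows, identical id set, nonneg integer counts
  expect_equal(sum(startsWith(counts$gene_id, "ERCC-")), 92)
  m <- as.matrix(counts[, -1])
  expect_true(all(m >= 0) && all(m == round(m)))
  expect_error(
    sim_rna_counts(lay, p, dplyr::filter(man, assay == "RNA", replicate == 1),
                   seed = 1),
    ">= 2 replicates")
})

test_that("ERCC totals scale with sequencing depth", {
  p1 <- small_params()
  p2 <- small_params(rna_depth = 2e5, rna_depth_sdlog = 0)
  p1$rna_depth_sdlog <- 0
  lay <- sim_layout(p1, seed = 8)
  man <- sim_manifest(p1, genotypes = "WT")
  c1 <- sim_rna_counts(lay, p1, man, seed = 9)
  c2 <- sim_rna_counts(lay, p2, man, seed = 9)
  e1 <- colSums(c1[startsWith(c1$gene_id, "ERCC-"), -1])
  e2 <- colSums(c2[startsWith(c2$gene_id, "ERCC-"), -1])
  expect_equal(unname(mean(e2 / e1)), 2, tolerance = 0.05)
})

test_that("peak simulation truth table matches emitted peak counts", {
  p <- small_params()
  lay <- sim_layout(p, seed = 10)
  pk <- sim_peaks(lay, p, seed = 11)
  truth <- attr(pk, "truth")
  for (fac in c("HIF1B", "HIF1A", "HIF2A")) {
    for (r in 1:2) {
      n_emitted <- sum(pk$factor == fac & pk$replicate == r)
      expect_equal(n_emitted, sum(truth[[paste0(tolower(fac), "_r", r)]]))
    }
  }
  expect_true(all(pk$end - pk$start == p$peak_width))
})

test_that("manifest design check reports missing cells", {
  p <- small_params()
  man <- sim_manifest(p, assays = c("H3K4me3", "H3"), rna = FALSE)
  expect_silent(check_manifest_design(man, assays = c("H3K4me3", "H3")))
  incomplete <- dplyr::filter(man, !(assay == "H3" & condition == "hypoxia"))
  expect_error(check_manifest_design(incomplete, assays = c("H3K4me3", "H3")),
               "H3.*hypoxia")
})

test_that("a written study can be read back and re-analysed from disk", {
  p <- small_params()
  man <- sim_manifest(p, assays = "H3K4me3", genotypes = "WT")
  dir <- withr::local_tempdir()
  sim <- simulate_study(dir, p, manifest = man, seed = 12)
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  genes <- read_bed6(file.path(dir, "genes.bed"))
  bl <- read_bed(file.path(dir, "blacklist.bed"))
  expect_equal(nrow(genes), p$n_genes)
  chip <- dplyr::filter(m, assay != "RNA")
  reads <- dplyr::bind_rows(lapply(seq_len(nrow(chip)), function(i) {
    dplyr::mutate(read_bed(file.path(dir, chip$path[i]), "tagged"),
                  sample_id = chip$sample_id[i])
  }))
  expect_equal(nrow(reads), nrow(sim$reads))
  counts <- read_counts(file.path(dir, "rna_counts.tsv"))
  expect_equal(dim(counts), dim(sim$counts))
})
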