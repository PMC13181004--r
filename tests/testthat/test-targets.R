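pk <- function(...) {
  x <- rbind(...)
  tibble::tibble(chrom = "chr1", start = as.integer(x[, 1]),
                 end = as.integer(x[, 2]))
}

test_that("reproducible peaks keep only cross-replicate overlaps, union-merged", {
  got <- reproducible_peaks(pk(c(100, 200)), pk(c(199, 300)))
  expect_equal(got, tibble::tibble(chrom = "chr1", start = 100L, end = 300L))
  expect_equal(nrow(reproducible_peaks(pk(c(100, 200)), pk(c(200, 300)))), 0)
  expect_equal(nrow(reproducible_peaks(pk(c(100, 200)), pk(c(100, 200))[0, ])), 0)
})

test_that("reproducible peaks are symmetric and match the brute-force oracle", {
  for (seed in 1:15) {
    withr::local_seed(400 + seed)
    r1 <- random_intervals(100, max_pos = 5e3, max_len = 300)
    r2 <- random_intervals(100, max_pos = 5e3, max_len = 300)
    got <- reproducible_peaks(r1, r2)
    want <- bf_reproducible(as.data.frame(r1), as.data.frame(r2))
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE,
                 info = paste("seed", seed))
    expect_equal(got, reproducible_peaks(r2, r1))
  }
})

test_that("HIF sites require a beta peak overlapping at least one alpha peak", {
  beta <- pk(c(100, 500), c(5000, 5400))
  a1 <- pk(c(400, 700))
  a2 <- pk(c(450, 650))
  one <- call_hif_sites(beta, a1, NULL)
  expect_equal(nrow(one), 1)  # the alpha-free beta peak yields no site
  expect_equal(one[, c("start", "end")],
               tibble::tibble(start = 100L, end = 700L))
  expect_equal(one$factors, "HIF1B,HIF1A")

  both <- call_hif_sites(pk(c(100, 500)), a1, a2)
  expect_equal(nrow(both), 1)  # one site even with both alphas
  expect_equal(both$factors, "HIF1B,HIF1A,HIF2A")
  expect_equal(both$start, 100L)
  expect_equal(both$end, 700L)

  expect_equal(nrow(call_hif_sites(pk(c(100, 500)), pk(c(600, 700)), NULL)), 0)
  # every site interval contains >= 1 bp covered by both beta and alpha
  expect_true(one$start <= 400 && one$end >= 500)
})

test_that("target assignment filters on inducibility and deduplicates genes", {
  genes <- tibble::tibble(chrom = "chr1", gene_id = c("up", "down", "far"),
                          tss = c(1000L, 6000L, 50000L))
  sites <- tibble::tibble(site_id = c("s1", "s2", "s3"), chrom = "chr1",
                          start = 0L, end = 0L,
                          midpoint = c(900L, 5900L, 1200L))
  de <- tibble::tibble(gene_id = c("up", "down", "far"),
                       log2fc = c(2, -1, 3), padj = c(1e-6, 1e-6, 1e-6))
  got <- assign_hif_targets(sites, genes, de)
  # "down" is nearest to s2 but not inducible; "up" nearest to s1 and s3,
  # kept once with the closer site
  expect_equal(got$gene_id, "up")
  expect_equal(got$site_id, "s1")
  expect_equal(got$tss_distance, 100)

  de2 <- dplyr::mutate(de, padj = c(0.2, 1e-6, 1e-6))
  expect_equal(nrow(assign_hif_targets(sites, genes, de2)), 0)
})

test_that("matched control sampling honours distance, matching and determinism", {
  p <- small_params()
  lay <- sim_layout(p, seed = 21)
  man <- sim_manifest(p)
  counts <- sim_rna_counts(lay, p, man, seed = 22)
  peaks <- sim_peaks(lay, p, seed = 23)
  reps <- function(f) reproducible_peaks(
    dplyr::filter(peaks, factor == f, replicate == 1),
    dplyr::filter(peaks, factor == f, replicate == 2))
  sites <- call_hif_sites(reps("HIF1B"), reps("HIF1A"), reps("HIF2A"))
  rna_man <- dplyr::filter(man, assay == "RNA")
  de <- de_welch(counts[, c("gene_id",
                            dplyr::filter(rna_man, genotype == "WT")$sample_id)],
                 rna_man)
  targets <- assign_hif_targets(sites, lay$genes, de)
  expect_gt(nrow(targets), 5)
  expression <- tibble::tibble(gene_id = de$gene_id, expression = de$base_mean)

  ctrl <- sample_matched_controls(targets, lay$genes, sites, expression,
                                  min_dist = 2e5, seed = 99)
  ctrl2 <- sample_matched_controls(targets, lay$genes, sites, expression,
                                   min_dist = 2e5, seed = 99)
  expect_identical(ctrl, ctrl2)
  expect_equal(nrow(ctrl), nrow(targets))
  expect_length(intersect(ctrl$gene_id, targets$gene_id), 0)
  expect_equal(anyDuplicated(ctrl$gene_id), 0)

  # brute-force distance check: every control TSS > min_dist from every site
  for (g in ctrl$gene_id) {
    row <- lay$genes[lay$genes$gene_id == g, ]
    same <- sites[sites$chrom == row$chrom, ]
    if (nrow(same) > 0) {
      expect_true(all(abs(same$midpoint - row$tss) > 2e5))
    }
  }

  all_chrom_sites <- tibble::tibble(site_id = paste0("x", 1:4),
                                    chrom = paste0("chr", 1:4),
                                    start = 0L, end = 100L, midpoint = 50L)
  err <- tryCatch(sample_matched_controls(targets, lay$genes,
                                          all_chrom_sites,
                                          expression, min_dist = 5e8),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "pool")
})

test_that("decile bookkeeping assigns each target a same-bin control", {
  targets <- tibble::tibble(gene_id = c("t1", "t2", "t3"))
  genes <- tibble::tibble(chrom = "chr2",
                          gene_id = c("t1", "t2", "t3",
                                      sprintf("c%02d", 1:30)),
                          tss = as.integer(seq(1e6, 33e6, length.out = 33)))
  sites <- tibble::tibble(site_id = "s1", chrom = "chr1", start = 0L,
                          end = 100L, midpoint = 50L)
  expression <- tibble::tibble(
    gene_id = genes$gene_id,
    expression = c(10, 100, 1000, rep(c(10, 100, 1000), each = 10)))
  ctrl <- sample_matched_controls(targets, genes, sites, expression,
                                  n_bins = 10, seed = 3)
  expect_equal(nrow(ctrl), 3)
  expect_false(any(ctrl$fallback))
  got_expr <- ctrl$expression[order(ctrl$matched_target)]
  expect_equal(got_expr, c(10, 100, 1000))
})
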