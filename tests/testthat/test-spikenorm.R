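test_that("read classification partitions exactly as the manual oracle", {
  # 10 reads: 6 target (1 overlapping blacklist), 3 spike, 1 ambiguous
  reads <- dplyr::bind_rows(
    make_reads("chr1", c(100, 500, 900, 1300, 1700, 5000)),
    make_reads("spike_2L", c(10, 60, 110), tag = "spike"),
    make_reads("chr1", 9000, tag = "ambiguous"))
  blacklist <- tibble::tibble(chrom = "chr1", start = 5040L, end = 6000L)
  cl <- classify_reads(reads, blacklist)
  sf <- scaling_factors(cl)
  expect_equal(sf$n_target, 5)
  expect_equal(sf$n_spike, 3)
  expect_equal(sf$n_ambiguous, 1)
  expect_equal(sf$n_blacklisted, 1)
  expect_equal(sf$n_total, 10)

  # without a blacklist every target read is retained
  sf0 <- scaling_factors(classify_reads(reads, NULL))
  expect_equal(sf0$n_target, 6)
  expect_equal(sf0$n_blacklisted, 0)

  # a 1 bp blacklist overlap suffices to exclude
  bl1 <- tibble::tibble(chrom = "chr1", start = 5049L, end = 5500L)
  expect_equal(scaling_factors(classify_reads(reads, bl1))$n_blacklisted, 1)
  bl_abut <- tibble::tibble(chrom = "chr1", start = 5050L, end = 5500L)
  expect_equal(scaling_factors(classify_reads(reads, bl_abut))$n_blacklisted, 0)
})

test_that("samples without spike reads cannot be normalized", {
  reads <- make_reads("chr1", c(1, 100))
  expect_error(scaling_factors(classify_reads(reads)), "zero spike")
  empty <- classify_reads(make_reads("chr1", integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("spike scaling identities hold", {
  f <- tibble::tibble(sample_id = "s", n_target = 1e6, n_spike = 1e4,
                      normalizer = 1e4 / 1e4)
  expect_equal(spike_scale(50, f), 50)              # K = n_spike identity
  expect_equal(f$n_target / f$n_spike, 100)         # conventional factor
  expect_equal(bulk_signal(f)$bulk_signal, 100)
})

test_that("doubling every read leaves normalized quantities bit-identical", {
  p <- small_params()
  lay <- sim_layout(p, seed = 1)
  man <- sim_manifest(p, assays = "H3K9me3", genotypes = "WT", rna = FALSE)
  reads <- sim_chip_reads(lay, p, man, seed = 2)
  doubled <- dplyr::bind_rows(reads, reads)

  run <- function(r) {
    cl <- classify_reads(r, lay$blacklist)
    sf <- scaling_factors(cl)
    tgt <- dplyr::filter(cl, read_class == "target")
    sig <- gene_signals(count_gene_reads(tgt, lay$genes), sf) |>
      dplyr::left_join(man, by = "sample_id")
    list(sig = sig$norm_signal,
         bulk = bulk_signal(sf)$bulk_signal,
         fc = gene_log2fc(sig)$log2fc,
         prof = metagene_profile(tgt, lay$genes, sf, flank = 2000,
                                 bin_width = 100, body_bins = 20)$value)
  }
  a <- run(reads); b <- run(doubled)
  expect_identical(a$sig, b$sig)
  expect_identical(a$bulk, b$bulk)
  expect_identical(a$fc, b$fc)
  expect_identical(a$prof, b$prof)
})

test_that("gene-body counting obeys the boundary arithmetic and the brute-force oracle", {
  genes <- tibble::tibble(chrom = "chr1", start = 3000L, end = 8000L,
                          gene_id = "g1")
  # extended region [1000, 10000): a read ending at 950 is not counted
  r1 <- make_reads("chr1", 900)
  expect_equal(count_gene_reads(r1, genes)$raw_count, 0L)
  r2 <- make_reads("chr1", 951)  # [951, 1001) overlaps by 1 bp
  expect_equal(count_gene_reads(r2, genes)$raw_count, 1L)
  expect_equal(count_gene_reads(r1[0, ], genes)$raw_count, 0L)

  for (seed in 1:8) {
    withr::local_seed(200 + seed)
    genes_r <- random_intervals(50, max_pos = 2e4, max_len = 3000)
    genes_r$gene_id <- sprintf("g%02d", seq_len(50))
    reads_r <- random_intervals(500, max_pos = 3e4, max_len = 100)
    got <- count_gene_reads(reads_r, genes_r, flank = 2000)
    expect_equal(got$raw_count,
                 bf_count_reads(reads_r, genes_r, flank = 2000),
                 info = paste("seed", seed))
  }
})

test_that("log2 fold-changes follow the pseudocount formula and drop undetected genes", {
  sig <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3", "g4"), each = 4),
    sample_id = rep(c("n1", "n2", "h1", "h2"), 4),
    condition = rep(c("normoxia", "normoxia", "hypoxia", "hypoxia"), 4),
    norm_signal = c(10, 10, 10, 10,    # identical
                    10, 10, 20, 20,    # exactly 2x
                    0, 0, 3, 3,        # zero reference
                    0, 0, 0, 0))       # undetected
  fc <- gene_log2fc(sig)
  expect_equal(nrow(fc), 3)  # g4 excluded as not detected
  expect_equal(fc$log2fc[fc$gene_id == "g1"], 0)
  expect_equal(fc$log2fc[fc$gene_id == "g2"],
               log2(20.5 / 10.5))
  expect_equal(fc$log2fc[fc$gene_id == "g3"], log2(3.5 / 0.5))
  expect_equal(fc$rank, seq_len(3))
  expect_error(gene_log2fc(dplyr::filter(sig, condition == "hypoxia")),
               "absent")
  # per-replicate averaging variant
  sigr <- dplyr::mutate(sig, replicate = rep(c(1, 2, 1, 2), 4))
  fcr <- gene_log2fc(sigr, per_replicate = TRUE)
  expect_equal(fcr$log2fc[fcr$gene_id == "g2"],
               mean(log2(20.5 / 10.5)))
})

test_that("metagene profiles are flat under uniform coverage and flip minus-strand genes", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(20000L, 60000L),
                          end = c(30000L, 70000L),
                          gene_id = c("gp", "gm"), strand = c("+", "-"))
  sf <- tibble::tibble(sample_id = "s1", normalizer = 2)
  # uniform coverage: tile reads end to end across the full region
  tile <- seq(5000, 95000, by = 50)
  reads <- make_reads("chr1", tile)
  prof <- metagene_profile(reads, genes, sf, body_bins = 20, flank = 2000,
                           bin_width = 100)
  expect_equal(nrow(prof), 20 + 2 * 20)
  expect_true(all(abs(prof$value - 1 * 2) < 1e-9))

  # reads confined to bodies leave flanks empty
  body_reads <- make_reads("chr1", seq(20000, 29900, by = 50))
  prof2 <- metagene_profile(body_reads, genes, sf, body_bins = 20,
                            flank = 2000, bin_width = 100)
  expect_true(all(prof2$value[prof2$segment != "body"] == 0))

  # 5' reads of a minus-strand gene appear at the profile start
  five_prime <- make_reads("chr1", seq(69000, 69900, by = 50))
  prof3 <- metagene_profile(five_prime,
                            genes[genes$gene_id == "gm", ], sf,
                            body_bins = 20, flank = 2000, bin_width = 100)
  body_vals <- prof3$value[prof3$segment == "body"]
  expect_gt(sum(body_vals[1:7]), 0)
  expect_equal(sum(body_vals[8:20]), 0)

  # genes shorter than the bin count are excluded
  short <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20010L,
                          gene_id = "tiny", strand = "+")
  expect_error(metagene_profile(reads, short, sf, body_bins = 20,
                                flank = 2000), "eligible")
})

test_that("H3-relative ratios cancel when the mark equals H3", {
  base <- tibble::tibble(gene_id = c("g1", "g2"),
                         condition = "normoxia", genotype = "WT",
                         replicate = 1, norm_signal = c(10, 40))
  out <- h3_relative(base, base)
  expect_equal(out$ratio, c(1, 1))
  h3_missing <- dplyr::mutate(base, replicate = 2)
  expect_error(h3_relative(base, h3_missing), "matching H3")
})
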