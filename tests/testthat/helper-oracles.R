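# Hand-written brute-force oracles, kept deliberately independent of the
# package's interval-tree / vectorized code paths.

# all-pairs overlap predicate under half-open coordinates
bf_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

bf_overlap_query <- function(query, subjects) {
  keep <- logical(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    for (j in seq_len(nrow(query))) {
      if (subjects$chrom[i] == query$chrom[j] &&
          subjects$start[i] < query$end[j] &&
          query$start[j] < subjects$end[i]) keep[i] <- TRUE
    }
  }
  subjects[keep, , drop = FALSE]
}

# exhaustive nearest-TSS scan with the smaller-tss / gene_id tie rules
bf_nearest_tss <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NA_character_)
  d <- abs(g$tss - pos)
  best <- g[d == min(d), , drop = FALSE]
  best <- best[order(best$tss, best$gene_id), , drop = FALSE]
  best$gene_id[1]
}

# all-pairs gene-body read counting with flank extension
bf_count_reads <- function(reads, genes, flank = 2000) {
  out <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    s <- max(genes$start[g] - flank, 0)
    e <- genes$end[g] + flank
    for (r in seq_len(nrow(reads))) {
      if (reads$chrom[r] == genes$chrom[g] &&
          reads$start[r] < e && s < reads$end[r]) {
        out[g] <- out[g] + 1L
      }
    }
  }
  out
}

# intersect-then-merge oracle for reproducible peaks: keep peaks with a
# cross-replicate partner, then merge transitively by repeated sweeps
bf_reproducible <- function(rep1, rep2) {
  keep1 <- logical(nrow(rep1)); keep2 <- logical(nrow(rep2))
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      if (rep1$chrom[i] == rep2$chrom[j] &&
          rep1$start[i] < rep2$end[j] && rep2$start[j] < rep1$end[i]) {
        keep1[i] <- TRUE; keep2[j] <- TRUE
      }
    }
  }
  kept <- rbind(rep1[keep1, c("chrom", "start", "end")],
                rep2[keep2, c("chrom", "start", "end")])
  bf_merge(kept)
}

bf_merge <- function(x) {
  if (nrow(x) == 0) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- x[1, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1]) {
    last <- nrow(out)
    if (x$chrom[i] == out$chrom[last] && x$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], x$end[i])
    } else {
      out <- rbind(out, x[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# Benjamini-Hochberg step-up, straight from the definition
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# textbook Pearson r and its t-transform p-value
bf_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_len, n, replace = TRUE))
}

# minimal gene annotation on one or two chromosomes
tiny_genes <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 6000L, 12000L, 2000L),
    end = c(3000L, 9000L, 15000L, 5000L),
    gene_id = c("gA", "gB", "gC", "gD"),
    score = 0,
    strand = c("+", "-", "+", "+"),
    tss = c(1000L, 9000L, 12000L, 2000L))
}

# tiny deterministic tagged read set builder
make_reads <- function(chrom, start, tag = "target", width = 50L,
                       sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start = as.integer(start),
                 end = as.integer(start + width), genome_tag = tag)
}

small_params <- function(...) {
  base <- list(n_genes = 200, n_targets = 20, depth = 2e4, n_chrom = 4,
               chrom_len = 4e6, n_blacklist = 5, rna_depth = 1e5,
               n_indep_up = 20, n_indep_down = 20)
  do.call(sim_params, utils::modifyList(base, list(...)))
}
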