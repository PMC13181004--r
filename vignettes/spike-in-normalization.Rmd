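---
title: "Spike-in normalized analysis of global chromatin changes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in normalized analysis of global chromatin changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models, parameter
choices and numerical conventions behind chiprx. It is written for a
reader who wants to know *why* the code does what it does, not only
which function to call.

## 1. The measurement model

A ChIP-seq library sequenced to depth $D$ reports, for region $i$ of
sample $s$, a count $c_{is}$ that is proportional to the *share* of the
library occupied by that region — not to the absolute amount of
immunoprecipitated chromatin. Any normalization that equalizes library
size across samples therefore removes a multiplicative change common to
all regions. When the biological effect of interest *is* such a common
multiplicative change (a genome-wide increase of a histone mark under
hypoxia), depth normalization removes the signal.

Adding a constant mass $m_0$ of exogenous chromatin to every sample
changes this. If sample $s$ contains target chromatin mass $M_s$, the
expected spike read count is
$E[n_{\text{spike},s}] = D_s\, m_0 / (M_s + m_0)$ and the expected
target count in region $i$ is proportional to
$D_s\, w_{is} / (M_s + m_0)$ where $w_{is}$ is the region's chromatin
mass. The ratio

$$\frac{c_{is}}{n_{\text{spike},s}} \propto \frac{w_{is}}{m_0}$$

is independent of both the sequencing depth and the total target mass:
it is an absolute measurement in units of the (constant) spike mass.
chiprx implements this as `norm_signal = c * K / n_spike` with a fixed
reference constant `K = 1e4` (reads per ten thousand spike reads); the
constant only sets the display scale. The conventional per-sample
factor `n_target / n_spike` is also reported because it is the number a
bench scientist compares between samples: applying depth normalization
(`/ n_target`) and then this factor is algebraically identical to the
`K / n_spike` normalizer. Both normalizers are exposed
(`scaling_factors(..., normalizer = "spike"` or `"depth")`) precisely
so the contrast between them — the central methodological point — is
testable.

Exact depth invariance is a design requirement, not an approximation:
duplicating every read multiplies numerator and denominator by two,
which is exact in floating point, so all normalized outputs are
bit-identical. The unit tests assert this literally.

RNA-seq uses the same idea with the 92 ERCC synthetic RNAs. Size
factors default to the scale-free form
$s_j = E_j / \text{geomean}(E)$ over per-sample ERCC totals $E_j$. A
fixed-reference variant (`center = "reference"`, $s_j = E_j/K$) is also
provided; it mirrors the ChIP normalizer and has the property that
rescaling one sample's entire column cancels *exactly*, whereas under
geometric-mean centring all samples pick up a common $k^{1/n}$ factor
that interacts (negligibly, but not bitwise) with the pseudocount. A
median-of-ratios variant restricted to ERCC rows is available behind
`method = "median-ratio"` for users who prefer robustness to a few
saturated spike species.

## 2. The synthetic study

The generator produces a complete desk-scale study with the statistical
structure the analysis assumes; it is first-class, tested code. Its
defaults are the package's declared study conditions:

* **Genome** — four 25 Mb target chromosomes, one 2 Mb spike
  chromosome. 2000 genes with log-normal lengths (median 5 kb, clipped
  to 1–50 kb), non-overlapping with ≥2 kb intergenic gaps and a 12 kb
  margin at chromosome ends so metagene flanks never leave the
  chromosome. 150 designated HIF target genes, all on chromosomes 1–2,
  which guarantees that chromosomes 3–4 always hold a background pool
  more than 0.5 Mb from every binding site.
* **Chromatin masses** — per gene $g$ and mark $m$ a log-normal
  baseline $b_{gm}$ (sdlog 0.5) whose log is coupled with coefficient
  0.7 to a latent expression variable — positively for the active marks
  H3K4me3/H3K36me3, negatively for the repressive marks
  H3K9me3/H3K27me3, uncoupled for total H3. The hypoxic sample of mark
  $m$ multiplies every gene by a global factor $G_m$ (defaults 1.5,
  1.4, 1.3, 1.3, and 1.05 for total H3 — a slight rise, as total
  histone occupancy shows) and, in the wild type only, target genes by
  an additional cis factor $H_m$ (1.4 for H3K4me3, 1.3 for H3K36me3, 1
  otherwise). H3K4me3 mass sits in a TSS ± 1 kb window; all other marks
  occupy the gene body.
* **Sequencing** — a fixed depth of $2\times10^5$ reads per sample is
  split between target and spike chromatin in proportion to mass
  (spike mass 250 ≈ 10% of baseline target mass), with independent
  Poisson counts per gene, a 10% uniform background fraction, and
  0.0005% of reads tagged as mapping to both genomes. This
  competition-for-reads model is deliberately the mechanism by which
  depth normalization hides global shifts: in hypoxia the target mass
  rises, spike reads are crowded out, and only the spike ratio records
  the change.
* **RNA** — negative-binomial counts (dispersion 0.05) over a mean
  library of $5\times10^5$ reads with ±20% log-normal depth variation
  and 4 replicates per condition × genotype. In hypoxia, wild-type
  targets are induced by a per-gene fold-change drawn uniformly from
  2–4; a HIF-independent set of 100 up- and 100 down-regulated genes
  (fold 1.5–2) is present in both genotypes; the knockout loses the
  target induction and keeps the independent response. ERCC rows are
  Poisson draws from a fixed log2-spaced 92-species ladder, identical
  across samples, at 3% of the library.
* **Peaks** — for each target gene a site centre within ±5 kb of the
  TSS; a HIF-1β peak (width 400 bp, ±50 bp replicate jitter, 10%
  per-replicate dropout) plus HIF-1α, HIF-2α or both at the same
  centre; decoy β-only, α-only and single-replicate sites (30 each)
  placed anywhere on chromosomes 1–2.

These effect sizes are configurable stand-ins chosen to be comfortably
detectable at desk scale; real experiments report directions, not
generative parameters. What the generator does **not** emulate —
GC/mappability bias, fragment-length structure, cell-line differences,
peak-caller artefacts — bounds what passing tests show about real data:
they validate the *arithmetic and logic* of the pipeline, not its
robustness to sequencing artefacts.

## 3. Analysis conventions and numerical choices

* **Coordinates** are 0-based half-open (BED) everywhere; the TSS of a
  minus-strand gene is its half-open end; overlap means ≥1 bp; abutting
  intervals do not overlap. Strand is ignored for counting (histone
  ChIP is unstranded).
* **Counting** is read-overlap counting (once per region), not
  per-base depth summation; the two differ by a gene-length factor that
  cancels in fold-changes. Gene bodies are extended ±2 kb, clipped at
  zero; overlapping extended regions may both count one read.
* **Fold-changes** use pseudocount ε = 0.5 in
  $\log_2\!\big((\bar x_{\text{hyp}}+\varepsilon)/(\bar x_{\text{nor}}+\varepsilon)\big)$,
  with replicate averaging on the linear scale; a per-replicate
  log-ratio variant is available (`per_replicate = TRUE`). Genes with
  zero signal in every sample of both conditions are reported as not
  detected and excluded, giving the "induced/detected" denominators.
  Rank ties break by `gene_id` for stable output.
* **Metagene profiles** use 100 fixed 100 bp bins per 10 kb flank and
  100 length-scaled body bins; genes shorter than the bin count or
  closer than one flank to the chromosome start are excluded;
  minus-strand genes are flipped so bin 1 is always 5′.
* **Nearest TSS** is measured from the site midpoint
  (`floor((start+end)/2)`); ties break to the smaller TSS coordinate,
  then lexicographic `gene_id` — an arbitrary but deterministic rule.
* **Differential expression** is a declared simplification: Welch's
  t-test on $\log_2(\text{normalized}+\varepsilon)$ with BH correction,
  not a negative-binomial shrinkage model. The claims exercised here
  (sign balance, knockout ablation, spike scaling) depend on the
  normalization, not the test. Two conventions close degenerate cases:
  equal constant groups give p = 1, unequal constant groups give p = 0.
  The cost of the simplification is power: with n = 4 replicates the
  test has ~6 degrees of freedom, so weakly induced genes (fold ≈ 2 at
  dispersion 0.05) are recovered at roughly 50–60% after BH, and the
  package's own recovery of designated targets plateaus near 70–75%
  rather than the ≳95% a dispersion-pooling model would reach. This is
  an inherent property of the per-gene t-test, documented rather than
  patched.
* **Target calling** is assignment-then-filter: each site takes its
  nearest TSS, and the gene is kept if inducible (log2fc > 0,
  BH-adjusted p < 0.05, thresholds configurable). The alternative order
  (filter genes first, then assign) changes which site–gene pairs
  survive; assignment-then-filter matches the reading that a site
  "has" a nearest gene regardless of that gene's regulation.
* **Matched controls** are drawn without replacement from genes whose
  TSS is >0.5 Mb from every site midpoint, matched on deciles of
  target expression with a nearest-expression fallback when a bin
  empties; fully deterministic given a seed.
* **ANOVA** is a multi-factor main-effects linear model (no
  interactions) with Type II sums of squares — on the balanced designs
  used here Type II coincides with the sequential decomposition, and a
  single two-level factor reproduces the pooled t-test exactly
  (F = t²). The response is analysed untransformed by default with a
  `log_response` switch. Confounded factors and designs without
  residual degrees of freedom are rejected rather than silently
  refitted.
* **Multiple testing**: BH is applied only to the DE p-values; ANOVA
  and correlation p-values are reported unadjusted, as is conventional
  in figure legends.

## 4. Problem sizes

The test suite and the acceptance script run entirely on simulated
data at the default scale: 2000 genes (5000 for the null-calibration
check), $2\times10^5$ reads per ChIP sample, two ChIP and four RNA
replicates per design cell, and 500 Monte-Carlo repeats for the ANOVA
null-uniformity check. These sizes were chosen so that every
distributional property asserted by the tests (medians within ±0.1
log2 units, type-I rates within ±0.01) has comfortably small
Monte-Carlo error while a complete run stays in the minutes range on a
single CPU.

## 5. Known limitations

* The DE stand-in's power ceiling, discussed above; effect-size
  estimates are unshrunken.
* Peak files are consumed, never produced: no peak calling.
* The simulation works at the aligned-read level; alignment,
  mappability and duplicate-removal effects are upstream of scope.
* `samtools bedcov`-style per-base summation is not implemented; the
  read-count convention is used throughout (their ratio differs by a
  constant per gene and cancels in contrasts).
* The H3-relative ratio (`h3_relative()`) is computed and reported;
  interpreting a mark that rises in parallel with total H3 is left to
  the analyst.
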