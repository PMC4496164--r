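---
title: "Methods: interval enrichment and the chromosomal-instability program"
author: "chipcin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval enrichment and the chromosomal-instability program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcin)
```

# Scope

`chipcin` packages the computational backbone of a recurring study design in
regulatory genomics: a chromatin-associated regulator is profiled by
ChIP-Seq, its peaks are annotated against gene models and tested for
co-occurrence with transcription-factor binding sites (TFBS) under a
genome-shuffling null, and its downstream program is read out three ways —
a chromosomal-instability (CIN) expression signature, karyotype aneuploidy
counts, and tumor-free survival of transgenic animals. The package
implements each analysis as a tidy, seedable function over plain tables,
plus generators that fabricate every input with planted, recoverable
structure so the whole pipeline can be exercised and calibrated without any
external data.

# Coordinates and data model

All intervals are 0-based half-open (`[start, end)`, the BED dialect);
1-based formats (GTF) are converted at the reader boundary. A genome is a
table of chromosome lengths and is the universe for validation, binning and
shuffling. Genes are strand-aware transcription units: the TSS of a
plus-strand gene is `start`, of a minus-strand gene `end - 1`, and all
windows (upstream, promoter, downstream) flip with strand.

# ChIP-Seq geometry

**Tag extension.** Sequenced tags mark the 5' ends of immunoprecipitated
fragments, so each tag is extended at its 3' end to the library's average
fragment length (default 110 bp) before density profiling, clipped at
chromosome bounds. A plus tag at `p` becomes `[p, p + L)`; a minus tag
`[p - L + 1, p + 1)`, making a plus tag at `p` and a minus tag at
`p + L - 1` describe the same fragment.

**Density binning.** Chromosomes are divided into fixed 32-bp bins and each
bin counts the fragments overlapping it by at least one base. Any-overlap
counting (rather than midpoint assignment) was chosen because it matches
fragment-pileup semantics; the two differ only at fragment edges. Tracks
export as bedGraph with zero bins omitted.

**Annotation.** Each peak is labelled relative to every gene: `upstream`
(within 10 kb before the TSS), `intragenic`, `downstream` (within 10 kb
past the transcription stop), else `distal`. Labels form a *set* — a peak
between two genes can be upstream of one and inside the other — so
aggregate counts are reported as Venn cells that sum exactly to the number
of peaks. Whether a multi-gene neighborhood should instead count a peak
once per gene is genuinely open; the per-peak label-set convention keeps
the partition property. TSS profiles use the peak midpoint
(floor-rounded), mapped to strand-flipped TSS-relative coordinates for
every gene on the same chromosome and binned over a window such as
(−10 kb, +50 kb).

# The shuffling permutation framework

The enrichment null model re-places every peak independently, uniformly
over all valid genome-wide start positions: a chromosome is chosen with
probability proportional to `length − peak_length + 1`, then a valid start
uniformly within it. Shuffled peaks may overlap one another — the null
treats placements as independent, which is what makes it exactly enumerable
on small instances (the property the calibration tests exploit). The
observed statistic is either the number of distinct TF sites overlapped
(TFBS enrichment) or the number of query intervals hitting the fixed
reference set (interval-set overlap). The reported p-value follows the
strict-exceedance rule — the fraction of shuffles whose count strictly
exceeds the observed count — implemented literally because it is the
classical definition for this test; since it can return exactly 0, the
conservative estimate `(b + 1)/(n + 1)` is reported alongside and is what
the calibration tests threshold on. The default `n_perm = 1e4` is a
desk-scale surrogate for the billions of permutations feasible on a
cluster; it bounds the smallest resolvable p at `1e-4`
(`~(n_perm + 1)^-1` for the conservative form) and is user-configurable.
The inner loop (placement + overlap counting over sorted site arrays) is
implemented in C++ for throughput; the exposed `shuffle_intervals()`
implements the identical placement model in R and is what the uniformity
tests interrogate. All randomness flows through R's RNG, so a seed makes
any result reproducible.

**Gene-based overlap.** Two peak sets are also compared through the genes
whose promoter window — the 2 kb immediately upstream of the TSS,
`[TSS − 2 kb, TSS)` — contains at least one peak. Whether "promoter
region" should additionally extend downstream of the TSS is ambiguous;
only the upstream window is used, and the window size is a parameter. The
shared-gene count is tested with the upper-tail hypergeometric
`P(X ≥ k)` for `N` universe genes, `K` and `n` hits, and `k` shared —
the universe is an explicit argument because "all annotated genes" versus
"genes with any peak" changes `N` materially.

**Differential TF counts.** When the same TF panel is counted under two
conditions, the absolute count differences are pooled and fitted with a
Gaussian kernel density (Silverman bandwidth by default). Because deltas
are discrete and bounded, the density is truncated to `[0, max delta]` and
renormalized, and each TF's p-value is `1 − CDF(delta)`; the closed form
through normal CDFs makes the truncated CDF exact (quadrature agreement to
1e-6 is a test). Consequences worth knowing: the largest delta always gets
p = 0, delta = 0 the largest p, and p is monotone non-increasing in delta.
If every delta is identical the kernel bandwidth degenerates and all
p-values are set to 1, flagged. The lower truncation at 0 is our choice
(deltas are non-negative); the upper truncation at the observed maximum is
the method's defining feature.

# Expression and the CIN signature

Differential expression between two conditions uses a per-gene one-way
ANOVA (equal-variance F test, equivalent to the pooled t test for two
groups) on linear-scale values, with fold change as the group-mean ratio.
Zero within-group variance makes F undefined; by convention p is 0 when
the means differ and 1 otherwise, flagged per gene. Filtering applies
`p ≤ p_max` and a *symmetric* fold rule `max(fold, 1/fold) ≥ fold_min`,
so 2-fold down-regulation passes a 1.5-fold cutoff. Two standard threshold
pairs appear throughout: a permissive (0.01, 1.25) profile filter and a
stricter (0.05, 1.5) condition-comparison filter.

**Enrichment curve.** The CIN signature is an external score table (gene →
score), never hard-coded. Genes are ranked by descending score (ties broken
by gene id for determinism) and the curve at cutoff `k` is observed query
hits in the top `k` divided by the expected `k·|Q|/N`, which normalizes
every curve to exactly 1 at `k = N`. A cumulative running-sum variant
(observed-minus-expected hit fraction) is returned alongside; the
observed/expected ratio is the default because its flat reference level of
1 matches the "enrichment versus rank" reading of such figures.

**Curve comparison.** Enrichment between two gene sets is summarized by the
Wilcoxon matched-pairs signed-rank statistic W over curve values paired at
a down-sampled rank grid (default ~100 points; against a flat reference
level 1 when only one curve is given). The *reference distribution* is the
method's one genuinely open design point. Values along a cumulative curve
are strongly autocorrelated, and every pairing of smooth functionals of the
same query we considered (cumulative values at any grid density,
disjoint-bin increments, order-statistic matching) violates the
independent-pairs assumption behind the tabulated signed-rank null — in
opposite directions, and badly. The package therefore keeps the paired
statistic but calibrates it by resampling: random gene sets of the same
sizes are drawn from the signature universe, the curves rebuilt, and the
two-sided p is the conservative exceedance fraction of `|W|`. This is the
default and is what the package's null-uniformity and power checks
validate. The classical analytic computation (exact for ≤ 25 informative
untied pairs, normal approximation with continuity correction above) is
retained as `method = "signed-rank"` for the case of genuinely independent
pairs. The resampling floor `(n_perm + 1)^-1` bounds attainable
significance; 499 resamples resolve p ≈ 0.002.

# Karyotype and survival statistics

A metaphase is euploid when its chromosome count lies in
`[2N − tol, 2N + tol] ∪ [4N − tol, 4N + tol]` (boundaries inclusive,
near-tetraploid cells counted as euploid per the shaded-band convention),
aneuploid otherwise. `2N = 40` (mouse) and `tol = 2` are defaults, not
constants. Per-sample summaries warn below 10 metaphases — the
conventional minimum — without failing. Sample-by-outcome contingency
tables go through the Pearson chi-square test of association (no
continuity correction); 2×2 comparisons use Fisher's exact test with the
probability-mass two-sided rule (the tail-doubling rule is available
behind a flag). Tumor-free survival uses the Kaplan–Meier product-limit
estimator and the log-rank test with the hypergeometric variance
correction for ties; animals alive without tumor at study end are censored
on that day (day 760 in the emulated design), and a comparison with no
events in either arm is reported as `NA` rather than a number. ChIP-qPCR
fold enrichment is computed as `2^−(Ct_input − Ct_IgG)`; the superficially
plausible literal reading "2 − ΔCt" is dimensionally nonsensical for a
ratio of exponentially amplified quantities and is rejected.

# The synthetic study

The generators are pure functions of `(config, seed)` — reruns are
byte-identical — and default to a configuration sized for seconds-scale
tests while preserving the data shapes the analyses care about:

* genome: 2 chromosomes × 1 Mb; 200 non-overlapping strand-randomized
  genes (2–10 kb, ≥ 500 bp spacing), packed with uniformly random gaps;
* peaks: 300 intervals of 200–800 bp, 60% centered within ±1 kb of a
  random TSS (reproducing the TSS-concentrated profile), the rest uniform;
* TFBS: 20 TFs × 200 12-bp sites placed uniformly; "enriched" TFs receive
  additional sites planted uniformly inside peaks so the expected in-peak
  count is multiplied by the configured factor (factor 1 plants nothing —
  the null construction used for calibration);
* expression: per-gene log2 baselines uniform on (5, 12), N(0, σ = 0.2)
  log2 noise, 3 + 3 samples, with the planted fold multiplying the
  signature genes in the "rescue" group; the signature itself is a
  standard-normal score per gene, its planted set the top 30 scorers;
* karyotypes: 12 metaphases/sample (mirroring the ≥ 10 convention), two
  samples at aneuploidy rates 0.07 and 0.42 emulating control and rescue
  conditions; euploid counts jitter within the 2N/4N bands (tetraploid
  with probability 0.2), aneuploid counts sit a shifted-geometric offset
  outside them (re-drawn if the offset lands in the other band — only the
  classification boundary matters, the real-data distribution of
  aberrant counts being unknowable);
* survival: 30 animals/arm, exponential hazards (5e-4 and 1.5e-3 per day,
  i.e. ~30% vs ~70% events by day 760), censored at day 760.

What the generator deliberately does **not** emulate: sequence content and
mappability structure (no FASTA), correlated fragment pileup, microarray
probe effects and normalization artifacts, gene-length biases, clustered
TFBS co-occurrence, or informative censoring. Passing recovery tests
therefore demonstrate that the *statistics* behave as designed under their
own assumptions, not that those assumptions hold on any particular real
dataset.

# Calibration experiments and problem sizes

The test suite fixes its designs and seeds up front: exact-null equivalence
on a 64-bp toy genome whose 57 placements are enumerable; type-I error of
the TFBS test over 500 null datasets (60 × 400-bp peaks, 1200 sites,
2000 permutations — sized so the overlap-count lattice is fine enough that
the discrete p-values track the nominal level); power across planted
factors {1, 2, 5} at 30 seeds each; signature recovery across 100 seeds of
the planted-fold-2 design; Wilcoxon null uniformity over 500 query pairs;
log-rank null uniformity over 1000 equal-hazard replicates. These sizes
are the package's chosen trade-off between resolution and a test suite
that runs in a couple of minutes; every calibration quantity is recomputed
at run time by `scripts/acceptance.R`.

# Known limitations

* The literal strict-exceedance p can be exactly 0; always prefer the
  conservative estimate for decisions.
* The shuffling null ignores mappability, GC and chromatin accessibility
  structure; on real genomes it is anti-conservative wherever peaks and
  TFBS are both drawn to accessible regions for reasons unrelated to the
  factor under study.
* The permutation and resampling p-values have resolution floors set by
  `n_perm`; headline p-values of the order 1e-11 reported in large-scale
  studies require correspondingly many permutations.
* `anova_de` assumes homoscedastic groups on the linear scale; with 3 + 3
  designs it has little power against variance heterogeneity and no
  moderation across genes (an empirical-Bayes layer such as limma's is out
  of scope here).
* The enrichment curve is unstable at very small `k` (expected counts
  ≪ 1); comparisons should use the calibrated test, not visual reading of
  the early curve.
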