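# chipcin

Tidy R toolkit for a recurring study design in regulatory genomics: a
chromatin-associated regulator (here modelled on cyclin D1) is profiled by
ChIP-Seq, its genomic occupancy is characterized and tested for enrichment
of transcription-factor binding sites, and its downstream
chromosomal-instability (CIN) program is read out through an expression
signature, karyotype aneuploidy counts, and tumor-free survival of
transgenic animals. `chipcin` is written for computational biologists who
want those analyses as composable, seedable functions over plain tables
(every function takes a data frame and returns a tibble), together with
synthetic-data generators that plant recoverable structure in every input
so the whole pipeline is testable end to end without external data.

## What it computes

* **ChIP-Seq geometry** — in-silico tag extension to fragment length
  (default 110 bp), 32-bp fragment-density binning with bedGraph export,
  strand-aware peak annotation (upstream −10 kb→TSS / intragenic /
  downstream stop→+10 kb / distal, as a Venn-cell partition), and
  TSS-relative midpoint profiles.
* **Shuffling permutation tests** — the null re-places each interval
  uniformly over all valid genome-wide starts (chromosome weighted by
  `L_chrom − L_iv + 1`). For a TF with binding-site set *S* and peak set
  *P*, the statistic is the number of distinct sites of *S* overlapped by
  *P*; the p-value is the fraction of shuffles whose count exceeds the
  observed count, `p = #{count* > count_obs}/n_perm`, reported with the
  conservative `(b+1)/(n+1)` companion. The same machinery tests overlap
  of two peak sets, and a hypergeometric upper tail
  `P(X ≥ k | N, K, n)` tests shared promoter-bound genes
  (promoter = `[TSS − 2 kb, TSS)`).
* **Differential TF counts** — per-TF count differences Δ pooled into a
  Gaussian KDE truncated to `[0, max Δ]` and renormalized;
  `p(Δ) = 1 − CDF(Δ)`.
* **CIN signature** — per-gene one-way ANOVA with symmetric fold filtering
  (e.g. p ≤ 0.01, |fold| ≥ 1.25), an observed/expected enrichment curve
  over genes ranked by descending CIN score
  (`curve(k) = hits(k)/(k·|Q|/N)`, so `curve(N) = 1`), and a
  matched-pairs Wilcoxon comparison of curves whose signed-rank statistic
  is calibrated by query resampling.
* **Karyotype statistics** — euploid iff the chromosome count lies in
  `2N ± 2` or `4N ± 2` (2N = 40 by default), per-sample aneuploidy
  fractions, Pearson chi-square association, and two-sided Fisher exact
  tests.
* **Survival** — Kaplan–Meier product-limit curves and the log-rank test
  with right-censoring at study end (day 760 in the emulated design), plus
  ChIP-qPCR fold enrichment `2^−(Ct_input − Ct_IgG)`.
* **Synthetic study** — seeded generators for genome, genes, TSS-biased
  peaks, TFBS tracks with planted in-peak enrichment, two-group expression
  with planted signature up-regulation, metaphase counts with a planted
  aneuploidy rate, and two-arm censored survival.

See `vignettes/methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(chipcin)

study <- simulate_study(sim_config(seed = 1,
                                   tfbs = list(enrichment_factor = 5),
                                   expression = list(planted_fold = 2)))

# Where do peaks sit relative to genes?
annotation_summary(annotate_intervals(study$peaks, study$genes))$labels
#>   label          n
#> 1 upstream     248
#> 2 intragenic   197
#> 3 downstream   191
#> 4 distal         0

# TF01 carries planted 5x in-peak enrichment; TF10 is a null TF
tfbs_enrichment_table(study$peaks,
                      dplyr::filter(study$tfbs, name %in% c("TF01", "TF10")),
                      study$genome, n_perm = 2000, seed = 1)
#>     tf observed null_mean n_perm n_exceeding p_value p_conservative
#> 1 TF01       68      19.0   2000           0   0.000         0.0005
#> 2 TF10        9      14.7   2000        1851   0.925         0.9255

# Expression: recover the planted CIN-signature up-regulation
de <- anova_de(study$expr, study$groups, "control", "rescue")
up <- filter_de(de[de$fold > 1, ], p_max = 0.05, fold_min = 1.5)
sum(study$signature_genes %in% up)          # 29 of 30 planted genes
curve <- cin_enrichment_curve(intersect(up, study$signature$gene_id),
                              study$signature)
compare_curves_wilcoxon(curve, n_perm = 499, seed = 1)
#>   statistic p_value n_pairs                       method
#> 1      4950   0.022      99 query-resampling calibration

# Karyotypes and survival
aneuploidy_summary(study$karyotypes)
#>   sample_id n_metaphases n_euploid n_aneuploid fraction_aneuploid
#> 1   control           12        11           1             0.0833
#> 2    rescue           12         8           4             0.3333
logrank_test(study$survival)
#>   statistic df  p_value  n n_events
#> 1      17.5  1 2.86e-05 60       26
```

Reading the output: the planted-enrichment TF overlaps 68 sites against a
shuffling-null mean of 19 (conservative p = 5e-4, the resolution floor at
2000 permutations), while the null TF sits below its null mean. The DE
filter recovers 29/30 planted signature genes, whose enrichment curve
differs from the flat reference with resampling-calibrated p = 0.022; the
"rescue" karyotype sample shows a higher aneuploid fraction than control,
and the two survival arms (hazards 5e-4 vs 1.5e-3/day) separate at
log-rank p = 2.9e-5.

A thin command-line wrapper over the same entry points ships at
`inst/cli/chipcin.R` (subcommands `simulate`, `annotate`, `enrich-tf`,
`overlap`, `cin`, `karyo`, `survival`); each run writes TSV/JSON results
plus a manifest recording parameters, seeds and input checksums.

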