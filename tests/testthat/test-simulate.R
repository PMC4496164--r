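test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(sim_config(seed = 5))
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_config(seed = 6))
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("simulated genes are non-overlapping with minimum spacing", {
  cfg <- sim_config(seed = 2)
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(cfg, genome)
  expect_equal(nrow(genes), cfg$genes$n_genes)
  by_chrom <- split(genes, genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] - g$end[-nrow(g)] >=
                        cfg$genes$min_spacing))
    }
  }
  expect_equal(nrow(simulate_genes(sim_config(genes = list(n_genes = 0)),
                                   genome)), 0)
  expect_error(
    simulate_genes(sim_config(genes = list(n_genes = 500,
                                           length_range = c(9000, 10000))),
                   genome),
    "packing"
  )
})

test_that("peak placement concentrates at TSSs when asked to", {
  cfg <- sim_config(seed = 3, peaks = list(tss_fraction = 1))
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(cfg, genome)
  pk <- simulate_peaks_tfbs(cfg, genome, genes)
  prof <- tss_profile(pk$peaks, genes, window = c(-10000, 10000),
                      bin_size = 1000)
  central <- sum(prof$count[abs(prof$bin_mid) <= 2000]) / sum(prof$count)
  expect_gt(central, 0.3)   # far above the uniform share (~0.2 of window)
})

test_that("enrichment factor 1 places sites independently of peaks", {
  cfg <- sim_config(seed = 4, tfbs = list(enrichment_factor = 1))
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(cfg, genome)
  pk <- simulate_peaks_tfbs(cfg, genome, genes)
  expect_true(all(!pk$meta$enriched))
  sites <- pk$tfbs
  hits <- count_tfbs_hits(pk$peaks, sites)
  p_cov <- sum(pk$peaks$end - pk$peaks$start) / sum(genome$length)
  expected <- nrow(sites) * p_cov
  expect_lt(abs(hits - expected), 4 * sqrt(expected))
})

test_that("planted TFBS enrichment is detected by the permutation test", {
  ps <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s,
                      tfbs = list(enrichment_factor = 5, n_enriched = 1,
                                  n_tfs = 1, sites_per_tf = 500))
    genome <- simulate_genome(cfg)
    genes <- simulate_genes(cfg, genome)
    pk <- simulate_peaks_tfbs(cfg, genome, genes)
    tfbs_permutation_test(pk$peaks, pk$tfbs, genome, n_perm = 500,
                          seed = s)$p_conservative
  }, numeric(1))
  expect_true(all(ps < 0.05))
})

test_that("planted expression effects are recovered by the DE filter", {
  cfg <- sim_config(seed = 8, expression = list(planted_fold = 2))
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(cfg, genome)
  sg <- simulate_signature(cfg, genes)
  ex <- simulate_expression(cfg, genes, sg$signature_genes)
  de <- anova_de(ex$expr, ex$groups, "control", "rescue")
  up <- filter_de(de[de$fold > 1, ], p_max = 0.05, fold_min = 1.5)
  expect_gte(mean(sg$signature_genes %in% up), 0.8)
  # null: no planted fold, strict thresholds yield few false positives
  cfg0 <- sim_config(seed = 9, expression = list(planted_fold = 1))
  ex0 <- simulate_expression(cfg0, genes, sg$signature_genes)
  de0 <- anova_de(ex0$expr, ex0$groups, "control", "rescue")
  expect_lte(length(filter_de(de0, p_max = 0.01, fold_min = 1.25)), 6)
})

test_that("signature genes are the top-scoring genes", {
  cfg <- sim_config(seed = 12)
  genes <- simulate_genes(cfg, simulate_genome(cfg))
  sg <- simulate_signature(cfg, genes)
  ranked <- sg$signature$gene_id[order(-sg$signature$score,
                                       sg$signature$gene_id)]
  expect_setequal(sg$signature_genes, ranked[seq_len(cfg$expression$n_sig)])
})

test_that("karyotype generator plants a recoverable aneuploidy rate", {
  cfg0 <- sim_config(seed = 13, karyotype = list(rates = c(s = 0)))
  k0 <- simulate_karyotypes(cfg0)
  expect_equal(aneuploidy_summary(k0, diploid_n = 40)$fraction_aneuploid, 0)
  cfg <- sim_config(seed = 14,
                    karyotype = list(rates = c(s = 0.42), n_metaphases = 100))
  k <- simulate_karyotypes(cfg)
  frac <- aneuploidy_summary(k)$fraction_aneuploid
  ci <- stats::binom.test(round(0.42 * 100), 100)$conf.int
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # classification agrees with the generator's own truth labels
  expect_equal(classify_metaphase(k$chromosome_count) == "aneuploid",
               k$aneuploid_truth)
})

test_that("survival generator censors at the study end day", {
  cfg <- sim_config(seed = 15)
  s <- simulate_survival(cfg)
  expect_true(all(s$time <= cfg$survival$censor_day))
  expect_true(all(s$event[s$time == cfg$survival$censor_day] == "censored"))
  expect_true(all(s$event[s$time < cfg$survival$censor_day] == "tumor"))
  expect_equal(nrow(s), 2 * cfg$survival$n_per_arm)
})
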