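test_that("shuffling preserves the interval length multiset", {
  g <- toy_genome()
  ivs <- random_intervals(200, g, seed = 2)
  sh <- shuffle_intervals(ivs, g, seed = 4)
  expect_equal(sort(sh$end - sh$start), sort(ivs$end - ivs$start))
  expect_true(all(sh$start >= 0))
  len <- setNames(g$length, g$chrom)
  expect_true(all(sh$end <= len[sh$chrom]))
})

test_that("a full-chromosome interval has a unique placement", {
  g <- define_genome("chr1", 100)
  sh <- shuffle_intervals(tibble::tibble(chrom = "chr1", start = 0,
                                         end = 100), g, seed = 1)
  expect_equal(c(sh$start, sh$end), c(0, 100))
  expect_error(
    shuffle_intervals(tibble::tibble(chrom = "chr1", start = 0, end = 100),
                      define_genome("chr1", 99)),
    "length"
  )
})

test_that("shuffled starts are uniform over all valid placements", {
  g <- define_genome("chr1", 64)
  ivs <- tibble::tibble(chrom = "chr1", start = 0, end = 8)[rep(1, 5e4), ]
  sh <- shuffle_intervals(ivs, g, seed = 6)
  counts <- tabulate(sh$start + 1, nbins = 57)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("shuffling is reproducible under a fixed seed", {
  g <- toy_genome()
  ivs <- random_intervals(50, g, seed = 9)
  expect_identical(shuffle_intervals(ivs, g, seed = 10),
                   shuffle_intervals(ivs, g, seed = 10))
})

test_that("site hit counting matches the brute-force pairwise oracle", {
  g <- toy_genome()
  expect_equal(count_tfbs_hits(
    tibble::tibble(chrom = "chrA", start = 0, end = 100),
    tibble::tibble(chrom = "chrA", start = 200, end = 210)
  ), 0)
  inside <- tibble::tibble(chrom = "chrA", start = c(10, 40), end = c(20, 60))
  expect_equal(count_tfbs_hits(
    tibble::tibble(chrom = "chrA", start = 0, end = 100), inside
  ), 2)
  withr::with_seed(21, {
    ivs <- random_intervals(5, g, max_len = 800)
    sites <- random_intervals(50, g, max_len = 30)
  })
  expect_equal(count_tfbs_hits(ivs, sites),
               sum(brute_overlaps_any(sites, ivs)))
})

test_that("degenerate permutation cases follow the strict-exceedance rule", {
  g <- define_genome("chr1", 1000)
  ivs <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  # empty site set: observed 0, no shuffle can exceed 0
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  r <- tfbs_permutation_test(ivs, empty, g, n_perm = 100, seed = 1)
  expect_equal(c(r$observed, r$p_value), c(0, 0))
  # observed at the attainable maximum
  sites <- tibble::tibble(chrom = "chr1", start = c(10, 100), end = c(20, 120))
  r2 <- tfbs_permutation_test(tibble::tibble(chrom = "chr1", start = 0,
                                             end = 1000), sites, g,
                              n_perm = 200, seed = 2)
  expect_equal(c(r2$observed, r2$p_value), c(2, 0))
  expect_equal(r2$p_conservative, 1 / 201)
})

test_that("permutation engine matches exhaustive enumeration on a toy", {
  g <- define_genome("c1", 64)
  iv <- tibble::tibble(chrom = "c1", start = 28, end = 36)
  sites <- tibble::tibble(chrom = "c1", start = c(5, 30, 38),
                          end = c(13, 36, 44))
  cnt <- enum_placement_counts(8, 64, sites)
  obs <- count_tfbs_hits(iv, sites)
  p_exact <- mean(cnt > obs)
  r <- tfbs_permutation_test(iv, sites, g, n_perm = 5000, seed = 7)
  expect_equal(r$observed, obs)
  se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(r$p_value - p_exact), 3 * se)
  # the null-count distribution itself matches the enumeration
  expect_equal(sort(unique(r$null_counts)), sort(unique(cnt)))
  expect_lt(abs(mean(r$null_counts) - mean(cnt)),
            3 * stats::sd(cnt) / sqrt(5000))
})

test_that("interval-overlap permutation counts query intervals hitting B", {
  g <- define_genome("c1", 64)
  a <- tibble::tibble(chrom = "c1", start = c(0, 20), end = c(8, 28))
  b <- tibble::tibble(chrom = "c1", start = c(2, 40), end = c(10, 44))
  r <- interval_overlap_permutation(a, b, g, n_perm = 4000, seed = 12)
  expect_equal(r$observed, 1)
  # exact null: both A intervals placed independently; count = X1 + X2
  cnt <- enum_placement_counts(8, 64, b)
  p_hit <- mean(cnt >= 1)
  exact_null <- c((1 - p_hit)^2, 2 * p_hit * (1 - p_hit), p_hit^2)
  p_exact <- exact_null[3]  # P(count > 1)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(r$p_value - p_exact), 3 * se)
})

test_that("observed overlap equals |A| when A = B and 0 across chromosomes", {
  g <- toy_genome()
  a <- random_intervals(20, g, seed = 30)
  r <- interval_overlap_permutation(a, a, g, n_perm = 10, seed = 1)
  expect_equal(r$observed, nrow(a))
  a2 <- tibble::tibble(chrom = "chrA", start = 0, end = 50)
  b2 <- tibble::tibble(chrom = "chrB", start = 0, end = 50)
  expect_equal(interval_overlap_permutation(a2, b2, g, n_perm = 10,
                                            seed = 1)$observed, 0)
})

test_that("permutation results are reproducible and self-consistent", {
  g <- toy_genome()
  ivs <- random_intervals(30, g, seed = 14)
  sites <- random_intervals(100, g, max_len = 20, seed = 15)
  r1 <- tfbs_permutation_test(ivs, sites, g, n_perm = 500, seed = 99)
  r2 <- tfbs_permutation_test(ivs, sites, g, n_perm = 500, seed = 99)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_equal(r1$p_value, r1$n_exceeding / r1$n_perm)
  expect_equal(r1$p_conservative, (r1$n_exceeding + 1) / (r1$n_perm + 1))
  td <- tidy(r1)
  expect_equal(td$observed, r1$observed)
})

test_that("multi-TF enrichment table reports one calibrated row per TF", {
  g <- toy_genome()
  ivs <- random_intervals(20, g, seed = 41)
  tfbs <- dplyr::bind_rows(
    dplyr::mutate(random_intervals(40, g, max_len = 15, seed = 42),
                  name = "TFa"),
    dplyr::mutate(random_intervals(40, g, max_len = 15, seed = 43),
                  name = "TFb")
  )
  tab <- tfbs_enrichment_table(ivs, tfbs, g, n_perm = 200, seed = 5)
  expect_equal(tab$tf, c("TFa", "TFb"))
  expect_true(all(tab$p_conservative > 0 & tab$p_conservative <= 1))
})
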