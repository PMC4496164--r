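test_that("metaphase classification follows the 2N/4N +/- 2 rule", {
  expect_equal(classify_metaphase(40), "euploid")
  expect_equal(classify_metaphase(43), "aneuploid")
  expect_equal(classify_metaphase(78), "euploid")   # 4N - 2, inclusive
  expect_equal(classify_metaphase(c(38, 42, 37, 82, 83)),
               c("euploid", "euploid", "aneuploid", "euploid", "aneuploid"))
  expect_error(classify_metaphase(0), ">= 1")
})

test_that("classification matches the set-membership oracle over 1..200", {
  bands <- c(38:42, 78:82)
  oracle <- ifelse(1:200 %in% bands, "euploid", "aneuploid")
  expect_equal(classify_metaphase(1:200, diploid_n = 40, tolerance = 2),
               oracle)
})

test_that("aneuploidy summary applies the rule element-wise", {
  counts <- c(40, 43, 55, 41, 80, 66, 39, 90, 70, 37)
  k <- tibble::tibble(sample_id = "s1", chromosome_count = counts)
  s <- aneuploidy_summary(k)
  expect_equal(s$n_aneuploid, 6)
  expect_equal(s$fraction_aneuploid, 0.6)
  # identical samples give identical rows
  k2 <- dplyr::bind_rows(k, dplyr::mutate(k, sample_id = "s2"))
  s2 <- aneuploidy_summary(k2)
  expect_equal(s2$fraction_aneuploid, c(0.6, 0.6))
  m <- karyotype_contingency(s2)
  expect_equal(rowSums(m), setNames(c(10, 10), c("s1", "s2")))
})

test_that("small metaphase counts warn and empty tables error", {
  k <- tibble::tibble(sample_id = "s1", chromosome_count = c(40, 41))
  expect_warning(aneuploidy_summary(k), "fewer than 10")
  expect_error(aneuploidy_summary(k[0, ]), "empty")
})

test_that("Pearson chi-square matches the hand-computed association test", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  r <- chisq_association(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  skewed <- matrix(c(30, 10, 10, 30), 2)
  r2 <- chisq_association(skewed)
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  expect_equal(r2$p_value, 7.744e-06, tolerance = 1e-3)
  # doubling all cells doubles the statistic exactly
  expect_equal(chisq_association(2 * skewed)$statistic, 40)
  expect_error(chisq_association(matrix(c(0, 0, 5, 5), 2)), "empty")
})

test_that("Fisher exact 2x2 matches margin enumeration", {
  tab <- matrix(c(1, 11, 9, 3), 2)
  r <- fisher_exact_2x2(tab)
  expect_equal(r$p_value, 0.00276, tolerance = 1e-2)
  expect_equal(r$p_value, fisher_enum(tab), tolerance = 1e-7)
  # transposition invariance
  expect_equal(fisher_exact_2x2(t(tab))$p_value, r$p_value)
  expect_warning(r0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2)), "margin")
  expect_equal(r0$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  # doubling rule is the capped doubled smaller tail
  rd <- fisher_exact_2x2(tab, method = "doubling")
  k <- tab[1, 1]; K <- sum(tab[1, ]); n <- sum(tab[, 1]); N <- sum(tab)
  expect_equal(rd$p_value,
               min(1, 2 * min(phyper(k, K, N - K, n),
                              phyper(k - 1, K, N - K, n,
                                     lower.tail = FALSE))))
})

test_that("Fisher probability-mass rule agrees with enumeration broadly", {
  withr::with_seed(61, {
    for (i in 1:150) {
      N <- sample(4:40, 1)
      K <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      k <- sample(max(0, K + n - N):min(K, n), 1)
      tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum(tab),
                   tolerance = 1e-7)
    }
  })
})

test_that("Kaplan-Meier handles all-censored and mixed records", {
  all_cens <- tibble::tibble(arm = "a", time = c(100, 200, 760),
                             event = "censored")
  km <- km_estimate(all_cens)
  expect_true(all(tidy(km)$surv == 1))
  s <- tibble::tibble(
    arm = "a", time = c(100, 200, 300, 760),
    event = c("tumor", "censored", "tumor", "censored")
  )
  km2 <- tidy(km_estimate(s))
  # product-limit: drops at events only, monotone non-increasing
  expect_equal(km2$surv[km2$time == 100], 3 / 4)
  expect_true(all(diff(km2$surv) <= 1e-12))
  expect_error(km_estimate(dplyr::mutate(s, time = 0)), "> 0")
})

test_that("log-rank matches manual risk-set tabulation on the toy arms", {
  s <- tibble::tibble(
    arm = rep(c("A", "B"), each = 2),
    time = c(1, 3, 2, 4),
    event = "tumor"
  )
  r <- logrank_test(s)
  manual <- logrank_enum(c(1, 3), c(2, 4), c(1, 1), c(1, 1))
  expect_equal(r$statistic, manual, tolerance = 1e-10)
  expect_equal(r$df, 1)
})

test_that("degenerate survival comparisons are reported as specified", {
  none <- tibble::tibble(arm = rep(c("a", "b"), each = 3),
                         time = rep(760, 6), event = "censored")
  r <- logrank_test(none)
  expect_true(is.na(r$statistic))
  expect_equal(r$n_events, 0L)
  one_arm <- tibble::tibble(arm = "a", time = c(1, 2), event = "tumor")
  expect_error(logrank_test(one_arm), "2 arms")
  same <- tibble::tibble(
    arm = rep(c("a", "b"), each = 4),
    time = rep(c(50, 120, 400, 760), 2),
    event = rep(c("tumor", "tumor", "tumor", "censored"), 2)
  )
  r2 <- logrank_test(same)
  expect_lt(r2$statistic, 1e-10)
  expect_gt(r2$p_value, 0.999)
})

test_that("qPCR fold enrichment follows the 2^-dCt convention", {
  expect_equal(qpcr_fold_enrichment(20, 20), 1)
  expect_equal(qpcr_fold_enrichment(20, 25), 32)
  expect_equal(qpcr_fold_enrichment(25, 20), 1 / 32)
  expect_error(qpcr_fold_enrichment(NA, 20), "finite")
  expect_error(qpcr_fold_enrichment(Inf, 20), "finite")
})
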