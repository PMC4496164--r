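#' Shuffle interval locations genome-wide
#'
#' The permutation null model: every interval keeps its length but is
#' independently re-placed uniformly at random over all valid start
#' positions in the genome. A chromosome is chosen with probability
#' proportional to its number of valid starts (`length - iv_length + 1`), so
#' placement is uniform over all genome-wide placements. Shuffled intervals
#' may overlap each other; the null treats placements as independent.
#'
#' @param ivs Interval tibble.
#' @param genome Genome tibble.
#' @param seed Optional integer; when given, the shuffle runs under a local
#'   RNG state so it is reproducible without disturbing the session RNG.
#' @return Interval tibble of the same size with an identical length multiset.
#' @export
shuffle_intervals <- function(ivs, genome, seed = NULL) {
  ivs <- validate_intervals(ivs, genome)
  run <- function() {
    n <- nrow(ivs)
    if (!n) return(ivs)
    L <- ivs$end - ivs$start
    valid <- outer(L, genome$length, function(l, cl) pmax(cl - l + 1, 0))
    cum <- valid
    if (ncol(cum) > 1) {
      for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
    }
    total <- cum[, ncol(cum)]
    if (any(total <= 0)) {
      abort("interval longer than every chromosome: cannot shuffle")
    }
    u <- pmin(floor(runif(n) * total), total - 1)
    ci <- rowSums(cum <= u) + 1L
    before <- cbind(0, cum)[cbind(seq_len(n), ci)]
    start <- u - before
    tibble(chrom = genome$chrom[ci], start = start, end = start + L,
           strand = rep("*", n))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Count binding sites overlapped by an interval set
#'
#' Number of site intervals overlapping at least one query interval by
#' >= 1 bp; each site is counted at most once regardless of how many
#' intervals cover it.
#'
#' @param ivs Interval tibble (e.g. ChIP peaks).
#' @param sites Interval tibble of TF binding sites.
#' @return Integer count.
#' @export
count_tfbs_hits <- function(ivs, sites) {
  sum(overlaps_any(sites, ivs))
}

# Shared engine for the two permutation tests. statistic:
# "sites" -> distinct sites overlapped; "query" -> query intervals hitting
# >= 1 site. Internal.
perm_test_engine <- function(ivs, sites, genome, n_perm, seed, statistic) {
  ivs <- validate_intervals(ivs, genome)
  sites <- validate_intervals(sites, genome)
  if (n_perm < 1) abort("n_perm must be >= 1")
  observed <- if (statistic == "sites") {
    count_tfbs_hits(ivs, sites)
  } else {
    sum(overlaps_any(ivs, sites))
  }
  ord <- order(match(sites$chrom, genome$chrom), sites$start)
  s_sorted <- sites[ord, ]
  site_starts <- lapply(genome$chrom, function(cn) {
    as.numeric(s_sorted$start[s_sorted$chrom == cn])
  })
  site_ends <- lapply(genome$chrom, function(cn) {
    as.numeric(s_sorted$end[s_sorted$chrom == cn])
  })
  run <- function() {
    perm_null_counts(site_starts, site_ends, as.numeric(genome$length),
                     as.integer(ivs$end - ivs$start), as.integer(n_perm),
                     statistic == "sites")
  }
  null_counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_exceeding <- sum(null_counts > observed)
  structure(
    list(
      observed = observed,
      n_perm = as.integer(n_perm),
      n_exceeding = n_exceeding,
      p_value = n_exceeding / n_perm,
      p_conservative = (n_exceeding + 1) / (n_perm + 1),
      null_mean = mean(null_counts),
      null_counts = null_counts,
      statistic = statistic,
      seed = seed
    ),
    class = "perm_test"
  )
}

#' Permutation test for TF binding-site enrichment in intervals
#'
#' Builds an empirical null by repeatedly shuffling the interval locations
#' genome-wide ([shuffle_intervals()] placement model) and counting, for
#' each pseudo-random experiment, the number of binding sites the shuffled
#' intervals overlap. The p-value is the fraction of shuffles whose count
#' strictly exceeds the observed count. Because that literal rule can return
#' exactly 0, the conservative estimate `(b + 1) / (n + 1)` is reported
#' alongside and should be preferred for downstream thresholding.
#'
#' @param ivs Interval tibble (ChIP peaks).
#' @param sites Interval tibble (binding sites of one TF).
#' @param genome Genome tibble.
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Optional integer seed recorded in the result.
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @export
tfbs_permutation_test <- function(ivs, sites, genome, n_perm = 1e4,
                                  seed = NULL) {
  perm_test_engine(ivs, sites, genome, n_perm, seed, "sites")
}

#' Permutation test for overlap between two interval sets
#'
#' Observed statistic: the number of `set_a` intervals overlapping at least
#' one `set_b` interval. The null is built by shuffling `set_a` exactly as in
#' [tfbs_permutation_test()]; `set_b` stays fixed.
#'
#' @param set_a,set_b Interval tibbles.
#' @inheritParams tfbs_permutation_test
#' @return A `perm_test` object.
#' @export
interval_overlap_permutation <- function(set_a, set_b, genome, n_perm = 1e4,
                                         seed = NULL) {
  perm_test_engine(set_a, set_b, genome, n_perm, seed, "query")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Genome-shuffling permutation test (", x$statistic, " statistic)\n",
      sep = "")
  cat("  observed: ", x$observed, ", null mean: ",
      signif(x$null_mean, 4), " (", x$n_perm, " permutations)\n", sep = "")
  cat("  p (strict exceedance): ", signif(x$p_value, 4),
      ", p (conservative): ", signif(x$p_conservative, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a permutation test result
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, null mean, permutation
#'   counts and both p-value estimates.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    observed = x$observed,
    null_mean = x$null_mean,
    n_perm = x$n_perm,
    n_exceeding = x$n_exceeding,
    p_value = x$p_value,
    p_conservative = x$p_conservative
  )
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Run the TFBS permutation test across a multi-TF map
#'
#' @param ivs Interval tibble (peaks).
#' @param tfbs Interval tibble with a `name` column identifying the TF of
#'   each site (a multi-track BED).
#' @param genome Genome tibble.
#' @param n_perm Permutations per TF.
#' @param seed Optional base seed; TF-specific seeds are derived from it.
#' @return Tibble with one row per TF: observed count, null mean and both
#'   p-value estimates.
#' @export
tfbs_enrichment_table <- function(ivs, tfbs, genome, n_perm = 1e4,
                                  seed = NULL) {
  if (!"name" %in% names(tfbs)) abort("tfbs table needs a name column (TF)")
  tfs <- sort(unique(tfbs$name))
  purrr::map_dfr(seq_along(tfs), function(i) {
    res <- tfbs_permutation_test(
      ivs, tfbs[tfbs$name == tfs[i], ], genome, n_perm,
      seed = if (is.null(seed)) NULL else seed + i
    )
    dplyr::bind_cols(tibble(tf = tfs[i]), tidy(res)[, -1])
  })
}
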