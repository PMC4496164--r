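# Independent oracles and tiny fixture builders shared across tests.

toy_genome <- function() define_genome(c("chrA", "chrB"), c(10000, 5000))

random_intervals <- function(n, genome, max_len = 200, seed = NULL) {
  draw <- function() {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    len <- sample.int(max_len, n, replace = TRUE)
    start <- floor(runif(n) * (genome$length[ci] - len))
    tibble::tibble(chrom = genome$chrom[ci], start = start,
                   end = start + len, strand = "*")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Brute-force: total number of (fragment, bin) overlap incidences.
brute_bin_mass <- function(fragments, bin_size) {
  sum((fragments$end - 1) %/% bin_size - fragments$start %/% bin_size + 1)
}

# Brute-force pairwise overlap of two interval tibbles: for each query row,
# does it overlap any subject row?
brute_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# Exact per-placement site-hit counts for a single interval of length L on
# one chromosome, enumerating every valid start.
enum_placement_counts <- function(iv_len, chrom_len, sites) {
  vapply(0:(chrom_len - iv_len), function(x) {
    sum(sites$start < x + iv_len & sites$end > x)
  }, numeric(1))
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial enumeration.
hyper_enum <- function(N, K, n, k) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided Fisher p on a 2x2 by probability-mass enumeration over all
# tables with the observed margins.
fisher_enum <- function(tab) {
  K <- sum(tab[1, ]); n <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- dhyper(ks, K, N - K, n)
  p_obs <- dhyper(tab[1, 1], K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Manual log-rank chi-square by risk-set tabulation (two arms, ties allowed).
logrank_enum <- function(time_a, time_b, event_a, event_b) {
  times <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  oe <- 0; v <- 0
  for (t in times) {
    na <- sum(time_a >= t); nb <- sum(time_b >= t); nt <- na + nb
    da <- sum(time_a == t & event_a == 1)
    db <- sum(time_b == t & event_b == 1)
    dt <- da + db
    oe <- oe + da - dt * na / nt
    if (nt > 1) v <- v + dt * (na / nt) * (nb / nt) * (nt - dt) / (nt - 1)
  }
  oe^2 / v
}
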