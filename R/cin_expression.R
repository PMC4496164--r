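#' Per-gene one-way ANOVA differential expression between two groups
#'
#' For every gene, a one-way ANOVA (equal-variance F test) of expression
#' between two biological conditions, plus the linear-scale fold change
#' `mean(group_b) / mean(group_a)`. With two groups this is equivalent to
#' the pooled-variance t test; ANOVA is used so the same machinery extends
#' to more conditions.
#'
#' Genes with zero within-group variance have an undefined F statistic; by
#' convention their p-value is 0 when the group means differ and 1 when
#' they are equal, and they are flagged in the `degenerate` column.
#'
#' @param expr Tibble with a `gene_id` column and one numeric column per
#'   sample (positive, linear scale).
#' @param groups Tibble with columns `sample`, `group`, or a named character
#'   vector mapping sample to group.
#' @param group_a,group_b Group labels to compare (fold = b over a).
#' @return Tibble: `gene_id`, `mean_a`, `mean_b`, `fold`, `p_value`,
#'   `degenerate`.
#' @export
anova_de <- function(expr, groups, group_a, group_b) {
  expr <- as_tibble(expr)
  if (!"gene_id" %in% names(expr)) abort("expr needs a gene_id column")
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample)
  }
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  sa <- intersect(sa, names(expr))
  sb <- intersect(sb, names(expr))
  if (length(sa) < 2 || length(sb) < 2) {
    abort("each compared group needs >= 2 samples present in expr")
  }
  ma <- as.matrix(expr[, sa])
  mb <- as.matrix(expr[, sb])
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  ssw <- rowSums((ma - mean_a)^2) + rowSums((mb - mean_b)^2)
  degenerate <- ssw <= 0
  g <- factor(rep(c("a", "b"), c(length(sa), length(sb))))
  p <- vapply(seq_len(nrow(ma)), function(i) {
    if (degenerate[i]) return(NA_real_)
    oneway.test(v ~ g, data.frame(v = c(ma[i, ], mb[i, ]), g = g),
                var.equal = TRUE)$p.value
  }, numeric(1))
  p[degenerate] <- ifelse(mean_a[degenerate] != mean_b[degenerate], 0, 1)
  tibble(
    gene_id = expr$gene_id,
    mean_a = mean_a, mean_b = mean_b,
    fold = mean_b / mean_a,
    p_value = p,
    degenerate = degenerate
  )
}

#' Filter a differential-expression table on p-value and fold change
#'
#' Keeps genes with `p_value <= p_max` and absolute fold change at least
#' `fold_min`, where fold change is interpreted symmetrically: a gene at
#' fold 0.5 is 2-fold down-regulated and passes `fold_min = 1.5`. The
#' default thresholds (p <= 0.01, |fold| >= 1.25) are the permissive
#' expression-profiling filter; `p_max = 0.05, fold_min = 1.5` is the
#' stricter variant used for condition comparisons.
#'
#' @param de Output of [anova_de()].
#' @param p_max Maximum p-value (default 0.01).
#' @param fold_min Minimum absolute fold change (default 1.25).
#' @return Character vector of passing gene ids.
#' @export
filter_de <- function(de, p_max = 0.01, fold_min = 1.25) {
  if (p_max <= 0 || fold_min <= 0) abort("thresholds must be positive")
  abs_fold <- pmax(de$fold, 1 / de$fold)
  de$gene_id[de$p_value <= p_max & abs_fold >= fold_min]
}

#' CIN-signature enrichment curve
#'
#' Orders the signature universe by descending CIN score and, at each rank
#' cutoff k, compares the number of query genes in the top k with the
#' count expected under exchangeability (`k * |Q| / N`). The curve value is
#' observed / expected, so a query concentrated among high-CIN genes rises
#' above 1 at the top of the ranking, and every curve ends at exactly 1 at
#' k = N. A running-sum variant (cumulative observed-minus-expected hit
#' fraction, as used by rank-based gene-set tests) is returned alongside in
#' the `running` column.
#'
#' @param query Character vector of gene ids (a subset of the signature
#'   universe; non-empty).
#' @param signature Tibble with columns `gene_id`, `score` (higher score =
#'   more CIN-associated). Ties are broken by gene id for determinism.
#' @return A `cin_curve` tibble: `rank`, `gene_id`, `score`, `hit`, `hits`,
#'   `expected`, `enrichment`, `running`.
#' @export
cin_enrichment_curve <- function(query, signature) {
  signature <- as_tibble(signature)
  if (!all(c("gene_id", "score") %in% names(signature))) {
    abort("signature must have columns gene_id, score")
  }
  query <- unique(query)
  if (!length(query)) abort("query gene set is empty")
  if (!all(query %in% signature$gene_id)) {
    abort("query genes must all be in the signature universe")
  }
  sig <- signature[order(-signature$score, signature$gene_id), ]
  N <- nrow(sig)
  Q <- length(query)
  hit <- sig$gene_id %in% query
  hits <- cumsum(hit)
  k <- seq_len(N)
  expected <- k * Q / N
  out <- tibble(
    rank = k, gene_id = sig$gene_id, score = sig$score,
    hit = hit, hits = hits, expected = expected,
    enrichment = hits / expected,
    running = hits / Q - k / N
  )
  structure(out, n_query = Q, class = c("cin_curve", class(out)))
}

# Enrichment values of a query at selected rank cutoffs, given the fixed
# descending-score gene order of a signature. Lean path used by the
# permutation calibration. Internal.
curve_values_at <- function(ordered_ids, query, idx) {
  pos <- sort(which(ordered_ids %in% query))
  hits <- findInterval(idx, pos)
  hits / (idx * length(pos) / length(ordered_ids))
}

# Centered Wilcoxon signed-rank statistic W = sum of signed ranks of the
# non-zero paired differences (0 when all pairs are tied). Internal.
signed_rank_statistic <- function(d) {
  d <- d[d != 0]
  if (!length(d)) return(0)
  sum(rank(abs(d)) * sign(d))
}

#' Compare two enrichment curves by a matched-pairs Wilcoxon statistic
#'
#' Pairs the two curves at a down-sampled grid of ranks and summarizes their
#' difference with the Wilcoxon signed-rank statistic W (sum of signed ranks
#' of the non-zero paired differences). With `curve_b = NULL` the first
#' curve is compared against the flat reference level 1 (no enrichment).
#'
#' Because the paired values along a cumulative enrichment curve are
#' strongly autocorrelated, the tabulated signed-rank null (which assumes
#' independent pairs) is badly anti-conservative here. The default therefore
#' calibrates W by a query-resampling null: random gene sets of the same
#' sizes are drawn from the signature universe, both curves are rebuilt, and
#' the two-sided p-value is the fraction of resamples with `|W|` at least
#' the observed one, with the conservative `(b + 1) / (n + 1)` estimate.
#' `method = "signed-rank"` gives the classical analytic test instead (exact
#' distribution for <= 25 informative untied pairs, normal approximation
#' with continuity correction above); its p-values are only meaningful when
#' the pairs can be treated as independent.
#'
#' @param curve_a,curve_b `cin_curve` objects over the same signature
#'   universe (`curve_b` may be `NULL`).
#' @param reference Reference level when `curve_b` is `NULL` (default 1).
#' @param grid_points Approximate number of rank-grid points (default 100).
#' @param method `"permutation"` (default) or `"signed-rank"`.
#' @param n_perm Resamples for the permutation calibration (default 499).
#' @param seed Optional seed for the resampling.
#' @return One-row tibble: `statistic` (W), `p_value`, `n_pairs`, `method`.
#' @export
compare_curves_wilcoxon <- function(curve_a, curve_b = NULL, reference = 1,
                                    grid_points = 100,
                                    method = c("permutation", "signed-rank"),
                                    n_perm = 499, seed = NULL) {
  method <- match.arg(method)
  N <- nrow(curve_a)
  if (!is.null(curve_b) && nrow(curve_b) != N) {
    abort("curves must be on identical rank grids")
  }
  step <- max(1, floor(N / grid_points))
  idx <- seq(step, N, by = step)
  a <- curve_a$enrichment[idx]
  b <- if (is.null(curve_b)) rep(reference, length(idx)) else
    curve_b$enrichment[idx]
  d <- a - b
  n_pairs <- sum(d != 0)
  if (method == "signed-rank") {
    d <- d[d != 0]
    if (!length(d)) {
      return(tibble(statistic = 0, p_value = 1, n_pairs = 0L,
                    method = "signed-rank (all pairs tied)"))
    }
    exact <- length(d) <= 25 && !anyDuplicated(abs(d))
    wt <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = "two.sided", exact = exact,
                  correct = TRUE)
    )
    return(tibble(
      statistic = signed_rank_statistic(d),
      p_value = min(wt$p.value, 1),
      n_pairs = length(d),
      method = if (exact) "exact signed-rank" else
        "signed-rank normal approximation"
    ))
  }
  w_obs <- signed_rank_statistic(d)
  ordered_ids <- curve_a$gene_id
  q_a <- attr(curve_a, "n_query")
  q_b <- if (is.null(curve_b)) NULL else attr(curve_b, "n_query")
  run <- function() {
    w_null <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      va <- curve_values_at(ordered_ids, sample(ordered_ids, q_a), idx)
      vb <- if (is.null(q_b)) rep(reference, length(idx)) else
        curve_values_at(ordered_ids, sample(ordered_ids, q_b), idx)
      w_null[r] <- signed_rank_statistic(va - vb)
    }
    w_null
  }
  w_null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  b_exc <- sum(abs(w_null) >= abs(w_obs))
  tibble(
    statistic = w_obs,
    p_value = (b_exc + 1) / (n_perm + 1),
    n_pairs = n_pairs,
    method = "query-resampling calibration"
  )
}
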