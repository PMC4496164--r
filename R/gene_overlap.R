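#' Genes with an interval in their promoter window
#'
#' A gene is reported when at least one interval overlaps its strand-aware
#' promoter window, the `promoter_bp` (default 2 kb) immediately upstream of
#' the TSS: `[TSS - promoter_bp, TSS)` in gene orientation.
#'
#' @param ivs Interval tibble.
#' @param genes Gene tibble.
#' @param promoter_bp Window size in bp (default 2000).
#' @return Sorted character vector of gene ids.
#' @export
genes_with_promoter_interval <- function(ivs, genes, promoter_bp = 2000) {
  ivs <- validate_intervals(ivs)
  genes <- gene_tss(genes)
  plus <- genes$strand == "+"
  w <- tibble(
    chrom = genes$chrom,
    start = pmax(ifelse(plus, genes$start - promoter_bp, genes$end), 0),
    end = ifelse(plus, genes$start, genes$end + promoter_bp)
  )
  ok <- w$end > w$start
  hit <- logical(nrow(genes))
  hit[ok] <- overlaps_any(w[ok, ], ivs)
  sort(unique(genes$gene_id[hit]))
}

#' Hypergeometric test for gene-set overlap
#'
#' Upper-tail probability of observing at least the seen number of shared
#' genes between two hit sets drawn from a common universe: with
#' `N = |universe|`, `K = |hits_a|`, `n = |hits_b|` and
#' `k = |hits_a intersect hits_b|`, reports `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (computed via [stats::phyper()], which
#' works in log space internally).
#'
#' @param hits_a,hits_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return One-row tibble with `n_universe`, `n_a`, `n_b`, `n_overlap`,
#'   `expected_overlap` and `p_value`.
#' @export
hypergeometric_gene_overlap <- function(hits_a, hits_b, universe) {
  universe <- unique(universe)
  hits_a <- unique(hits_a)
  hits_b <- unique(hits_b)
  if (!all(hits_a %in% universe)) abort("hits_a not contained in universe")
  if (!all(hits_b %in% universe)) abort("hits_b not contained in universe")
  N <- length(universe)
  K <- length(hits_a)
  n <- length(hits_b)
  k <- length(intersect(hits_a, hits_b))
  tibble(
    n_universe = N, n_a = K, n_b = n, n_overlap = k,
    expected_overlap = K * n / N,
    p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  )
}
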