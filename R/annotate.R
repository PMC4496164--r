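#' Strand-aware TSS and transcription-stop coordinates
#'
#' For a plus-strand gene the TSS is `start` and the transcription stop is
#' `end - 1`; for a minus-strand gene the TSS is `end - 1` and the stop is
#' `start` (0-based coordinates).
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @return `genes` with `tss` and `tes` columns added.
#' @export
gene_tss <- function(genes) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes))) {
    abort(paste0("gene table must have columns ", paste(need, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (any(genes$start >= genes$end)) abort("genes require start < end")
  plus <- genes$strand == "+"
  genes$tss <- ifelse(plus, genes$start, genes$end - 1)
  genes$tes <- ifelse(plus, genes$end - 1, genes$start)
  genes
}

# Strand-aware windows around genes as 0-based half-open interval tibbles.
# which = "upstream": the upstream_bp window ending at the TSS;
# "body": the transcription unit; "downstream": the downstream_bp window
# past the transcription stop. Starts are clipped at 0. Internal.
gene_windows <- function(genes, which, upstream_bp = 10000,
                         downstream_bp = 10000) {
  plus <- genes$strand == "+"
  if (which == "upstream") {
    start <- ifelse(plus, genes$start - upstream_bp, genes$end)
    end <- ifelse(plus, genes$start, genes$end + upstream_bp)
  } else if (which == "body") {
    start <- genes$start
    end <- genes$end
  } else {
    start <- ifelse(plus, genes$end, genes$start - downstream_bp)
    end <- ifelse(plus, genes$end + downstream_bp, genes$start)
  }
  keep <- end > pmax(start, 0)
  tibble(chrom = genes$chrom[keep], start = pmax(start[keep], 0),
         end = end[keep])
}

#' Annotate intervals relative to neighboring genes
#'
#' Classifies each interval by its position relative to every gene, using the
#' standard promoter-proximal geometry: `upstream` if it overlaps the window
#' from 10 kb before the TSS to the TSS (in gene orientation), `intragenic`
#' if it overlaps the transcription unit, `downstream` if it overlaps the
#' 10 kb past the transcription stop, and `distal` if and only if none of the
#' above apply for any gene. Labels are a set: one interval can be upstream
#' of one gene and inside another, which is why the aggregate counts are
#' reported as Venn cells by [annotation_summary()].
#'
#' @param ivs Interval tibble.
#' @param genes Gene tibble.
#' @param upstream_bp,downstream_bp Window sizes in bp (default 10000).
#' @return `ivs` with logical columns `upstream`, `intragenic`, `downstream`,
#'   `distal`.
#' @export
annotate_intervals <- function(ivs, genes, upstream_bp = 10000,
                               downstream_bp = 10000) {
  ivs <- validate_intervals(ivs)
  if (nrow(genes)) genes <- gene_tss(genes)
  empty <- !nrow(genes)
  ivs$upstream <- if (empty) FALSE else
    overlaps_any(ivs, gene_windows(genes, "upstream", upstream_bp))
  ivs$intragenic <- if (empty) FALSE else
    overlaps_any(ivs, gene_windows(genes, "body"))
  ivs$downstream <- if (empty) FALSE else
    overlaps_any(ivs, gene_windows(genes, "downstream",
                                   downstream_bp = downstream_bp))
  ivs$distal <- !(ivs$upstream | ivs$intragenic | ivs$downstream)
  ivs
}

#' Summarize an annotation as label counts and Venn cells
#'
#' @param annotated Output of [annotate_intervals()].
#' @return A list with `labels` (per-label interval counts; an interval can
#'   contribute to several labels) and `venn` (counts per label combination;
#'   these sum to the number of intervals).
#' @export
annotation_summary <- function(annotated) {
  labs <- c("upstream", "intragenic", "downstream", "distal")
  label_counts <- tibble(
    label = labs,
    n = vapply(labs, function(l) sum(annotated[[l]]), integer(1))
  )
  cell <- apply(as.matrix(annotated[labs]), 1, function(r) {
    paste(labs[r], collapse = "&")
  })
  venn <- dplyr::count(tibble(cell = cell), .data$cell, name = "n")
  list(labels = label_counts, venn = venn, n_intervals = nrow(annotated))
}

#' Histogram of interval positions relative to TSSs
#'
#' Maps each interval's midpoint (floor-rounded) to TSS-relative, strand-
#' flipped coordinates for every gene, keeps positions inside `window`, and
#' bins the result. The classic presentations use windows of (-10 kb, +50 kb)
#' and (-1 kb, +1 kb) around the TSS.
#'
#' @param ivs Interval tibble.
#' @param genes Gene tibble.
#' @param window Length-2 numeric, `c(lo, hi)` with `lo < 0 < hi`.
#' @param bin_size Histogram bin width in bp.
#' @return A `tss_profile`: tibble with `bin_start`, `bin_mid`, `count`
#'   (TSS-relative coordinates).
#' @export
tss_profile <- function(ivs, genes, window = c(-10000, 50000),
                        bin_size = 500) {
  if (length(window) != 2 || !(window[1] < 0 && window[2] > 0)) {
    abort("window must satisfy lo < 0 < hi")
  }
  if (bin_size >= diff(window)) abort("bin_size must be < window width")
  if (bin_size < 1) abort("bin_size must be >= 1")
  ivs <- validate_intervals(ivs)
  genes <- gene_tss(genes)
  mids <- tibble(chrom = ivs$chrom, mid = (ivs$start + ivs$end) %/% 2)
  pairs <- dplyr::inner_join(
    mids, genes[, c("chrom", "strand", "tss")],
    by = "chrom", relationship = "many-to-many"
  )
  rel <- ifelse(pairs$strand == "+", pairs$mid - pairs$tss,
                pairs$tss - pairs$mid)
  rel <- rel[rel >= window[1] & rel < window[2]]
  breaks <- seq(window[1], window[2], by = bin_size)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
  idx <- findInterval(rel, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble(
    bin_start = breaks[-length(breaks)],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts
  )
  structure(out, window = window, bin_size = bin_size,
            class = c("tss_profile", class(out)))
}
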