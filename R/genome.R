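#' Define a genome as a table of chromosome lengths
#'
#' The genome is the coordinate universe for every interval operation:
#' validation, density binning and, importantly, the shuffling null model,
#' where it defines the space of admissible interval placements.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (>= 1).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' define_genome(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
define_genome <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length < 1)) {
    abort("chromosome lengths must be finite and >= 1")
  }
  tibble(chrom = as.character(chrom), length = length)
}

#' Validate a genomic interval table against a genome
#'
#' Intervals use 0-based half-open coordinates (`start` inclusive, `end`
#' exclusive) throughout the package; 1-based inputs are converted at the
#' reader boundary. Strand is `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param ivs A tibble with columns `chrom`, `start`, `end` and optionally
#'   `strand` (filled with `"*"` when absent).
#' @param genome A genome tibble from [define_genome()], or `NULL` to skip
#'   bounds checking against chromosome lengths.
#' @return The validated interval tibble (invisibly unchanged apart from a
#'   `strand` column being added when missing).
#' @export
validate_intervals <- function(ivs, genome = NULL) {
  ivs <- as_tibble(ivs)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(ivs))) {
    abort(paste0("interval table must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (!"strand" %in% names(ivs)) ivs$strand <- "*"
  bad <- which(!(ivs$strand %in% c("+", "-", "*")))
  if (length(bad)) abort(paste0("invalid strand at row ", bad[1]))
  if (any(ivs$start < 0) || any(ivs$end <= ivs$start)) {
    abort("intervals require 0 <= start < end")
  }
  if (!is.null(genome)) {
    len <- setNames(genome$length, genome$chrom)
    unknown <- setdiff(unique(ivs$chrom), genome$chrom)
    if (length(unknown)) {
      abort(paste0("chromosome not in genome: ", unknown[1]))
    }
    if (any(ivs$end > len[ivs$chrom])) {
      abort("interval end exceeds chromosome length")
    }
  }
  ivs
}

#' Extend sequenced tags to fragment length
#'
#' The 5' end of a sequenced ChIP tag marks one end of the immunoprecipitated
#' fragment, so each tag is extended in silico at its 3' end to the average
#' library fragment length (default 110 bp) before density profiling. A plus
#' tag at position p becomes `[p, p + L)`; a minus tag becomes
#' `[p - L + 1, p + 1)`. Extensions are clipped at chromosome bounds.
#'
#' @param tags Tibble with columns `chrom`, `pos` (0-based 5' position) and
#'   `strand` (`"+"` or `"-"`).
#' @param genome Genome tibble; used for bounds clipping and validation.
#' @param fragment_length Target fragment length in bp (default 110).
#' @return Interval tibble (`chrom`, `start`, `end`, `strand`).
#' @export
extend_tags <- function(tags, genome, fragment_length = 110) {
  tags <- as_tibble(tags)
  if (!all(c("chrom", "pos", "strand") %in% names(tags))) {
    abort("tag table must have columns chrom, pos, strand")
  }
  if (!all(tags$strand %in% c("+", "-"))) abort("tag strand must be + or -")
  if (fragment_length < 1) abort("fragment_length must be >= 1")
  len <- setNames(genome$length, genome$chrom)
  unknown <- setdiff(unique(tags$chrom), genome$chrom)
  if (length(unknown)) abort(paste0("chromosome not in genome: ", unknown[1]))
  cl <- len[tags$chrom]
  if (any(tags$pos < 0 | tags$pos >= cl)) {
    abort("tag position outside chromosome")
  }
  plus <- tags$strand == "+"
  start <- ifelse(plus, tags$pos, tags$pos - fragment_length + 1)
  end <- ifelse(plus, tags$pos + fragment_length, tags$pos + 1)
  tibble(
    chrom = tags$chrom,
    start = pmax(start, 0),
    end = pmin(end, cl),
    strand = tags$strand
  )
}

#' Bin fragment density along the genome
#'
#' Divides every chromosome into fixed-width bins (default 32 bp, the
#' resolution used for ChIP-Seq fragment pileups) and counts, for each bin,
#' the number of fragments overlapping it by at least 1 bp. A fragment
#' spanning several bins increments each of them.
#'
#' @param fragments Interval tibble of (extended) fragments.
#' @param genome Genome tibble.
#' @param bin_size Bin width in bp (default 32).
#' @return A `density_track`: tibble with `chrom`, `start`, `end`, `count`
#'   covering every bin (zeros included), with attributes `bin_size` and
#'   `genome`.
#' @export
bin_density <- function(fragments, genome, bin_size = 32) {
  if (bin_size < 1) abort("bin_size must be >= 1")
  fragments <- validate_intervals(fragments, genome)
  track <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    cn <- genome$chrom[i]
    n_bins <- ceiling(genome$length[i] / bin_size)
    counts <- integer(n_bins)
    fr <- fragments[fragments$chrom == cn, ]
    if (nrow(fr)) {
      b0 <- fr$start %/% bin_size
      b1 <- (fr$end - 1) %/% bin_size
      hit <- sequence(b1 - b0 + 1, from = b0 + 1)
      tab <- tabulate(hit, nbins = n_bins)
      counts <- counts + tab
    }
    starts <- (seq_len(n_bins) - 1) * bin_size
    tibble(chrom = cn, start = starts,
           end = pmin(starts + bin_size, genome$length[i]),
           count = counts)
  })
  structure(track, bin_size = bin_size, genome = genome,
            class = c("density_track", class(track)))
}

#' Export a density track as bedGraph
#'
#' Zero-count bins are omitted, following bedGraph convention.
#'
#' @param track A `density_track` from [bin_density()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  nz <- track[track$count > 0, ]
  gr <- GenomicRanges::GRanges(
    seqnames = nz$chrom,
    ranges = IRanges::IRanges(start = nz$start + 1, end = nz$end),
    score = nz$count
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# 1-based closed IRanges view of a 0-based half-open interval tibble,
# split by chromosome. Internal.
iv_ranges_by_chrom <- function(ivs) {
  split(IRanges::IRanges(start = ivs$start + 1, end = ivs$end), ivs$chrom)
}

# For each row of `query`, TRUE iff it overlaps >= 1 row of `subject`
# (>= 1 bp, same chromosome). Internal workhorse for hit counting and
# annotation.
overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  if (!nrow(query) || !nrow(subject)) return(out)
  sub_by <- iv_ranges_by_chrom(subject)
  for (cn in intersect(unique(query$chrom), names(sub_by))) {
    sel <- which(query$chrom == cn)
    qr <- IRanges::IRanges(start = query$start[sel] + 1, end = query$end[sel])
    out[sel] <- IRanges::overlapsAny(qr, sub_by[[cn]])
  }
  out
}
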