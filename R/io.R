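#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based half-open, matching the package's internal
#' convention, so no shifting occurs. The optional name column is kept
#' (useful for multi-track TFBS maps, where `name` is the TF).
#'
#' @param path BED file path.
#' @param genome Optional genome tibble for validation.
#' @return Interval tibble with `chrom`, `start`, `end`, `strand` and, when
#'   present in the file, `name`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^(#|track\\b|browser\\b)", lines) &
                      nzchar(trimws(lines)))
  if (!length(data_idx)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character()))
  }
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      as.numeric(f[2]) < as.numeric(f[3])
    if (!ok) abort(paste0("malformed BED line ", i, " in ", path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  validate_intervals(out, genome)
}

#' Write genomic intervals to a BED file
#'
#' @param ivs Interval tibble (optionally with a `name` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ivs, path) {
  ivs <- validate_intervals(ivs)
  gr <- GenomicRanges::GRanges(
    seqnames = ivs$chrom,
    ranges = IRanges::IRanges(start = ivs$start + 1, end = ivs$end),
    strand = ivs$strand
  )
  if ("name" %in% names(ivs)) S4Vectors::mcols(gr)$name <- ivs$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from a TSV or GTF file
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `strand`, `start`, `end`
#' in 0-based half-open coordinates (this package's own export format).
#' GTF/GFF input (1-based closed) is converted at the boundary; only `gene`
#' features are used when the file distinguishes feature types.
#'
#' @param path File path; format chosen by extension (`.gtf`/`.gff` vs TSV).
#' @return Gene tibble.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    type <- as.character(S4Vectors::mcols(gr)$type)
    if (!is.null(type) && any(type == "gene")) gr <- gr[type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) abort("GTF lacks gene_id attribute")
    out <- tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr)
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    if (!all(need %in% names(out))) {
      abort(paste0("gene TSV must have columns ",
                   paste(need, collapse = ", "), ": ", path))
    }
  }
  gene_tss(out)[, c("gene_id", "chrom", "strand", "start", "end")]
}

#' Write gene models as TSV
#' @param genes Gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  genes <- gene_tss(genes)
  readr::write_tsv(genes[, c("gene_id", "chrom", "strand", "start", "end")],
                   path)
  invisible(path)
}

#' Read a genome table (chrom, length TSV)
#' @param path TSV with columns `chrom`, `length`.
#' @return Genome tibble.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("chrom", "length") %in% names(x))) {
    abort(paste0("genome TSV must have columns chrom, length: ", path))
  }
  define_genome(x$chrom, x$length)
}

#' Write a genome table as TSV
#' @param genome Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  readr::write_tsv(genome, path)
  invisible(path)
}

# Generic TSV readers for the tabular study inputs; each checks its
# required columns and names the offending path on failure. Internal
# helpers shared by the pipeline entry points.
read_checked_tsv <- function(path, need) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(need %in% names(x))) {
    abort(paste0(path, " must have columns ", paste(need, collapse = ", ")))
  }
  x
}

#' Read an expression matrix TSV (gene_id + one column per sample)
#' @param path TSV path.
#' @return Tibble with `gene_id` and numeric sample columns.
#' @export
read_expression <- function(path) read_checked_tsv(path, "gene_id")

#' Read a sample-to-group map TSV
#' @param path TSV with columns `sample`, `group`.
#' @return Tibble.
#' @export
read_groups <- function(path) read_checked_tsv(path, c("sample", "group"))

#' Read a CIN-signature score table TSV
#' @param path TSV with columns `gene_id`, `score`.
#' @return Tibble.
#' @export
read_signature <- function(path) read_checked_tsv(path, c("gene_id", "score"))

#' Read a per-metaphase karyotype table TSV
#' @param path TSV with columns `sample_id`, `chromosome_count`.
#' @return Tibble.
#' @export
read_karyotypes <- function(path) {
  read_checked_tsv(path, c("sample_id", "chromosome_count"))
}

#' Read a survival table TSV
#' @param path TSV with columns `arm`, `time`, `event`.
#' @return Tibble.
#' @export
read_survival <- function(path) read_checked_tsv(path, c("arm", "time", "event"))
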