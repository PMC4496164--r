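#' @title Pipeline entry points
#' @description Thin orchestration around the analysis stages: each `run_*`
#'   function reads the standard tabular inputs, executes one of the study's
#'   analyses, writes TSV/JSON results to an output directory, and records a
#'   JSON manifest (package version, parameters, seed, input checksums,
#'   output files). Outputs are deterministic for a fixed seed: the manifest
#'   intentionally carries no timestamps. A thin command-line wrapper over
#'   these functions ships in `inst/cli/chipcin.R`.
#' @name pipeline
NULL

write_manifest <- function(out_dir, subcommand, params, inputs, outputs) {
  manifest <- list(
    tool = "chipcin",
    version = as.character(utils::packageVersion("chipcin")),
    subcommand = subcommand,
    parameters = params,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Simulate a full synthetic study and write it to disk
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written file paths, invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  ensure_dir(out_dir)
  study <- simulate_study(cfg)
  paths <- c(
    genome = write_genome(study$genome, file.path(out_dir, "genome.tsv")),
    genes = write_genes(study$genes, file.path(out_dir, "genes.tsv")),
    peaks = write_bed(study$peaks, file.path(out_dir, "peaks.bed")),
    tfbs = write_bed(study$tfbs, file.path(out_dir, "tfbs.bed"))
  )
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    p
  }
  paths <- c(
    paths,
    signature = wt(study$signature, "signature.tsv"),
    expression = wt(study$expr, "expression.tsv"),
    groups = wt(study$groups, "groups.tsv"),
    karyotypes = wt(study$karyotypes, "karyotypes.tsv"),
    survival = wt(study$survival, "survival.tsv")
  )
  truth <- list(
    seed = cfg$seed,
    enriched_tfs = study$tfbs_meta$tf[study$tfbs_meta$enriched],
    enrichment_factor = cfg$tfbs$enrichment_factor,
    signature_genes = study$signature_genes,
    planted_fold = cfg$expression$planted_fold,
    aneuploidy_rates = as.list(cfg$karyotype$rates),
    hazards = as.list(cfg$survival$hazards)
  )
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, truth = truth_path)
  write_manifest(out_dir, "simulate",
                 params = list(seed = cfg$seed), inputs = character(),
                 outputs = as.list(paths))
  invisible(paths)
}

#' Annotate peaks relative to genes and profile them around TSSs
#'
#' @param peaks_bed,genes_tsv,genome_tsv Input file paths.
#' @param out_dir Output directory.
#' @param upstream_bp,downstream_bp Annotation window sizes.
#' @return List with `annotation`, `summary` and `profile` tibbles,
#'   invisibly; files are written to `out_dir`.
#' @export
run_annotate <- function(peaks_bed, genes_tsv, genome_tsv, out_dir,
                         upstream_bp = 10000, downstream_bp = 10000) {
  ensure_dir(out_dir)
  genome <- read_genome(genome_tsv)
  peaks <- read_bed(peaks_bed, genome)
  genes <- read_genes(genes_tsv)
  ann <- annotate_intervals(peaks, genes, upstream_bp, downstream_bp)
  summ <- annotation_summary(ann)
  prof_wide <- tss_profile(peaks, genes, window = c(-10000, 50000),
                           bin_size = 1000)
  prof_tss <- tss_profile(peaks, genes, window = c(-1000, 1000),
                          bin_size = 50)
  ann_path <- file.path(out_dir, "annotation.tsv")
  readr::write_tsv(ann, ann_path)
  venn_path <- file.path(out_dir, "annotation_venn.json")
  jsonlite::write_json(
    list(n_intervals = summ$n_intervals, labels = summ$labels,
         venn = summ$venn),
    venn_path, auto_unbox = TRUE, digits = NA
  )
  p1 <- file.path(out_dir, "tss_profile_wide.tsv")
  p2 <- file.path(out_dir, "tss_profile_proximal.tsv")
  readr::write_tsv(prof_wide, p1)
  readr::write_tsv(prof_tss, p2)
  write_manifest(
    out_dir, "annotate",
    params = list(upstream_bp = upstream_bp, downstream_bp = downstream_bp),
    inputs = c(peaks_bed, genes_tsv, genome_tsv),
    outputs = list(ann_path, venn_path, p1, p2)
  )
  invisible(list(annotation = ann, summary = summ, profile = prof_wide))
}

#' Run the TF binding-site enrichment analysis
#'
#' @param peaks_bed,tfbs_bed,genome_tsv Input file paths (`tfbs_bed` is a
#'   multi-track BED whose name column is the TF).
#' @param out_dir Output directory.
#' @param n_perm Permutations per TF.
#' @param seed Integer seed.
#' @return The per-TF enrichment tibble, invisibly.
#' @export
run_enrich_tf <- function(peaks_bed, tfbs_bed, genome_tsv, out_dir,
                          n_perm = 1e4, seed = 1) {
  ensure_dir(out_dir)
  genome <- read_genome(genome_tsv)
  peaks <- read_bed(peaks_bed, genome)
  tfbs <- read_bed(tfbs_bed, genome)
  res <- tfbs_enrichment_table(peaks, tfbs, genome, n_perm = n_perm,
                               seed = seed)
  out_path <- file.path(out_dir, "tf_enrichment.tsv")
  readr::write_tsv(res, out_path)
  write_manifest(out_dir, "enrich_tf",
                 params = list(n_perm = n_perm, seed = seed),
                 inputs = c(peaks_bed, tfbs_bed, genome_tsv),
                 outputs = list(out_path))
  invisible(res)
}

#' Run the interval-overlap permutation and promoter-gene overlap analysis
#'
#' @param bed_a,bed_b,genes_tsv,genome_tsv Input file paths.
#' @param out_dir Output directory.
#' @param n_perm Permutations.
#' @param promoter_bp Promoter window for the gene-based test.
#' @param seed Integer seed.
#' @return List with `interval_test` and `gene_test` tibbles, invisibly.
#' @export
run_overlap <- function(bed_a, bed_b, genes_tsv, genome_tsv, out_dir,
                        n_perm = 1e4, promoter_bp = 2000, seed = 1) {
  ensure_dir(out_dir)
  genome <- read_genome(genome_tsv)
  set_a <- read_bed(bed_a, genome)
  set_b <- read_bed(bed_b, genome)
  genes <- read_genes(genes_tsv)
  ires <- tidy(interval_overlap_permutation(set_a, set_b, genome,
                                            n_perm = n_perm, seed = seed))
  hits_a <- genes_with_promoter_interval(set_a, genes, promoter_bp)
  hits_b <- genes_with_promoter_interval(set_b, genes, promoter_bp)
  gres <- hypergeometric_gene_overlap(hits_a, hits_b, genes$gene_id)
  p1 <- file.path(out_dir, "interval_overlap.tsv")
  p2 <- file.path(out_dir, "gene_overlap.tsv")
  readr::write_tsv(ires, p1)
  readr::write_tsv(gres, p2)
  write_manifest(out_dir, "overlap",
                 params = list(n_perm = n_perm, promoter_bp = promoter_bp,
                               seed = seed),
                 inputs = c(bed_a, bed_b, genes_tsv, genome_tsv),
                 outputs = list(p1, p2))
  invisible(list(interval_test = ires, gene_test = gres))
}

#' Run the differential-expression and CIN-signature enrichment analysis
#'
#' @param expr_tsv,groups_tsv,signature_tsv Input file paths.
#' @param out_dir Output directory.
#' @param group_a,group_b Group labels to compare.
#' @param p_max,fold_min DE filter thresholds.
#' @param seed Seed for the label-permuted control.
#' @return List with `de`, `query`, `curve`, `wilcoxon`, invisibly.
#' @export
run_cin <- function(expr_tsv, groups_tsv, signature_tsv, out_dir,
                    group_a = "control", group_b = "rescue",
                    p_max = 0.01, fold_min = 1.25, seed = 1) {
  ensure_dir(out_dir)
  expr <- read_expression(expr_tsv)
  groups <- read_groups(groups_tsv)
  signature <- read_signature(signature_tsv)
  de <- anova_de(expr, groups, group_a, group_b)
  up <- filter_de(de[de$fold > 1, ], p_max, fold_min)
  up <- intersect(up, signature$gene_id)
  curve <- NULL
  wres <- tibble(statistic = NA_real_, p_value = NA_real_, n_pairs = 0L,
                 method = "empty query")
  if (length(up)) {
    curve <- cin_enrichment_curve(up, signature)
    perm_groups <- withr::with_seed(seed, {
      g <- groups
      g$group <- sample(g$group)
      g
    })
    de_perm <- anova_de(expr, perm_groups, group_a, group_b)
    up_perm <- intersect(filter_de(de_perm[de_perm$fold > 1, ],
                                   p_max, fold_min),
                         signature$gene_id)
    ctrl <- if (length(up_perm)) cin_enrichment_curve(up_perm, signature)
    wres <- compare_curves_wilcoxon(curve, ctrl, seed = seed + 1)
  }
  p1 <- file.path(out_dir, "de_table.tsv")
  readr::write_tsv(de, p1)
  outs <- list(p1)
  if (!is.null(curve)) {
    p2 <- file.path(out_dir, "cin_curve.tsv")
    readr::write_tsv(curve, p2)
    outs <- c(outs, p2)
  }
  p3 <- file.path(out_dir, "cin_test.json")
  jsonlite::write_json(
    list(n_up = length(up), wilcoxon = as.list(wres)),
    p3, auto_unbox = TRUE, digits = NA
  )
  outs <- c(outs, p3)
  write_manifest(out_dir, "cin",
                 params = list(group_a = group_a, group_b = group_b,
                               p_max = p_max, fold_min = fold_min,
                               seed = seed),
                 inputs = c(expr_tsv, groups_tsv, signature_tsv),
                 outputs = outs)
  invisible(list(de = de, query = up, curve = curve, wilcoxon = wres))
}

#' Run the karyotype aneuploidy analysis
#'
#' @param karyo_tsv Input karyotype TSV.
#' @param out_dir Output directory.
#' @param diploid_n,tolerance Classification parameters.
#' @return List with `summary` and `chisq`, invisibly.
#' @export
run_karyo <- function(karyo_tsv, out_dir, diploid_n = 40, tolerance = 2) {
  ensure_dir(out_dir)
  karyo <- read_karyotypes(karyo_tsv)
  summ <- aneuploidy_summary(karyo, diploid_n, tolerance)
  chsq <- if (nrow(summ) >= 2) {
    chisq_association(karyotype_contingency(summ))
  } else {
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  p1 <- file.path(out_dir, "aneuploidy_summary.tsv")
  readr::write_tsv(summ, p1)
  p2 <- file.path(out_dir, "karyotype_test.json")
  jsonlite::write_json(as.list(chsq), p2, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "karyo",
                 params = list(diploid_n = diploid_n, tolerance = tolerance),
                 inputs = karyo_tsv, outputs = list(p1, p2))
  invisible(list(summary = summ, chisq = chsq))
}

#' Run the tumor-free survival analysis
#'
#' @param surv_tsv Input survival TSV.
#' @param out_dir Output directory.
#' @return List with `km` and `logrank`, invisibly.
#' @export
run_survival <- function(surv_tsv, out_dir) {
  ensure_dir(out_dir)
  surv <- read_survival(surv_tsv)
  km <- km_estimate(surv)
  lr <- if (length(unique(surv$arm)) >= 2) logrank_test(surv) else
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
           n = nrow(surv), n_events = NA_integer_)
  p1 <- file.path(out_dir, "km_steps.tsv")
  readr::write_tsv(tidy(km), p1)
  p2 <- file.path(out_dir, "logrank.json")
  jsonlite::write_json(as.list(lr), p2, auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "survival", params = list(),
                 inputs = surv_tsv, outputs = list(p1, p2))
  invisible(list(km = km, logrank = lr))
}
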