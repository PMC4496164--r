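#' Simulation configuration for the synthetic study
#'
#' Central configuration for the seeded generators that fabricate every
#' input the pipeline consumes, with planted, recoverable structure.
#' Defaults are sized for seconds-scale runs while preserving the study's
#' data shapes: a two-chromosome 2 Mb genome, 200 genes, 300 ChIP peaks
#' concentrated near TSSs, 20 TF binding-site tracks with optional planted
#' enrichment inside peaks, a 3 + 3 two-group expression design with
#' up-regulation planted on the CIN-signature genes, 12 metaphases per
#' karyotyped sample (mirroring the >= 10-metaphase convention), and two
#' 30-animal survival arms right-censored at study end day 760.
#'
#' @param seed Integer master seed; every generator derives its RNG state
#'   from it, so reruns are byte-identical.
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list with components `genome`, `genes`, `peaks`,
#'   `tfbs`, `expression`, `karyotype`, `survival`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chrom = 2, chrom_length = 1e6),
    genes = list(n_genes = 200, length_range = c(2000, 10000),
                 min_spacing = 500),
    peaks = list(n_peaks = 300, length_range = c(200, 800),
                 tss_fraction = 0.6, tss_jitter = 1000),
    tfbs = list(n_tfs = 20, sites_per_tf = 200, site_length = 12,
                n_enriched = 3, enrichment_factor = 1),
    expression = list(n_sig = 30, group_sizes = c(3, 3), planted_fold = 1,
                      sigma = 0.2, base_log2_range = c(5, 12)),
    karyotype = list(n_metaphases = 12, diploid_n = 40, tolerance = 2,
                     rates = c(control = 0.07, rescue = 0.42),
                     tetraploid_fraction = 0.2, dispersion = 0.4),
    survival = list(n_per_arm = 30, hazards = c(control = 0.0005,
                                                case = 0.0015),
                    censor_day = 760)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "sim_config")
}

# Offset the master seed per generator so each is an independent, pure
# function of (config, seed). Offsets are fixed and small.
sim_seed <- function(cfg, offset) (cfg$seed %% 2000000000L) + offset

#' Simulate a genome
#' @param cfg A [sim_config()].
#' @return Genome tibble.
#' @export
simulate_genome <- function(cfg) {
  g <- cfg$genome
  define_genome(paste0("chr", seq_len(g$n_chrom)),
                rep(g$chrom_length, g$n_chrom))
}

#' Simulate non-overlapping strand-randomized genes
#'
#' Genes are apportioned among chromosomes proportionally to length, given
#' uniform lengths in `length_range`, and packed with uniformly random gaps
#' subject to a minimum spacing; an infeasible packing (total gene length
#' plus spacing exceeding the chromosome) is a configuration error.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble from [simulate_genome()].
#' @return Gene tibble.
#' @export
simulate_genes <- function(cfg, genome) {
  gs <- cfg$genes
  if (gs$n_genes == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = numeric(), end = numeric()))
  }
  withr::with_seed(sim_seed(cfg, 1L), {
    alloc <- diff(round(cumsum(c(0, genome$length)) /
                          sum(genome$length) * gs$n_genes))
    idx <- 0L
    out <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      k <- alloc[i]
      if (k == 0) return(NULL)
      len <- round(runif(k, gs$length_range[1], gs$length_range[2]))
      free <- genome$length[i] - sum(len) - k * gs$min_spacing
      if (free < 0) {
        abort("infeasible gene packing: reduce n_genes or gene lengths")
      }
      gaps <- diff(c(0, sort(runif(k, 0, free))))
      start <- cumsum(gaps + gs$min_spacing) - gs$min_spacing +
        cumsum(c(0, len[-k]))
      ids <- paste0("gene", seq.int(idx + 1L, idx + k))
      idx <<- idx + k
      tibble(gene_id = ids, chrom = genome$chrom[i],
             strand = sample(c("+", "-"), k, replace = TRUE),
             start = start, end = start + len)
    })
    out
  })
}

# Place n intervals of the given lengths uniformly over the genome
# (chromosome weighted by valid starts). Internal helper reusing the
# shuffle placement model.
place_uniform <- function(n, lengths, genome) {
  if (!n) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character()))
  }
  shuffle_intervals(
    tibble(chrom = genome$chrom[1], start = 0, end = lengths,
           strand = "*"),
    genome
  )
}

#' Simulate ChIP peaks and TF binding-site tracks
#'
#' A configurable fraction of peaks is centered within +/- `tss_jitter` bp
#' of randomly chosen TSSs (giving the characteristic TSS-concentrated
#' profile); the remainder is placed uniformly. Each TF receives
#' `sites_per_tf` uniformly placed sites; for the first `n_enriched` TFs,
#' additional sites are planted uniformly inside peaks so that the expected
#' in-peak site count is multiplied by `enrichment_factor` (factor 1 plants
#' nothing and is the null construction).
#'
#' @param cfg A [sim_config()].
#' @param genome Genome tibble.
#' @param genes Gene tibble (TSS anchors for peak placement).
#' @return List: `peaks` (interval tibble), `tfbs` (interval tibble with a
#'   `name` column = TF), `meta` (per-TF tibble of planted truth: `tf`,
#'   `enriched`, `factor`, `n_sites`).
#' @export
simulate_peaks_tfbs <- function(cfg, genome, genes) {
  ps <- cfg$peaks
  ts <- cfg$tfbs
  withr::with_seed(sim_seed(cfg, 2L), {
    n <- ps$n_peaks
    len <- round(runif(n, ps$length_range[1], ps$length_range[2]))
    n_tss <- if (nrow(genes)) rbinom(1, n, ps$tss_fraction) else 0L
    peaks <- place_uniform(n - n_tss, len[seq_len(n - n_tss)], genome)
    if (n_tss > 0) {
      gi <- sample.int(nrow(genes), n_tss, replace = TRUE)
      tss <- gene_tss(genes)$tss[gi]
      center <- tss + round(runif(n_tss, -ps$tss_jitter, ps$tss_jitter))
      l2 <- len[seq.int(n - n_tss + 1L, n)]
      cl <- setNames(genome$length, genome$chrom)[genes$chrom[gi]]
      start <- pmin(pmax(center - l2 %/% 2, 0), cl - l2)
      near <- tibble(chrom = genes$chrom[gi], start = start,
                     end = start + l2, strand = "*")
      peaks <- dplyr::bind_rows(peaks, near)
    }
    peaks <- peaks[order(match(peaks$chrom, genome$chrom), peaks$start), ]
    peaks$name <- paste0("peak", seq_len(nrow(peaks)))

    genome_bp <- sum(genome$length)
    peak_bp <- sum(peaks$end - peaks$start)
    tf_names <- sprintf("TF%02d", seq_len(ts$n_tfs))
    enriched <- seq_len(ts$n_tfs) <= ts$n_enriched &
      ts$enrichment_factor > 1
    tfbs <- purrr::map_dfr(seq_len(ts$n_tfs), function(i) {
      base <- place_uniform(ts$sites_per_tf,
                            rep(ts$site_length, ts$sites_per_tf), genome)
      extra <- 0L
      if (enriched[i]) {
        expected_in <- ts$sites_per_tf * peak_bp / genome_bp
        extra <- round((ts$enrichment_factor - 1) * expected_in)
        if (extra > 0) {
          pk <- sample.int(nrow(peaks), extra, replace = TRUE,
                           prob = peaks$end - peaks$start)
          room <- pmax((peaks$end - peaks$start)[pk] - ts$site_length, 0)
          off <- floor(runif(extra) * (room + 1))
          planted <- tibble(chrom = peaks$chrom[pk],
                            start = peaks$start[pk] + off,
                            end = peaks$start[pk] + off + ts$site_length,
                            strand = "*")
          base <- dplyr::bind_rows(base, planted)
        }
      }
      base$name <- tf_names[i]
      base
    })
    meta <- tibble(tf = tf_names, enriched = enriched,
                   factor = ifelse(enriched, ts$enrichment_factor, 1),
                   n_sites = as.integer(table(factor(tfbs$name,
                                                     levels = tf_names))))
    list(peaks = peaks, tfbs = tfbs, meta = meta)
  })
}

#' Simulate a CIN-score signature over the gene universe
#'
#' Assigns every gene a standard-normal CIN score; the planted signature
#' gene set is the `n_sig` top-scoring genes, so up-regulating it in the
#' expression simulator creates genuine high-CIN enrichment.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene tibble.
#' @return List: `signature` (tibble `gene_id`, `score`),
#'   `signature_genes` (character vector, the planted set).
#' @export
simulate_signature <- function(cfg, genes) {
  withr::with_seed(sim_seed(cfg, 3L), {
    sig <- tibble(gene_id = genes$gene_id, score = rnorm(nrow(genes)))
    top <- sig$gene_id[order(-sig$score, sig$gene_id)]
    list(signature = sig,
         signature_genes = sort(utils::head(top, cfg$expression$n_sig)))
  })
}

#' Simulate a two-group expression study with planted CIN up-regulation
#'
#' Expression is log-normal around per-gene baselines: on log2 scale each
#' value is the gene baseline plus N(0, sigma) noise. In the second
#' ("rescue") group, signature genes are multiplied by `planted_fold`.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene tibble.
#' @param signature_genes Character vector of genes to up-regulate.
#' @return List: `expr` (tibble `gene_id` + sample columns), `groups`
#'   (tibble `sample`, `group` with groups `control`/`rescue`), `meta`
#'   (planted fold and gene set).
#' @export
simulate_expression <- function(cfg, genes, signature_genes) {
  es <- cfg$expression
  withr::with_seed(sim_seed(cfg, 4L), {
    ng <- nrow(genes)
    n_a <- es$group_sizes[1]
    n_b <- es$group_sizes[2]
    samples <- c(paste0("control_", seq_len(n_a)),
                 paste0("rescue_", seq_len(n_b)))
    base <- runif(ng, es$base_log2_range[1], es$base_log2_range[2])
    effect <- ifelse(genes$gene_id %in% signature_genes,
                     log2(es$planted_fold), 0)
    m <- matrix(rnorm(ng * (n_a + n_b), sd = es$sigma), nrow = ng)
    m <- m + base
    m[, seq.int(n_a + 1L, n_a + n_b)] <-
      m[, seq.int(n_a + 1L, n_a + n_b)] + effect
    expr <- as_tibble(setNames(as.data.frame(2^m), samples))
    expr <- dplyr::bind_cols(tibble(gene_id = genes$gene_id), expr)
    groups <- tibble(sample = samples,
                     group = rep(c("control", "rescue"), c(n_a, n_b)))
    list(expr = expr, groups = groups,
         meta = list(planted_fold = es$planted_fold,
                     signature_genes = signature_genes, sigma = es$sigma))
  })
}

#' Simulate per-metaphase karyotype counts
#'
#' Each sample mixes euploid and aneuploid metaphases at its configured
#' aneuploidy rate. Euploid counts sit at 2N or 4N (tetraploid with
#' probability `tetraploid_fraction`) jittered within the +/- tolerance
#' band; aneuploid counts are displaced beyond a band by a shifted
#' geometric offset (rate `dispersion`) on a random side, re-drawn if the
#' displacement happens to land inside the other euploid band.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: `sample_id`, `metaphase_id`, `chromosome_count`, and
#'   per-class rearrangement counts (`deletion`, `duplication`,
#'   `translocation`).
#' @export
simulate_karyotypes <- function(cfg) {
  ks <- cfg$karyotype
  withr::with_seed(sim_seed(cfg, 5L), {
    purrr::map_dfr(names(ks$rates), function(sm) {
      n <- ks$n_metaphases
      aneu <- runif(n) < ks$rates[[sm]]
      count <- integer(n)
      for (i in seq_len(n)) {
        base <- if (runif(1) < ks$tetraploid_fraction) 4L else 2L
        center <- base * ks$diploid_n / 2
        if (!aneu[i]) {
          count[i] <- center + sample(seq(-ks$tolerance, ks$tolerance), 1)
        } else {
          repeat {
            off <- (ks$tolerance + 1 + rgeom(1, ks$dispersion)) *
              sample(c(-1, 1), 1)
            cand <- center + off
            if (cand >= 1 &&
                classify_metaphase(cand, ks$diploid_n,
                                   ks$tolerance) == "aneuploid") {
              count[i] <- cand
              break
            }
          }
        }
      }
      lam <- ifelse(aneu, 0.5, 0.1)
      tibble(
        sample_id = sm, metaphase_id = seq_len(n),
        chromosome_count = count,
        deletion = stats::rpois(n, lam),
        duplication = stats::rpois(n, lam),
        translocation = stats::rpois(n, lam),
        aneuploid_truth = aneu
      )
    })
  })
}

#' Simulate two-arm tumor-free survival with end-of-study censoring
#'
#' Event times are exponential with the per-arm hazard; animals whose
#' latent time exceeds the study end day are censored on that day.
#'
#' @param cfg A [sim_config()].
#' @return Tibble: `arm`, `animal_id`, `time` (days), `event`
#'   (`"tumor"`/`"censored"`).
#' @export
simulate_survival <- function(cfg) {
  ss <- cfg$survival
  withr::with_seed(sim_seed(cfg, 6L), {
    purrr::map_dfr(names(ss$hazards), function(arm) {
      t_latent <- rexp(ss$n_per_arm, rate = ss$hazards[[arm]])
      censored <- t_latent > ss$censor_day
      tibble(
        arm = arm,
        animal_id = paste0(arm, "_", seq_len(ss$n_per_arm)),
        time = ifelse(censored, ss$censor_day, t_latent),
        event = ifelse(censored, "censored", "tumor")
      )
    })
  })
}

#' Simulate every pipeline input at once
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `genes`, `peaks`, `tfbs`, `tfbs_meta`,
#'   `signature`, `signature_genes`, `expr`, `groups`, `expression_meta`,
#'   `karyotypes`, `survival`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(cfg, genome)
  pt <- simulate_peaks_tfbs(cfg, genome, genes)
  sg <- simulate_signature(cfg, genes)
  ex <- simulate_expression(cfg, genes, sg$signature_genes)
  list(
    genome = genome, genes = genes,
    peaks = pt$peaks, tfbs = pt$tfbs, tfbs_meta = pt$meta,
    signature = sg$signature, signature_genes = sg$signature_genes,
    expr = ex$expr, groups = ex$groups, expression_meta = ex$meta,
    karyotypes = simulate_karyotypes(cfg),
    survival = simulate_survival(cfg)
  )
}
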