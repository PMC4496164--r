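#' Plot a TSS-relative interval profile
#'
#' @param profile A `tss_profile` from [tss_profile()].
#' @return A ggplot histogram of interval midpoints relative to the TSS.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(profile, "bin_size"),
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "intervals") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_tss_profile autoplot method.
#' @param object A `tss_profile`.
#' @param ... Unused.
#' @export
autoplot.tss_profile <- function(object, ...) plot_tss_profile(object)

#' Plot a permutation null distribution with the observed statistic
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot histogram of null counts with the observed count marked.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(count = object$null_counts),
                  ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, color = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "overlap count under shuffling null", y = "shuffles",
                  subtitle = paste0("observed = ", object$observed,
                                    ", p = ", signif(object$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' Plot a CIN-signature enrichment curve
#'
#' @param object A `cin_curve`.
#' @param ... Unused.
#' @return A ggplot of observed/expected enrichment against CIN-score rank.
#' @export
autoplot.cin_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rank, y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "rank by descending CIN score",
                  y = "observed / expected query genes") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier tumor-free survival curves
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of step survival curves per arm, with censor marks.
#' @export
autoplot.km_fit <- function(object, ...) {
  steps <- object$steps
  base <- dplyr::distinct(steps, .data$arm) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(base, steps[, c("arm", "time", "surv")])
  cens <- steps[steps$n_censor > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days", y = "tumor-free survival") +
    ggplot2::theme_minimal()
}

#' Scatter plot of metaphase chromosome counts with euploid bands
#'
#' Mirrors the standard presentation of per-metaphase counts: one jittered
#' column per sample with the expected 2N and 4N +/- tolerance bands shaded.
#'
#' @param karyo Karyotype tibble (`sample_id`, `chromosome_count`).
#' @param diploid_n,tolerance Classification parameters (see
#'   [classify_metaphase()]).
#' @return A ggplot.
#' @export
plot_karyotype_counts <- function(karyo, diploid_n = 40, tolerance = 2) {
  bands <- tibble(
    lo = c(diploid_n - tolerance, 2 * diploid_n - tolerance),
    hi = c(diploid_n + tolerance, 2 * diploid_n + tolerance)
  )
  karyo <- as_tibble(karyo)
  karyo$class <- classify_metaphase(karyo$chromosome_count, diploid_n,
                                    tolerance)
  ggplot2::ggplot(karyo, ggplot2::aes(x = .data$sample_id,
                                      y = .data$chromosome_count)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                       xmin = -Inf, xmax = Inf, fill = "grey85",
                       inherit.aes = FALSE) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$class), width = 0.15,
                         height = 0) +
    ggplot2::labs(x = NULL, y = "chromosomes per metaphase",
                  color = NULL) +
    ggplot2::theme_minimal()
}
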