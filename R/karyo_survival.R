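#' Classify metaphase chromosome counts as euploid or aneuploid
#'
#' A metaphase is euploid when its chromosome count lies within the expected
#' deviation around the diploid (2N) or tetraploid (4N) complement —
#' `[2N - tol, 2N + tol]` or `[4N - tol, 4N + tol]`, boundaries inclusive —
#' and aneuploid otherwise. The default `diploid_n = 40` is the mouse
#' complement; the default tolerance of +/- 2 chromosomes is the standard
#' allowance for counting error in metaphase spreads.
#'
#' @param count Integer vector of per-metaphase chromosome counts (>= 1).
#' @param diploid_n Diploid chromosome number 2N (default 40).
#' @param tolerance Allowed deviation in chromosomes (default 2).
#' @return Character vector, `"euploid"` or `"aneuploid"`.
#' @export
classify_metaphase <- function(count, diploid_n = 40, tolerance = 2) {
  if (any(count < 1)) abort("chromosome counts must be >= 1")
  eu <- (abs(count - diploid_n) <= tolerance) |
    (abs(count - 2 * diploid_n) <= tolerance)
  ifelse(eu, "euploid", "aneuploid")
}

#' Per-sample aneuploidy summary
#'
#' Applies [classify_metaphase()] to every metaphase and aggregates per
#' sample. Samples with fewer than 10 analyzed metaphases trigger a warning
#' (the conventional minimum for karyotype calls), not an error.
#'
#' @param karyo Tibble with columns `sample_id`, `chromosome_count`.
#' @inheritParams classify_metaphase
#' @return Tibble per sample: `n_metaphases`, `n_euploid`, `n_aneuploid`,
#'   `fraction_aneuploid`.
#' @export
aneuploidy_summary <- function(karyo, diploid_n = 40, tolerance = 2) {
  karyo <- as_tibble(karyo)
  if (!all(c("sample_id", "chromosome_count") %in% names(karyo))) {
    abort("karyotype table needs sample_id, chromosome_count columns")
  }
  if (!nrow(karyo)) abort("karyotype table is empty")
  karyo$class <- classify_metaphase(karyo$chromosome_count, diploid_n,
                                    tolerance)
  out <- karyo |>
    dplyr::group_by(sample_id = .data$sample_id) |>
    dplyr::summarise(
      n_metaphases = dplyr::n(),
      n_euploid = sum(.data$class == "euploid"),
      n_aneuploid = sum(.data$class == "aneuploid"),
      fraction_aneuploid = .data$n_aneuploid / .data$n_metaphases,
      .groups = "drop"
    )
  low <- out$sample_id[out$n_metaphases < 10]
  if (length(low)) {
    warn(paste0("fewer than 10 metaphases for sample(s): ",
                paste(low, collapse = ", ")))
  }
  out
}

#' Normal/abnormal karyotype contingency table
#'
#' @param summary Output of [aneuploidy_summary()].
#' @return Integer matrix (samples x normal/abnormal), rows summing to each
#'   sample's metaphase count, ready for [chisq_association()].
#' @export
karyotype_contingency <- function(summary) {
  m <- cbind(normal = summary$n_euploid, abnormal = summary$n_aneuploid)
  rownames(m) <- summary$sample_id
  m
}

#' Pearson chi-square test of association
#'
#' Classical Pearson X^2 = sum (O - E)^2 / E on an r x c contingency table,
#' without continuity correction, df = (r - 1)(c - 1).
#'
#' @param tab Matrix or data frame of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chisq_association <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) <= 0) abort("contingency table total must be > 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has an empty row or column")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Fisher's exact test on a 2 x 2 contingency table
#'
#' Two-sided p by the probability-mass rule (sum of hypergeometric
#' probabilities of all tables with the same margins and probability no
#' greater than the observed table's), the convention of
#' [stats::fisher.test()]. The tail-doubling rule (twice the smaller
#' one-sided tail, capped at 1) is available with `method = "doubling"`.
#'
#' @param tab 2 x 2 matrix or data frame of non-negative counts.
#' @param method `"probability"` (default) or `"doubling"`.
#' @return One-row tibble: `p_value`, `odds_ratio` (conditional MLE, NA for
#'   the doubling rule), `method`.
#' @export
fisher_exact_2x2 <- function(tab, method = c("probability", "doubling")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("fisher_exact_2x2 requires a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("empty margin in 2x2 table; p = 1")
    return(tibble(p_value = 1, odds_ratio = NA_real_, method = method))
  }
  if (method == "probability") {
    ft <- fisher.test(tab)
    return(tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
                  method = method))
  }
  # doubling rule: 2 * min(one-sided tails) via the hypergeometric
  k <- tab[1, 1]
  K <- sum(tab[1, ])
  n <- sum(tab[, 1])
  N <- sum(tab)
  lower <- phyper(k, K, N - K, n)
  upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(p_value = min(1, 2 * min(lower, upper)),
         odds_ratio = NA_real_, method = method)
}

# event column -> 0/1 indicator (1 = event occurred). Accepts labels such
# as "tumor"/"censored", logicals, or 0/1 numerics.
as_event_indicator <- function(event) {
  if (is.numeric(event)) {
    if (!all(event %in% c(0, 1))) abort("numeric event must be 0/1")
    return(as.integer(event))
  }
  if (is.logical(event)) return(as.integer(event))
  ev <- tolower(as.character(event))
  out <- rep(NA_integer_, length(ev))
  out[ev %in% c("tumor", "event", "dead", "death", "yes", "1", "true")] <- 1L
  out[ev %in% c("censored", "censor", "alive", "no", "0", "false")] <- 0L
  if (anyNA(out)) abort("unrecognized event labels")
  out
}

#' Kaplan-Meier tumor-free survival estimate
#'
#' Product-limit estimator per arm, with right-censoring (animals alive
#' without tumor at the study end are censored on that day).
#'
#' @param surv Tibble with columns `arm`, `time` (days, > 0), `event`
#'   (`"tumor"`/`"censored"`, logical, or 0/1).
#' @return A `km_fit`: list with the underlying [survival::survfit()] object
#'   (`fit`) and a tidy per-timepoint tibble (`steps`: `arm`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`).
#' @export
km_estimate <- function(surv) {
  surv <- as_tibble(surv)
  if (!all(c("arm", "time", "event") %in% names(surv))) {
    abort("survival table needs arm, time, event columns")
  }
  if (any(surv$time <= 0)) abort("survival times must be > 0")
  status <- as_event_indicator(surv$event)
  d <- data.frame(arm = as.character(surv$arm), time = surv$time,
                  status = status)
  fit <- survival::survfit(survival::Surv(time, status) ~ arm, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(unique(d$arm), length(fit$time))
  } else {
    rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  }
  steps <- tibble(
    arm = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv
  )
  structure(list(fit = fit, steps = steps, data = d), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return The per-timepoint step tibble.
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' Log-rank comparison of survival arms
#'
#' Standard log-rank test ([survival::survdiff()]), with the hypergeometric
#' variance correction for tied event times. With no events in either arm
#' the statistic is undefined and reported as `NA`.
#'
#' @param surv Survival tibble as in [km_estimate()].
#' @param arm_a,arm_b Optional pair of arm labels to restrict the
#'   comparison to (default: all arms).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(surv, arm_a = NULL, arm_b = NULL) {
  surv <- as_tibble(surv)
  if (!is.null(arm_a)) surv <- surv[surv$arm %in% c(arm_a, arm_b), ]
  status <- as_event_indicator(surv$event)
  n_arms <- length(unique(surv$arm))
  if (n_arms < 2) abort("need >= 2 arms to compare")
  if (sum(status) == 0) {
    return(tibble(statistic = NA_real_, df = n_arms - 1, p_value = NA_real_,
                  n = nrow(surv), n_events = 0L))
  }
  d <- data.frame(arm = as.character(surv$arm), time = surv$time,
                  status = status)
  sd <- survival::survdiff(survival::Surv(time, status) ~ arm, data = d)
  tibble(
    statistic = sd$chisq,
    df = n_arms - 1,
    p_value = pchisq(sd$chisq, df = n_arms - 1, lower.tail = FALSE),
    n = nrow(surv),
    n_events = sum(status)
  )
}

#' ChIP-qPCR relative fold enrichment
#'
#' Computes `2^-(Ct_input - Ct_IgG)`: the relative abundance of
#' immunoprecipitated DNA versus the IgG control, from raw cycle-threshold
#' values.
#'
#' @param ct_input,ct_igg Finite positive Ct values (vectorized).
#' @return Numeric fold enrichment.
#' @export
qpcr_fold_enrichment <- function(ct_input, ct_igg) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_igg)) ||
      any(ct_input <= 0) || any(ct_igg <= 0)) {
    abort("Ct values must be finite and > 0")
  }
  2^(-(ct_input - ct_igg))
}
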