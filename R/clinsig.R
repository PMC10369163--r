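#' High-end-state functioning proportion
#'
#' Jacobson-Truax high-end-state functioning for a depression outcome: the
#' fraction of non-missing endpoint scores inside the none-to-minimal band
#' (BDI-II 0-13, boundary inclusive). An arm with no non-missing scores is
#' reported with `n = 0` and an `NA` proportion.
#'
#' @param score Numeric endpoint scores.
#' @param arm Arm labels, same length as `score`.
#' @param threshold Upper bound of the high-end-state band (default 13).
#' @return data.frame with columns `arm`, `n`, `n_high_end`, `proportion`.
#' @export
high_end_state_proportion <- function(score, arm, threshold = 13) {
  stopifnot(length(score) == length(arm))
  out <- do.call(rbind, lapply(unique(arm), function(a) {
    s <- score[arm == a & !is.na(score)]
    n <- length(s)
    k <- sum(s >= 0 & s <= threshold)
    data.frame(arm = a, n = n, n_high_end = k,
               proportion = if (n == 0) NA_real_ else k / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Jacobson-Truax reliable change index
#'
#' `RCI = (post - pre) / S_diff` with
#' `S_diff = sqrt(2 * (sd_pre * sqrt(1 - reliability))^2)`: the standard
#' error of the difference between two scores from an instrument with the
#' given baseline spread and reliability. `|RCI| > 1.96` marks change
#' reliable at 95% confidence.
#'
#' @param pre,post Scores (vectors recycle as usual).
#' @param sd_pre Baseline standard deviation of the instrument (> 0).
#' @param reliability Reliability estimate in \[0, 1), typically the baseline
#'   Cronbach's alpha.
#' @return Signed RCI value(s).
#' @examples
#' reliable_change_index(20, 10, sd_pre = 10, reliability = 0.5) # -1
#' @export
reliable_change_index <- function(pre, post, sd_pre, reliability) {
  if (!is_scalar_number(sd_pre) || sd_pre <= 0)
    lcs_stop("sd_pre must be positive", "lcs_range_error")
  if (!is_scalar_number(reliability) || reliability >= 1 || reliability < 0)
    lcs_stop("reliability must lie in [0, 1)", "lcs_degenerate_error")
  (post - pre) / rci_sdiff(sd_pre, reliability)
}

#' @rdname reliable_change_index
#' @export
rci_sdiff <- function(sd_pre, reliability) {
  sqrt(2 * (sd_pre * sqrt(1 - reliability))^2)
}

#' Between-group Cohen's d on change scores
#'
#' `d = (mean change, treatment - mean change, control) / pooled SD`, with
#' the SD pooled over the two groups using `n - 1` weights. An alternative
#' denominator, the control-plus-treatment baseline SD, is available for
#' sensitivity (`denominator = "baseline"` with `baseline` supplied).
#'
#' @param changes_treatment,changes_control Numeric change scores per arm
#'   (baseline-to-endpoint), at least 2 non-missing each.
#' @param denominator `"pooled"` (default) or `"baseline"`.
#' @param baseline Baseline scores of all participants (both arms), required
#'   for the `"baseline"` denominator.
#' @return Scalar d (negative when treatment decreases more).
#' @export
cohens_d <- function(changes_treatment, changes_control,
                     denominator = c("pooled", "baseline"), baseline = NULL) {
  denominator <- match.arg(denominator)
  x <- changes_treatment[!is.na(changes_treatment)]
  y <- changes_control[!is.na(changes_control)]
  if (length(x) < 2 || length(y) < 2)
    lcs_stop("both groups need at least 2 non-missing values",
             "lcs_data_error")
  s <- if (denominator == "pooled") {
    sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
           (length(x) + length(y) - 2))
  } else {
    if (is.null(baseline))
      lcs_stop("baseline scores required for the baseline denominator",
               "lcs_config_error")
    stats::sd(baseline, na.rm = TRUE)
  }
  if (!is.finite(s) || s <= 0)
    lcs_stop("degenerate (zero) denominator for Cohen's d",
             "lcs_degenerate_error")
  (mean(x) - mean(y)) / s
}

#' Clinical-significance summary for a trial table
#'
#' Combines the endpoint severity distribution, high-end-state proportions,
#' per-participant reliable change indices (with the group mean-change RCI
#' reported alongside, both labeled), and the between-group Cohen's d on
#' baseline-to-endpoint changes.
#'
#' @param table Wide trial data.frame.
#' @param outcome Outcome scale name (default `"bdi"`).
#' @param endpoint_wave Wave index of the endpoint (default 3).
#' @param reliability Reliability estimate used for the RCI (e.g. baseline
#'   Cronbach's alpha).
#' @param spec Instrument spec used for severity bands.
#' @return A list of class `clinsig_summary`.
#' @export
clinical_significance <- function(table, outcome = "bdi", endpoint_wave = 3,
                                  reliability = 0.83,
                                  spec = default_instruments()$bdi) {
  pre <- table[[paste0(outcome, "_0")]]
  post <- table[[paste0(outcome, "_", endpoint_wave)]]
  arm_lab <- ifelse(table$arm == 1, "treatment", "control")
  sd_pre <- stats::sd(pre, na.rm = TRUE)
  rci_ind <- (post - pre) / rci_sdiff(sd_pre, reliability)
  chg <- post - pre
  grp_mean_change <- tapply(chg, arm_lab, mean, na.rm = TRUE)
  structure(list(
    severity = severity_distribution(post, arm_lab, spec = spec),
    high_end_state = high_end_state_proportion(post, arm_lab),
    rci_individual = data.frame(id = table$id, arm = arm_lab, rci = rci_ind),
    rci_group = c(treatment = unname(grp_mean_change["treatment"]) /
                    rci_sdiff(sd_pre, reliability),
                  control = unname(grp_mean_change["control"]) /
                    rci_sdiff(sd_pre, reliability)),
    reliability = reliability, sd_pre = sd_pre,
    cohens_d = cohens_d(chg[table$arm == 1], chg[table$arm == 0]),
    endpoint_wave = endpoint_wave),
    class = "clinsig_summary")
}

#' @export
print.clinsig_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Clinical significance at wave %d (reliability %.2f, baseline SD %.2f)\n",
              x$endpoint_wave, x$reliability, x$sd_pre))
  cat(sprintf("Cohen's d (pooled change SD): %.2f\n", x$cohens_d))
  cat(sprintf("Group mean-change RCI: treatment %.2f, control %.2f\n",
              x$rci_group["treatment"], x$rci_group["control"]))
  cat("High-end-state functioning:\n")
  print(x$high_end_state, row.names = FALSE)
  cat("Severity distribution (%):\n")
  hs <- x$severity
  hs$percent <- round(hs$percent, 1)
  print(hs, row.names = FALSE)
  invisible(x)
}
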