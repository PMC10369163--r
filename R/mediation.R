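#' Indirect, total, and percent-mediated summaries
#'
#' Pure path arithmetic: each mediator's indirect effect is `a * b`, the
#' combined indirect is their sum, the total effect adds the direct effect
#' `c_prime`, and percent mediated is `100 * indirect / total` (per mediator
#' and combined). When the total effect is exactly zero the percentages are
#' flagged undefined (`NA` with `undefined_percent = TRUE`) rather than
#' raising an error, so batch summaries keep flowing.
#'
#' @param a,b Numeric vectors of a- and b-path estimates, one per mediator
#'   (scalars for a single-mediator model).
#' @param c_prime Direct-effect estimate.
#' @return List with `indirect`, `combined_indirect`, `total`,
#'   `percent_mediated` (per mediator), `percent_combined`, and
#'   `undefined_percent`.
#' @examples
#' indirect_summary(7.03, -0.75, -4.01) # the behavioral-activation block
#' @export
indirect_summary <- function(a, b, c_prime) {
  stopifnot(length(a) == length(b))
  indirect <- a * b
  combined <- sum(indirect)
  total <- combined + c_prime
  undefined <- total == 0
  pct <- if (undefined) rep(NA_real_, length(indirect)) else
    100 * indirect / total
  list(indirect = indirect, combined_indirect = combined, total = total,
       percent_mediated = pct,
       percent_combined = if (undefined) NA_real_ else 100 * combined / total,
       undefined_percent = undefined)
}

#' Bias-corrected bootstrap confidence interval
#'
#' Resamples whole participants (rows) with replacement, recomputes the
#' statistic on each draw, and forms the bias-corrected percentile interval:
#' the bias constant `z0` is the standard-normal quantile of the fraction of
#' draws below the full-sample statistic (draws exactly equal to it count
#' half, the usual mid-p convention), and the interval endpoints sit at the
#' bootstrap-distribution quantiles `pnorm(2*z0 + qnorm((1-level)/2))` and
#' `pnorm(2*z0 + qnorm(1-(1-level)/2))`. No acceleration constant is used
#' (bias correction only). Degenerate fractions of 0 or 1 are clamped to
#' `1/(draws+1)` and `draws/(draws+1)` with a warning. Draws on which the
#' statistic fails (e.g. a singular refit) are dropped and counted.
#'
#' @param statistic Function mapping a table (data.frame) to a numeric
#'   scalar or vector.
#' @param table Data.frame of participant rows to resample.
#' @param draws Number of bootstrap draws.
#' @param level Confidence level.
#' @param seed Integer seed; identical seed and draws give identical
#'   intervals.
#' @param stratify_by Optional column name; resampling is then done within
#'   the levels of that column (e.g. `"arm"`). Default unstratified.
#' @return An object of class `bc_bootstrap`: data.frame `intervals`
#'   (`component`, `estimate`, `low`, `high`, `z0`), plus `draws`,
#'   `failed_draws`, `level`, `seed`.
#' @export
bc_bootstrap_ci <- function(statistic, table, draws = 10000, level = 0.95,
                            seed = NULL, stratify_by = NULL) {
  if (draws < 1) lcs_stop("draws must be >= 1", "lcs_config_error")
  obs <- statistic(table)
  k <- length(obs)
  comp <- names(obs) %||% paste0("stat", seq_len(k))
  n <- nrow(table)
  strata_idx <- if (is.null(stratify_by)) list(seq_len(n)) else
    split(seq_len(n), table[[stratify_by]])
  stats <- with_seed(seed, {
    t(vapply(seq_len(draws), function(d) {
      idx <- unlist(lapply(strata_idx, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE)
      out <- tryCatch(statistic(table[idx, , drop = FALSE]),
                      error = function(e) rep(NA_real_, k))
      if (length(out) != k) rep(NA_real_, k) else as.numeric(out)
    }, numeric(k)))
  })
  stats <- matrix(stats, ncol = k)
  ok <- stats::complete.cases(stats)
  failed <- sum(!ok)
  if (failed == draws)
    lcs_stop("all bootstrap draws failed", "lcs_bootstrap_error")
  stats <- stats[ok, , drop = FALSE]
  m <- nrow(stats)
  alpha <- (1 - level) / 2
  rows <- lapply(seq_len(k), function(j) {
    frac <- (sum(stats[, j] < obs[j]) + 0.5 * sum(stats[, j] == obs[j])) / m
    if (frac <= 0 || frac >= 1) {
      warning("bootstrap distribution entirely on one side of the estimate; ",
              "bias constant clamped")
      frac <- min(max(frac, 1 / (m + 1)), m / (m + 1))
    }
    z0 <- stats::qnorm(frac)
    p_lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
    p_hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
    q <- stats::quantile(stats[, j], c(p_lo, p_hi), names = FALSE, type = 7)
    data.frame(component = comp[j], estimate = unname(obs[j]),
               low = q[1], high = q[2], z0 = z0, stringsAsFactors = FALSE)
  })
  structure(list(intervals = do.call(rbind, rows), draws = draws,
                 failed_draws = failed, level = level, seed = seed),
            class = "bc_bootstrap")
}

#' @export
print.bc_bootstrap <- function(x, digits = 3, ...) {
  cat(sprintf("<bc_bootstrap> %d draws (%d failed), %.0f%% level\n",
              x$draws, x$failed_draws, 100 * x$level))
  print(cbind(component = x$intervals$component,
              round(x$intervals[-1], digits)), row.names = FALSE)
  invisible(x)
}

## Complete-case analysis frame shared by the mediation fitters.
mediation_frame <- function(table, mediators, outcome, mediator_window,
                            outcome_window) {
  f <- data.frame(arm = table$arm)
  f$trt_c <- table$arm - mean(table$arm)
  f[[paste0(outcome, "_0")]] <- table[[paste0(outcome, "_0")]]
  for (m in mediators) {
    f[[paste0(m, "_0")]] <- table[[paste0(m, "_0")]]
    f[[paste0("d_", m)]] <- compute_change_scores(table, m,
                                                  mediator_window[1],
                                                  mediator_window[2])
  }
  f[[paste0("d_", outcome)]] <- compute_change_scores(table, outcome,
                                                      outcome_window[1],
                                                      outcome_window[2])
  f[stats::complete.cases(f), , drop = FALSE]
}

## Fast bootstrap statistic over a prebuilt frame: refits the a-equations
## and the outcome equation with .lm.fit and returns the indirect effects
## (per mediator, plus the combined sum when there are several mediators).
indirect_statistic <- function(mediators, outcome, baselines) {
  a_terms <- "trt_c"
  function(f) {
    n <- nrow(f)
    Xbase <- cbind(1, f$trt_c, as.matrix(f[baselines]))
    a_hat <- vapply(mediators, function(m)
      .lm.fit(Xbase, f[[paste0("d_", m)]])$coefficients[2], numeric(1))
    Xb <- cbind(as.matrix(f[paste0("d_", mediators)]), Xbase)
    cf <- .lm.fit(Xb, f[[paste0("d_", outcome)]])$coefficients
    b_hat <- cf[seq_along(mediators)]
    ind <- a_hat * b_hat
    if (length(mediators) > 1) {
      out <- c(ind, sum(ind))
      names(out) <- c(paste0("indirect_", mediators), "indirect_combined")
    } else {
      out <- ind
      names(out) <- paste0("indirect_", mediators)
    }
    out
  }
}

#' Single-mediator change-score mediation
#'
#' Fits the two-equation mediation system on baseline-to-endpoint change
#' scores: the mediator change is regressed on the centered treatment plus
#' the baseline mediator and baseline outcome (the `a` path); the outcome
#' change is regressed on the mediator change (`b` path), the centered
#' treatment (`c'` path), and the same baselines. The indirect effect `a*b`
#' gets a bias-corrected bootstrap interval via [bc_bootstrap_ci()].
#' Default change windows are baseline to 3 months for both mediator and
#' outcome.
#'
#' @param table Wide trial data.frame.
#' @param mediator Mediator scale name (e.g. `"bads"`).
#' @param outcome Outcome scale name (default `"bdi"`).
#' @param mediator_window,outcome_window Length-2 wave windows `c(from, to)`.
#' @param draws Bootstrap draws (the trial used 10,000); `0` skips the
#'   bootstrap.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @param se SE convention passed to [fit_equation()].
#' @param stratified Resample within arms? Default `FALSE`.
#' @return An object of class `mediation_fit` with the `a`/`b`/`c'` path
#'   tables, the indirect/total/percent summary, and the bootstrap interval.
#' @export
fit_single_mediator <- function(table, mediator, outcome = "bdi",
                                mediator_window = c(0, 3),
                                outcome_window = c(0, 3),
                                draws = 10000, level = 0.95, seed = 1,
                                se = "ml", stratified = FALSE) {
  f <- mediation_frame(table, mediator, outcome, mediator_window,
                       outcome_window)
  baselines <- c(paste0(mediator, "_0"), paste0(outcome, "_0"))
  eq_a <- fit_equation(f, paste0("d_", mediator), c("trt_c", baselines),
                       se = se, level = level)
  eq_b <- fit_equation(f, paste0("d_", outcome),
                       c(paste0("d_", mediator), "trt_c", baselines),
                       se = se, level = level)
  a_hat <- eq_a$paths$estimate[eq_a$paths$term == "trt_c"]
  b_hat <- eq_b$paths$estimate[eq_b$paths$term == paste0("d_", mediator)]
  c_hat <- eq_b$paths$estimate[eq_b$paths$term == "trt_c"]
  summ <- indirect_summary(a_hat, b_hat, c_hat)
  boot <- NULL
  if (draws > 0)
    boot <- bc_bootstrap_ci(indirect_statistic(mediator, outcome, baselines),
                            f, draws = draws, level = level, seed = seed,
                            stratify_by = if (stratified) "arm" else NULL)
  structure(list(mediators = mediator, outcome = outcome,
                 mediator_window = mediator_window,
                 outcome_window = outcome_window,
                 a = stats::setNames(a_hat, mediator),
                 b = stats::setNames(b_hat, mediator), c_prime = c_hat,
                 equations = list(a = eq_a, outcome = eq_b),
                 summary = summ, boot = boot, n = nrow(f), level = level),
            class = "mediation_fit")
}

#' Multi-mediator change-score mediation
#'
#' Fits one a-equation per mediator (mediator change on centered treatment
#' plus all baseline covariates) and a single outcome equation containing
#' every mediator change, the centered treatment, and the baselines.
#' Independent indirect effects are `a_j * b_j`; the combined indirect is
#' their sum; the total effect adds `c'`. Following the trial's multiple-
#' mediator specification, the default mediator window is baseline to
#' 2 months and the outcome window baseline to 3 months.
#'
#' @inheritParams fit_single_mediator
#' @param mediators Character vector of mediator scale names.
#' @return An object of class `mediation_fit`; the bootstrap covers each
#'   independent indirect plus the combined indirect.
#' @export
fit_multiple_mediator <- function(table, mediators = c("bads", "cds", "ptq"),
                                  outcome = "bdi",
                                  mediator_window = c(0, 2),
                                  outcome_window = c(0, 3),
                                  draws = 10000, level = 0.95, seed = 1,
                                  se = "ml", stratified = FALSE) {
  f <- mediation_frame(table, mediators, outcome, mediator_window,
                       outcome_window)
  baselines <- c(paste0(mediators, "_0"), paste0(outcome, "_0"))
  eqs_a <- lapply(mediators, function(m)
    fit_equation(f, paste0("d_", m), c("trt_c", baselines), se = se,
                 level = level))
  names(eqs_a) <- mediators
  eq_b <- fit_equation(f, paste0("d_", outcome),
                       c(paste0("d_", mediators), "trt_c", baselines),
                       se = se, level = level)
  a_hat <- vapply(mediators, function(m) {
    p <- eqs_a[[m]]$paths
    p$estimate[p$term == "trt_c"]
  }, numeric(1))
  b_hat <- vapply(mediators, function(m)
    eq_b$paths$estimate[eq_b$paths$term == paste0("d_", m)], numeric(1))
  c_hat <- eq_b$paths$estimate[eq_b$paths$term == "trt_c"]
  summ <- indirect_summary(a_hat, b_hat, c_hat)
  boot <- NULL
  if (draws > 0)
    boot <- bc_bootstrap_ci(indirect_statistic(mediators, outcome, baselines),
                            f, draws = draws, level = level, seed = seed,
                            stratify_by = if (stratified) "arm" else NULL)
  structure(list(mediators = mediators, outcome = outcome,
                 mediator_window = mediator_window,
                 outcome_window = outcome_window,
                 a = a_hat, b = b_hat, c_prime = c_hat,
                 equations = c(stats::setNames(eqs_a, paste0("a_", mediators)),
                               list(outcome = eq_b)),
                 summary = summ, boot = boot, n = nrow(f), level = level),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, digits = 2, ...) {
  multi <- length(x$mediators) > 1
  cat(sprintf("Change-score mediation: %s -> %s (n = %d)\n",
              paste(x$mediators, collapse = " + "), x$outcome, x$n))
  cat(sprintf("Windows: mediator %d->%d, outcome %d->%d\n",
              x$mediator_window[1], x$mediator_window[2],
              x$outcome_window[1], x$outcome_window[2]))
  for (m in x$mediators)
    cat(sprintf("  a (%s): %8.2f   b (%s): %6.2f   indirect: %6.2f\n",
                m, x$a[m], m, x$b[m],
                x$summary$indirect[match(m, x$mediators)]))
  cat(sprintf("  c': %.2f   %s indirect: %.2f   total: %.2f\n",
              x$c_prime, if (multi) "combined" else "",
              x$summary$combined_indirect, x$summary$total))
  pc <- x$summary$percent_combined
  cat(sprintf("  percent mediated%s: %s\n",
              if (multi) " (combined)" else "",
              if (is.na(pc)) "undefined (total = 0)" else
                sprintf("%.1f%%", pc)))
  if (!is.null(x$boot)) {
    cat(sprintf("  bias-corrected bootstrap (%d draws, %d failed):\n",
                x$boot$draws, x$boot$failed_draws))
    print(cbind(component = x$boot$intervals$component,
                round(x$boot$intervals[-1], digits)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.mediation_fit <- function(x, ...) {
  rows <- do.call(rbind, lapply(names(x$equations), function(nm) {
    p <- x$equations[[nm]]$paths
    cbind(equation = nm, p, n = x$equations[[nm]]$n)
  }))
  rows
}
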