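#' Compute wave-to-wave change scores
#'
#' With every autoregression between adjacent waves fixed to 1 and a
#' unit-loading latent difference factor on the later wave, the latent
#' change score of a single-indicator construct is algebraically the
#' observed difference `score(to) - score(from)`. The change is missing if
#' either endpoint is missing.
#'
#' @param table Wide trial data.frame with `<variable>_<wave>` columns.
#' @param variable Scale name, e.g. `"bdi"`.
#' @param from,to Wave indices with `from < to`.
#' @return Numeric vector of per-participant changes.
#' @export
compute_change_scores <- function(table, variable, from, to) {
  if (!(from < to))
    lcs_stop("change-score spec requires from < to", "lcs_spec_error")
  cols <- paste0(variable, "_", c(from, to))
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0)
    lcs_stop(paste("unknown wave column(s):", paste(miss, collapse = ", ")),
             "lcs_spec_error")
  table[[cols[2]]] - table[[cols[1]]]
}

#' Center predictors and report the constants
#'
#' Subtracts each variable's observed mean (or an externally supplied
#' constant, e.g. the pretreatment mean for later-wave depression levels) so
#' that regression intercepts are interpretable as the change for a
#' participant at average pretreatment levels, averaged across arms. With
#' 1/0 arm coding this turns the arm column into the trial's centered
#' contrast (e.g. 0.51 / -0.49 for a 50:53 split).
#'
#' @param table Data.frame.
#' @param variables Character vector of column names to center.
#' @param at Optional named numeric vector of centering constants; variables
#'   not named here are centered on their own observed mean.
#' @return List with `table` (centered copy) and `constants` (named vector
#'   of the means that were subtracted).
#' @export
center_predictors <- function(table, variables, at = NULL) {
  constants <- numeric(0)
  for (v in variables) {
    if (!v %in% names(table))
      lcs_stop(paste("unknown variable:", v), "lcs_spec_error")
    ctr <- if (!is.null(at) && v %in% names(at)) unname(at[[v]]) else
      mean(table[[v]], na.rm = TRUE)
    if (!is.finite(ctr))
      lcs_stop(paste("cannot center all-missing variable:", v),
               "lcs_centering_error")
    table[[v]] <- table[[v]] - ctr
    constants[v] <- ctr
  }
  list(table = table, constants = constants)
}

#' Fit one change-score regression equation
#'
#' Solves the least-squares normal equations for `response ~ predictors`
#' (an intercept is always included) via a rank-revealing QR decomposition.
#' Standard errors follow either the maximum-likelihood convention
#' (residual variance over `n`, matching typical structural-equation
#' software) or the least-squares convention (over `n - p`); `z = est/SE`,
#' two-sided p-values come from the standard normal, and the Wald interval
#' is `est +/- z_{1-(1-level)/2} * SE`.
#'
#' @param data Data.frame holding the (already centered) analysis columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param se `"ml"` (default) or `"ols"` residual-variance denominator.
#' @param policy Missing-data policy: `"listwise"` (default; drop rows with
#'   any missing analysis variable) or `"fiml"` (full-information maximum
#'   likelihood under a multivariate-normal model, see [mvn_fiml()]).
#' @param level Confidence level for the Wald intervals.
#' @return An object of class `lcs_equation`: list with `paths` (data.frame
#'   `term`, `estimate`, `se`, `z`, `p`, `ci_lo`, `ci_hi`), `n`, `policy`,
#'   `se_type`, `sigma2`.
#' @export
fit_equation <- function(data, response, predictors,
                         se = c("ml", "ols"), policy = c("listwise", "fiml"),
                         level = 0.95) {
  se <- match.arg(se)
  policy <- match.arg(policy)
  vars <- c(response, predictors)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0)
    lcs_stop(paste("unknown variable(s):", paste(miss, collapse = ", ")),
             "lcs_spec_error")
  if (anyDuplicated(predictors) > 0)
    lcs_stop("duplicate predictors", "lcs_spec_error")

  if (policy == "fiml") {
    fit <- fiml_equation(data, response, predictors, level = level)
    fit$se_type <- "fiml"
    return(fit)
  }

  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  p <- length(predictors) + 1L
  if (n < p + 1)
    lcs_stop(sprintf("only %d usable rows for %d parameters", n, p),
             "lcs_data_error")
  X <- cbind(`(Intercept)` = 1, as.matrix(d[predictors]))
  y <- d[[response]]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    lcs_stop(paste("rank-deficient design; collinear predictor(s):",
                   paste(dropped, collapse = ", ")), "lcs_singular_error")
  }
  R <- qr.R(qr_x)
  if (kappa(R, exact = FALSE) > 1e12)
    lcs_stop("near-singular design (condition number above 1e12)",
             "lcs_singular_error")
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / if (se == "ml") n else (n - p)
  xtx_inv <- chol2inv(R[, order(qr_x$pivot), drop = FALSE][order(qr_x$pivot), ,
                                                           drop = FALSE])
  ses <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  build_equation(colnames(X), beta, ses, n, policy, se, sigma2, level)
}

## Assemble the path table shared by the listwise and FIML routes.
build_equation <- function(terms, beta, ses, n, policy, se_type, sigma2,
                           level) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- ifelse(ses > 0, beta / ses, NA_real_)
  paths <- data.frame(
    term = terms, estimate = unname(beta), se = unname(ses),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    ci_lo = unname(beta - zq * ses), ci_hi = unname(beta + zq * ses),
    stringsAsFactors = FALSE)
  structure(list(paths = paths, n = n, policy = policy, se_type = se_type,
                 sigma2 = sigma2, level = level),
            class = "lcs_equation")
}

#' @export
print.lcs_equation <- function(x, digits = 3, ...) {
  cat(sprintf("<lcs_equation> n = %d, policy = %s, SE = %s\n",
              x$n, x$policy, x$se_type))
  print(cbind(term = x$paths$term,
              round(x$paths[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Fit the four-wave latent change score model
#'
#' Reproduces the trial's efficacy-model layout: a baseline-balance equation
#' regressing the centered baseline level on the centered treatment
#' indicator, followed by one equation per monthly change, each controlling
#' for the centered treatment, the prior-month level, and the pretreatment
#' level (all depression levels centered on the pretreatment mean so that
#' intercepts read as the change from the previous month for a participant
#' with average pretreatment depression, averaged over arms).
#'
#' @param table Wide trial data.frame (`arm` coded 1/0, `<outcome>_<wave>`
#'   columns for waves 0-3).
#' @param outcome Scale name of the outcome (default `"bdi"`).
#' @param se,policy,level Passed to [fit_equation()].
#' @return An object of class `lcs_model`: list of `lcs_equation`s
#'   (`baseline`, `change_0_1`, `change_1_2`, `change_2_3`), plus the
#'   centering constants used.
#' @export
fit_change_model <- function(table, outcome = "bdi", se = "ml",
                             policy = "listwise", level = 0.95) {
  waves <- paste0(outcome, "_", 0:3)
  miss <- setdiff(waves, names(table))
  if (length(miss) > 0)
    lcs_stop(paste("missing wave column(s):", paste(miss, collapse = ", ")),
             "lcs_spec_error")
  if (any(is.na(table[[waves[1]]])))
    lcs_stop("baseline outcome must be non-missing", "lcs_data_error")

  pre_mean <- mean(table[[waves[1]]], na.rm = TRUE)
  d <- table
  d$trt_c <- d$arm - mean(d$arm)
  ## all depression levels centered on the pretreatment mean
  for (w in 0:2) d[[paste0("lvl_", w)]] <- d[[waves[w + 1]]] - pre_mean
  for (w in 0:2) d[[paste0("chg_", w, "_", w + 1)]] <-
    compute_change_scores(table, outcome, w, w + 1)

  eqs <- list(
    baseline   = fit_equation(d, "lvl_0", "trt_c", se = se, policy = policy,
                              level = level),
    change_0_1 = fit_equation(d, "chg_0_1", c("trt_c", "lvl_0"), se = se,
                              policy = policy, level = level),
    change_1_2 = fit_equation(d, "chg_1_2", c("trt_c", "lvl_1", "lvl_0"),
                              se = se, policy = policy, level = level),
    change_2_3 = fit_equation(d, "chg_2_3", c("trt_c", "lvl_2", "lvl_0"),
                              se = se, policy = policy, level = level))
  structure(list(equations = eqs, outcome = outcome,
                 centering = c(pretreatment_mean = pre_mean,
                               treatment_mean = mean(table$arm)),
                 policy = policy, se_type = se),
            class = "lcs_model")
}

#' @export
print.lcs_model <- function(x, digits = 2, ...) {
  cat(sprintf("Latent change score model for '%s' (policy %s, %s SEs)\n",
              x$outcome, x$policy, x$se_type))
  cat(sprintf("Centered treatment: %.2f / %.2f (treatment / control)\n",
              1 - x$centering["treatment_mean"],
              -x$centering["treatment_mean"]))
  for (nm in names(x$equations)) {
    cat("\n==", nm, sprintf("(n = %d) ==\n", x$equations[[nm]]$n))
    print(cbind(term = x$equations[[nm]]$paths$term,
                round(x$equations[[nm]]$paths[-1], digits)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.lcs_model <- function(x, ...) {
  do.call(rbind, lapply(names(x$equations), function(nm) {
    p <- x$equations[[nm]]$paths
    cbind(equation = nm, p, n = x$equations[[nm]]$n,
          policy = x$equations[[nm]]$policy,
          se_type = x$equations[[nm]]$se_type)
  }))
}
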