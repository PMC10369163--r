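#' Stratified permuted-block randomization
#'
#' Allocates participants 1:1 to treatment (1) and control (0) within strata
#' (typically sex), using permuted blocks of a fixed even size: each block is
#' an independent uniformly random permutation of `block_size/2` copies of
#' each arm, so every complete block splits exactly evenly. The assignment is
#' a deterministic function of `(strata, block_size, seed)`; strata are
#' processed in sorted label order so input order of participants within a
#' stratum is what determines their block position.
#'
#' @param strata Vector of stratum labels (e.g. `"female"` / `"male"`), one
#'   per participant.
#' @param block_size Even block size; the trial design uses 10.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return Integer vector of arm codes (1 = treatment, 0 = control) in the
#'   input participant order.
#' @examples
#' table(stratified_block_randomize(rep("f", 10), block_size = 10, seed = 1))
#' @export
stratified_block_randomize <- function(strata, block_size = 10, seed = NULL) {
  if (!is_scalar_number(block_size) || block_size < 2 ||
      block_size %% 2 != 0)
    lcs_stop("block_size must be a positive even integer", "lcs_config_error")
  strata <- as.character(strata)
  arm <- integer(length(strata))
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      n_blocks <- ceiling(length(idx) / block_size)
      alloc <- unlist(lapply(seq_len(n_blocks), function(b)
        sample(rep(c(1L, 0L), each = block_size / 2))))
      arm[idx] <- alloc[seq_along(idx)]
    }
  })
  arm
}

#' Structural parameters of the synthetic trial
#'
#' Defines the ground-truth data-generating model: treatment shifts each
#' mediator's baseline-to-3-month change by its `a` path; the depression
#' change responds to each mediator change through its `b` path and to
#' treatment directly through `c_prime`. Total changes are apportioned across
#' the three monthly intervals by `wave_weights` (largest change in month 1,
#' mirroring the trial's observed pattern), with interval residuals scaled so
#' the total-change residual spread equals `residual_sd`.
#'
#' Default effect sizes are deliberately mild enough that simulated
#' trajectories rarely reach the instrument floors/ceilings, so the
#' structural paths remain directly recoverable by the fitting engine; see
#' the methods vignette for the rationale and the values.
#'
#' @param outcome List describing the depression outcome: `name`,
#'   `baseline_mean`, `baseline_sd`, `eligibility_min` (baseline floor
#'   enforcing at-least-moderate severity), `change_mean` (mean total change
#'   under control), `residual_sd`.
#' @param mediators Named list of mediator descriptions, each with
#'   `baseline_mean`, `baseline_sd`, `change_mean`, `a`, `b`, `residual_sd`,
#'   and optionally its own `wave_weights`.
#' @param c_prime Direct treatment effect on the depression total change.
#' @param wave_weights Length-3 non-negative weights summing to 1.
#' @return An object of class `structural_parameters`.
#' @export
structural_parameters <- function(outcome, mediators, c_prime,
                                  wave_weights = c(0.55, 0.20, 0.25)) {
  check_w <- function(w, who) {
    if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      lcs_stop(sprintf("wave weights for %s must be 3 non-negative values summing to 1",
                       who), "lcs_config_error")
  }
  check_w(wave_weights, "the trial")
  if (outcome$residual_sd < 0)
    lcs_stop("residual spreads must be non-negative", "lcs_config_error")
  for (nm in names(mediators)) {
    m <- mediators[[nm]]
    if (m$residual_sd < 0)
      lcs_stop("residual spreads must be non-negative", "lcs_config_error")
    if (!is.null(m$wave_weights)) check_w(m$wave_weights, nm)
  }
  structure(list(outcome = outcome, mediators = mediators,
                 c_prime = c_prime, wave_weights = wave_weights),
            class = "structural_parameters")
}

#' @rdname structural_parameters
#' @export
default_structural_parameters <- function() {
  structural_parameters(
    outcome = list(name = "bdi", baseline_mean = 33, baseline_sd = 6.5,
                   eligibility_min = 20, change_mean = -7, residual_sd = 5.5),
    mediators = list(
      bads = list(baseline_mean = 18, baseline_sd = 7, change_mean = 2,
                  a = 7, b = -0.25, residual_sd = 7),
      cds  = list(baseline_mean = 45, baseline_sd = 9, change_mean = -3,
                  a = -12, b = 0.05, residual_sd = 8),
      ptq  = list(baseline_mean = 42, baseline_sd = 8, change_mean = -3,
                  a = -8, b = 0.20, residual_sd = 7)),
    c_prime = -3.5)
}

#' Configure a synthetic two-arm trial
#'
#' Bundles the design quantities of the emulated trial: 103 participants,
#' 1:1 allocation stratified by sex in permuted blocks of 10, an 84.5% female
#' sample, four assessment waves (baseline and 1, 2, 3 months), and per-wave
#' follow-up retention.
#'
#' @param n Number of participants.
#' @param allocation Intended arm ratio; only 1:1 is supported.
#' @param female_fraction Probability a participant is female.
#' @param block_size Randomization block size (even).
#' @param retention Length-3 vector of per-wave retention probabilities for
#'   the 1-, 2-, and 3-month assessments.
#' @param structural A [structural_parameters()] object.
#' @param truncation Optional named list of `c(min, max)` score bounds per
#'   variable; defaults to the instrument ranges in [default_instruments()].
#' @param seed Integer trial-level seed; operation-level streams are derived
#'   from it by fixed offsets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 103, allocation = c(1, 1), female_fraction = 0.845,
                       block_size = 10, retention = c(0.97, 0.96, 0.97),
                       structural = default_structural_parameters(),
                       truncation = NULL, seed = 1) {
  if (!is_scalar_number(n) || n < 1)
    lcs_stop("n must be a positive integer", "lcs_config_error")
  if (length(allocation) != 2 || allocation[1] != allocation[2])
    lcs_stop("only 1:1 allocation is supported", "lcs_config_error")
  if (female_fraction < 0 || female_fraction > 1)
    lcs_stop("female_fraction must be in [0, 1]", "lcs_config_error")
  if (any(retention < 0) || any(retention > 1) || length(retention) != 3)
    lcs_stop("retention must be 3 probabilities in [0, 1]", "lcs_config_error")
  if (block_size %% 2 != 0)
    lcs_stop("block_size must be even for 1:1 allocation", "lcs_config_error")
  if (is.null(truncation)) {
    reg <- default_instruments()
    vars <- c(structural$outcome$name, names(structural$mediators))
    truncation <- lapply(vars, function(v) {
      s <- reg[[v]]
      if (is.null(s)) lcs_stop(sprintf(
        "no default score bounds for '%s'; supply `truncation`", v),
        "lcs_config_error")
      c(s$score_min, s$score_max)
    })
    names(truncation) <- vars
  }
  structure(list(n = as.integer(n), allocation = allocation,
                 female_fraction = female_fraction,
                 block_size = as.integer(block_size), retention = retention,
                 structural = structural, truncation = truncation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Exact truncated-normal sampler via inverse CDF (no rejection loop).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-6)
    lcs_stop(sprintf(
      "infeasible truncation: [%g, %g] carries almost no mass under N(%g, %g)",
      lo, hi, mean, sd), "lcs_config_error")
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

clip_round <- function(x, bounds) pmin(pmax(round(x), bounds[1]), bounds[2])

#' Generate a complete synthetic trial
#'
#' Draws sex, randomizes arms by stratified permuted blocks, draws truncated
#' baseline scores (depression baselines respect the eligibility floor), and
#' then builds the three monthly interval changes so that the total
#' baseline-to-3-month changes follow the structural model
#' `d_mediator = change_mean + a * T + noise` and
#' `d_depression = change_mean + sum(b * d_mediator) + c_prime * T + noise`.
#' Interval `i` receives weight `w_i` of each systematic change and an
#' independent residual with spread `sqrt(w_i) * residual_sd`, so the total
#' residual spread is exactly `residual_sd`. Observed wave scores accumulate
#' the interval changes, rounded and clipped to the instrument bounds.
#'
#' @param config A [sim_config()].
#' @param apply_retention Drop follow-up waves per `config$retention`?
#'   Default `TRUE`; use `FALSE` for complete-data studies.
#' @return A list of class `lcs_trial` with elements `data` (wide trial
#'   data.frame), `truth` (exact parameters used, plus implied per-mediator
#'   indirect effects, the combined indirect, the total effect, and the
#'   direct effect implied for single-mediator fits), and `config`.
#' @export
generate_trial <- function(config, apply_retention = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$structural
  n <- config$n
  out_v <- st$outcome$name
  meds <- names(st$mediators)

  sex <- with_seed(derive_seed(config$seed, 1),
                   ifelse(stats::runif(n) < config$female_fraction,
                          "female", "male"))
  arm <- stratified_block_randomize(sex, config$block_size,
                                    seed = derive_seed(config$seed, 2))

  tab <- data.frame(id = seq_len(n), arm = arm, sex = sex,
                    stringsAsFactors = FALSE)

  with_seed(derive_seed(config$seed, 3), {
    ob <- config$truncation[[out_v]]
    lo0 <- max(ob[1], st$outcome$eligibility_min %||% ob[1])
    y <- clip_round(rtruncnorm(n, st$outcome$baseline_mean,
                               st$outcome$baseline_sd, lo0, ob[2]),
                    c(lo0, ob[2]))
    m <- lapply(meds, function(k) {
      d <- st$mediators[[k]]
      bk <- config$truncation[[k]]
      clip_round(stats::rnorm(n, d$baseline_mean, d$baseline_sd), bk)
    })
    names(m) <- meds
    tab[[paste0(out_v, "_0")]] <- y
    for (k in meds) tab[[paste0(k, "_0")]] <- m[[k]]

    for (i in 1:3) {
      dm <- lapply(meds, function(k) {
        d <- st$mediators[[k]]
        w <- (d$wave_weights %||% st$wave_weights)[i]
        w * (d$change_mean + d$a * arm) +
          stats::rnorm(n, 0, sqrt(w) * d$residual_sd)
      })
      names(dm) <- meds
      w_y <- st$wave_weights[i]
      b_sum <- Reduce(`+`, Map(function(k) st$mediators[[k]]$b * dm[[k]], meds),
                      accumulate = FALSE)
      dy <- w_y * (st$outcome$change_mean + st$c_prime * arm) + b_sum +
        stats::rnorm(n, 0, sqrt(w_y) * st$outcome$residual_sd)
      for (k in meds) {
        m[[k]] <- clip_round(m[[k]] + dm[[k]], config$truncation[[k]])
        tab[[paste0(k, "_", i)]] <- m[[k]]
      }
      y <- clip_round(y + dy, config$truncation[[out_v]])
      tab[[paste0(out_v, "_", i)]] <- y
    }
  })

  if (apply_retention)
    tab <- apply_missingness(tab, config$retention,
                             seed = derive_seed(config$seed, 4))

  ab <- vapply(meds, function(k)
    st$mediators[[k]]$a * st$mediators[[k]]$b, numeric(1))
  cum_w2 <- sum(st$wave_weights[1:2])
  truth <- list(
    a = vapply(meds, function(k) st$mediators[[k]]$a, numeric(1)),
    b = vapply(meds, function(k) st$mediators[[k]]$b, numeric(1)),
    c_prime = st$c_prime,
    indirect = ab,
    combined_indirect = sum(ab),
    total_effect = sum(ab) + st$c_prime,
    ## single-mediator fits absorb the other mediators' indirect paths into
    ## the direct effect:
    c_prime_single = st$c_prime + sum(ab) - ab,
    ## mediator changes measured over waves 0->2 carry this fraction of a:
    a_wave2 = vapply(meds, function(k) {
      d <- st$mediators[[k]]
      d$a * sum((d$wave_weights %||% st$wave_weights)[1:2])
    }, numeric(1)),
    wave_weights = st$wave_weights, structural = st)
  structure(list(data = tab, truth = truth, config = config),
            class = "lcs_trial")
}

#' @export
print.lcs_trial <- function(x, ...) {
  cat(sprintf("<lcs_trial> %d participants (%d treatment / %d control), %s\n",
              nrow(x$data), sum(x$data$arm == 1), sum(x$data$arm == 0),
              paste(names(x$truth$a), collapse = "/")))
  invisible(x)
}

#' Impose wave-specific attrition
#'
#' Each participant independently misses each follow-up assessment with
#' probability `1 - retention[wave]`; a missed wave blanks every scale score
#' at that wave. Baseline is never removed. With `monotone = TRUE`, a missed
#' wave also blanks all later waves (drop-out rather than intermittent
#' missingness).
#'
#' @param table Wide trial data.frame.
#' @param retention Length-3 vector of retention probabilities for waves 1-3.
#' @param seed Integer seed.
#' @param monotone Enforce monotone drop-out? Default `FALSE`.
#' @return The table with follow-up scores set to `NA` where missed.
#' @export
apply_missingness <- function(table, retention, seed = NULL,
                              monotone = FALSE) {
  if (any(retention < 0) || any(retention > 1) || length(retention) != 3)
    lcs_stop("retention must be 3 probabilities in [0, 1]", "lcs_config_error")
  n <- nrow(table)
  miss <- with_seed(seed, vapply(1:3, function(i)
    stats::runif(n) > retention[i], logical(n)))
  miss <- matrix(miss, nrow = n)
  if (monotone)
    for (i in 2:3) miss[, i] <- miss[, i] | miss[, i - 1]
  for (i in 1:3) {
    cols <- grep(paste0("_", i, "$"), names(table), value = TRUE)
    for (cl in cols) table[[cl]][miss[, i]] <- NA
  }
  table
}
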