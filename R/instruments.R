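#' Define a sum-score instrument
#'
#' An instrument is a fixed-length questionnaire whose items share one integer
#' response range and whose total score is the plain item sum. Severity bands
#' partition the total-score range into closed integer intervals
#' (e.g. the BDI-II's none-to-minimal / mild / moderate / severe cut-offs).
#'
#' @param name Short identifier, e.g. `"bdi"`.
#' @param n_items Number of items (positive integer).
#' @param item_min,item_max Integer response range shared by all items.
#' @param bands Optional data.frame with columns `label`, `low`, `high`
#'   giving non-overlapping closed integer intervals that together cover the
#'   full total-score range. Defaults to a single band spanning the range.
#' @return An object of class `instrument_spec`.
#' @examples
#' bdi <- default_instruments()$bdi
#' bdi$bands
#' @export
instrument_spec <- function(name, n_items, item_min, item_max, bands = NULL) {
  if (!is_scalar_number(n_items) || n_items < 1 || n_items != round(n_items))
    lcs_stop("n_items must be a positive integer", "lcs_config_error")
  if (!is_scalar_number(item_min) || !is_scalar_number(item_max) ||
      item_min >= item_max)
    lcs_stop("item range requires item_min < item_max", "lcs_config_error")
  lo <- n_items * item_min
  hi <- n_items * item_max
  if (is.null(bands)) {
    bands <- data.frame(label = "total", low = lo, high = hi,
                        stringsAsFactors = FALSE)
  }
  bands <- bands[order(bands$low), , drop = FALSE]
  rownames(bands) <- NULL
  if (bands$low[1] != lo || bands$high[nrow(bands)] != hi ||
      any(bands$low > bands$high) ||
      (nrow(bands) > 1 && any(bands$low[-1] != bands$high[-nrow(bands)] + 1)))
    lcs_stop(sprintf(
      "bands for '%s' must be non-overlapping closed intervals covering [%d, %d]",
      name, lo, hi), "lcs_config_error")
  structure(list(name = name, n_items = as.integer(n_items),
                 item_min = as.integer(item_min), item_max = as.integer(item_max),
                 score_min = as.integer(lo), score_max = as.integer(hi),
                 bands = bands),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items scored %d-%d (total %d-%d)\n",
              x$name, x$n_items, x$item_min, x$item_max, x$score_min, x$score_max))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Registry of the five trial instruments
#'
#' Scale metadata for the depression outcome and screen plus the three
#' mechanism-of-change questionnaires:
#' \describe{
#'   \item{bdi}{BDI-II, 21 items scored 0-3 (total 0-63), with the standard
#'     severity bands none-to-minimal 0-13, mild 14-19, moderate 20-28,
#'     severe 29-63.}
#'   \item{phq9}{PHQ-9 depression screen, 9 items scored 0-3 (total 0-27).}
#'   \item{bads}{Behavioral Activation for Depression Scale, Short Form,
#'     9 items scored 0-6 (total 0-54); higher = more activation.}
#'   \item{ptq}{Perseverative Thinking Questionnaire, 15 items scored 0-4
#'     (total 0-60); higher = more repetitive negative thinking.}
#'   \item{cds}{Cognitive Distortions Scale, 10 thinking biases rated 0-7
#'     (total 0-70); higher = more distortion. The published response anchors
#'     ("0 = never" through "7 = all the time") describe 8 response options;
#'     the range is configurable via [instrument_spec()] if a 1-7 coding is
#'     preferred.}
#' }
#' @return Named list of `instrument_spec` objects.
#' @export
default_instruments <- function() {
  bdi_bands <- data.frame(
    label = c("none-to-minimal", "mild", "moderate", "severe"),
    low = c(0L, 14L, 20L, 29L), high = c(13L, 19L, 28L, 63L),
    stringsAsFactors = FALSE)
  list(
    bdi  = instrument_spec("bdi", 21, 0, 3, bands = bdi_bands),
    phq9 = instrument_spec("phq9", 9, 0, 3),
    bads = instrument_spec("bads", 9, 0, 6),
    ptq  = instrument_spec("ptq", 15, 0, 4),
    cds  = instrument_spec("cds", 10, 0, 7)
  )
}

#' Bundle item-level responses for one instrument at one wave
#'
#' @param responses Integer matrix or data.frame, participants in rows and
#'   items in columns. `NA` marks a missing response.
#' @param instrument An [instrument_spec()].
#' @param ids Optional participant identifiers (default `1:nrow`).
#' @param wave Wave label (default `NA`).
#' @return An object of class `item_response_table`.
#' @export
item_response_table <- function(responses, instrument, ids = NULL, wave = NA) {
  stopifnot(inherits(instrument, "instrument_spec"))
  m <- as.matrix(responses)
  storage.mode(m) <- "double"
  if (ncol(m) != instrument$n_items)
    lcs_stop(sprintf("'%s' expects %d items, got %d columns",
                     instrument$name, instrument$n_items, ncol(m)),
             "lcs_validation_error")
  ids <- ids %||% seq_len(nrow(m))
  bad <- which(!is.na(m) & (m < instrument$item_min | m > instrument$item_max |
                              m != round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    lcs_stop(sprintf(
      "out-of-range response for participant %s, item %d: value %s (allowed %d-%d)",
      ids[i], j, format(m[i, j]), instrument$item_min, instrument$item_max),
      "lcs_validation_error")
  }
  dimnames(m) <- list(NULL, paste0("item", seq_len(ncol(m))))
  structure(list(ids = ids, wave = wave, responses = m, instrument = instrument),
            class = "item_response_table")
}

#' Sum item responses into total scores
#'
#' A participant with any missing item gets a missing total by default (no
#' prorating). With `impute_missing = TRUE`, a participant's missing items
#' are replaced by the mean of their observed items and the prorated sum is
#' rounded to the nearest integer; participants with no observed items stay
#' missing either way.
#'
#' @param items An [item_response_table()].
#' @param impute_missing Prorate scales with missing items? Default `FALSE`.
#' @return data.frame with columns `id`, `wave`, `instrument`, `score`, `band`.
#' @export
score_scale <- function(items, impute_missing = FALSE) {
  stopifnot(inherits(items, "item_response_table"))
  m <- items$responses
  n_miss <- rowSums(is.na(m))
  score <- rowSums(m)
  if (impute_missing) {
    part <- which(n_miss > 0 & n_miss < ncol(m))
    for (i in part) {
      score[i] <- round(mean(m[i, ], na.rm = TRUE) * ncol(m))
    }
  }
  spec <- items$instrument
  data.frame(id = items$ids, wave = items$wave, instrument = spec$name,
             score = score, band = band_label(score, spec),
             stringsAsFactors = FALSE)
}

## Map total scores to severity-band labels (NA-safe, vectorized).
band_label <- function(score, spec) {
  b <- spec$bands
  idx <- vapply(score, function(s) {
    if (is.na(s)) return(NA_integer_)
    which(b$low <= s & s <= b$high)[1]
  }, integer(1))
  b$label[idx]
}

#' Classify a BDI-II total score into a severity band
#'
#' Cut-offs: 0-13 none-to-minimal, 14-19 mild, 20-28 moderate, 29-63 severe.
#' Boundaries are inclusive (13 is none-to-minimal, 28 is moderate).
#'
#' @param score Integer vector of BDI-II totals in \[0, 63\].
#' @return Character vector of band labels (`NA` for missing scores).
#' @examples
#' classify_bdi_severity(c(13, 14, 29))
#' @export
classify_bdi_severity <- function(score) {
  spec <- default_instruments()$bdi
  ok <- is.na(score) | (score >= spec$score_min & score <= spec$score_max)
  if (!all(ok))
    lcs_stop(sprintf("BDI-II score out of range [0, 63]: %s",
                     paste(score[!ok], collapse = ", ")), "lcs_range_error")
  band_label(score, spec)
}

#' PHQ-9 eligibility screen
#'
#' Eligibility requires a PHQ-9 total of at least 10 (at least moderate
#' depressive symptom severity).
#'
#' @param score Integer vector of PHQ-9 totals in \[0, 27\].
#' @return Logical vector.
#' @export
phq9_eligible <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 27)
  if (!all(ok))
    lcs_stop(sprintf("PHQ-9 score out of range [0, 27]: %s",
                     paste(score[!ok], collapse = ", ")), "lcs_range_error")
  score >= 10
}

#' Cronbach's alpha internal consistency
#'
#' Computes `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`
#' on complete cases (rows with any missing item are dropped, matching the
#' covariance requirements of the formula).
#'
#' @param items An [item_response_table()] or a numeric matrix
#'   (participants x items).
#' @return Scalar alpha (at most 1; can be negative).
#' @examples
#' m <- cbind(c(0, 1, 2, 3), c(1, 2, 3, 4))
#' cronbach_alpha(m) # parallel items -> 1
#' @export
cronbach_alpha <- function(items) {
  m <- if (inherits(items, "item_response_table")) items$responses else
    as.matrix(items)
  if (ncol(m) < 2)
    lcs_stop("Cronbach's alpha requires at least 2 items", "lcs_arity_error")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2)
    lcs_stop("Cronbach's alpha requires at least 2 complete rows",
             "lcs_arity_error")
  tot_var <- stats::var(rowSums(m))
  if (tot_var <= 0)
    lcs_stop("total-score variance is zero; alpha undefined",
             "lcs_undefined_alpha_error")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / tot_var)
}

#' Per-arm severity-band distribution
#'
#' Tabulates, per trial arm, the percentage of non-missing scores falling in
#' each severity band (denominator = non-missing scores in that arm). An arm
#' with no non-missing scores is reported explicitly with `n = 0` and `NA`
#' percentages rather than triggering a division by zero.
#'
#' @param score Numeric vector of total scores (NA = missing).
#' @param arm Vector of arm labels, same length as `score`.
#' @param spec Instrument whose bands are used; defaults to the BDI-II.
#' @return data.frame with columns `arm`, `band`, `n`, `percent`.
#' @export
severity_distribution <- function(score, arm,
                                  spec = default_instruments()$bdi) {
  stopifnot(length(score) == length(arm))
  bad <- !is.na(score) & (score < spec$score_min | score > spec$score_max)
  if (any(bad))
    lcs_stop("scores outside the instrument's total range", "lcs_range_error")
  arms <- unique(arm)
  out <- do.call(rbind, lapply(arms, function(a) {
    s <- score[arm == a & !is.na(score)]
    n <- length(s)
    pct <- if (n == 0) rep(NA_real_, nrow(spec$bands)) else
      vapply(seq_len(nrow(spec$bands)), function(i)
        100 * sum(s >= spec$bands$low[i] & s <= spec$bands$high[i]) / n,
        numeric(1))
    data.frame(arm = a, band = spec$bands$label, n = n, percent = pct,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
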