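#' Build the intervention message schedule
#'
#' Places messages on every `cadence_days`-th day of the treatment period
#' (starting day 1), groups the treatment days into consecutive "weeks" of
#' equal length matching `weekly_counts`, splits each week's message count as
#' evenly as possible across its treatment days (largest-remainder), and
#' allocates response prompts across days proportionally to the daily message
#' counts (largest-remainder again), so both totals are conserved exactly.
#'
#' The defaults encode the trial's dose: 474 texts over a 64-day period,
#' delivered every other day (32 treatment days, a mean of 14.8 texts per
#' treatment day), with weekly counts 62, 72, 62, 57, 55, 53, 59, 54 and 198
#' response prompts in total.
#'
#' @param total_messages Total number of intervention texts.
#' @param period_days Length of the treatment period in days.
#' @param cadence_days Days between treatment days (2 = every other day).
#' @param weekly_counts Integer message counts per week; must sum to
#'   `total_messages`.
#' @param total_prompts Total number of response prompts across the period.
#' @return An object of class `message_schedule`: a list with `days`
#'   (data.frame `day`, `week`, `messages`, `prompts`) and the configured
#'   totals.
#' @examples
#' sched <- build_message_schedule()
#' nrow(sched$days)                  # 32 treatment days
#' round(mean(sched$days$messages), 1) # 14.8
#' @export
build_message_schedule <- function(total_messages = 474, period_days = 64,
                                   cadence_days = 2,
                                   weekly_counts = c(62, 72, 62, 57, 55, 53, 59, 54),
                                   total_prompts = 198) {
  if (sum(weekly_counts) != total_messages)
    lcs_stop(sprintf("weekly counts sum to %d, not the configured total %d",
                     sum(weekly_counts), total_messages), "lcs_config_error")
  days <- seq(1, period_days, by = cadence_days)
  n_days <- length(days)
  n_weeks <- length(weekly_counts)
  if (n_days < n_weeks)
    lcs_stop("period has fewer treatment days than weeks", "lcs_config_error")
  ## consecutive groups of treatment days, as even as possible
  per_week <- largest_remainder(n_days, rep(1, n_weeks))
  week <- rep(seq_len(n_weeks), per_week)
  messages <- unlist(lapply(seq_len(n_weeks), function(w)
    largest_remainder(weekly_counts[w], rep(1, per_week[w]))))
  prompts <- largest_remainder(total_prompts, messages)
  structure(list(days = data.frame(day = days, week = week,
                                   messages = messages, prompts = prompts),
                 total_messages = as.integer(total_messages),
                 total_prompts = as.integer(total_prompts),
                 period_days = as.integer(period_days),
                 cadence_days = as.integer(cadence_days)),
            class = "message_schedule")
}

#' @export
print.message_schedule <- function(x, ...) {
  cat(sprintf(
    "<message_schedule> %d messages / %d prompts over %d treatment days (%d-day period, every %d days)\n",
    x$total_messages, x$total_prompts, nrow(x$days), x$period_days,
    x$cadence_days))
  cat(sprintf("mean messages per treatment day: %.1f\n",
              mean(x$days$messages)))
  invisible(x)
}

#' Simulate participant engagement with the message stream
#'
#' Each participant responds to each day's prompts independently with their
#' response propensity (binomial per day), and is a completer when their
#' total response count reaches `completion_threshold`. The trial's printed
#' completion rule is responding to at least 192 of the 198 prompts.
#'
#' @param schedule A [build_message_schedule()] result.
#' @param response_propensity Probability of responding to a prompt; scalar
#'   or one value per participant.
#' @param completion_threshold Responses needed to count as a completer.
#' @param seed Integer seed.
#' @return A list of class `engagement` with `responses` (participants x
#'   days integer matrix) and `summary` (data.frame `id`, `total_responses`,
#'   `completer`).
#' @export
simulate_engagement <- function(schedule, response_propensity,
                                completion_threshold = 192, seed = NULL) {
  stopifnot(inherits(schedule, "message_schedule"))
  p <- response_propensity
  if (any(p < 0) || any(p > 1))
    lcs_stop("response_propensity must be in [0, 1]", "lcs_config_error")
  if (completion_threshold > schedule$total_prompts)
    lcs_stop(sprintf("completion threshold %d exceeds total prompts %d",
                     completion_threshold, schedule$total_prompts),
             "lcs_config_error")
  n <- length(p)
  prompts <- schedule$days$prompts
  resp <- with_seed(seed, t(vapply(seq_len(n), function(i)
    stats::rbinom(length(prompts), prompts, p[i]), integer(length(prompts)))))
  total <- rowSums(resp)
  structure(list(responses = resp,
                 summary = data.frame(id = seq_len(n), total_responses = total,
                                      completer = total >= completion_threshold)),
            class = "engagement")
}
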