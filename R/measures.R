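#' The six NASA-TLX subscales, in canonical order
#'
#' @format Character vector of length 6.
#' @export
TLX_SUBSCALES <- c("mental", "physical", "temporal", "performance",
                   "effort", "frustration")

#' NASA-TLX subscale ratings
#'
#' The six-subscale workload instrument: mental demand, physical demand,
#' temporal demand, own performance, effort, and frustration, each rated on
#' a 0-100 scale.
#'
#' @param ratings Named numeric vector over the six subscales, each in
#'   `[0, 100]`. Names may be in any order; the result is stored in
#'   canonical subscale order.
#' @return An object of class `tlx_rating`.
#' @export
#' @examples
#' tlx_rating(c(mental = 40, physical = 10, temporal = 30,
#'              performance = 20, effort = 35, frustration = 15))
tlx_rating <- function(ratings) {
  if (!is.numeric(ratings) || length(ratings) != 6L ||
      !setequal(names(ratings), TLX_SUBSCALES)) {
    abort_sr(sprintf("ratings must be a numeric vector named %s",
                     paste(TLX_SUBSCALES, collapse = ", ")),
             "sr_validation_error")
  }
  ratings <- ratings[TLX_SUBSCALES]
  if (anyNA(ratings) || any(ratings < 0) || any(ratings > 100)) {
    abort_sr("every TLX rating must lie in [0, 100]", "sr_validation_error")
  }
  structure(as.numeric(ratings), names = TLX_SUBSCALES, class = "tlx_rating")
}

#' NASA-TLX subscale weights
#'
#' Importance weights over the six subscales; each weight is the number of
#' the subscale's wins among the 15 pairwise comparisons, so weights are
#' integers in 0-5 summing to 15.
#'
#' @param weights Named integer vector over the six subscales.
#' @return An object of class `tlx_weights`.
#' @export
tlx_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 6L ||
      !setequal(names(weights), TLX_SUBSCALES)) {
    abort_sr(sprintf("weights must be a numeric vector named %s",
                     paste(TLX_SUBSCALES, collapse = ", ")),
             "sr_validation_error")
  }
  weights <- weights[TLX_SUBSCALES]
  if (anyNA(weights) || any(weights != round(weights)) ||
      any(weights < 0) || any(weights > 5)) {
    abort_sr("every TLX weight must be an integer in 0..5", "sr_validation_error")
  }
  if (sum(weights) != 15) {
    abort_sr(sprintf("TLX weights must sum to 15 (one per pairwise comparison); got %g",
                     sum(weights)), "sr_validation_error")
  }
  structure(as.integer(weights), names = TLX_SUBSCALES, class = "tlx_weights")
}

#' Derive TLX weights from the 15 pairwise comparisons
#'
#' The weighting step of the NASA-TLX procedure: the respondent judges, for
#' each of the 15 unordered pairs of subscales, which member contributed
#' more to workload. A subscale's weight is the number of pairs it wins.
#'
#' @param pair_choices A data frame with columns `a`, `b`, `winner` (all
#'   subscale names), one row per unordered pair; all 15 pairs must appear
#'   exactly once and each winner must be a member of its pair.
#' @return A [tlx_weights()].
#' @export
#' @examples
#' # strict ranking: mental > physical > temporal > performance > effort > frustration
#' pairs <- t(utils::combn(TLX_SUBSCALES, 2))
#' choices <- data.frame(a = pairs[, 1], b = pairs[, 2], winner = pairs[, 1])
#' tlx_weights_from_pairs(choices)  # weights 5,4,3,2,1,0
tlx_weights_from_pairs <- function(pair_choices) {
  req <- c("a", "b", "winner")
  if (!is.data.frame(pair_choices) || !all(req %in% names(pair_choices))) {
    abort_sr("pair_choices must be a data frame with columns a, b, winner",
             "sr_validation_error")
  }
  if (nrow(pair_choices) != 15L) {
    abort_sr(sprintf("exactly 15 pairwise choices are required; got %d",
                     nrow(pair_choices)), "sr_validation_error")
  }
  problems <- character()
  key <- character(nrow(pair_choices))
  for (i in seq_len(nrow(pair_choices))) {
    a <- pair_choices$a[i]; b <- pair_choices$b[i]; w <- pair_choices$winner[i]
    if (!a %in% TLX_SUBSCALES || !b %in% TLX_SUBSCALES || a == b) {
      problems <- c(problems, sprintf("row %d: ('%s', '%s') is not a subscale pair", i, a, b))
      next
    }
    key[i] <- paste(sort(c(a, b)), collapse = "|")
    if (!w %in% c(a, b)) {
      problems <- c(problems, sprintf("row %d: winner '%s' is not in pair ('%s', '%s')",
                                      i, w, a, b))
    }
  }
  dup <- duplicated(key) & nzchar(key)
  if (any(dup)) {
    problems <- c(problems, sprintf("duplicate pair(s): %s",
                                    paste(unique(key[dup]), collapse = ", ")))
  }
  all_pairs <- apply(utils::combn(TLX_SUBSCALES, 2), 2,
                     function(p) paste(sort(p), collapse = "|"))
  missing <- setdiff(all_pairs, key)
  if (length(missing)) {
    problems <- c(problems, sprintf("missing pair(s): %s", paste(missing, collapse = ", ")))
  }
  if (length(problems)) {
    abort_sr(paste0("invalid pairwise choices:\n", paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  tally <- table(factor(pair_choices$winner, levels = TLX_SUBSCALES))
  tlx_weights(stats::setNames(as.integer(tally), TLX_SUBSCALES))
}

#' Overall weighted NASA-TLX workload score
#'
#' The overall workload score is the weighted average of the six subscale
#' ratings, with the pairwise-comparison weights summing to 15:
#' `sum(weight * rating) / 15`, on the same 0-100 scale as the ratings.
#'
#' @param ratings A [tlx_rating()].
#' @param weights A [tlx_weights()]; defaults to equal-importance weights
#'   obtained by rating (not recommended - pass real pairwise weights).
#' @param weighted If `FALSE`, return the raw (unweighted) mean of the six
#'   ratings instead.
#' @return Workload score in `[0, 100]`.
#' @export
#' @examples
#' r <- tlx_rating(c(mental = 10, physical = 20, temporal = 30,
#'                   performance = 40, effort = 50, frustration = 60))
#' w <- tlx_weights(c(mental = 5, physical = 4, temporal = 3,
#'                    performance = 2, effort = 1, frustration = 0))
#' tlx_score(r, w)  # 350/15 = 23.33
tlx_score <- function(ratings, weights, weighted = TRUE) {
  if (!inherits(ratings, "tlx_rating")) ratings <- tlx_rating(ratings)
  if (!weighted) return(mean(unclass(ratings)))
  if (!inherits(weights, "tlx_weights")) weights <- tlx_weights(weights)
  sum(as.numeric(weights) * as.numeric(ratings)) / 15
}

#' Average response time of a session
#'
#' Mean time between question presentation and the participant's selection
#' of an answer choice, over all answered trials (correct or wrong).
#' Timeout trials are excluded: no choice was selected.
#'
#' @param log A `session_log`.
#' @return Mean response latency in seconds.
#' @export
avg_response_time <- function(log) {
  stopifnot(inherits(log, "session_log"))
  lat <- log$trials$response_latency_s[log$trials$outcome %in% c("correct", "wrong")]
  if (!length(lat)) {
    abort_sr("average response time is undefined: the log has no answered trials",
             "sr_undefined_measure")
  }
  mean(lat)
}

#' Average elapsed time per question
#'
#' For each distinct item, the total item-attributable time across all of
#' its attempts - reading time, response latency or charged timeout, and
#' feedback screens - excluding every scheduled recall delay; the measure
#' is the mean of these per-item totals.
#'
#' @param log A `session_log`.
#' @return Mean elapsed time per question in seconds.
#' @export
avg_elapsed_per_question <- function(log) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  if (!nrow(tr)) {
    abort_sr("elapsed time per question is undefined: empty log", "sr_undefined_measure")
  }
  answer_time <- ifelse(tr$outcome == "timeout",
                        log$config$response_timeout_s, tr$response_latency_s)
  per_trial <- tr$reading_time_s + answer_time + tr$feedback_duration_s
  per_item <- tapply(per_trial, factor(tr$item_id, levels = unique(tr$item_id)), sum)
  mean(per_item)
}

#' Correct answer score
#'
#' The number of distinct items answered correctly at their first
#' presentation, on the 0-10 count scale; `as_percentage = TRUE` returns
#' the equivalent percentage of presented items.
#'
#' @param log A `session_log`.
#' @param as_percentage Return the percentage view instead of the count.
#' @return Count of first-attempt-correct items (or percentage).
#' @export
correct_answer_score <- function(log, as_percentage = FALSE) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  first <- tr[tr$attempt_number == 1L, , drop = FALSE]
  count <- sum(first$outcome == "correct")
  if (!as_percentage) return(count)
  if (!nrow(first)) return(NA_real_)
  100 * count / nrow(first)
}

#' Assemble the five experimental measures for one session
#'
#' Combines the three objective measures derived from the session log
#' (average response time, average elapsed time per question, correct
#' answer score) with the two subjective instruments (post-task
#' questionnaire score on 0-7 and the weighted NASA-TLX score on 0-100)
#' into one row of study data.
#'
#' @param log A completed `session_log`.
#' @param tlx_ratings A [tlx_rating()].
#' @param tlx_wts A [tlx_weights()] (or 15 pairwise choices via
#'   [tlx_weights_from_pairs()] upstream).
#' @param posttask Post-task questionnaire score in `[0, 7]`.
#' @return An object of class `measure_set`: a list with
#'   `avg_response_time_s`, `avg_elapsed_per_question_s`,
#'   `correct_answer_score`, `posttask_score`, `tlx_score`, plus the
#'   identifying `participant_id` and `modality`.
#' @export
compute_measures <- function(log, tlx_ratings, tlx_wts, posttask) {
  stopifnot(inherits(log, "session_log"))
  if (!is_number(posttask) || posttask < 0 || posttask > 7) {
    abort_sr("posttask score must lie in [0, 7]", "sr_validation_error")
  }
  out <- structure(
    list(
      participant_id = log$participant_id,
      modality = log$modality,
      avg_response_time_s = avg_response_time(log),
      avg_elapsed_per_question_s = avg_elapsed_per_question(log),
      correct_answer_score = correct_answer_score(log),
      posttask_score = posttask,
      tlx_score = tlx_score(tlx_ratings, tlx_wts)
    ),
    class = "measure_set"
  )
  n_items <- length(unique(log$trials$item_id))
  if (out$correct_answer_score > n_items) {
    abort_sr("correct answer score exceeds the number of presented items",
             "sr_validation_error")
  }
  out
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("<measure_set> participant '%s', %s task\n", x$participant_id, x$modality))
  cat(sprintf("  avg response time:        %.2f s\n", x$avg_response_time_s))
  cat(sprintf("  avg elapsed per question: %.2f s\n", x$avg_elapsed_per_question_s))
  cat(sprintf("  correct answer score:     %d / 10\n", x$correct_answer_score))
  cat(sprintf("  posttask score:           %.2f / 7\n", x$posttask_score))
  cat(sprintf("  NASA-TLX workload:        %.2f / 100\n", x$tlx_score))
  invisible(x)
}
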