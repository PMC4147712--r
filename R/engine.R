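#' Next scheduled delay under the staircase / expanding-interval rules
#'
#' The assessment phase is an adaptive staircase on the
#' information-to-question delay: a correct answer lengthens the next delay
#' by one step, a wrong answer or timeout shortens it by one step (floored
#' at `min_delay_s`). The training phase uses expanding intervals: a
#' correct answer lengthens the delay by the training increment; a wrong
#' answer or timeout leaves it unchanged.
#'
#' @param current_delay_s The delay used on the trial just completed (> 0).
#' @param outcome `"correct"`, `"wrong"`, or `"timeout"`.
#' @param phase `"assessment"` or `"training"`.
#' @param config An [engine_config()].
#' @return The delay, in seconds, for the next trial.
#' @export
#' @examples
#' cfg <- engine_config()
#' next_delay(90, "correct", "assessment", cfg)  # 100
#' next_delay(90, "wrong",   "assessment", cfg)  # 80
#' next_delay(120, "wrong",  "training",   cfg)  # 120
next_delay <- function(current_delay_s, outcome, phase, config = engine_config()) {
  if (!is_number(current_delay_s) || current_delay_s <= 0) {
    abort_sr("current_delay_s must be a positive duration", "sr_contract_error")
  }
  if (!is_string(outcome) || !outcome %in% c("correct", "wrong", "timeout")) {
    abort_sr("outcome must be 'correct', 'wrong', or 'timeout'", "sr_contract_error")
  }
  if (!is_string(phase) || !phase %in% c("assessment", "training")) {
    abort_sr("phase must be 'assessment' or 'training'", "sr_contract_error")
  }
  if (phase == "assessment") {
    if (outcome == "correct") {
      current_delay_s + config$delay_step_s
    } else {
      max(config$min_delay_s, current_delay_s - config$delay_step_s)
    }
  } else {
    if (outcome == "correct") current_delay_s + config$training_increment_s
    else current_delay_s
  }
}

#' Run an assessment session
#'
#' Presents the bank's items in their fixed order. Each trial shows the
#' information (participant-controlled reading time), waits the current
#' staircase delay, then quizzes with the four choices under the answer
#' timeout. A correct answer advances to the next item; a wrong answer or
#' timeout re-presents the same item. The staircase delay is one running
#' value, updated after every trial via [next_delay()] and carried across
#' items. The session ends when the distinct-item cap is reached, the bank
#' is exhausted, or - checked at trial boundaries - the session time cap
#' has passed. The scheduled delay of the final trial is recorded as the
#' participant's recall time, which seeds the training phase.
#'
#' @param bank A non-empty [item_bank()].
#' @param participant A [scripted_participant()] or [participant_model()].
#' @param config An [engine_config()].
#' @param clock A [sim_clock()]; defaults to a fresh clock at 0 s.
#' @return A `session_log` (see Details) with `recall_time_s` set.
#'
#' @details A `session_log` holds the participant/bank identifiers, phase,
#' a config snapshot, a `trials` data frame (one row per trial with
#' timestamps, scheduled delay, outcome, chosen index, latency, and
#' feedback flag), session start/end times, the termination reason
#' (`completed_all_items`, `item_cap`, or `time_cap`), and for assessment
#' the recall time.
#' @export
run_assessment <- function(bank, participant, config = engine_config(),
                           clock = sim_clock()) {
  run_phase(bank, participant, config, clock,
            phase = "assessment",
            initial_delay_s = config$initial_delay_s,
            max_items = config$assessment_max_questions,
            max_time_s = config$assessment_max_time_s,
            feedback = config$show_feedback_in_assessment)
}

#' Run a training session
#'
#' Same presentation loop as [run_assessment()], but the initial delay is
#' the recall time calibrated by the assessment, the delay is lengthened on
#' every success and held on every failure, each answered trial is followed
#' by a feedback screen ("correct answer" / "wrong answer"), and a failed
#' item is re-presented after its feedback. A session that resolves all its
#' items carries the completion message "well done, task completed."
#'
#' @inheritParams run_assessment
#' @param recall_time_s Initial delay, seconds; the assessment's output
#'   (must be at least `min_delay_s`).
#' @return A `session_log` for the training phase.
#' @export
run_training <- function(bank, participant, config = engine_config(),
                         recall_time_s, clock = sim_clock()) {
  if (!is_number(recall_time_s) || recall_time_s < config$min_delay_s) {
    abort_sr("recall_time_s must be at least min_delay_s", "sr_contract_error")
  }
  run_phase(bank, participant, config, clock,
            phase = "training",
            initial_delay_s = recall_time_s,
            max_items = config$training_max_questions,
            max_time_s = Inf,
            feedback = TRUE)
}

# The shared presentation loop. One trial = info presentation (reading),
# scheduled delay, question (answer or timeout), optional feedback. Failed
# items are re-presented; the delay variable is phase-global and updated
# after every trial.
run_phase <- function(bank, participant, config, clock, phase,
                      initial_delay_s, max_items, max_time_s, feedback) {
  stopifnot(inherits(bank, "item_bank"), inherits(config, "engine_config"),
            inherits(clock, "sim_clock"))
  if (!length(bank$items)) abort_sr("bank is empty", "sr_contract_error")

  session_start <- clock$now()
  delay <- initial_delay_s
  trials <- list()
  item_idx <- 1L
  attempt <- 1L
  resolved <- 0L
  termination <- NULL

  while (TRUE) {
    if (resolved >= max_items) {
      termination <- if (item_idx > length(bank$items)) "completed_all_items" else "item_cap"
      break
    }
    if (item_idx > length(bank$items)) {
      termination <- "completed_all_items"
      break
    }
    if (clock$now() - session_start >= max_time_s) {
      termination <- "time_cap"
      break
    }
    item <- bank$items[[item_idx]]
    resp <- respond(participant, item, delay, config)
    if (!is_number(resp$reading_time_s) || resp$reading_time_s <= 0) {
      abort_sr("participant returned a non-positive reading time", "sr_contract_error")
    }

    info_onset <- clock$now()
    clock$advance(resp$reading_time_s)
    info_dismiss <- clock$now()
    clock$advance(delay)
    question_onset <- clock$now()

    if (isTRUE(resp$timeout)) {
      outcome <- "timeout"
      chosen <- NA_integer_
      latency <- NA_real_
      clock$advance(config$response_timeout_s)
    } else {
      chosen <- resp$chosen_index
      if (!is_count(chosen) || chosen < 0L || chosen > 3L) {
        abort_sr(sprintf(
          "participant '%s' returned choice index %s (must be 0..3)",
          participant$participant_id, format(chosen)), "sr_contract_error")
      }
      latency <- resp$latency_s
      if (!is_number(latency) || latency <= 0 || latency > config$response_timeout_s) {
        abort_sr("response latency must lie in (0, response_timeout_s]", "sr_contract_error")
      }
      clock$advance(latency)
      outcome <- if (chosen == item$correct_index) "correct" else "wrong"
    }

    fb_shown <- feedback && outcome != "timeout"
    if (fb_shown) clock$advance(config$feedback_duration_s)

    trials[[length(trials) + 1L]] <- list(
      item_id = item$item_id, phase = phase, attempt_number = attempt,
      scheduled_delay_s = delay, reading_time_s = resp$reading_time_s,
      info_onset_s = info_onset, info_dismiss_s = info_dismiss,
      question_onset_s = question_onset, outcome = outcome,
      chosen_index = chosen, response_latency_s = latency,
      feedback_shown = fb_shown,
      feedback_duration_s = if (fb_shown) config$feedback_duration_s else 0
    )

    delay <- next_delay(delay, outcome, phase, config)
    if (outcome == "correct") {
      resolved <- resolved + 1L
      item_idx <- item_idx + 1L
      attempt <- 1L
    } else {
      attempt <- attempt + 1L
    }
  }

  trials_df <- do.call(rbind, lapply(trials, function(tr) {
    as.data.frame(tr, stringsAsFactors = FALSE)
  }))
  if (!is.null(trials_df)) rownames(trials_df) <- NULL
  if (is.null(trials_df)) {
    trials_df <- data.frame(
      item_id = character(), phase = character(), attempt_number = integer(),
      scheduled_delay_s = numeric(), reading_time_s = numeric(),
      info_onset_s = numeric(), info_dismiss_s = numeric(),
      question_onset_s = numeric(), outcome = character(),
      chosen_index = integer(), response_latency_s = numeric(),
      feedback_shown = logical(), feedback_duration_s = numeric(),
      stringsAsFactors = FALSE
    )
  }

  all_resolved <- termination %in% c("completed_all_items", "item_cap")
  log <- structure(
    list(
      participant_id = participant$participant_id,
      bank_id = bank$bank_id,
      modality = bank$modality,
      phase = phase,
      config = config,
      trials = trials_df,
      session_start_s = session_start,
      session_end_s = clock$now(),
      recall_time_s = if (phase == "assessment" && nrow(trials_df)) {
        trials_df$scheduled_delay_s[nrow(trials_df)]
      } else {
        NA_real_
      },
      termination_reason = termination,
      completion_message = if (phase == "training" && all_resolved) {
        "well done, task completed."
      } else {
        NA_character_
      }
    ),
    class = "session_log"
  )
  log
}

#' Validate a session log against the protocol rules
#'
#' Re-derives every scheduled delay and timestamp from the log's outcome
#' sequence and the supplied configuration, and checks the structural
#' invariants (timeout trials carry no choice or latency; attempts number
#' consecutively; the timeline is gap-free). A log produced by this engine
#' always validates; any externally recorded or perturbed log gets a
#' per-trial violation report.
#'
#' @param log A `session_log` (from the engine or [read_session_log()]).
#' @param config The [engine_config()] the session claims to follow;
#'   defaults to the log's own snapshot.
#' @return An object of class `replay_report`: a list with `valid` (logical)
#'   and `violations` (data frame with `trial`, `field`, `expected`,
#'   `actual`, `message`).
#' @export
replay_log <- function(log, config = log$config) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  viol <- list()
  add <- function(trial, field, expected, actual, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      trial = trial, field = field, expected = as.character(expected),
      actual = as.character(actual), message = message,
      stringsAsFactors = FALSE)
  }
  tol <- 1e-9

  expected_delay <- if (log$phase == "assessment") {
    config$initial_delay_s
  } else if (nrow(tr)) {
    tr$scheduled_delay_s[1]  # training seed delay is the session's recall time
  } else {
    NA_real_
  }
  t_cursor <- log$session_start_s
  prev_item <- NULL
  prev_attempt <- 0L

  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (abs(row$scheduled_delay_s - expected_delay) > tol) {
      add(i, "scheduled_delay_s", expected_delay, row$scheduled_delay_s,
          "scheduled delay does not follow the staircase recurrence")
    }
    if (abs(row$info_onset_s - t_cursor) > tol) {
      add(i, "info_onset_s", t_cursor, row$info_onset_s,
          "trial does not start where the previous trial ended")
    }
    if (abs(row$info_dismiss_s - (row$info_onset_s + row$reading_time_s)) > tol) {
      add(i, "info_dismiss_s", row$info_onset_s + row$reading_time_s,
          row$info_dismiss_s, "info dismissal must follow the reading time")
    }
    if (abs(row$question_onset_s - (row$info_dismiss_s + row$scheduled_delay_s)) > tol) {
      add(i, "question_onset_s", row$info_dismiss_s + row$scheduled_delay_s,
          row$question_onset_s, "question onset must equal dismissal + scheduled delay")
    }
    if (row$outcome == "timeout") {
      if (!is.na(row$response_latency_s)) {
        add(i, "response_latency_s", NA, row$response_latency_s,
            "timeout trials must not record a latency")
      }
      if (!is.na(row$chosen_index)) {
        add(i, "chosen_index", NA, row$chosen_index,
            "timeout trials must not record a choice")
      }
      answer_time <- config$response_timeout_s
    } else {
      if (is.na(row$response_latency_s) || row$response_latency_s <= 0 ||
          row$response_latency_s > config$response_timeout_s + tol) {
        add(i, "response_latency_s", "(0, response_timeout_s]", row$response_latency_s,
            "answered trials need a latency within the timeout")
      }
      answer_time <- if (is.na(row$response_latency_s)) 0 else row$response_latency_s
    }
    expected_attempt <- if (identical(row$item_id, prev_item)) prev_attempt + 1L else 1L
    if (row$attempt_number != expected_attempt) {
      add(i, "attempt_number", expected_attempt, row$attempt_number,
          "attempt numbers must increment on re-presentation and reset on a new item")
    }
    t_cursor <- row$question_onset_s + answer_time + row$feedback_duration_s
    # propagate the recurrence from the expected chain: one corrupted delay
    # yields one violation, not a cascade
    expected_delay <- next_delay(expected_delay, row$outcome, log$phase, config)
    prev_item <- row$item_id
    prev_attempt <- row$attempt_number
  }

  if (nrow(tr) && abs(log$session_end_s - t_cursor) > tol) {
    add(nrow(tr), "session_end_s", t_cursor, log$session_end_s,
        "session end must equal the end of the final trial")
  }
  if (log$phase == "assessment" && nrow(tr) &&
      (is.na(log$recall_time_s) ||
       abs(log$recall_time_s - tr$scheduled_delay_s[nrow(tr)]) > tol)) {
    add(nrow(tr), "recall_time_s", tr$scheduled_delay_s[nrow(tr)], log$recall_time_s,
        "recall time must equal the final trial's scheduled delay")
  }

  violations <- if (length(viol)) do.call(rbind, viol) else data.frame(
    trial = integer(), field = character(), expected = character(),
    actual = character(), message = character(), stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "replay_report")
}

#' @export
print.replay_report <- function(x, ...) {
  if (x$valid) {
    cat("<replay_report> log is consistent with the protocol\n")
  } else {
    cat(sprintf("<replay_report> %d violation(s):\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %s phase: participant '%s', bank '%s' (%s)\n  %d trials over %.1f s; termination: %s\n",
    x$phase, x$participant_id, x$bank_id, x$modality, nrow(x$trials),
    x$session_end_s - x$session_start_s, x$termination_reason))
  if (!is.na(x$recall_time_s)) {
    cat(sprintf("  recall time: %.0f s\n", x$recall_time_s))
  }
  if (!is.na(x$completion_message)) cat(sprintf("  \"%s\"\n", x$completion_message))
  invisible(x)
}
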