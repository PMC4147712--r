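#' Write a session log as JSON-lines events
#'
#' Serialises a `session_log` as one event per line: `session_start`
#' (carrying identifiers and the config snapshot), then per trial
#' `info_onset`, `info_dismiss`, `question_onset`, `response` or `timeout`,
#' and `feedback_onset`/`feedback_end` where feedback was shown, closed by
#' `session_end`. Every event has a `timestamp_s` field on the simulated
#' clock. The round trip through [read_session_log()] reproduces the log
#' exactly.
#'
#' @param log A `session_log`.
#' @param path Output path (`.jsonl`).
#' @return Invisibly, `path`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  ev <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
  lines <- character()
  lines <- c(lines, ev(list(
    event = "session_start", timestamp_s = log$session_start_s,
    participant_id = log$participant_id, bank_id = log$bank_id,
    modality = log$modality, phase = log$phase,
    config = unclass(log$config)
  )))
  tr <- log$trials
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    lines <- c(lines, ev(list(
      event = "info_onset", timestamp_s = row$info_onset_s,
      item_id = row$item_id, attempt_number = row$attempt_number,
      scheduled_delay_s = row$scheduled_delay_s
    )))
    lines <- c(lines, ev(list(
      event = "info_dismiss", timestamp_s = row$info_dismiss_s,
      reading_time_s = row$reading_time_s
    )))
    lines <- c(lines, ev(list(
      event = "question_onset", timestamp_s = row$question_onset_s
    )))
    if (row$outcome == "timeout") {
      lines <- c(lines, ev(list(
        event = "timeout",
        timestamp_s = row$question_onset_s + log$config$response_timeout_s
      )))
    } else {
      lines <- c(lines, ev(list(
        event = "response",
        timestamp_s = row$question_onset_s + row$response_latency_s,
        outcome = row$outcome, chosen_index = row$chosen_index,
        response_latency_s = row$response_latency_s
      )))
    }
    if (row$feedback_shown) {
      t_answer <- row$question_onset_s +
        if (row$outcome == "timeout") log$config$response_timeout_s else row$response_latency_s
      lines <- c(lines, ev(list(event = "feedback_onset", timestamp_s = t_answer)))
      lines <- c(lines, ev(list(event = "feedback_end",
                                timestamp_s = t_answer + row$feedback_duration_s)))
    }
  }
  end <- list(event = "session_end", timestamp_s = log$session_end_s,
              termination_reason = log$termination_reason)
  if (!is.na(log$recall_time_s)) end$recall_time_s <- log$recall_time_s
  if (!is.na(log$completion_message)) end$completion_message <- log$completion_message
  lines <- c(lines, ev(end))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session log from a JSON-lines file
#'
#' Inverse of [write_session_log()]; validates the event structure and
#' reconstructs the `session_log` exactly.
#'
#' @param path Path to a `.jsonl` session log.
#' @return A `session_log`.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) {
    abort_sr(sprintf("session log not found: '%s'", path), "sr_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  events <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) abort_sr(
               sprintf("line %d of '%s' is not valid JSON: %s", i, path,
                       conditionMessage(e)), "sr_format_error"))
  })
  if (!length(events) || !identical(events[[1]]$event, "session_start") ||
      !identical(events[[length(events)]]$event, "session_end")) {
    abort_sr(sprintf(
      "'%s' must start with a session_start event and end with session_end", path),
      "sr_format_error")
  }
  start <- events[[1]]
  end <- events[[length(events)]]
  cfg_list <- start$config
  cfg_list$assessment_max_questions <- as.integer(cfg_list$assessment_max_questions)
  cfg_list$training_max_questions <- as.integer(cfg_list$training_max_questions)
  config <- do.call(engine_config, cfg_list)

  trials <- list()
  cur <- NULL
  finish_trial <- function(cur) {
    if (is.null(cur$outcome)) {
      abort_sr("trial block is missing its response/timeout event", "sr_format_error")
    }
    as.data.frame(cur, stringsAsFactors = FALSE)
  }
  for (e in events[-c(1L, length(events))]) {
    switch(e$event,
      info_onset = {
        if (!is.null(cur)) trials[[length(trials) + 1L]] <- finish_trial(cur)
        cur <- list(
          item_id = e$item_id, phase = start$phase,
          attempt_number = as.integer(e$attempt_number),
          scheduled_delay_s = as.numeric(e$scheduled_delay_s),
          reading_time_s = NA_real_, info_onset_s = as.numeric(e$timestamp_s),
          info_dismiss_s = NA_real_, question_onset_s = NA_real_,
          outcome = NULL, chosen_index = NA_integer_,
          response_latency_s = NA_real_, feedback_shown = FALSE,
          feedback_duration_s = 0)
      },
      info_dismiss = {
        cur$info_dismiss_s <- as.numeric(e$timestamp_s)
        cur$reading_time_s <- as.numeric(e$reading_time_s)
      },
      question_onset = cur$question_onset_s <- as.numeric(e$timestamp_s),
      response = {
        cur$outcome <- e$outcome
        cur$chosen_index <- as.integer(e$chosen_index)
        cur$response_latency_s <- as.numeric(e$response_latency_s)
      },
      timeout = cur$outcome <- "timeout",
      feedback_onset = {
        cur$feedback_shown <- TRUE
        cur$feedback_onset_tmp <- e$timestamp_s
      },
      feedback_end = {
        cur$feedback_duration_s <- config$feedback_duration_s
        cur$feedback_onset_tmp <- NULL
      },
      abort_sr(sprintf("unknown event type '%s' in '%s'", e$event, path),
               "sr_format_error")
    )
  }
  if (!is.null(cur)) trials[[length(trials) + 1L]] <- finish_trial(cur)
  col_order <- c("item_id", "phase", "attempt_number", "scheduled_delay_s",
                 "reading_time_s", "info_onset_s", "info_dismiss_s",
                 "question_onset_s", "outcome", "chosen_index",
                 "response_latency_s", "feedback_shown", "feedback_duration_s")
  trials_df <- if (length(trials)) {
    out <- do.call(rbind, lapply(trials, function(d) d[col_order]))
    rownames(out) <- NULL
    out
  } else {
    data.frame(
      item_id = character(), phase = character(), attempt_number = integer(),
      scheduled_delay_s = numeric(), reading_time_s = numeric(),
      info_onset_s = numeric(), info_dismiss_s = numeric(),
      question_onset_s = numeric(), outcome = character(),
      chosen_index = integer(), response_latency_s = numeric(),
      feedback_shown = logical(), feedback_duration_s = numeric(),
      stringsAsFactors = FALSE)
  }
  structure(
    list(
      participant_id = start$participant_id, bank_id = start$bank_id,
      modality = start$modality, phase = start$phase, config = config,
      trials = trials_df, session_start_s = as.numeric(start$timestamp_s),
      session_end_s = as.numeric(end$timestamp_s),
      recall_time_s = if (is.null(end$recall_time_s)) NA_real_ else as.numeric(end$recall_time_s),
      termination_reason = end$termination_reason,
      completion_message = if (is.null(end$completion_message)) NA_character_
                           else end$completion_message
    ),
    class = "session_log"
  )
}
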