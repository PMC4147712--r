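#' Engine configuration
#'
#' Every protocol parameter of the two-phase spaced-retrieval exercise.
#' Defaults reproduce the published protocol: the assessment staircase
#' starts at a 90 s information-to-question delay and moves in 10 s steps
#' (up on a correct answer, down on a wrong answer or timeout); answers
#' time out after 60 s; feedback screens last 5 s; each phase is capped at
#' 10 distinct questions and the assessment additionally at 30 minutes.
#'
#' @param initial_delay_s Assessment starting delay, seconds (default 90).
#' @param delay_step_s Assessment staircase step, seconds (default 10).
#' @param training_increment_s Training-phase delay increment on success,
#'   seconds (default 10, reusing the assessment step).
#' @param response_timeout_s Answer timeout, seconds (default 60). A timeout
#'   counts as a failure and charges the full timeout to the timeline.
#' @param feedback_duration_s Feedback screen duration, seconds (default 5).
#' @param assessment_max_questions Distinct-item cap for assessment
#'   (default 10).
#' @param assessment_max_time_s Assessment wall-time cap, seconds
#'   (default 1800, i.e. 30 minutes). Checked at trial boundaries: no new
#'   presentation starts at or after the cap; an in-flight trial completes.
#' @param training_max_questions Distinct-item cap for training (default 10).
#' @param min_delay_s Floor on the staircase delay, seconds (default 10),
#'   keeping the delay positive under repeated failures.
#' @param show_feedback_in_assessment Show the 5 s feedback screens during
#'   assessment too (default `FALSE`; the protocol describes feedback only
#'   in the training phase).
#'
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(initial_delay_s = 90,
                          delay_step_s = 10,
                          training_increment_s = 10,
                          response_timeout_s = 60,
                          feedback_duration_s = 5,
                          assessment_max_questions = 10L,
                          assessment_max_time_s = 1800,
                          training_max_questions = 10L,
                          min_delay_s = 10,
                          show_feedback_in_assessment = FALSE) {
  cfg <- structure(
    list(
      initial_delay_s = as.numeric(initial_delay_s),
      delay_step_s = as.numeric(delay_step_s),
      training_increment_s = as.numeric(training_increment_s),
      response_timeout_s = as.numeric(response_timeout_s),
      feedback_duration_s = as.numeric(feedback_duration_s),
      assessment_max_questions = as.integer(assessment_max_questions),
      assessment_max_time_s = as.numeric(assessment_max_time_s),
      training_max_questions = as.integer(training_max_questions),
      min_delay_s = as.numeric(min_delay_s),
      show_feedback_in_assessment = isTRUE(show_feedback_in_assessment)
    ),
    class = "engine_config"
  )
  durations <- c("initial_delay_s", "delay_step_s", "training_increment_s",
                 "response_timeout_s", "feedback_duration_s",
                 "assessment_max_time_s", "min_delay_s")
  problems <- character()
  for (f in durations) {
    if (!is_number(cfg[[f]]) || cfg[[f]] <= 0) {
      problems <- c(problems, sprintf("%s must be a positive duration", f))
    }
  }
  if (is_number(cfg$min_delay_s) && is_number(cfg$initial_delay_s) &&
      cfg$min_delay_s > cfg$initial_delay_s) {
    problems <- c(problems, "min_delay_s must not exceed initial_delay_s")
  }
  for (f in c("assessment_max_questions", "training_max_questions")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      problems <- c(problems, sprintf("%s must be at least 1", f))
    }
  }
  if (length(problems)) {
    abort_sr(paste0("invalid engine config:\n", paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  cfg
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  for (f in names(x)) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read an engine configuration from a TOML file
#'
#' The config file is flat TOML: one `key = value` line per
#' [engine_config()] field (`#` comments and blank lines allowed). Keys
#' absent from the file keep their defaults; unknown keys are an error.
#' Values may be numbers, `true`/`false`, or quoted strings.
#'
#' @param path Path to the TOML file.
#' @param overrides Named list of field overrides applied on top of the file
#'   (used by the command-line front end for flag precedence).
#' @return An [engine_config()].
#' @export
read_engine_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    abort_sr(sprintf("config file not found: '%s'", path), "sr_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_sr(sprintf("config line is not 'key = value': '%s'", ln), "sr_format_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    raw <- trimws(sub("^[^=]*=", "", ln))
    vals[[key]] <- parse_toml_scalar(raw, key)
  }
  known <- names(formals(engine_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_sr(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "sr_format_error")
  }
  vals[names(overrides)] <- overrides
  do.call(engine_config, vals)
}

parse_toml_scalar <- function(raw, key) {
  if (raw %in% c("true", "false")) return(raw == "true")
  if (grepl('^".*"$', raw)) return(substr(raw, 2, nchar(raw) - 1))
  num <- suppressWarnings(as.numeric(raw))
  if (is.na(num)) {
    abort_sr(sprintf("cannot parse config value for '%s': '%s'", key, raw),
             "sr_format_error")
  }
  num
}

#' Write an engine configuration as flat TOML
#'
#' @param config An [engine_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_engine_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    format(v, scientific = FALSE)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' Simulated clock
#'
#' A virtual time source starting at 0 s, advanced explicitly by the session
#' engine. All timestamps in a session log are read from this clock, so
#' timed sessions execute instantaneously and deterministically.
#'
#' @param start_s Starting time in seconds (default 0).
#' @return An object of class `sim_clock` with `$now()` and `$advance(dt)`.
#' @export
sim_clock <- function(start_s = 0) {
  t <- as.numeric(start_s)
  env <- new.env(parent = emptyenv())
  env$now <- function() t
  env$advance <- function(dt) {
    if (!is_number(dt) || dt < 0) {
      abort_sr("clock can only advance by a non-negative duration", "sr_contract_error")
    }
    t <<- t + dt
    invisible(t)
  }
  class(env) <- "sim_clock"
  env
}
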