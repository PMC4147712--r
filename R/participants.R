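#' Scripted participant
#'
#' A deterministic responder that plays back a fixed script of responses,
#' one entry per trial, in order. Scripted participants make engine traces
#' fully predictable and are the basis of the trace-level tests.
#'
#' @param script A list of per-trial entries, each a list with elements
#'   `outcome` (`"correct"`, `"wrong"`, `"timeout"`, or an explicit
#'   zero-based choice index 0-3), `reading_time_s`, and `latency_s`
#'   (ignored for timeouts).
#' @param participant_id Identifier recorded in session logs.
#' @return An object of class `scripted_participant`. Requesting more trials
#'   than the script holds raises an explicit exhaustion error.
#' @export
#' @examples
#' p <- scripted_participant(rep(list(
#'   list(outcome = "correct", reading_time_s = 5, latency_s = 10)), 10))
scripted_participant <- function(script, participant_id = "scripted") {
  if (!is.list(script) || !length(script)) {
    abort_sr("script must be a non-empty list of trial entries", "sr_validation_error")
  }
  for (i in seq_along(script)) {
    e <- script[[i]]
    ok_outcome <- (is_string(e$outcome) && e$outcome %in% c("correct", "wrong", "timeout")) ||
      (is_count(e$outcome) && e$outcome >= 0 && e$outcome <= 3)
    if (!ok_outcome || !is_number(e$reading_time_s) || e$reading_time_s <= 0) {
      abort_sr(sprintf("script entry %d is malformed", i), "sr_validation_error")
    }
    if (!identical(e$outcome, "timeout") &&
        (!is_number(e$latency_s) || e$latency_s <= 0)) {
      abort_sr(sprintf("script entry %d needs a positive latency_s", i),
               "sr_validation_error")
    }
  }
  env <- new.env(parent = emptyenv())
  env$pos <- 0L
  structure(list(participant_id = participant_id, script = script, state = env),
            class = c("scripted_participant", "sr_participant"))
}

#' Helper scripts for common scripted participants
#'
#' @param n Number of trial entries.
#' @param reading_time_s,latency_s Constant per-trial times, seconds.
#' @return A script list usable with [scripted_participant()].
#' @export
always_correct_script <- function(n, reading_time_s = 5, latency_s = 10) {
  rep(list(list(outcome = "correct", reading_time_s = reading_time_s,
                latency_s = latency_s)), n)
}

#' @rdname always_correct_script
#' @export
always_timeout_script <- function(n, reading_time_s = 5) {
  rep(list(list(outcome = "timeout", reading_time_s = reading_time_s,
                latency_s = NA_real_)), n)
}

#' Stochastic participant model
#'
#' A simulated responder whose recall follows an exponential forgetting
#' curve with a guessing floor: the probability of a correct answer after a
#' retention delay `d` is `g + (1 - g) * exp(-d / (tau * m))`, where `g` is
#' the four-choice guessing floor, `tau` the memory time constant, and `m`
#' a per-modality difficulty multiplier (larger multiplier = slower
#' forgetting = easier task). Response latencies are log-normal and grow
#' with retrieval uncertainty, so harder material both lowers accuracy and
#' slows responding. All randomness flows from the model's own seed through
#' a private stream; the caller's RNG state is never touched.
#'
#' @param participant_id Identifier recorded in session logs.
#' @param tau_s Memory time constant, seconds (> 0).
#' @param guess_floor Probability of a lucky guess; default 0.25 (one of
#'   four choices).
#' @param reading_time_s Mean self-paced reading time, seconds.
#' @param latency_log_mean,latency_log_sd Log-scale parameters of the
#'   log-normal response-latency distribution (seconds scale).
#' @param latency_uncertainty Added to the log-latency mean in proportion to
#'   `1 - recall_probability`: retrieval difficulty slows responses.
#' @param non_response_prob Probability of a timeout independent of memory
#'   (attention lapse / interface failure).
#' @param modality_difficulty Named multipliers on `tau_s` for `text` and
#'   `graphic` material, both > 0.
#' @param seed Integer seed for the model's private RNG stream.
#'
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(participant_id = "sim",
                              tau_s = 600,
                              guess_floor = 0.25,
                              reading_time_s = 10,
                              latency_log_mean = log(12),
                              latency_log_sd = 0.35,
                              latency_uncertainty = 1,
                              non_response_prob = 0.02,
                              modality_difficulty = c(text = 1, graphic = 2),
                              seed = 1L) {
  problems <- character()
  if (!is_number(tau_s) || tau_s <= 0) problems <- c(problems, "tau_s must be > 0")
  for (p in c("guess_floor", "non_response_prob")) {
    v <- get(p)
    if (!is_number(v) || v < 0 || v > 1) {
      problems <- c(problems, sprintf("%s must be a probability in [0,1]", p))
    }
  }
  if (!is.numeric(modality_difficulty) ||
      !all(MODALITIES %in% names(modality_difficulty)) ||
      any(modality_difficulty <= 0)) {
    problems <- c(problems, "modality_difficulty must name positive 'text' and 'graphic' multipliers")
  }
  if (!is_number(reading_time_s) || reading_time_s <= 0) {
    problems <- c(problems, "reading_time_s must be > 0")
  }
  if (length(problems)) {
    abort_sr(paste0("invalid participant model:\n", paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  structure(
    list(participant_id = participant_id, tau_s = tau_s, guess_floor = guess_floor,
         reading_time_s = reading_time_s, latency_log_mean = latency_log_mean,
         latency_log_sd = latency_log_sd, latency_uncertainty = latency_uncertainty,
         non_response_prob = non_response_prob,
         modality_difficulty = modality_difficulty[MODALITIES],
         seed = as.integer(seed), state = rng_stream(seed)),
    class = c("participant_model", "sr_participant")
  )
}

#' Recall probability under the forgetting-curve model
#'
#' `g + (1 - g) * exp(-delay / (tau * m))`: strictly decreasing in the
#' delay, equal to 1 at delay 0, and approaching the guessing floor `g` as
#' the delay grows.
#'
#' @param delay_s Retention delay in seconds (>= 0).
#' @param model A [participant_model()].
#' @param modality `"text"` or `"graphic"` (selects the difficulty
#'   multiplier).
#' @return Probability of a correct answer.
#' @export
#' @examples
#' m <- participant_model(tau_s = 100)
#' recall_probability(0, m, "text")    # 1
#' recall_probability(100, m, "text")  # 0.25 + 0.75 * exp(-1)
recall_probability <- function(delay_s, model, modality) {
  if (any(!is.finite(delay_s)) || any(delay_s < 0)) {
    abort_sr("delay_s must be non-negative", "sr_contract_error")
  }
  check_modality(modality)
  g <- model$guess_floor
  tau_eff <- model$tau_s * model$modality_difficulty[[modality]]
  g + (1 - g) * exp(-delay_s / tau_eff)
}

#' Simulate one trial response
#'
#' Draws, in order: a non-response (timeout) indicator, a reading time
#' (log-normal around the model's mean), and - unless timing out - a recall
#' outcome at the scheduled delay, the chosen answer (the correct choice on
#' recall, otherwise uniform over the three distractors), and a log-normal
#' response latency clamped to the answer timeout. Fully reproducible from
#' the model's seed.
#'
#' @param item A [quiz_item()].
#' @param scheduled_delay_s Delay between information dismissal and the
#'   question, seconds.
#' @param model A [participant_model()].
#' @param response_timeout_s Latency clamp (the engine's answer timeout).
#' @return A list with `timeout` (logical), `chosen_index` (0-3 or `NA`),
#'   `reading_time_s`, and `latency_s` (`NA` on timeout).
#' @export
simulate_response <- function(item, scheduled_delay_s, model,
                              response_timeout_s = 60) {
  p_recall <- recall_probability(scheduled_delay_s, model, item$modality)
  with_stream(model$state, {
    sigma_r <- 0.3
    reading <- stats::rlnorm(1, log(model$reading_time_s) - sigma_r^2 / 2, sigma_r)
    if (stats::runif(1) < model$non_response_prob) {
      list(timeout = TRUE, chosen_index = NA_integer_,
           reading_time_s = reading, latency_s = NA_real_)
    } else {
      recalled <- stats::runif(1) < p_recall
      chosen <- if (recalled) {
        item$correct_index
      } else {
        distractors <- setdiff(0:3, item$correct_index)
        distractors[sample.int(3L, 1L)]
      }
      mu <- model$latency_log_mean + model$latency_uncertainty * (1 - p_recall)
      latency <- stats::rlnorm(1, mu, model$latency_log_sd)
      latency <- min(max(latency, 1e-3), response_timeout_s)
      list(timeout = FALSE, chosen_index = as.integer(chosen),
           reading_time_s = reading, latency_s = latency)
    }
  })
}

# Responder contract used by the engine: given the item about to be quizzed
# and the scheduled delay, produce reading time and either an answer (with
# latency) or a timeout.
respond <- function(participant, item, scheduled_delay_s, config) {
  UseMethod("respond")
}

#' @export
respond.scripted_participant <- function(participant, item, scheduled_delay_s, config) {
  env <- participant$state
  env$pos <- env$pos + 1L
  if (env$pos > length(participant$script)) {
    abort_sr(sprintf(
      "scripted participant '%s' exhausted its %d-entry script at trial %d",
      participant$participant_id, length(participant$script), env$pos),
      "sr_script_exhausted")
  }
  e <- participant$script[[env$pos]]
  if (identical(e$outcome, "timeout")) {
    return(list(timeout = TRUE, chosen_index = NA_integer_,
                reading_time_s = e$reading_time_s, latency_s = NA_real_))
  }
  chosen <- if (is.numeric(e$outcome)) {
    as.integer(e$outcome)
  } else if (identical(e$outcome, "correct")) {
    item$correct_index
  } else {
    # deterministic distractor: the next choice cyclically
    as.integer((item$correct_index + 1L) %% 4L)
  }
  list(timeout = FALSE, chosen_index = chosen,
       reading_time_s = e$reading_time_s, latency_s = e$latency_s)
}

#' @export
respond.participant_model <- function(participant, item, scheduled_delay_s, config) {
  simulate_response(item, scheduled_delay_s, participant,
                    response_timeout_s = config$response_timeout_s)
}

#' Generate a simulated cohort
#'
#' Draws `n` participant models whose memory time constants are log-normal
#' around a base model (`tau_i = tau_base * exp(N(0, heterogeneity_sd))`),
#' emulating between-participant variability in recall ability. Each member
#' receives its own derived seed; the whole cohort is deterministic under
#' `seed`.
#'
#' @param n Cohort size (>= 1).
#' @param base A [participant_model()] supplying all non-varying parameters.
#' @param heterogeneity_sd Log-scale SD of the `tau_s` spread (0 = identical
#'   members).
#' @param seed Integer seed.
#' @return A list of `n` [participant_model()]s with ids `P01`, `P02`, ...
#' @export
generate_cohort <- function(n, base = participant_model(),
                            heterogeneity_sd = 0.5, seed = 1L) {
  if (!is_count(n) || n < 1) abort_sr("n must be >= 1", "sr_contract_error")
  withr::with_seed(as.integer(seed), {
    taus <- base$tau_s * exp(stats::rnorm(n, 0, heterogeneity_sd))
    member_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      participant_model(
        participant_id = sprintf("P%02d", i),
        tau_s = taus[i],
        guess_floor = base$guess_floor,
        reading_time_s = base$reading_time_s,
        latency_log_mean = base$latency_log_mean,
        latency_log_sd = base$latency_log_sd,
        latency_uncertainty = base$latency_uncertainty,
        non_response_prob = base$non_response_prob,
        modality_difficulty = base$modality_difficulty,
        seed = member_seeds[i]
      )
    })
  })
}

#' Simulate subjective session outcomes
#'
#' Produces a NASA-TLX rating and a post-task satisfaction score (0-7) whose
#' deterministic cores are tied to the session's difficulty: every subscale
#' rating grows with the number of failed trials (wrong answers and
#' timeouts) and with total session time, and satisfaction falls with
#' failures. Gaussian noise (from the model's private stream) is added on
#' top, so simulated studies carry the assumed workload-performance
#' structure without being degenerate.
#'
#' @param model A [participant_model()] (supplies the RNG stream).
#' @param session A completed [run_assessment()] / [run_training()] log.
#' @param base_rating Baseline subscale rating for an effortless session.
#' @param failure_weight Named per-subscale rating increase per failed trial.
#' @param time_weight Named per-subscale rating increase per minute of
#'   session time.
#' @param noise_sd SD of the additive rating noise (0 = deterministic).
#' @param posttask_failure_drop Satisfaction points lost per failed trial.
#' @return A list with `tlx` (a [tlx_rating()]) and `posttask` (0-7).
#' @export
simulate_subjective_outcomes <- function(model, session,
                                         base_rating = 5,
                                         failure_weight = c(mental = 6, physical = 0.5,
                                                            temporal = 2, performance = 7,
                                                            effort = 5, frustration = 6),
                                         time_weight = c(mental = 0.2, physical = 0.1,
                                                         temporal = 0.6, performance = 0.1,
                                                         effort = 0.3, frustration = 0.2),
                                         noise_sd = 3,
                                         posttask_failure_drop = 0.6) {
  stopifnot(inherits(session, "session_log"))
  failures <- sum(session$trials$outcome != "correct")
  dur_min <- (session$session_end_s - session$session_start_s) / 60
  failure_weight <- failure_weight[TLX_SUBSCALES]
  time_weight <- time_weight[TLX_SUBSCALES]
  with_stream(model$state, {
    noise <- stats::rnorm(6, 0, noise_sd)
    ratings <- base_rating + failure_weight * failures + time_weight * dur_min + noise
    ratings <- pmin(pmax(ratings, 0), 100)
    names(ratings) <- TLX_SUBSCALES
    post_noise <- stats::rnorm(1, 0, noise_sd / 10)
    posttask <- min(max(7 - posttask_failure_drop * failures + post_noise, 0), 7)
    list(tlx = tlx_rating(ratings), posttask = posttask)
  })
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf(
    "<participant_model> '%s': tau = %.1f s, guess floor %.2f, P(timeout) = %.3f, seed %d\n",
    x$participant_id, x$tau_s, x$guess_floor, x$non_response_prob, x$seed))
  invisible(x)
}
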