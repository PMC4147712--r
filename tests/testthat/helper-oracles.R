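# Independent oracles and tiny fixtures used across the suite.

# Brute-force staircase recurrence: the scheduled delay before each trial,
# evaluated independently of the engine.
oracle_delay_sequence <- function(outcomes, phase, initial, step = 10,
                                  increment = 10, floor = 10) {
  delays <- numeric(length(outcomes))
  d <- initial
  for (i in seq_along(outcomes)) {
    delays[i] <- d
    d <- if (phase == "assessment") {
      if (outcomes[i] == "correct") d + step else max(floor, d - step)
    } else {
      if (outcomes[i] == "correct") d + increment else d
    }
  }
  delays
}

# Definitional one-way two-group ANOVA from sums of squares.
oracle_anova <- function(a, b) {
  n <- length(a) + length(b)
  gm <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- msb / msw
  list(F = f, df_between = 1L, df_within = n - 2L,
       p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# Pearson r from definitional sums plus the t-transform p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(t), n - 2))
}

# A small bank of n text items, valid by construction.
tiny_bank <- function(n = 3, modality = "text", bank_id = "tiny") {
  items <- lapply(seq_len(n), function(i) {
    if (modality == "text") {
      quiz_item(sprintf("it%02d", i), "text",
                sprintf("Sentence number %d holds five words", i),
                choices = paste0("choice-", 1:4),
                correct_index = (i - 1L) %% 4L, order_rank = i,
                question_prompt = sprintf("Which sentence was number %d?", i))
    } else {
      quiz_item(sprintf("it%02d", i), "graphic",
                sprintf("img:fixture/%d", i),
                choices = sprintf("img:choice/%d-%d", i, 1:4),
                correct_index = (i - 1L) %% 4L, order_rank = i)
    }
  })
  item_bank(bank_id, modality, items)
}

# Scripted participant from a plain outcome vector, constant times.
script_from_outcomes <- function(outcomes, reading = 5, latency = 10) {
  scripted_participant(lapply(outcomes, function(o) {
    list(outcome = o, reading_time_s = reading,
         latency_s = if (identical(o, "timeout")) NA_real_ else latency)
  }))
}

# A synthetic session log built directly (not via the engine), for measure
# unit tests where per-trial fields need exact control. Each trial is a list
# with item_id, attempt, delay, reading, outcome, latency, feedback.
fake_log <- function(trials, config = engine_config(), phase = "training",
                     modality = "text") {
  t <- 0
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    fb <- tr$feedback %||% 0
    info_onset <- t
    info_dismiss <- info_onset + tr$reading
    question_onset <- info_dismiss + tr$delay
    answer <- if (tr$outcome == "timeout") config$response_timeout_s else tr$latency
    t <<- question_onset + answer + fb
    data.frame(
      item_id = tr$item_id, phase = phase, attempt_number = tr$attempt,
      scheduled_delay_s = tr$delay, reading_time_s = tr$reading,
      info_onset_s = info_onset, info_dismiss_s = info_dismiss,
      question_onset_s = question_onset, outcome = tr$outcome,
      chosen_index = if (tr$outcome == "timeout") NA_integer_ else 0L,
      response_latency_s = if (tr$outcome == "timeout") NA_real_ else tr$latency,
      feedback_shown = fb > 0, feedback_duration_s = fb,
      stringsAsFactors = FALSE)
  })
  structure(
    list(participant_id = "fixture", bank_id = "fixture", modality = modality,
         phase = phase, config = config, trials = do.call(rbind, rows),
         session_start_s = 0, session_end_s = t, recall_time_s = NA_real_,
         termination_reason = "completed_all_items",
         completion_message = NA_character_),
    class = "session_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical valid pairwise-choice table: higher-priority subscale wins.
ranked_pair_choices <- function(ranking = TLX_SUBSCALES) {
  pairs <- t(utils::combn(TLX_SUBSCALES, 2))
  winner <- apply(pairs, 1, function(p) {
    p[which.min(match(p, ranking))]
  })
  data.frame(a = pairs[, 1], b = pairs[, 2], winner = winner,
             stringsAsFactors = FALSE)
}
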