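test_that("staircase and expanding-interval delay updates follow the protocol", {
  cfg <- engine_config()
  expect_equal(next_delay(90, "correct", "assessment", cfg), 100)
  expect_equal(next_delay(90, "wrong", "assessment", cfg), 80)
  expect_equal(next_delay(90, "timeout", "assessment", cfg), 80)
  expect_equal(next_delay(10, "timeout", "assessment", cfg), 10)  # floor clamp
  expect_equal(next_delay(120, "wrong", "training", cfg), 120)
  expect_equal(next_delay(120, "timeout", "training", cfg), 120)
  expect_equal(next_delay(120, "correct", "training", cfg), 130)
  expect_error(next_delay(0, "correct", "assessment", cfg), class = "sr_contract_error")
  expect_error(next_delay(-5, "wrong", "assessment", cfg), class = "sr_contract_error")
})

test_that("an always-correct assessment walks the staircase 90..180", {
  bank <- builtin_bank("text")
  log <- run_assessment(bank, script_from_outcomes(rep("correct", 10)))
  expect_equal(nrow(log$trials), 10L)
  expect_equal(log$trials$scheduled_delay_s, seq(90, 180, by = 10))
  expect_equal(log$recall_time_s, 180)
  expect_identical(log$termination_reason, "completed_all_items")
  expect_false(any(log$trials$feedback_shown))
  # hand-rolled timestamp trace: trial i starts at (i-1)*(5 + delay + 10)
  expected_start <- cumsum(c(0, head(5 + seq(90, 180, 10) + 10, -1)))
  expect_equal(log$trials$info_onset_s, expected_start)
  expect_equal(log$trials$info_dismiss_s, expected_start + 5)
  expect_equal(log$trials$question_onset_s,
               log$trials$info_dismiss_s + log$trials$scheduled_delay_s)
  expect_equal(log$session_end_s, sum(5 + seq(90, 180, 10) + 10))
})

test_that("a never-responding participant descends to the floor and hits the time cap", {
  bank <- builtin_bank("text")
  log <- run_assessment(bank, script_from_outcomes(rep("timeout", 100)))
  expect_identical(log$termination_reason, "time_cap")
  expect_true(all(log$trials$item_id == "text-01"))
  expect_true(all(log$trials$outcome == "timeout"))
  n <- nrow(log$trials)
  expect_equal(log$trials$scheduled_delay_s,
               pmax(10, seq(90, by = -10, length.out = n)))
  expect_true(all(log$trials$info_onset_s < 1800))
  expect_true(is.na(log$trials$response_latency_s[1]))
  expect_true(is.na(log$trials$chosen_index[1]))
  expect_equal(log$trials$attempt_number, seq_len(n))
})

test_that("the smallest session: one item answered on the first attempt", {
  bank <- tiny_bank(1)
  log <- run_assessment(bank, script_from_outcomes("correct"))
  expect_equal(nrow(log$trials), 1L)
  expect_equal(log$recall_time_s, 90)
  expect_identical(log$termination_reason, "completed_all_items")
})

test_that("training expands from the recall time and shows 5 s feedback", {
  bank <- builtin_bank("text")
  log <- run_training(bank, script_from_outcomes(rep("correct", 10)),
                      recall_time_s = 180)
  expect_equal(log$trials$scheduled_delay_s, seq(180, 270, by = 10))
  expect_true(all(log$trials$feedback_shown))
  expect_true(all(log$trials$feedback_duration_s == 5))
  expect_identical(log$completion_message, "well done, task completed.")
  # failed item re-presented with its delay maintained
  outcomes <- c("correct", "correct", "wrong", "correct",
                rep("correct", 7))
  log2 <- run_training(bank, script_from_outcomes(outcomes), recall_time_s = 120)
  reps <- log2$trials[log2$trials$item_id == "text-03", ]
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$scheduled_delay_s[1], reps$scheduled_delay_s[2])
  expect_equal(reps$attempt_number, 1:2)
  expect_equal(nrow(log2$trials), 11L)
})

test_that("simulated time is conserved over the whole session", {
  cfg <- engine_config()
  set.seed(71)
  for (rep_i in 1:10) {
    outcomes <- sample(c("correct", "wrong", "timeout"), 40, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15))
    p <- script_from_outcomes(outcomes, reading = 4, latency = 7)
    log <- run_assessment(builtin_bank("text"), p, cfg)
    tr <- log$trials
    answer <- ifelse(tr$outcome == "timeout", cfg$response_timeout_s,
                     tr$response_latency_s)
    expect_equal(log$session_end_s - log$session_start_s,
                 sum(tr$reading_time_s + tr$scheduled_delay_s + answer +
                       tr$feedback_duration_s))
  }
})

test_that("engine delay sequences equal the brute-force recurrence (property)", {
  cfg_a <- engine_config(assessment_max_questions = 30L,
                         assessment_max_time_s = 1e7,
                         training_max_questions = 30L)
  big_bank <- tiny_bank(30)
  set.seed(42)
  for (rep_i in 1:60) {
    n <- sample(1:30, 1)
    outcomes <- sample(c("correct", "wrong", "timeout"), n, replace = TRUE)
    # pad with successes so every session terminates inside the script
    outcomes <- c(outcomes, rep("correct", 40))
    log <- run_assessment(big_bank, script_from_outcomes(outcomes), cfg_a)
    m <- nrow(log$trials)
    expect_equal(log$trials$scheduled_delay_s,
                 oracle_delay_sequence(log$trials$outcome, "assessment", 90)[seq_len(m)])
    log_t <- run_training(big_bank, script_from_outcomes(outcomes), cfg_a,
                          recall_time_s = 100)
    mt <- nrow(log_t$trials)
    expect_equal(log_t$trials$scheduled_delay_s,
                 oracle_delay_sequence(log_t$trials$outcome, "training", 100)[seq_len(mt)])
    # training delays never decrease
    expect_true(all(diff(log_t$trials$scheduled_delay_s) >= 0))
  }
})

test_that("assessment delays stay within the staircase bounds", {
  cfg <- engine_config()
  set.seed(9)
  for (rep_i in 1:10) {
    outcomes <- c(sample(c("correct", "wrong", "timeout"), 25, replace = TRUE),
                  rep("correct", 40))
    log <- run_assessment(builtin_bank("text"), script_from_outcomes(outcomes), cfg)
    d <- log$trials$scheduled_delay_s
    idx <- seq_along(d)
    expect_true(all(d >= cfg$min_delay_s))
    expect_true(all(d <= cfg$initial_delay_s + cfg$delay_step_s * (idx - 1)))
  }
})

test_that("identical scripted inputs produce byte-identical logs", {
  outcomes <- c("correct", "wrong", "correct", "timeout", rep("correct", 9))
  run_once <- function() {
    log <- run_assessment(builtin_bank("text"), script_from_outcomes(outcomes))
    path <- tempfile(fileext = ".jsonl")
    write_session_log(log, path)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})

test_that("engine enforces its contracts", {
  expect_error(run_assessment(builtin_bank("text"),
                              script_from_outcomes(rep("correct", 3))),
               class = "sr_script_exhausted")
  bad <- scripted_participant(list(list(outcome = 2, reading_time_s = 5,
                                        latency_s = 10)))
  bad$script[[1]]$outcome <- 7L  # out-of-range choice index injected post hoc
  expect_error(run_assessment(tiny_bank(1), bad), class = "sr_contract_error")
  expect_error(run_training(tiny_bank(1), script_from_outcomes("correct"),
                            recall_time_s = 2),
               class = "sr_contract_error")
})
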