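test_that("average response time averages answered trials and skips timeouts", {
  log <- fake_log(list(
    list(item_id = "a", attempt = 1L, delay = 90, reading = 5,
         outcome = "correct", latency = 10),
    list(item_id = "b", attempt = 1L, delay = 100, reading = 5,
         outcome = "wrong", latency = 20)))
  expect_equal(avg_response_time(log), 15)

  log2 <- fake_log(list(
    list(item_id = "a", attempt = 1L, delay = 90, reading = 5,
         outcome = "timeout", latency = NA),
    list(item_id = "a", attempt = 2L, delay = 80, reading = 5,
         outcome = "correct", latency = 12)))
  expect_equal(avg_response_time(log2), 12)

  all_to <- fake_log(list(list(item_id = "a", attempt = 1L, delay = 90,
                               reading = 5, outcome = "timeout", latency = NA)))
  expect_error(avg_response_time(all_to), class = "sr_undefined_measure")

  # constant-latency session passes straight through
  sess <- run_assessment(builtin_bank("text"),
                         script_from_outcomes(rep("correct", 10), latency = 14.04))
  expect_equal(avg_response_time(sess), 14.04)
})

test_that("elapsed time per question excludes recall delays and sums attempts", {
  one <- fake_log(list(list(item_id = "a", attempt = 1L, delay = 90,
                            reading = 5, outcome = "correct", latency = 10)))
  expect_equal(avg_elapsed_per_question(one), 15)

  retry <- fake_log(list(
    list(item_id = "a", attempt = 1L, delay = 90, reading = 5,
         outcome = "timeout", latency = NA),
    list(item_id = "a", attempt = 2L, delay = 80, reading = 5,
         outcome = "correct", latency = 10)))
  expect_equal(avg_elapsed_per_question(retry), 5 + 60 + 5 + 10)

  two <- fake_log(list(
    list(item_id = "a", attempt = 1L, delay = 50, reading = 8,
         outcome = "correct", latency = 12),
    list(item_id = "b", attempt = 1L, delay = 70, reading = 15,
         outcome = "correct", latency = 25)))
  expect_equal(avg_elapsed_per_question(two), 30)

  # feedback time is item-attributable
  fb <- fake_log(list(list(item_id = "a", attempt = 1L, delay = 90, reading = 5,
                           outcome = "correct", latency = 10, feedback = 5)))
  expect_equal(avg_elapsed_per_question(fb), 20)
})

test_that("elapsed-per-question is delay-exclusion consistent", {
  outcomes <- c("correct", "wrong", "correct", "timeout", rep("correct", 9))
  log <- run_assessment(builtin_bank("text"), script_from_outcomes(outcomes))
  zero_delay <- log
  zero_delay$trials$scheduled_delay_s <- 0
  tr <- zero_delay$trials
  answer <- ifelse(tr$outcome == "timeout", 60, tr$response_latency_s)
  per_item_total <- tapply(tr$reading_time_s + answer + tr$feedback_duration_s,
                           factor(tr$item_id, levels = unique(tr$item_id)), sum)
  expect_equal(avg_elapsed_per_question(zero_delay), mean(per_item_total))
  expect_equal(avg_elapsed_per_question(zero_delay), avg_elapsed_per_question(log))
})

test_that("correct answer score counts first-attempt successes", {
  outcomes <- c("correct", "wrong", "correct", rep("correct", 8))  # item 2 fails once
  log <- run_assessment(builtin_bank("text"), script_from_outcomes(outcomes))
  expect_equal(correct_answer_score(log), 9)
  expect_equal(correct_answer_score(log, as_percentage = TRUE), 90)

  all_good <- run_assessment(builtin_bank("text"),
                             script_from_outcomes(rep("correct", 10)))
  expect_equal(correct_answer_score(all_good), 10)

  cfg <- engine_config(assessment_max_time_s = 4000)
  bad_first <- unlist(lapply(1:10, function(i) c("timeout", "correct")))
  none <- run_assessment(builtin_bank("text"), script_from_outcomes(bad_first), cfg)
  expect_equal(correct_answer_score(none), 0)
  # first-attempt failures + score = distinct items presented
  first <- none$trials[none$trials$attempt_number == 1L, ]
  expect_equal(correct_answer_score(none) + sum(first$outcome != "correct"),
               length(unique(none$trials$item_id)))
})

test_that("pairwise comparisons tally into valid TLX weights", {
  w <- tlx_weights_from_pairs(ranked_pair_choices())
  expect_identical(as.integer(w), c(5L, 4L, 3L, 2L, 1L, 0L))
  expect_equal(sum(w), 15)

  # any valid random choice set conserves the 15 comparison points
  set.seed(5)
  pairs <- t(utils::combn(TLX_SUBSCALES, 2))
  for (i in 1:20) {
    pick <- ifelse(runif(15) < 0.5, pairs[, 1], pairs[, 2])
    w_i <- tlx_weights_from_pairs(data.frame(a = pairs[, 1], b = pairs[, 2],
                                             winner = pick))
    expect_equal(sum(w_i), 15)
  }

  # structured errors: winner outside pair, duplicate pair, missing pair
  bad <- ranked_pair_choices(); bad$winner[1] <- "frustration"
  if (!bad$winner[1] %in% c(bad$a[1], bad$b[1])) {
    expect_error(tlx_weights_from_pairs(bad), class = "sr_validation_error")
  }
  dup <- ranked_pair_choices(); dup[2, ] <- dup[1, ]
  expect_error(tlx_weights_from_pairs(dup), class = "sr_validation_error")
  expect_error(tlx_weights_from_pairs(ranked_pair_choices()[-1, ]),
               class = "sr_validation_error")
})

test_that("weighted TLX scoring matches its closed form", {
  ranked <- tlx_weights(c(mental = 5, physical = 4, temporal = 3,
                          performance = 2, effort = 1, frustration = 0))
  flat50 <- tlx_rating(setNames(rep(50, 6), TLX_SUBSCALES))
  expect_equal(tlx_score(flat50, ranked), 50)

  maxed <- tlx_rating(setNames(rep(100, 6), TLX_SUBSCALES))
  expect_equal(tlx_score(maxed, ranked), 100)

  graded <- tlx_rating(c(mental = 10, physical = 20, temporal = 30,
                         performance = 40, effort = 50, frustration = 60))
  expect_equal(tlx_score(graded, ranked), 350 / 15)

  # permutation invariance: permute subscales in both ratings and weights
  set.seed(2)
  for (i in 1:10) {
    perm <- sample(TLX_SUBSCALES)
    r_perm <- tlx_rating(setNames(as.numeric(graded)[match(perm, TLX_SUBSCALES)], perm))
    w_perm <- tlx_weights(setNames(as.integer(ranked)[match(perm, TLX_SUBSCALES)], perm))
    expect_equal(tlx_score(r_perm, w_perm), tlx_score(graded, ranked))
  }

  # any valid weighting stays within the rating range
  pairs <- t(utils::combn(TLX_SUBSCALES, 2))
  for (i in 1:10) {
    pick <- ifelse(runif(15) < 0.5, pairs[, 1], pairs[, 2])
    w_i <- tlx_weights_from_pairs(data.frame(a = pairs[, 1], b = pairs[, 2],
                                             winner = pick))
    s <- tlx_score(graded, w_i)
    expect_gte(s, min(graded)); expect_lte(s, max(graded))
  }

  expect_error(tlx_weights(c(mental = 6, physical = 4, temporal = 3,
                             performance = 2, effort = 1, frustration = 0)),
               class = "sr_validation_error")
  expect_error(tlx_rating(setNames(c(rep(50, 5), 101), TLX_SUBSCALES)),
               class = "sr_validation_error")
})

test_that("compute_measures composes the five measures with range checks", {
  log <- run_training(builtin_bank("text"),
                      script_from_outcomes(rep("correct", 10)),
                      recall_time_s = 120)
  ratings <- tlx_rating(c(mental = 30, physical = 10, temporal = 25,
                          performance = 15, effort = 30, frustration = 10))
  wts <- tlx_weights_from_pairs(ranked_pair_choices())
  ms <- compute_measures(log, ratings, wts, posttask = 7)
  expect_s3_class(ms, "measure_set")
  expect_equal(ms$avg_response_time_s, avg_response_time(log))
  expect_equal(ms$avg_elapsed_per_question_s, avg_elapsed_per_question(log))
  expect_equal(ms$correct_answer_score, correct_answer_score(log))
  expect_equal(ms$posttask_score, 7)
  expect_equal(ms$tlx_score, tlx_score(ratings, wts))
  expect_error(compute_measures(log, ratings, wts, posttask = 8),
               class = "sr_validation_error")
})
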