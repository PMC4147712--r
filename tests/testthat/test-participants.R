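test_that("recall probability follows the forgetting curve closed form", {
  m <- participant_model(tau_s = 100, guess_floor = 0.25,
                         modality_difficulty = c(text = 1, graphic = 2))
  expect_equal(recall_probability(0, m, "text"), 1)
  expect_equal(recall_probability(1e9, m, "text"), 0.25)
  expect_equal(recall_probability(100, m, "text"), 0.25 + 0.75 * exp(-1))
  # the graphic multiplier slows forgetting
  expect_equal(recall_probability(200, m, "graphic"), 0.25 + 0.75 * exp(-1))
  expect_error(recall_probability(-1, m, "text"), class = "sr_contract_error")
})

test_that("recall probability is monotone in delay and in tau (property)", {
  set.seed(13)
  for (i in 1:25) {
    m <- participant_model(tau_s = runif(1, 10, 2000),
                           guess_floor = runif(1, 0, 0.5), seed = i)
    delays <- sort(runif(10, 0, 3000))
    p <- recall_probability(delays, m, "text")
    expect_true(all(diff(p) <= 0))
    taus <- sort(runif(8, 5, 5000))
    d <- runif(1, 1, 1000)
    p_tau <- vapply(taus, function(tau) {
      recall_probability(d, participant_model(tau_s = tau, seed = 1), "text")
    }, numeric(1))
    expect_true(all(diff(p_tau) >= 0))
  }
})

test_that("simulate_response hits its limit behaviors", {
  it <- tiny_bank(1)$items[[1]]
  perfect <- participant_model(tau_s = 1e12, non_response_prob = 0, seed = 2)
  for (i in 1:20) {
    r <- simulate_response(it, 500, perfect)
    expect_false(r$timeout)
    expect_equal(r$chosen_index, it$correct_index)
    expect_true(r$latency_s > 0 && r$latency_s <= 60)
  }
  lapsed <- participant_model(non_response_prob = 1, seed = 3)
  for (i in 1:5) {
    r <- simulate_response(it, 10, lapsed)
    expect_true(r$timeout)
    expect_true(is.na(r$latency_s))
  }
})

test_that("empirical correct rate matches the closed form at delay = tau", {
  it <- tiny_bank(1)$items[[1]]
  m <- participant_model(tau_s = 100, guess_floor = 0.25,
                         non_response_prob = 0, seed = 99,
                         modality_difficulty = c(text = 1, graphic = 1))
  n <- 10000
  hits <- sum(vapply(seq_len(n), function(i) {
    simulate_response(it, 100, m)$chosen_index == it$correct_index
  }, logical(1)))
  p <- 0.25 + 0.75 * exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("participant randomness never touches the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  m <- participant_model(seed = 77)
  invisible(simulate_response(tiny_bank(1)$items[[1]], 50, m))
  invisible(run_assessment(builtin_bank("text"), m))
  expect_identical(.Random.seed, before)
})

test_that("cohort generation is deterministic with the stated tau spread", {
  base <- participant_model()
  flat <- generate_cohort(10, base, heterogeneity_sd = 0, seed = 4)
  taus <- vapply(flat, function(p) p$tau_s, numeric(1))
  expect_true(all(taus == base$tau_s))
  expect_identical(vapply(flat, function(p) p$participant_id, character(1)),
                   sprintf("P%02d", 1:10))
  a <- generate_cohort(5, base, 0.4, seed = 8)
  b <- generate_cohort(5, base, 0.4, seed = 8)
  expect_identical(lapply(a, function(p) p[c("tau_s", "seed")]),
                   lapply(b, function(p) p[c("tau_s", "seed")]))
  big <- generate_cohort(1000, base, heterogeneity_sd = 0.5, seed = 6)
  log_sd <- sd(log(vapply(big, function(p) p$tau_s, numeric(1))))
  se <- 0.5 / sqrt(2 * (1000 - 1))
  expect_lt(abs(log_sd - 0.5), 3 * se)
})

test_that("subjective outcomes track session difficulty", {
  cfg <- engine_config()
  clean <- fake_log(lapply(1:5, function(i) list(
    item_id = paste0("i", i), attempt = 1L, delay = 1, reading = 1,
    outcome = "correct", latency = 1, feedback = 0)), cfg)
  m <- participant_model(seed = 21)
  base <- simulate_subjective_outcomes(m, clean, noise_sd = 0)
  # an effortless, near-instant session sits at the configured baseline
  expect_true(all(abs(unclass(base$tlx) - 5) < 0.5))
  expect_gt(base$posttask, 6.9)

  failing <- fake_log(lapply(1:5, function(i) list(
    item_id = paste0("i", i), attempt = 1L, delay = 1, reading = 1,
    outcome = "wrong", latency = 1, feedback = 0)), cfg)
  hard <- simulate_subjective_outcomes(m, failing, noise_sd = 0)
  expect_gt(hard$tlx[["mental"]], base$tlx[["mental"]])
  expect_lt(hard$posttask, base$posttask)
})

test_that("failure count and TLX workload correlate positively by construction", {
  m <- participant_model(seed = 31)
  pairs <- t(utils::combn(TLX_SUBSCALES, 2))
  wts <- tlx_weights_from_pairs(ranked_pair_choices())
  set.seed(17)
  res <- t(vapply(1:200, function(i) {
    k <- sample(0:8, 1)
    trials <- lapply(1:10, function(j) list(
      item_id = paste0("i", j), attempt = 1L, delay = 5, reading = 2,
      outcome = if (j <= k) "wrong" else "correct", latency = 3, feedback = 0))
    log <- fake_log(trials)
    subj <- simulate_subjective_outcomes(m, log)
    c(failures = k, tlx = tlx_score(subj$tlx, wts))
  }, c(failures = 0, tlx = 0)))
  expect_gt(cor(res[, "failures"], res[, "tlx"]), 0)
})
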