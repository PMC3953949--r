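test_that("score_trial reproduces the lick-bin rule on all 16 patterns", {
  pats <- expand.grid(b1 = c(FALSE, TRUE), b2 = c(FALSE, TRUE),
                      b3 = c(FALSE, TRUE), b4 = c(FALSE, TRUE))
  for (val in c("S+", "S-")) {
    for (i in seq_len(nrow(pats))) {
      bins <- as.logical(pats[i, ])
      got <- score_trial(list(valence = val, bin_licks = bins))
      expect_identical(got$correct, oracle_score(val, bins),
                       info = paste(val, paste(bins, collapse = "")))
    }
  }
  # outcome labels
  expect_equal(score_trial(list(valence = "S+",
                                bin_licks = c(TRUE, TRUE, TRUE, FALSE)))$outcome,
               "hit")
  expect_equal(score_trial(list(valence = "S-",
                                bin_licks = c(TRUE, FALSE, FALSE, FALSE)))$outcome,
               "correct_rejection")
  expect_equal(score_trial(list(valence = "S-",
                                bin_licks = c(TRUE, TRUE, FALSE, FALSE)))$outcome,
               "false_alarm")
  expect_equal(score_trial(list(valence = "S+",
                                bin_licks = c(TRUE, TRUE, FALSE, FALSE)))$outcome,
               "miss")
})

test_that("score_trial is pure and validates its input", {
  tr <- list(valence = "S+", bin_licks = c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(score_trial(tr), score_trial(tr))
  expect_error(score_trial(list(valence = "S+", bin_licks = c(TRUE, TRUE))),
               "4 boolean")
  expect_error(score_trial(list(valence = "X",
                                bin_licks = rep(TRUE, 4))), "valence")
})

test_that("lick_bins uses half-open 500 ms bins", {
  expect_identical(lick_bins(c(0, 499.9)), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(lick_bins(500), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(lick_bins(c(10, 1999.9)), c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(lick_bins(2000), rep(FALSE, 4))   # outside the stimulus
  expect_identical(lick_bins(numeric(0)), rep(FALSE, 4))
  # feeds straight into the scoring rule
  expect_true(score_trial(list(
    valence = "S+", bin_licks = lick_bins(c(100, 600, 1100))))$correct)
})

test_that("performance and block_performance agree with direct counting", {
  gt <- behavior_ground_truth(n_trials = 1200L, seed = 5L)
  s <- score_session(generate_session(gt))
  expect_equal(performance(s, 300),
               100 * mean(tail(s$trials$correct, 300)))
  expect_equal(performance(s, 1200), 100 * mean(s$trials$correct))
  blocks <- block_performance(s, 100)
  expect_length(blocks, 12)
  # window = n equals the block-size-weighted mean of full blocks
  expect_equal(performance(s, 1200), mean(blocks))
  expect_error(performance(s, 1300), "window")
  expect_error(block_performance(s, 0), "positive")
})

test_that("block logic drops trailing partial blocks", {
  gt <- behavior_ground_truth(
    n_trials = 250L, dilution_exponents = 0L,
    p_correct_by_dilution = c("0" = 1.0), day_trials = 250L, seed = 6L)
  s <- score_session(generate_session(gt))
  expect_equal(block_performance(s, 100), c(100, 100))
})

test_that("discrimination threshold brackets the criterion crossing", {
  curve <- list(dilution_exponents = c(-10, -5, -3, -2),
                accuracy_pct = c(50, 52, 70, 92))
  th <- discrimination_threshold(curve, 70)
  expect_equal(th$lower, -5)
  expect_equal(th$upper, -3)   # a tie at 70% counts as discriminating
  expect_true(th$monotone)

  all_high <- list(dilution_exponents = c(-8, -4, 0),
                   accuracy_pct = c(90, 95, 99))
  th2 <- discrimination_threshold(all_high, 70)
  expect_true(th2$open_lower)
  expect_equal(th2$upper, -8)

  never <- list(dilution_exponents = c(-8, -4, 0),
                accuracy_pct = c(50, 55, 60))
  th3 <- discrimination_threshold(never, 70)
  expect_true(th3$open_upper)
  expect_error(discrimination_threshold(
    list(dilution_exponents = 0, accuracy_pct = 50)), "two dilutions")
})

test_that("threshold recovery from a programmed dilution series", {
  p <- c("0" = 0.95, "-2" = 0.93, "-4" = 0.85, "-6" = 0.55, "-8" = 0.5)
  gt <- behavior_ground_truth(dilution_exponents = c(0L, -2L, -4L, -6L, -8L),
                              p_correct_by_dilution = p,
                              n_trials = 300L, seed = 7L)
  sessions <- lapply(c(0L, -2L, -4L, -6L, -8L), function(d)
    score_session(generate_session(gt, dilution_exponent = d)))
  curve <- performance_curve(sessions)
  th <- discrimination_threshold(curve, 70)
  expect_equal(th$lower, -6)
  expect_equal(th$upper, -4)
})

test_that("validate_sequence reports runs, ITI and imbalance", {
  gt <- behavior_ground_truth(n_trials = 300L, seed = 8L)
  s <- generate_session(gt)
  expect_equal(validate_sequence(s)$n_violations, 0)

  bad <- s
  bad$trials$odor[1:3] <- "CIN"
  v <- validate_sequence(bad)
  expect_true(3 %in% v$run_violations)

  bad2 <- s
  bad2$trials$iti_s[10] <- 2
  expect_equal(validate_sequence(bad2)$iti_violations, 10)

  bad3 <- s
  flip <- which(bad3$trials$valence == "S-")[1]
  bad3$trials$valence[flip] <- "S+"   # 151/149 split
  v3 <- validate_sequence(bad3)
  expect_equal(nrow(v3$imbalanced_days), 1)
  expect_equal(v3$imbalanced_days$n_sp, 151)
})
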