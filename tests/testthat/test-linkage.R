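amp_row <- function(mouse, group, odorant, dil, roi, amp)
  data.frame(mouse = mouse, group = group, odorant = odorant,
             dilution_exponent = dil, roi_id = roi, amplitude_permil = amp)

test_that("group_summary aggregates hierarchically and normalises to naive", {
  amps <- rbind(
    amp_row("t1", "trained", "CIN", -2L, 1:2, c(-3, -3)),
    amp_row("t2", "trained", "CIN", -2L, 1:2, c(-3.6, -2.4)),
    amp_row("n1", "naive", "CIN", -2L, 1:2, c(-2, -2)),
    amp_row("n2", "naive", "CIN", -2L, 1:2, c(-2.2, -1.8)))
  gs <- group_summary(amps)
  expect_equal(gs$normalized$normalized_mean[gs$normalized$group == "naive"], 1)
  expect_equal(gs$normalized$normalized_mean[gs$normalized$group == "trained"],
               1.5)
  a <- gs$amplitude
  expect_equal(a$mean[a$group == "trained"], -3)
  expect_equal(a$n_mice[a$group == "trained"], 2)
  expect_true(all(a$sem >= 0, na.rm = TRUE))

  single <- rbind(amp_row("m1", "naive", "CIN", -2L, 1L, -2))
  gs1 <- group_summary(single)
  expect_equal(gs1$amplitude$mean, -2)
  expect_true(is.na(gs1$amplitude$sem))

  expect_error(group_summary(amp_row("m", "mutant", "CIN", 0L, 1L, -1)),
               "unknown group")
  expect_error(group_summary(data.frame(x = 1)), "columns")
})

test_that("fold_change_counts is a ratio of class means, scale-equivariant", {
  counts <- expand.grid(mouse = c("a", "b"), group = c("trained", "naive"),
                        odorant = "CIN", dilution_exponent = c(-3L, -2L))
  counts$count <- ifelse(counts$group == "trained", 12, 4)
  fc <- fold_change_counts(counts, dilutions = c(-3, -2))
  expect_equal(fc$ratio, 3)
  counts2 <- counts; counts2$count <- counts$count * 7
  expect_equal(fold_change_counts(counts2, dilutions = c(-3, -2))$ratio, 3)

  counts$count <- 0
  expect_true(fold_change_counts(counts, dilutions = c(-3, -2))$undefined)
  expect_error(fold_change_counts(counts, dilutions = -9), "no counts")
})

test_that("amplitude CDF comparison detects shifts and nothing else", {
  set.seed(41)
  naive <- -2 + rnorm(431, 0, 0.6)
  same <- amplitude_cdf_compare(naive, naive)
  expect_equal(same$statistic, 0)

  trained <- 1.5 * (-2 + rnorm(512, 0, 0.6))
  shift <- amplitude_cdf_compare(trained, naive)
  expect_lt(shift$p_value, 1e-6)
  expect_equal(shift$direction, "a_larger_magnitude")
  expect_equal(shift$n_a, 512)

  expect_warning(amplitude_cdf_compare(naive[1:5], naive[1:5]), "pool size")
})

test_that("null calibration: KS p is roughly uniform for resampled pools", {
  set.seed(42)
  pool <- -2 + rnorm(300, 0, 0.5)
  ps <- replicate(200, {
    idx <- sample(300, 150)   # random disjoint split: exchangeable halves
    suppressWarnings(stats::ks.test(pool[idx], pool[-idx])$p.value)
  })
  # empirical type-I error at 5% within binomial scatter
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("reward_value_split pairs ROIs across valence", {
  set.seed(44)
  base <- seq(-3, -2, length.out = 10)
  amps <- rbind(amp_row("m1", "trained", "CIN", -2L, 1:10, base),
                amp_row("m1", "trained", "EU", -2L, 1:10,
                        base + rnorm(10, 0, 0.05)))
  vmap <- data.frame(mouse = "m1", odorant = c("CIN", "EU"),
                     valence = c("S+", "S-"))
  rv <- reward_value_split(amps, vmap)
  expect_equal(rv$n_pairs, 10)
  expect_gt(rv$test$p.value, 0.01)    # near-identical distributions

  pot <- amps
  pot$amplitude_permil[pot$odorant == "CIN"] <-
    pot$amplitude_permil[pot$odorant == "CIN"] * 2
  rv2 <- reward_value_split(pot, vmap)
  expect_lt(rv2$test$p.value, 0.01)

  expect_error(reward_value_split(amps, vmap[1, ]), "missing valence")
  expect_error(reward_value_split(amps[amps$odorant == "CIN", ], vmap),
               "both rewarded")
})

test_that("boltzmann_fit inverts noiseless data to machine precision", {
  x <- seq(0.1, 2.5, length.out = 8)
  y <- 95 + (50 - 95) / (1 + exp((x - 1.0) / 0.3))
  f <- boltzmann_fit(x, y)
  expect_equal(f$a1, 50, tolerance = 1e-6)
  expect_equal(f$a2, 95, tolerance = 1e-6)
  expect_equal(f$x0, 1.0, tolerance = 1e-6)
  expect_equal(f$dx, 0.3, tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_true(f$a1 < f$a2 && f$dx > 0)

  # first-order optimality: residuals orthogonal to the parameter gradients
  g <- f$nls$m$gradient()
  expect_lt(max(abs(crossprod(g, f$residuals))), 1e-4)

  expect_true(boltzmann_fit(1:4, rep(70, 4))$degenerate)
  expect_error(boltzmann_fit(1:3, c(50, 70, 90)), "at least 4")
})

test_that("threshold_accuracy_contrast attributes the accuracy gain", {
  mice <- paste0("m", 1:5)
  mk <- function(lo, hi, col) rbind(
    data.frame(mouse = mice, dilution_exponent = -3L, v = lo + rnorm(5, 0, 0.01)),
    data.frame(mouse = mice, dilution_exponent = -2L, v = hi + rnorm(5, 0, 0.01))) |>
    (\(d) { names(d)[3] <- col; d })()
  set.seed(43)
  acc <- mk(70, 90, "accuracy_pct")
  cnt_flat <- mk(5, 5, "count")
  amp_up <- mk(-1.0, -1.8, "amplitude_permil")     # magnitude rises
  res <- threshold_accuracy_contrast(acc, cnt_flat, amp_up, c(-3L, -2L))
  expect_identical(res$attribution, "amplitude")

  cnt_up <- mk(4, 9, "count")
  amp_flat <- mk(-1.2, -1.2, "amplitude_permil")
  res2 <- threshold_accuracy_contrast(acc, cnt_up, amp_flat, c(-3L, -2L))
  expect_identical(res2$attribution, "count")

  res3 <- threshold_accuracy_contrast(mk(80, 80, "accuracy_pct"),
                                      cnt_flat, amp_flat, c(-3L, -2L))
  expect_length(res3$attribution, 0)
  expect_error(threshold_accuracy_contrast(acc, cnt_up, amp_flat, -2L),
               "two exponents")
})

test_that("dilution classes cover both odor pairs", {
  dc <- dilution_classes()
  expect_setequal(unique(dc$odor_pair), c("CIN/EU", "IAA/EB"))
  expect_equal(sort(dc$dilution_exponent[dc$odor_pair == "CIN/EU" &
                                           dc$class == "high"]), c(-3, -2))
  expect_equal(sort(dc$dilution_exponent[dc$odor_pair == "IAA/EB" &
                                           dc$class == "high"]), c(-6, -4))
})
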