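noiseless_gt <- function(seed = 1L, ...)
  imaging_ground_truth(seed = seed, noise_sd_permil = 0, n_vessels = 0L, ...)

test_that("delta_map implements the ratio formula exactly", {
  # constant stack -> identically zero map
  gt <- noiseless_gt()
  st <- generate_trial_stack(gt, "CIN", -8L, 1L)  # below floor: no response
  dm <- delta_map(st)
  expect_true(all(dm$values == 0))

  # noiseless blob: map equals the injected amplitude at blob pixels
  st2 <- generate_trial_stack(gt, "CIN", 0L, 1L, group = "naive")
  dm2 <- delta_map(st2)
  blob <- st2$truth$blob_field
  expect_equal(dm2$values[blob != 0], blob[blob != 0], tolerance = 1e-9)

  # invariance to a positive gain applied to the whole stack
  st3 <- st2
  st3$frames <- st2$frames * 3.7
  expect_equal(delta_map(st3)$values, dm2$values, tolerance = 1e-12)
})

test_that("the optional spatial high-pass removes slow vignetting", {
  gt <- noiseless_gt(seed = 13L, n_glomeruli = 1L)
  st <- generate_trial_stack(gt, "CIN", 0L, 1L, group = "naive")
  # multiplicative vignette applied to response frames only: a slow spatial
  # gradient that a reference-map analysis should suppress
  w <- glomplast:::stack_windows(st)
  vignette <- outer(seq(0.999, 1.001, length.out = dim(st$frames)[2]),
                    rep(1, dim(st$frames)[3]))
  for (f in w$response) st$frames[f, , ] <- st$frames[f, , ] * vignette
  raw <- delta_map(st)
  hp <- delta_map(st, highpass_px = 15)
  blob <- st$truth$blob_field != 0
  amp <- unname(st$truth$amplitudes_permil[1])
  # the gradient adds up to +/-1 permil to the raw map; the high-pass
  # brings background pixels back near zero and keeps the blob contrast
  expect_gt(max(abs(raw$values[!blob])), 0.5)
  expect_lt(stats::median(abs(hp$values[!blob])), 0.15)
  expect_equal(mean(hp$values[blob]) - stats::median(hp$values[!blob]), amp,
               tolerance = 0.1)
})

test_that("delta_map masks zero-baseline pixels with a warning", {
  gt <- noiseless_gt()
  st <- generate_trial_stack(gt, "CIN", 0L, 1L)
  st$frames[, 1, 1] <- 0
  expect_warning(dm <- delta_map(st), "zero-baseline")
  expect_true(is.na(dm$values[1, 1]))
})

test_that("noisy blob means sit within 3 analytic SEs of the injection", {
  gt <- imaging_ground_truth(seed = 6L, noise_sd_permil = 0.3, n_vessels = 0L)
  st <- generate_trial_stack(gt, "CIN", 0L, 1L, group = "naive")
  dm <- delta_map(st)
  for (i in seq_len(gt$n_glomeruli)) {
    mask <- glomplast:::disc_mask(gt$field_shape, gt$centers[i, ], gt$radii[i])
    est <- mean(dm$values[mask])
    se <- 0.3 * sqrt(1 / length(dm$response_frames) +
                       1 / length(dm$baseline_frames)) / sqrt(sum(mask))
    expect_lt(abs(est - st$truth$amplitudes_permil[i]), 4 * se)
  }
  # the robust noise estimate recovers the injected noise level
  expect_equal(dm$noise_sd_permil, 0.3, tolerance = 0.05)
})

test_that("average_repetitions averages values and enforces metadata", {
  gt <- noiseless_gt(seed = 7L)
  maps <- lapply(make_rep_stacks(gt), delta_map)
  avg <- average_repetitions(maps)
  expect_equal(avg$values, maps[[1]]$values)  # noiseless: all reps identical
  expect_equal(avg$n_reps, 4L)

  # permuting repetition order changes nothing
  avg2 <- average_repetitions(maps[c(3, 1, 4, 2)])
  expect_equal(avg2$values, avg$values)

  other <- delta_map(generate_trial_stack(gt, "EU", 0L, 1L))
  expect_error(average_repetitions(list(maps[[1]], other)), "mismatched")

  # averaging reduces noise variance by the number of repetitions
  gtn <- imaging_ground_truth(seed = 8L, n_glomeruli = 0L, n_vessels = 0L)
  mn <- lapply(make_rep_stacks(gtn), delta_map)
  v1 <- var(as.numeric(mn[[1]]$values))
  v4 <- var(as.numeric(average_repetitions(mn)$values))
  expect_equal(v1 / v4, 4, tolerance = 0.6)
})

test_that("detect_rois recovers blobs and applies both exclusion rules", {
  for (sd in 1:3) {
    gt <- imaging_ground_truth(seed = sd, artifact = TRUE)
    stacks <- list(CIN = make_rep_stacks(gt))
    rois <- detect_rois(stacks)
    m <- oracle_match_rois(rois, gt)
    expect_equal(m$recall, 1)
    expect_equal(m$precision, 1)
    # determinism
    rois2 <- detect_rois(stacks)
    expect_identical(lapply(rois, `[[`, "pixels"),
                     lapply(rois2, `[[`, "pixels"))
    # no ROI touches a vessel or the single-frame artifact
    vmask <- Reduce(`|`, lapply(gt$vessels, function(v)
      glomplast:::vessel_mask(gt$field_shape, v)))
    amask <- glomplast:::disc_mask(gt$field_shape, gt$artifact_center, 3)
    for (r in rois) {
      lin <- (r$pixels[, 2] - 1L) * gt$field_shape[1] + r$pixels[, 1]
      expect_equal(sum(vmask[lin]), 0L)
      expect_equal(sum(amask[lin]), 0L)
    }
  }
})

test_that("empty fields give an empty map with a warning", {
  gt <- noiseless_gt(seed = 9L)
  st <- make_rep_stacks(gt, dil = -8L)   # below floor: nothing responds
  expect_warning(rois <- detect_rois(list(CIN = st)), "no ROIs")
  expect_length(rois, 0)
})

test_that("quantify reads exact amplitudes through the reference map", {
  gt <- noiseless_gt(seed = 10L)
  stacks <- list(CIN = make_rep_stacks(gt, group = "trained"))
  gmap <- build_reference_map(stacks, group = "trained")
  avg <- average_repetitions(lapply(stacks$CIN, delta_map))
  gmap <- quantify(gmap, avg)
  a <- gmap$amplitudes
  # every quantified amplitude equals an injected amplitude exactly
  inj <- sort(generate_trial_stack(gt, "CIN", 0L, 1L,
                                   group = "trained")$truth$amplitudes_permil)
  expect_equal(sort(a$amplitude_permil), inj, tolerance = 1e-9)

  # dilution series reproduces the programmed attenuation (trained group:
  # every glomerulus stays responsive across these dilutions)
  for (d in c(-3L, -1L)) {
    avg_d <- average_repetitions(lapply(
      make_rep_stacks(gt, dil = d, group = "trained"), delta_map))
    gmap <- quantify(gmap, avg_d)
  }
  a <- gmap$amplitudes
  att <- dilution_attenuation(c(-3, -1), gt) / dilution_attenuation(0, gt)
  for (r in gmap$rois) {
    amps <- a$amplitude_permil[a$roi_id == r$id]
    expect_equal(amps[2] / amps[1], att[1], tolerance = 1e-6)
    expect_equal(amps[3] / amps[1], att[2], tolerance = 1e-6)
  }

  bad <- gmap
  bad$rois[[1]]$pixels[1, ] <- c(500L, 500L)
  expect_error(quantify(bad, avg), "outside image")
})

test_that("count_activated counts supra-threshold ROIs, monotone in k", {
  gt <- noiseless_gt(seed = 11L)
  stacks <- list(CIN = make_rep_stacks(gt, group = "naive"))
  gmap <- build_reference_map(stacks, group = "naive")
  avg <- average_repetitions(lapply(stacks$CIN, delta_map))
  gmap <- quantify(gmap, avg)
  expect_equal(count_activated(gmap, "CIN", 0L), gt$n_glomeruli)

  # zero-amplitude stimulus: nothing is activated
  blank <- average_repetitions(lapply(
    make_rep_stacks(gt, dil = -8L, group = "naive"), delta_map))
  gmap <- quantify(gmap, blank, odorant = "CIN", dilution_exponent = -8L)
  expect_equal(count_activated(gmap, "CIN", -8L), 0L)

  # monotone non-increasing in the activation threshold (noisy case)
  gtn <- imaging_ground_truth(seed = 12L, n_vessels = 0L)
  sn <- list(CIN = make_rep_stacks(gtn, group = "naive"))
  gm <- build_reference_map(sn, group = "naive")
  gm <- quantify(gm, average_repetitions(lapply(sn$CIN, delta_map)))
  ks <- c(1, 2, 3, 5, 10, 100)
  counts <- vapply(ks, function(k)
    count_activated(gm, "CIN", 0L, activation_k = k), integer(1))
  expect_true(all(diff(counts) <= 0))
})
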