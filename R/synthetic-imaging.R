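#' Ground truth for synthetic IOS trial stacks
#'
#' Describes a synthetic dorsal-olfactory-bulb field of view: glomerular
#' blob positions, radii and per-odorant response amplitudes (negative
#' delta-R/R, i.e. reflectance darkening at 700 nm), blood-vessel artifact
#' masks, camera noise, and acquisition timing. Group-level plasticity is
#' programmed with two multipliers: \code{group_amplitude_scale} scales the
#' response amplitude of trained mice, and \code{group_count_scale} scales
#' the fraction of glomeruli that remain responsive at high (weak-stimulus)
#' dilutions relative to the naive group.
#'
#' @param field_shape integer c(rows, cols) of the imaging field.
#' @param n_glomeruli number of glomerular blobs.
#' @param odorants character vector of odorant labels; each glomerulus gets
#'   an independent base amplitude per odorant.
#' @param amplitude_range_permil range (negative) from which per-odorant
#'   base amplitudes are drawn, in permil delta-R/R at the strongest
#'   dilution.
#' @param group_amplitude_scale multiplier applied to trained-group
#'   amplitudes (default 1.5).
#' @param group_count_scale trained-vs-naive ratio of the fraction of
#'   glomeruli responsive at high dilutions (default 3).
#' @param naive_high_fraction fraction of glomeruli responsive at high
#'   dilutions in the naive and exposed groups (default 1/3 so the default
#'   count ratio is 3).
#' @param high_floor_exponent glomeruli not in the high-dilution responsive
#'   set respond only for dilution exponents strictly above this value.
#' @param floor_exponent dilution exponent at and below which no glomerulus
#'   responds (below the behavioural discrimination threshold no activated
#'   glomeruli are detectable).
#' @param atten_midpoint,atten_width Boltzmann-shaped dilution attenuation
#'   of blob amplitudes: \code{1/(1 + exp(-(d - midpoint)/width))} for
#'   exponent \code{d} above \code{floor_exponent}, 0 otherwise.
#' @param n_vessels number of elongated vessel artifacts (aspect ratio > 4).
#' @param vessel_amplitude_permil delta-R/R injected along vessels during
#'   the odor window.
#' @param artifact if TRUE, inject one large-amplitude blob present in a
#'   single frame only (exercises the single-frame exclusion rule).
#' @param noise_sd_permil per-frame, per-pixel Gaussian noise SD in permil
#'   of the baseline reflectance.
#' @param frame_rate_hz acquisition rate; default 2 Hz.
#' @param duration_s stack duration; default 10 s.
#' @param odor_window_s odor onset/offset in seconds (default c(2, 7):
#'   odor delivered for 5 s starting 2 s after recording onset).
#' @param baseline_level mean reflectance counts.
#' @param seed integer seed.
#'
#' @return An object of class \code{imaging_ground_truth}; the blob layout
#'   (centres, radii, per-odorant amplitudes, high-dilution responsiveness)
#'   and vessel masks are drawn here once so that every stack generated from
#'   the same ground truth shares one anatomical field.
#' @export
imaging_ground_truth <- function(field_shape = c(72L, 72L),
                                 n_glomeruli = 10L,
                                 odorants = c("CIN", "EU"),
                                 amplitude_range_permil = c(-3.5, -1.5),
                                 group_amplitude_scale = 1.5,
                                 group_count_scale = 3,
                                 naive_high_fraction = 1 / 3,
                                 high_floor_exponent = -1.5,
                                 floor_exponent = -5,
                                 atten_midpoint = -3,
                                 atten_width = 0.8,
                                 n_vessels = 2L,
                                 vessel_amplitude_permil = -1.5,
                                 artifact = FALSE,
                                 noise_sd_permil = 0.3,
                                 frame_rate_hz = 2,
                                 duration_s = 10,
                                 odor_window_s = c(2, 7),
                                 baseline_level = 4000,
                                 seed = 1L) {
  stopifnot(length(field_shape) == 2L, all(field_shape > 0))
  if (group_amplitude_scale <= 0 || group_count_scale <= 0)
    stop_invalid("group scales must be positive")
  set.seed(seed)
  nr <- field_shape[1]; nc <- field_shape[2]

  # non-overlapping blob placement away from the field edge
  radii <- runif(n_glomeruli, 2.5, 4.5)
  centers <- matrix(NA_real_, n_glomeruli, 2L)
  margin <- if (n_glomeruli > 0L) max(radii) + 2 else 5
  for (i in seq_len(n_glomeruli)) {
    for (try in 1:2000) {
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (i == 1L) break
      d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 2L, byrow = TRUE))^2))
      if (all(d > radii[i] + radii[seq_len(i - 1L)] + 6)) break
      if (try == 2000) stop("blob placement failed; field too crowded")
    }
    centers[i, ] <- cand
  }
  stopifnot(all(centers[, 1] > radii), all(centers[, 1] < nr - radii + 1),
            all(centers[, 2] > radii), all(centers[, 2] < nc - radii + 1))

  base_amp <- matrix(runif(n_glomeruli * length(odorants),
                           amplitude_range_permil[1],
                           amplitude_range_permil[2]),
                     n_glomeruli, length(odorants),
                     dimnames = list(NULL, odorants))
  if (any(base_amp >= 0))
    stop_invalid("base amplitudes must be negative (reflectance darkening)")

  n_high_naive <- max(0L, round(naive_high_fraction * n_glomeruli))
  n_high_trained <- min(n_glomeruli,
                        round(naive_high_fraction * group_count_scale *
                                n_glomeruli))
  # deterministic membership by index keeps reference maps comparable
  high_set <- list(trained = seq_len(n_high_trained),
                   exposed = seq_len(n_high_naive),
                   naive = seq_len(n_high_naive))

  # vessels avoid the glomerular discs so elongation cleanly separates the
  # two structure classes (surface vessels run between glomeruli here)
  seg_clear <- function(center, len, wid, ang) {
    e <- c(cos(ang), sin(ang)) * len / 2
    p1 <- center - e; p2 <- center + e
    d <- vapply(seq_len(n_glomeruli), function(i) {
      v <- p2 - p1; w <- centers[i, ] - p1
      tt <- max(0, min(1, sum(w * v) / sum(v * v)))
      sqrt(sum((w - tt * v)^2))
    }, numeric(1))
    all(d > radii + wid / 2 + 3)
  }
  seg_points <- function(v)
    cbind(v$center[1] + cos(v$angle) * seq(-v$length / 2, v$length / 2,
                                           length.out = 25),
          v$center[2] + sin(v$angle) * seq(-v$length / 2, v$length / 2,
                                           length.out = 25))
  vessels <- list()
  for (v in seq_len(n_vessels)) {
    placed <- FALSE
    for (try in 1:2000) {
      wid <- runif(1, 3.5, 4.5)
      len <- wid * runif(1, 5.5, 6.5)  # aspect well above the ratio-4 rule
      ang <- runif(1, 0, pi)
      ctr <- c(runif(1, len / 2 + 2, nr - len / 2 - 2),
               runif(1, len / 2 + 2, nc - len / 2 - 2))
      cand <- list(center = ctr, length = len, width = wid, angle = ang)
      if (!seg_clear(ctr, len, wid, ang)) next
      # vessels must not touch each other (a crossing would defeat the
      # elongation criterion even for a perfect detector)
      clear <- TRUE
      for (prev in vessels) {
        pd <- min(as.matrix(stats::dist(rbind(seg_points(cand),
                                              seg_points(prev))))[
                                                seq_len(25), 25 + seq_len(25)])
        if (pd < (wid + prev$width) / 2 + 4) { clear <- FALSE; break }
      }
      if (clear) { vessels[[v]] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("vessel placement failed; field too crowded")
  }

  artifact_center <- NULL
  if (isTRUE(artifact)) {
    seg_dist <- function(p, v) {
      e <- c(cos(v$angle), sin(v$angle)) * v$length / 2
      p1 <- v$center - e; vv <- 2 * e; w <- p - p1
      tt <- max(0, min(1, sum(w * vv) / sum(vv * vv)))
      sqrt(sum((w - tt * vv)^2)) - v$width / 2
    }
    for (try in 1:2000) {
      cand <- c(runif(1, 6, nr - 6), runif(1, 6, nc - 6))
      d_blob <- sqrt(rowSums((centers -
                                matrix(cand, nrow(centers), 2,
                                       byrow = TRUE))^2)) - radii
      d_ves <- vapply(vessels, seg_dist, numeric(1), p = cand)
      if (all(d_blob > 6) && all(d_ves > 6)) { artifact_center <- cand; break }
    }
    if (is.null(artifact_center)) stop("artifact placement failed")
  }

  structure(list(field_shape = as.integer(field_shape),
                 n_glomeruli = as.integer(n_glomeruli),
                 odorants = odorants,
                 centers = centers, radii = radii, base_amp = base_amp,
                 group_amplitude_scale = group_amplitude_scale,
                 group_count_scale = group_count_scale,
                 high_set = high_set,
                 high_floor_exponent = high_floor_exponent,
                 floor_exponent = floor_exponent,
                 atten_midpoint = atten_midpoint,
                 atten_width = atten_width,
                 vessels = vessels,
                 vessel_amplitude_permil = vessel_amplitude_permil,
                 artifact = isTRUE(artifact),
                 artifact_center = artifact_center,
                 noise_sd_permil = noise_sd_permil,
                 frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s,
                 odor_window_s = odor_window_s,
                 baseline_level = baseline_level,
                 seed = as.integer(seed)),
            class = "imaging_ground_truth")
}

#' Dilution attenuation of synthetic blob amplitudes
#'
#' Log-linear saturating ramp: zero at and below the floor exponent
#' (stimuli below the discrimination threshold evoke no detectable
#' glomerular response), Boltzmann-shaped above it, saturating towards 1
#' at the undiluted stimulus.
#'
#' @param d dilution exponent(s) (log10 percentile dilution, <= 0).
#' @param gt an \code{\link{imaging_ground_truth}}.
#' @return attenuation factor(s) in [0, 1].
#' @export
dilution_attenuation <- function(d, gt) {
  a <- 1 / (1 + exp(-(d - gt$atten_midpoint) / gt$atten_width))
  a[d <= gt$floor_exponent] <- 0
  a
}

disc_mask <- function(shape, center, radius) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

vessel_mask <- function(shape, v) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rows - v$center[1]; dc <- cols - v$center[2]
  along <- dr * cos(v$angle) + dc * sin(v$angle)
  across <- -dr * sin(v$angle) + dc * cos(v$angle)
  abs(along) <= v$length / 2 & abs(across) <= v$width / 2
}

# injected per-glomerulus amplitudes (permil) for one stimulus
injected_amplitudes <- function(gt, odorant, dilution_exponent, group) {
  att <- dilution_attenuation(dilution_exponent, gt)
  amp <- gt$base_amp[, odorant] * att
  if (group == "trained") amp <- amp * gt$group_amplitude_scale
  responsive <- seq_len(gt$n_glomeruli) %in% gt$high_set[[group]] |
    dilution_exponent > gt$high_floor_exponent
  amp[!responsive] <- 0
  amp
}

#' Generate a synthetic IOS trial stack
#'
#' Builds one imaging acquisition: baseline frames before odor onset, then
#' odor frames in which each responsive glomerulus darkens by its injected
#' delta-R/R (base amplitude x dilution attenuation x group amplitude
#' scale), plus vessel artifacts, an optional single-frame transient, and
#' per-frame Gaussian camera noise. The injected per-glomerulus amplitudes
#' and the noiseless delta field are recorded in \code{$truth}.
#'
#' @param gt an \code{\link{imaging_ground_truth}}.
#' @param odorant one of \code{gt$odorants}.
#' @param dilution_exponent integer log10 dilution.
#' @param repetition repetition index in 1..4.
#' @param group experimental group of the imaged mouse.
#' @param seed optional seed override for the noise draw; defaults to a
#'   value derived from \code{gt$seed} and the stimulus coordinates so that
#'   repetitions differ but are reproducible.
#'
#' @return An object of class \code{glom_stack}: \code{frames} (time x rows
#'   x cols reflectance array), acquisition metadata, and \code{truth}.
#' @export
generate_trial_stack <- function(gt, odorant, dilution_exponent,
                                 repetition = 1L, group = "trained",
                                 seed = NULL) {
  stopifnot(inherits(gt, "imaging_ground_truth"))
  group <- match.arg(group, c("trained", "exposed", "naive"))
  if (!odorant %in% gt$odorants) stop_invalid("unknown odorant ", odorant)
  if (!repetition %in% 1:4) stop_invalid("repetition must be in 1..4")
  if (gt$odor_window_s[2] > gt$duration_s)
    stop_invalid("odor window exceeds stack duration")

  shape <- gt$field_shape
  n_frames <- round(gt$duration_s * gt$frame_rate_hz)
  frame_t <- (seq_len(n_frames) - 0.5) / gt$frame_rate_hz  # frame mid-times
  in_odor <- frame_t > gt$odor_window_s[1] & frame_t < gt$odor_window_s[2]

  amp <- injected_amplitudes(gt, odorant, dilution_exponent, group)
  blob_field <- matrix(0, shape[1], shape[2])
  for (i in seq_len(gt$n_glomeruli))
    if (amp[i] != 0)
      blob_field <- blob_field +
        amp[i] * disc_mask(shape, gt$centers[i, ], gt$radii[i])
  vessel_field <- matrix(0, shape[1], shape[2])
  for (v in gt$vessels)
    vessel_field <- vessel_field + gt$vessel_amplitude_permil *
      vessel_mask(shape, v)

  if (is.null(seed))
    seed <- (gt$seed * 7L + match(odorant, gt$odorants) * 1009L +
               (dilution_exponent + 12L) * 131L + repetition * 17L +
               match(group, c("trained", "exposed", "naive")) * 23L) %%
      .Machine$integer.max
  set.seed(seed)

  # one transient artifact per stimulus set, injected in the first
  # repetition only; its frame is drawn here, its location is fixed in the
  # ground truth (clear of blobs and vessels, so the single-frame
  # exclusion rule has an unambiguous correct answer)
  inject_artifact <- gt$artifact && repetition == 1L
  artifact_frame <- if (inject_artifact) sample(which(in_odor), 1L)
    else NA_integer_
  artifact_field <- if (inject_artifact)
    -40 * disc_mask(shape, gt$artifact_center, 3) else NULL

  R0 <- gt$baseline_level
  frames <- array(0, dim = c(n_frames, shape[1], shape[2]))
  delta <- (blob_field + vessel_field) / 1000
  flat <- matrix(0, shape[1], shape[2])
  for (f in seq_len(n_frames)) {
    img <- R0 * (1 + (if (in_odor[f]) delta else flat))
    if (inject_artifact && f == artifact_frame)
      img <- img + R0 * artifact_field / 1000
    if (gt$noise_sd_permil > 0)
      img <- img + rnorm(length(img), 0, R0 * gt$noise_sd_permil / 1000)
    frames[f, , ] <- img
  }

  structure(list(frames = frames,
                 frame_rate_hz = gt$frame_rate_hz,
                 odor_window_s = gt$odor_window_s,
                 odorant = odorant,
                 dilution_exponent = as.integer(dilution_exponent),
                 repetition = as.integer(repetition),
                 group = group,
                 truth = list(amplitudes_permil = amp,
                              centers = gt$centers, radii = gt$radii,
                              blob_field = blob_field,
                              vessel_field = vessel_field,
                              artifact_frame = artifact_frame,
                              artifact_field = artifact_field,
                              noise_sd_permil = gt$noise_sd_permil)),
            class = "glom_stack")
}

#' @export
print.glom_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<glom_stack> %s 10^%d rep %d (%s): %d frames %dx%d @ %g Hz\n",
              x$odorant, x$dilution_exponent, x$repetition, x$group,
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}
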