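#' Ground truth for a synthetic respiration trace
#'
#' @param base_frequency_hz breathing frequency in Hz; must lie in the
#'   physiological band 1-12 Hz (awake head-restrained mice breathe near
#'   3.1 Hz).
#' @param jitter_cv coefficient of variation of the cycle period.
#' @param duration_s trace duration in seconds.
#' @param sample_rate_hz sampling rate of the airflow sensor signal.
#' @param seed integer seed.
#' @return An object of class \code{respiration_ground_truth}.
#' @export
respiration_ground_truth <- function(base_frequency_hz = 3.1,
                                     jitter_cv = 0.05,
                                     duration_s = 10,
                                     sample_rate_hz = 200,
                                     seed = 1L) {
  if (base_frequency_hz < 1 || base_frequency_hz > 12)
    stop_invalid("base_frequency_hz outside physiological band 1-12 Hz")
  if (duration_s <= 0 || sample_rate_hz <= 0)
    stop_invalid("duration and sample rate must be positive")
  structure(list(base_frequency_hz = base_frequency_hz,
                 jitter_cv = jitter_cv, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
            class = "respiration_ground_truth")
}

#' Generate a synthetic airflow (respiration) trace
#'
#' Quasi-sinusoidal directional airflow signal whose cycle periods are
#' jittered multiplicatively by \code{jitter_cv}. Inspiration is negative
#' and expiration positive by convention. Ground-truth cycle start times
#' are recorded alongside.
#'
#' @param gt a \code{\link{respiration_ground_truth}}.
#' @param odor_window_s analysis window carried as metadata (default
#'   \code{c(2, 4)}: the 2 s odor presentation).
#' @return An object of class \code{airflow_trace}: \code{times_s},
#'   \code{signal}, \code{odor_window_s}, and \code{cycle_times_s} (ground
#'   truth).
#' @export
generate_respiration <- function(gt, odor_window_s = c(2, 4)) {
  stopifnot(inherits(gt, "respiration_ground_truth"))
  set.seed(gt$seed)
  t0 <- 1 / gt$base_frequency_hz
  n_cycles <- ceiling(gt$duration_s / t0 * 1.8) + 4L
  periods <- t0 * pmax(0.2, 1 + gt$jitter_cv * rnorm(n_cycles))
  starts <- cumsum(c(0, periods))
  starts <- starts[starts < gt$duration_s + t0]

  times <- seq(0, gt$duration_s, by = 1 / gt$sample_rate_hz)
  # phase advances by one turn per jittered cycle; signal = sin(2*pi*phase)
  idx <- findInterval(times, starts)
  idx[idx < 1L] <- 1L
  frac <- (times - starts[idx]) / diff(starts)[pmin(idx, length(starts) - 1L)]
  signal <- sin(2 * pi * pmin(pmax(frac, 0), 1))
  structure(list(times_s = times, signal = signal,
                 odor_window_s = odor_window_s,
                 cycle_times_s = starts,
                 ground_truth = gt),
            class = "airflow_trace")
}

# centred moving-average low-pass (zero-phase: a pure sinusoid below the
# cutoff maps to a positively scaled sinusoid, so zero crossings move only
# at the trace edges, which are excluded from the analysis window)
lowpass_ma <- function(x, sample_rate_hz, cutoff_hz) {
  L <- 2L * floor(sample_rate_hz / cutoff_hz / 2) + 1L
  if (L <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / L, L), sides = 2))
}

#' Breathing frequency from an airflow trace
#'
#' Cycles are detected as successive negative-to-positive zero crossings of
#' the mean-subtracted, low-pass-filtered signal (zero-phase moving-average
#' filter, cutoff 15 Hz by default) inside the analysis window; crossing
#' times are refined by linear interpolation. Frequency is the number of complete
#' cycles divided by the time spanned by those cycles, which is exact for a
#' pure tone and grid-free for jittered breathing.
#'
#' @param trace an \code{airflow_trace} (or a list with \code{times_s},
#'   \code{signal}).
#' @param window_s analysis window \code{c(start, end)} in seconds;
#'   defaults to the trace's odor window.
#' @param cutoff_hz low-pass cutoff.
#' @return An object of class \code{breathing_estimate}: \code{frequency_hz},
#'   \code{n_cycles}, \code{window_s}, \code{crossing_times_s}. Frequency is
#'   \code{NA} with a warning if fewer than two crossings fall in the
#'   window.
#' @export
breathing_frequency <- function(trace, window_s = NULL, cutoff_hz = 15) {
  window_s <- window_s %||% trace$odor_window_s
  t <- trace$times_s; x <- trace$signal
  if (window_s[1] < t[1] - 1e-9 || window_s[2] > t[length(t)] + 1e-9)
    stop_invalid("analysis window outside trace")
  dt <- diff(t[1:2])
  y <- lowpass_ma(x - mean(x, na.rm = TRUE), 1 / dt, cutoff_hz)
  up <- which(y[-length(y)] < 0 & y[-1] >= 0)
  cross <- t[up] + dt * y[up] / (y[up] - y[up + 1])
  cross <- cross[cross >= window_s[1] & cross <= window_s[2]]
  if (length(cross) < 2L) {
    warning("no complete breathing cycle in window")
    return(structure(list(frequency_hz = NA_real_, n_cycles = 0L,
                          window_s = window_s, crossing_times_s = cross),
                     class = "breathing_estimate"))
  }
  n_cycles <- length(cross) - 1L
  structure(list(frequency_hz = n_cycles / (cross[n_cycles + 1L] - cross[1L]),
                 n_cycles = n_cycles, window_s = window_s,
                 crossing_times_s = cross),
            class = "breathing_estimate")
}

#' IOS amplitude as a function of breathing frequency
#'
#' Bins per-trial glomerular response amplitudes by the breathing frequency
#' measured on the same trial, normalises every bin to the reference bin
#' (1.8 Hz by default), and runs a paired nonparametric comparison (Wilcoxon
#' signed-rank over ROI means) between the reference bin and the fastest
#' bin. Under frequency-independent responses all normalised bin means are
#' close to 1 and the paired test is non-significant.
#'
#' @param data data frame with columns \code{roi}, \code{freq_hz},
#'   \code{amplitude_permil} (one row per trial x ROI).
#' @param bins_hz nominal bin centres.
#' @param ref_hz reference bin centre for normalisation.
#' @param tol_hz half-width of each frequency bin.
#' @param test_hz bin compared against the reference (default the largest
#'   bin centre).
#' @return list with \code{bins} (data frame: \code{freq_hz},
#'   \code{normalized_mean}, \code{sem}, \code{n_roi}) and \code{test}
#'   (the paired \code{wilcox.test} result, or NULL if not computable).
#' @export
amplitude_vs_frequency <- function(data,
                                   bins_hz = c(1.8, 2, 2.2, 2.4, 2.6, 2.8, 3),
                                   ref_hz = 1.8, tol_hz = 0.1,
                                   test_hz = max(bins_hz)) {
  stopifnot(all(c("roi", "freq_hz", "amplitude_permil") %in% names(data)))
  if (!ref_hz %in% bins_hz) stop_invalid("ref_hz must be one of bins_hz")
  per_bin_roi <- lapply(bins_hz, function(b) {
    sel <- abs(data$freq_hz - b) <= tol_hz
    if (!any(sel)) return(NULL)
    stats::aggregate(amplitude_permil ~ roi, data = data[sel, ], FUN = mean)
  })
  names(per_bin_roi) <- as.character(bins_hz)
  ref <- per_bin_roi[[as.character(ref_hz)]]
  if (is.null(ref)) stop_invalid("reference bin is empty")
  rows <- list()
  for (b in as.character(bins_hz)) {
    bb <- per_bin_roi[[b]]
    if (is.null(bb)) { warning("empty frequency bin ", b, " Hz omitted"); next }
    m <- merge(bb, ref, by = "roi", suffixes = c("", "_ref"))
    ratio <- m$amplitude_permil / m$amplitude_permil_ref
    rows[[b]] <- data.frame(freq_hz = as.numeric(b),
                            normalized_mean = mean(ratio),
                            sem = sd(ratio) / sqrt(length(ratio)),
                            n_roi = nrow(m))
  }
  bins <- do.call(rbind, rows)
  test <- NULL
  tb <- per_bin_roi[[as.character(test_hz)]]
  if (!is.null(tb) && !is.null(ref)) {
    m <- merge(tb, ref, by = "roi", suffixes = c("_test", "_ref"))
    if (nrow(m) >= 3L)
      test <- wilcox.test(m$amplitude_permil_test, m$amplitude_permil_ref,
                          paired = TRUE, exact = FALSE)
  }
  list(bins = bins, test = test, ref_hz = ref_hz, test_hz = test_hz)
}
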