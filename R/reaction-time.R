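#' Beam-break matrices from a session
#'
#' Splits the session's beam-break traces (trials x time, logical: beam
#' broken) into the S+ and S- trial classes over a common time grid.
#'
#' @param session a \code{glom_session}.
#' @return An object of class \code{beam_break_matrix}: \code{times_ms},
#'   \code{sp_traces}, \code{sm_traces}.
#' @export
beam_break_matrix <- function(session) {
  sp <- session$trials$valence == "S+"
  m <- structure(list(times_ms = session$beam$times_ms,
                      sp_traces = session$beam$traces[sp, , drop = FALSE],
                      sm_traces = session$beam$traces[!sp, , drop = FALSE]),
                 class = "beam_break_matrix")
  if (nrow(m$sp_traces) == 0L || nrow(m$sm_traces) == 0L)
    stop_invalid("both trial classes must be non-empty")
  m
}

#' Time-resolved bootstrap comparison of S+ vs S- beam breaking
#'
#' At each time point t after odor onset the observed statistic is
#' d(t) = (fraction of S+ trials with the beam broken at t) minus the same
#' fraction for S- trials. Trials are resampled with replacement within
#' class B times; the significance value p(t) is the bootstrap probability
#' that the resampled statistic d*(t) is at or below zero (one-sided: S+
#' animals keep breaking the beam, S- animals retract). p is floored at
#' 1/(B + 1) so that log p stays finite.
#'
#' @param m a \code{\link{beam_break_matrix}}.
#' @param n_boot number of bootstrap resamples B (default 1000).
#' @param seed integer seed for the resampling.
#' @param alpha significance threshold carried to the RT estimators.
#' @param alternative \code{"greater"} (default, one-sided d > 0) or
#'   \code{"two.sided"}.
#' @param min_trials minimum trials required per class.
#' @return An object of class \code{pvalue_curve}: \code{times_ms},
#'   \code{p}, \code{d} (observed statistic), plus the call parameters.
#' @export
pvalue_curve <- function(m, n_boot = 1000L, seed = 1L, alpha = 0.05,
                         alternative = c("greater", "two.sided"),
                         min_trials = 10L) {
  alternative <- match.arg(alternative)
  sp <- m$sp_traces * 1; sm <- m$sm_traces * 1
  n_sp <- nrow(sp); n_sm <- nrow(sm)
  if (n_sp < min_trials || n_sm < min_trials)
    stop_invalid("need at least ", min_trials, " trials per class")
  set.seed(seed)
  # bootstrap class means via multinomial resampling counts; sums stay
  # integer-exact so resampled ties at d* = 0 are counted as such
  w_sp <- rmultinom(n_boot, n_sp, rep(1, n_sp))   # n_sp x B
  w_sm <- rmultinom(n_boot, n_sm, rep(1, n_sm))
  d_star <- crossprod(w_sp, sp) / n_sp - crossprod(w_sm, sm) / n_sm  # B x T
  tol <- 1e-12
  p_le0 <- colMeans(d_star <= tol)
  p <- switch(alternative,
              greater = p_le0,
              two.sided = pmin(1, 2 * pmin(p_le0, colMeans(d_star >= -tol))))
  p <- pmax(p, 1 / (n_boot + 1))
  structure(list(times_ms = m$times_ms, p = p,
                 d = colMeans(sp) - colMeans(sm),
                 alpha = alpha, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), alternative = alternative),
            class = "pvalue_curve")
}

#' Reaction time as the last crossing of the significance line
#'
#' The reaction time is the latest time t* such that p(t) stays below
#' alpha from t* through the end of the 2 s window, with p at the grid
#' point before t* at or above alpha (the final downward crossing of the
#' p = alpha line). If p never stays below alpha the RT is undefined; if p
#' is below alpha from the first grid point, the first grid point is
#' returned with a boundary flag.
#'
#' @param curve a \code{\link{pvalue_curve}}.
#' @param alpha significance threshold; defaults to the curve's.
#' @return An object of class \code{reaction_time}: \code{rt_ms} (NA when
#'   undefined), \code{method = "last_crossing"}, \code{boundary},
#'   \code{defined}, and the curve.
#' @export
reaction_time_last_crossing <- function(curve, alpha = curve$alpha) {
  p <- curve$p; t <- curve$times_ms
  n <- length(p)
  if (p[n] >= alpha)
    return(structure(list(rt_ms = NA_real_, method = "last_crossing",
                          defined = FALSE, boundary = FALSE, curve = curve),
                     class = "reaction_time"))
  at_or_above <- which(p >= alpha)
  if (length(at_or_above) == 0L)
    return(structure(list(rt_ms = t[1], method = "last_crossing",
                          defined = TRUE, boundary = TRUE, curve = curve),
                     class = "reaction_time"))
  j <- max(at_or_above)
  structure(list(rt_ms = t[j + 1L], method = "last_crossing",
                 defined = TRUE, boundary = FALSE, curve = curve),
            class = "reaction_time")
}

#' Reaction time as the point of largest curvature of log p vs t
#'
#' Fallback estimator mirroring visual identification of the reaction
#' time: after a 3-point moving-average smoothing of log10 p(t), the
#' discrete curvature |y''| / (1 + y'^2)^(3/2) (with time in seconds so
#' slope and curvature are on comparable scales) is evaluated at interior
#' grid points, and the RT is the time of its maximum. A flat or purely
#' linear log-p curve has no distinguished point and yields an undefined
#' RT.
#'
#' @param curve a \code{\link{pvalue_curve}} with at least 5 points.
#' @param flat_tol curvature below this value (and log-p range below 0.1
#'   decades) is treated as flat/linear.
#' @return A \code{reaction_time} with \code{method = "curvature"}.
#' @export
reaction_time_curvature <- function(curve, flat_tol = 1e-6) {
  t <- curve$times_ms; p <- curve$p
  if (length(p) < 5L) stop_invalid("need at least 5 points")
  y <- log10(p)
  y <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  y[1] <- y[2]; y[length(y)] <- y[length(y) - 1]
  ts <- t / 1000
  h <- diff(ts[1:2])
  # endpoints are padded after smoothing, so the two outermost interior
  # points carry spurious curvature and are excluded from the argmax
  i <- if (length(y) >= 7L) 3:(length(y) - 2L) else 2:(length(y) - 1L)
  d1 <- (y[i + 1L] - y[i - 1L]) / (2 * h)
  d2 <- (y[i + 1L] - 2 * y[i] + y[i - 1L]) / h^2
  kappa <- abs(d2) / (1 + d1^2)^(3 / 2)
  if (max(kappa) < flat_tol || diff(range(y)) < 0.1)
    return(structure(list(rt_ms = NA_real_, method = "curvature",
                          defined = FALSE, boundary = FALSE, curve = curve),
                     class = "reaction_time"))
  structure(list(rt_ms = t[i[which.max(kappa)]], method = "curvature",
                 defined = TRUE, boundary = FALSE, curve = curve),
            class = "reaction_time")
}

#' Session-level reaction time
#'
#' Convenience wrapper: builds the beam-break matrix, computes the
#' bootstrap p(t) curve, and applies the requested estimator.
#'
#' @param session a \code{glom_session}.
#' @param method \code{"last_crossing"} (default) or \code{"curvature"}.
#' @param ... passed to \code{\link{pvalue_curve}}.
#' @return a \code{reaction_time}.
#' @export
reaction_time <- function(session, method = c("last_crossing", "curvature"),
                          ...) {
  method <- match.arg(method)
  curve <- pvalue_curve(beam_break_matrix(session), ...)
  if (method == "last_crossing") reaction_time_last_crossing(curve)
  else reaction_time_curvature(curve)
}

#' @export
print.reaction_time <- function(x, ...) {
  cat(sprintf("<reaction_time> %s: %s\n", x$method,
              if (x$defined) sprintf("%.0f ms%s", x$rt_ms,
                                     if (x$boundary) " (boundary)" else "")
              else "undefined"))
  invisible(x)
}
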