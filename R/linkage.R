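#' Default high/low dilution classes per odor pair
#'
#' High (weak-stimulus) dilutions are the ones just above the behavioural
#' discrimination threshold; low dilutions are the strong stimuli at which
#' all groups respond alike. Defaults follow the standard protocol:
#' cineol/eugenol high = 10^-3, 10^-2 and low = 10^-1, 10^0; isoamyl
#' acetate/ethyl butyrate high = 10^-6, 10^-4 and low = 10^-2, 10^0.
#'
#' @return data frame with columns \code{odor_pair}, \code{class},
#'   \code{dilution_exponent}.
#' @export
dilution_classes <- function() {
  rbind(
    data.frame(odor_pair = "CIN/EU", class = "high",
               dilution_exponent = c(-3L, -2L)),
    data.frame(odor_pair = "CIN/EU", class = "low",
               dilution_exponent = c(-1L, 0L)),
    data.frame(odor_pair = "IAA/EB", class = "high",
               dilution_exponent = c(-6L, -4L)),
    data.frame(odor_pair = "IAA/EB", class = "low",
               dilution_exponent = c(-2L, 0L)))
}

check_amp_table <- function(amps) {
  need <- c("mouse", "group", "odorant", "dilution_exponent", "roi_id",
            "amplitude_permil")
  if (!all(need %in% names(amps)))
    stop_invalid("amplitude table must have columns: ",
                 paste(need, collapse = ", "))
  bad <- setdiff(unique(amps$group), c("trained", "exposed", "naive"))
  if (length(bad))
    stop_invalid("unknown group label(s): ", paste(bad, collapse = ", "))
  invisible(amps)
}

#' Group-level summary of glomerular responses
#'
#' Hierarchical aggregation with the mouse as the unit of replication:
#' per-ROI amplitudes (repetition-averaged) are averaged within mouse for
#' each (odorant, dilution), then across mice within group; SEM is over
#' mice. Activated-glomerulus counts are averaged the same way. Amplitude
#' means are additionally normalised to the naive group's grand mean, so
#' the naive normalised amplitude is 1 by construction.
#'
#' @param amps data frame with columns \code{mouse}, \code{group},
#'   \code{odorant}, \code{dilution_exponent}, \code{roi_id},
#'   \code{amplitude_permil} (one row per ROI x stimulus, repetitions
#'   already averaged or given as extra rows).
#' @param counts data frame with columns \code{mouse}, \code{group},
#'   \code{odorant}, \code{dilution_exponent}, \code{count}.
#' @return An object of class \code{group_summary}: \code{amplitude}
#'   (per group x odorant x dilution: mean, sem, n_mice,
#'   normalized_mean), \code{count} (same for counts), and \code{pooled}
#'   (per-group pooled ROI amplitude vectors for CDF analysis).
#' @export
group_summary <- function(amps, counts = NULL) {
  check_amp_table(amps)
  # rep-average then mouse-average
  roi_mean <- stats::aggregate(
    amplitude_permil ~ mouse + group + odorant + dilution_exponent + roi_id,
    data = amps, FUN = mean)
  mouse_mean <- stats::aggregate(
    amplitude_permil ~ mouse + group + odorant + dilution_exponent,
    data = roi_mean, FUN = mean)
  amp_sum <- stats::aggregate(
    amplitude_permil ~ group + odorant + dilution_exponent,
    data = mouse_mean,
    FUN = function(x) c(mean = mean(x), sem = sd(x) / sqrt(length(x)),
                        n = length(x)))
  amp_sum <- do.call(data.frame, amp_sum)
  names(amp_sum)[4:6] <- c("mean", "sem", "n_mice")
  naive_grand <- mean(mouse_mean$amplitude_permil[mouse_mean$group == "naive"])
  grand <- stats::aggregate(amplitude_permil ~ group, data = mouse_mean,
                            FUN = mean)
  grand$normalized_mean <- grand$amplitude_permil / naive_grand
  amp_sum$normalized_mean <- amp_sum$mean / naive_grand

  count_sum <- NULL
  if (!is.null(counts)) {
    count_sum <- stats::aggregate(
      count ~ group + odorant + dilution_exponent, data = counts,
      FUN = function(x) c(mean = mean(x), sem = sd(x) / sqrt(length(x)),
                          n = length(x)))
    count_sum <- do.call(data.frame, count_sum)
    names(count_sum)[4:6] <- c("mean", "sem", "n_mice")
  }
  pooled <- split(roi_mean$amplitude_permil, roi_mean$group)
  structure(list(amplitude = amp_sum, count = count_sum,
                 normalized = grand, pooled = pooled,
                 naive_grand_mean = naive_grand),
            class = "group_summary")
}

#' Fold change of activated-glomerulus counts between groups
#'
#' Ratio of group-mean activated-glomerulus counts over the dilutions of
#' one class (high = near threshold, low = strong stimuli). The trained vs
#' naive ratio at high dilutions is the headline plasticity effect (about
#' threefold); at low dilutions counts are similar across groups.
#'
#' @param counts data frame as in \code{\link{group_summary}}.
#' @param group_a,group_b numerator and denominator groups.
#' @param dilutions integer vector of dilution exponents defining the
#'   class.
#' @return list with \code{ratio} (NA with \code{undefined = TRUE} when
#'   the denominator mean is zero), \code{mean_a}, \code{mean_b}.
#' @export
fold_change_counts <- function(counts, group_a = "trained",
                               group_b = "naive", dilutions) {
  sel <- counts$dilution_exponent %in% dilutions
  if (!any(sel)) stop_invalid("no counts at the requested dilutions")
  m <- function(g) mean(counts$count[sel & counts$group == g])
  a <- m(group_a); b <- m(group_b)
  if (!is.finite(b) || b == 0)
    return(list(ratio = NA_real_, mean_a = a, mean_b = b, undefined = TRUE))
  list(ratio = a / b, mean_a = a, mean_b = b, undefined = FALSE)
}

#' Compare pooled amplitude distributions between two groups
#'
#' Empirical CDFs and the two-sample Kolmogorov-Smirnov test on pooled
#' per-ROI amplitudes (ROI is the unit here, matching pooled population
#' analyses of several hundred ROIs per group).
#'
#' @param pooled_a,pooled_b numeric vectors of per-ROI amplitudes (permil;
#'   negative-going responses).
#' @param min_n warn below this pool size.
#' @return list with \code{ecdf_a}, \code{ecdf_b}, \code{statistic},
#'   \code{p_value}, \code{direction} (\code{"a_larger_magnitude"} or
#'   \code{"b_larger_magnitude"}), \code{n_a}, \code{n_b}.
#' @export
amplitude_cdf_compare <- function(pooled_a, pooled_b, min_n = 20L) {
  if (length(pooled_a) < min_n || length(pooled_b) < min_n)
    warning("pool size below ", min_n, "; KS test may be underpowered")
  ks <- suppressWarnings(ks.test(pooled_a, pooled_b))
  dir <- if (mean(abs(pooled_a)) >= mean(abs(pooled_b)))
    "a_larger_magnitude" else "b_larger_magnitude"
  list(ecdf_a = ecdf(pooled_a), ecdf_b = ecdf(pooled_b),
       statistic = unname(ks$statistic), p_value = ks$p.value,
       direction = dir, n_a = length(pooled_a), n_b = length(pooled_b))
}

#' Rewarded vs non-rewarded glomerular amplitudes
#'
#' Splits per-ROI amplitudes by the valence of the activating odorant
#' (S+ rewarded vs S- unrewarded; valence is counterbalanced across
#' animals) and runs a paired Wilcoxon signed-rank test across ROIs that
#' respond to both odorants of the pair.
#'
#' @param amps amplitude table as in \code{\link{group_summary}}.
#' @param valence_map data frame with columns \code{mouse}, \code{odorant},
#'   \code{valence} (\code{"S+"}/\code{"S-"}).
#' @return list with pooled \code{rewarded} and \code{non_rewarded}
#'   amplitude vectors, \code{test} (paired Wilcoxon), \code{n_pairs}.
#' @export
reward_value_split <- function(amps, valence_map) {
  need <- c("mouse", "odorant", "valence")
  if (!all(need %in% names(valence_map)))
    stop_invalid("valence_map needs columns mouse, odorant, valence")
  m <- merge(amps, valence_map, by = c("mouse", "odorant"))
  if (nrow(m) < nrow(amps))
    stop_invalid("missing valence assignment for some amplitude rows")
  if (length(unique(m$valence)) < 2L)
    stop_invalid("need both rewarded and non-rewarded odorants")
  roi_mean <- stats::aggregate(
    amplitude_permil ~ mouse + roi_id + valence, data = m, FUN = mean)
  wide <- merge(roi_mean[roi_mean$valence == "S+", ],
                roi_mean[roi_mean$valence == "S-", ],
                by = c("mouse", "roi_id"), suffixes = c("_sp", "_sm"))
  test <- if (nrow(wide) >= 3L)
    wilcox.test(wide$amplitude_permil_sp, wide$amplitude_permil_sm,
                paired = TRUE, exact = FALSE) else NULL
  list(rewarded = roi_mean$amplitude_permil[roi_mean$valence == "S+"],
       non_rewarded = roi_mean$amplitude_permil[roi_mean$valence == "S-"],
       test = test, n_pairs = nrow(wide))
}

#' Boltzmann (four-parameter sigmoid) psychometric fit
#'
#' Least-squares fit of accuracy against glomerular input strength:
#' \deqn{y = a_2 + (a_1 - a_2) / (1 + \exp((x - x_0)/dx))}
#' with lower asymptote \code{a1} (chance), upper asymptote \code{a2},
#' midpoint \code{x0} and slope scale \code{dx > 0}. Uses \code{nls}
#' (port algorithm, \code{dx} bounded positive) with multi-start
#' initialisation over a grid of plausible midpoints and slopes.
#'
#' @param x input strength per dilution (e.g. mean glomerular delta-R/R
#'   magnitude, permil).
#' @param y discrimination accuracy per dilution, percent.
#' @return An object of class \code{psychometric_fit}: \code{a1},
#'   \code{a2}, \code{x0}, \code{dx}, \code{r_squared}, \code{fitted},
#'   \code{residuals}, \code{converged}, \code{degenerate} (TRUE for flat
#'   response data where \code{dx} is unidentifiable).
#' @export
boltzmann_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop_invalid("need at least 4 (x, y) points")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (diff(range(y)) < 1e-8)
    return(structure(list(a1 = mean(y), a2 = mean(y), x0 = NA_real_,
                          dx = NA_real_, r_squared = NA_real_,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y),
                          converged = FALSE, degenerate = TRUE),
                     class = "psychometric_fit"))
  xr <- range(x)
  starts <- expand.grid(
    x0 = seq(xr[1], xr[2], length.out = 5),
    dx = diff(xr) * c(0.05, 0.15, 0.4, 1))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(nls(
      y ~ a2 + (a1 - a2) / (1 + exp((x - x0) / dx)),
      start = list(a1 = min(y), a2 = max(y),
                   x0 = starts$x0[i], dx = starts$dx[i]),
      lower = c(a1 = -Inf, a2 = -Inf, x0 = -Inf, dx = 1e-9),
      algorithm = "port",
      control = list(maxiter = 500, warnOnly = FALSE))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(resid(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("Boltzmann fit failed to converge from all starts; x range ",
         paste(signif(xr, 4), collapse = " to "))
  co <- as.list(coef(best))
  if (co$a1 > co$a2) {
    # canonical orientation (a1 = lower asymptote); the identity
    # f(a1, a2, x0, dx) = f(a2, a1, x0, -dx) keeps the curve unchanged
    tmp <- co$a1; co$a1 <- co$a2; co$a2 <- tmp; co$dx <- -co$dx
  }
  r2 <- 1 - best_rss / sum((y - mean(y))^2)
  structure(list(a1 = co$a1, a2 = co$a2, x0 = co$x0, dx = co$dx,
                 r_squared = r2, fitted = fitted(best),
                 residuals = resid(best), converged = TRUE,
                 degenerate = FALSE, nls = best),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$degenerate) cat("<psychometric_fit> degenerate (flat response)\n")
  else cat(sprintf(
    "<psychometric_fit> a1=%.3g a2=%.3g x0=%.4g dx=%.4g R2=%.4f\n",
    x$a1, x$a2, x$x0, x$dx, x$r_squared))
  invisible(x)
}

#' Paired near-threshold contrast of accuracy, counts and amplitudes
#'
#' For the two adjacent dilutions bracketing the discrimination threshold,
#' computes per-mouse paired contrasts of discrimination accuracy,
#' activated-glomerulus count, and response amplitude, and attributes the
#' accuracy gain to whichever input-strength component (count, amplitude,
#' or both) changes significantly across the pair.
#'
#' @param acc data frame: \code{mouse}, \code{dilution_exponent},
#'   \code{accuracy_pct}.
#' @param counts data frame: \code{mouse}, \code{dilution_exponent},
#'   \code{count} (mouse-level, pooled over odorants).
#' @param amp data frame: \code{mouse}, \code{dilution_exponent},
#'   \code{amplitude_permil} (mouse-level mean).
#' @param bracket two dilution exponents, more dilute first.
#' @param alpha significance level for the attribution (default 0.05).
#' @return list of per-measure paired test results plus
#'   \code{attribution}: subset of \code{c("count", "amplitude")}.
#' @export
threshold_accuracy_contrast <- function(acc, counts, amp, bracket,
                                        alpha = 0.05) {
  if (length(bracket) != 2L) stop_invalid("bracket must be two exponents")
  paired <- function(df, col) {
    lo <- df[df$dilution_exponent == bracket[1], c("mouse", col)]
    hi <- df[df$dilution_exponent == bracket[2], c("mouse", col)]
    m <- merge(lo, hi, by = "mouse", suffixes = c("_lo", "_hi"))
    if (nrow(m) < 2L) {
      warning("missing bracketing dilutions for ", col, "; skipped")
      return(NULL)
    }
    d <- m[[paste0(col, "_hi")]] - m[[paste0(col, "_lo")]]
    tt <- if (sd(d) < 1e-12) NULL else t.test(d)
    list(n = nrow(m), mean_delta = mean(d),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  res <- list(accuracy = paired(acc, "accuracy_pct"),
              count = paired(counts, "count"),
              amplitude = paired(amp, "amplitude_permil"))
  sig <- function(r, magnitude = FALSE) {
    if (is.null(r) || is.na(r$p_value)) return(FALSE)
    delta <- if (magnitude) -r$mean_delta else r$mean_delta  # darkening
    r$p_value < alpha && delta > 0
  }
  attribution <- c(if (sig(res$count)) "count",
                   if (sig(res$amplitude, magnitude = TRUE)) "amplitude")
  res$attribution <- attribution %||% character(0)
  res$bracket <- bracket
  res
}
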