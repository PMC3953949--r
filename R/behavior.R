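#' Score a single go/no-go trial from its lick bins
#'
#' The 2 s odor stimulus is tiled by four 500 ms lick bins. An S+ trial is
#' correct (a hit) iff the animal licked in at least three of the four
#' bins; an S- trial is correct (a correct rejection) iff licking occurred
#' in no more than one of the four bins. The complements are a miss and a
#' false alarm respectively.
#'
#' @param trial a list (or one-row data frame) with \code{valence}
#'   (\code{"S+"} or \code{"S-"}) and either \code{bin_licks} (logical
#'   vector of length 4) or columns \code{bin1..bin4}.
#' @return list with \code{correct} (logical) and \code{outcome} (one of
#'   \code{"hit"}, \code{"miss"}, \code{"correct_rejection"},
#'   \code{"false_alarm"}).
#' @export
score_trial <- function(trial) {
  bins <- if (!is.null(trial$bin_licks)) trial$bin_licks else
    unlist(trial[c("bin1", "bin2", "bin3", "bin4")], use.names = FALSE)
  if (length(bins) != 4L || anyNA(bins) || !is.logical(as.vector(bins)) &&
      !all(bins %in% c(0, 1)))
    stop_invalid("trial must carry exactly 4 boolean lick bins")
  bins <- as.logical(bins)
  if (!trial$valence %in% c("S+", "S-"))
    stop_invalid("valence must be 'S+' or 'S-'")
  n <- sum(bins)
  if (trial$valence == "S+") {
    correct <- n >= 3L
    outcome <- if (correct) "hit" else "miss"
  } else {
    correct <- n <= 1L
    outcome <- if (correct) "correct_rejection" else "false_alarm"
  }
  list(correct = correct, outcome = outcome)
}

#' Lick bins from lick-event timestamps
#'
#' When a session records lick events rather than bin booleans, bin b
#' (0-based) is occupied iff at least one lick timestamp falls in the
#' half-open interval [500 b, 500 (b + 1)) ms after odor onset.
#'
#' @param lick_times_ms numeric vector of lick timestamps (ms after odor
#'   onset).
#' @param bin_ms bin width (default 500 ms).
#' @param n_bins number of bins tiling the stimulus (default 4).
#' @return logical vector of length \code{n_bins}.
#' @export
lick_bins <- function(lick_times_ms, bin_ms = 500, n_bins = 4L) {
  b <- floor(lick_times_ms / bin_ms)
  vapply(seq_len(n_bins) - 1L, function(k) any(b == k), logical(1))
}

#' Score every trial of a session
#'
#' @param session a \code{glom_session}.
#' @return the session with \code{trials$correct} and \code{trials$outcome}
#'   columns filled in from \code{\link{score_trial}}.
#' @export
score_session <- function(session) {
  tr <- session$trials
  if (nrow(tr) == 0L) stop_invalid("empty session")
  n <- rowSums(as.matrix(tr[, c("bin1", "bin2", "bin3", "bin4")]))
  sp <- tr$valence == "S+"
  correct <- ifelse(sp, n >= 3L, n <= 1L)
  outcome <- ifelse(sp, ifelse(correct, "hit", "miss"),
                    ifelse(correct, "correct_rejection", "false_alarm"))
  session$trials$correct <- correct
  session$trials$outcome <- outcome
  session
}

session_correct <- function(session) {
  if (is.null(session$trials$correct)) session <- score_session(session)
  session$trials$correct
}

#' Discrimination performance over the last trials of a session
#'
#' Percent correct over the last \code{window} trials (default 300,
#' matching accuracy measured on the last 300 trials of a training stage).
#'
#' @param session a \code{glom_session}.
#' @param window number of trailing trials to score; must not exceed the
#'   session length.
#' @return percent correct in [0, 100].
#' @export
performance <- function(session, window = 300L) {
  correct <- session_correct(session)
  n <- length(correct)
  if (n == 0L) stop_invalid("empty session")
  if (window > n) stop_invalid("window exceeds session length")
  100 * mean(tail(correct, window))
}

#' Block-wise performance
#'
#' Percent correct in consecutive non-overlapping blocks of trials; a
#' trailing partial block is dropped.
#'
#' @param session a \code{glom_session}.
#' @param block block size in trials (default 100).
#' @return numeric vector of percent correct, one value per full block.
#' @export
block_performance <- function(session, block = 100L) {
  if (block <= 0L) stop_invalid("block size must be positive")
  correct <- session_correct(session)
  n_blocks <- length(correct) %/% block
  if (n_blocks == 0L) return(numeric(0))
  idx <- rep(seq_len(n_blocks), each = block)
  as.numeric(tapply(correct[seq_len(n_blocks * block)], idx, mean)) * 100
}

#' Performance curve across a dilution series
#'
#' @param sessions list of scored \code{glom_session}s at different
#'   dilutions (same mouse and odor pair).
#' @param window trailing window for \code{\link{performance}}.
#' @param block block size for \code{\link{block_performance}}.
#' @return An object of class \code{performance_curve}: sorted
#'   \code{dilution_exponents}, \code{accuracy_pct}, and per-dilution
#'   \code{block_accuracy}.
#' @export
performance_curve <- function(sessions, window = 300L, block = 100L) {
  d <- vapply(sessions, function(s) s$dilution_exponent, integer(1))
  acc <- vapply(sessions, function(s)
    performance(s, min(window, nrow(s$trials))), numeric(1))
  blocks <- lapply(sessions, block_performance, block = block)
  ord <- order(d)
  structure(list(dilution_exponents = d[ord], accuracy_pct = acc[ord],
                 block_accuracy = blocks[ord]),
            class = "performance_curve")
}

#' Behavioural discrimination threshold from a performance curve
#'
#' Scans the dilution series from most to least dilute and returns the
#' bracketing pair: the highest (least negative) exponent with accuracy
#' below the criterion and the lowest exponent with accuracy at or above
#' it. A tie at the criterion counts as discriminating.
#'
#' @param curve a \code{performance_curve}, or a list with
#'   \code{dilution_exponents} and \code{accuracy_pct}.
#' @param criterion_pct accuracy criterion in percent (default 70).
#' @return list with \code{lower} and \code{upper} exponents and flags:
#'   \code{open_lower} (\code{TRUE} when every dilution is discriminated,
#'   lower bound reported as \code{-Inf}), \code{open_upper} (\code{TRUE}
#'   when the criterion is never reached, upper bound \code{NA}), and
#'   \code{monotone} (\code{FALSE} when accuracies cross the criterion more
#'   than once; the first crossing from the dilute end is then reported).
#' @export
discrimination_threshold <- function(curve, criterion_pct = 70) {
  d <- curve$dilution_exponents
  acc <- curve$accuracy_pct
  if (length(d) < 2L) stop_invalid("need at least two dilutions")
  ord <- order(d)
  d <- d[ord]; acc <- acc[ord]
  above <- acc >= criterion_pct
  if (!any(above))
    return(list(lower = d[length(d)], upper = NA_real_,
                open_lower = FALSE, open_upper = TRUE, monotone = TRUE))
  if (all(above))
    return(list(lower = -Inf, upper = d[1], open_lower = TRUE,
                open_upper = FALSE, monotone = TRUE))
  first_above <- which(above)[1]
  monotone <- all(above[first_above:length(above)])
  list(lower = d[first_above - 1L], upper = d[first_above],
       open_lower = FALSE, open_upper = FALSE, monotone = monotone)
}

#' Validate the trial sequence of a session
#'
#' Report-only checks of the stimulus protocol: no more than two successive
#' presentations of the same odor, inter-trial intervals of at least 5 s,
#' and exact S+/S- balance within each training day (150/150 for 300-trial
#' days).
#'
#' @param session a \code{glom_session}.
#' @param day_trials trials per day used for the balance check.
#' @param min_iti_s minimum allowed inter-trial interval.
#' @return list with \code{run_violations} (trial indices at which a third
#'   successive identical odor occurs), \code{iti_violations} (indices with
#'   ITI below the minimum), \code{imbalanced_days} (data frame of days
#'   whose S+/S- split is uneven), and \code{n_violations}.
#' @export
validate_sequence <- function(session, day_trials = 300L, min_iti_s = 5) {
  tr <- session$trials
  odors <- tr$odor
  n <- length(odors)
  runs <- integer(0)
  if (n >= 3L) {
    same3 <- odors[-(1:2)] == odors[-c(1, n)] & odors[-c(1, n)] == odors[-((n - 1):n)]
    runs <- which(same3) + 2L
  }
  iti_bad <- which(tr$iti_s < min_iti_s)
  day <- (tr$index - 1L) %/% day_trials + 1L
  tab <- table(day, tr$valence)
  full_days <- as.integer(names(which(tapply(tr$index, day, length) == day_trials)))
  imb <- data.frame(day = integer(0), n_sp = integer(0), n_sm = integer(0))
  for (dd in full_days) {
    nsp <- sum(tr$valence[day == dd] == "S+")
    nsm <- day_trials - nsp
    if (nsp != nsm)
      imb <- rbind(imb, data.frame(day = dd, n_sp = nsp, n_sm = nsm))
  }
  list(run_violations = runs, iti_violations = iti_bad,
       imbalanced_days = imb,
       n_violations = length(runs) + length(iti_bad) + nrow(imb))
}
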