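#' Ground truth for a synthetic go/no-go behavioural session
#'
#' Describes the programmed statistical structure of a synthetic
#' discrimination session: the dilution series, the per-dilution probability
#' of a correct choice, and the latency at which S+ and S- beam-break
#' behaviour diverges.
#'
#' @param dilution_exponents integer vector, log10 percentile dilution
#'   (e.g. \code{c(0, -2, -4)}); 0 is the undiluted (strongest) stimulus.
#' @param p_correct_by_dilution named numeric vector mapping dilution
#'   exponent (as character) to probability of a correct choice, each in
#'   \code{[0.5, 1]}. Must be monotonically non-increasing as the exponent
#'   decreases (more dilute is never easier).
#' @param divergence_time_ms positive scalar; programmed latency (ms after
#'   odor onset) at which retracting trials release the beam.
#' @param divergence_jitter_ms scale (ms) of the one-sided half-normal
#'   retraction-latency jitter added to \code{divergence_time_ms}.
#' @param lick_bin_ms lick bin width in ms; four bins tile the 2 s stimulus.
#' @param n_trials even positive integer, trials per session.
#' @param day_trials trials per training day (balanced S+/S- within a day).
#' @param seed integer seed driving all randomness in the generator.
#'
#' @return An object of class \code{behavior_ground_truth}.
#' @export
behavior_ground_truth <- function(dilution_exponents = c(0L, -2L, -4L),
                                  p_correct_by_dilution = NULL,
                                  divergence_time_ms = 400,
                                  divergence_jitter_ms = 50,
                                  lick_bin_ms = 500,
                                  n_trials = 300L,
                                  day_trials = 300L,
                                  seed = 1L) {
  dilution_exponents <- as.integer(dilution_exponents)
  if (is.null(p_correct_by_dilution)) {
    # default: saturating accuracy for strong stimuli, chance when very dilute
    p <- 0.5 + 0.45 / (1 + exp(-(dilution_exponents + 3)))
    p_correct_by_dilution <- setNames(p, as.character(dilution_exponents))
  }
  p <- p_correct_by_dilution
  if (is.null(names(p)))
    names(p) <- as.character(dilution_exponents)
  if (any(p < 0.5 - 1e-12) || any(p > 1 + 1e-12))
    stop_invalid("p_correct must lie in [0.5, 1]")
  ord <- order(as.numeric(names(p)))
  if (is.unsorted(p[ord] + 1e-9))
    stop_invalid("p_correct must be non-increasing with increasing dilution")
  if (n_trials %% 2L != 0L)
    stop_invalid("n_trials must be even")
  if (divergence_time_ms <= 0 || lick_bin_ms <= 0)
    stop_invalid("divergence_time_ms and lick_bin_ms must be positive")
  structure(list(dilution_exponents = dilution_exponents,
                 p_correct_by_dilution = p,
                 divergence_time_ms = divergence_time_ms,
                 divergence_jitter_ms = divergence_jitter_ms,
                 lick_bin_ms = lick_bin_ms,
                 n_trials = as.integer(n_trials),
                 day_trials = as.integer(day_trials),
                 seed = as.integer(seed)),
            class = "behavior_ground_truth")
}

# Balanced pseudo-random odor sequence with no run of 3+ identical odors.
# Greedy sampler weighted by remaining counts, with restart on dead ends.
pseudorandom_sequence <- function(n_a, n_b, labels, prev = character(0),
                                  max_restarts = 1000L) {
  for (attempt in seq_len(max_restarts)) {
    rem <- c(n_a, n_b)
    names(rem) <- labels
    seq_out <- character(n_a + n_b)
    last2 <- tail(prev, 2L)
    ok <- TRUE
    for (i in seq_along(seq_out)) {
      cand <- labels[rem[labels] > 0L]
      if (length(last2) == 2L && last2[1] == last2[2])
        cand <- setdiff(cand, last2[1])
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = rem[cand])
      seq_out[i] <- pick
      rem[pick] <- rem[pick] - 1L
      last2 <- c(tail(last2, 1L), pick)
    }
    if (ok) return(seq_out)
  }
  stop("sequence generation failed: constraint unreachable")
}

#' Generate a synthetic go/no-go session
#'
#' Produces a full behavioural session for one mouse, odor pair and dilution.
#' Odors follow a pseudo-randomised scheme with no more than two successive
#' presentations of the same odor and an exact S+/S- balance within each
#' training day (150/150 for 300-trial days). Per trial, lick-bin occupancy
#' and beam-break traces are drawn so that the trial is scored correct with
#' the programmed probability, and so that trials in which the animal
#' disengages release the beam at \code{divergence_time_ms} plus one-sided
#' half-normal jitter, so the S+ and S- trace ensembles are exchangeable
#' before the programmed latency and diverge exactly at it. The correct/incorrect ground-truth label is recorded per trial.
#'
#' @param gt a \code{\link{behavior_ground_truth}} object.
#' @param odor_pair character vector of two odor labels, S+ first.
#' @param dilution_exponent dilution for this session; must be present in
#'   \code{gt$p_correct_by_dilution}.
#' @param mouse_id,group session metadata; \code{group} is one of
#'   \code{"trained"}, \code{"exposed"}, \code{"naive"}.
#' @param times_ms beam-break sampling grid in ms after odor onset.
#'
#' @return An object of class \code{glom_session}: a list with
#'   \code{trials} (data frame: \code{index}, \code{odor}, \code{valence},
#'   \code{bin1..bin4}, \code{iti_s}, \code{correct_gt}), \code{beam}
#'   (list with \code{times_ms} and a trials-by-time logical matrix
#'   \code{traces}), and the session metadata.
#' @export
generate_session <- function(gt, odor_pair = c("CIN", "EU"),
                             dilution_exponent = gt$dilution_exponents[1],
                             mouse_id = "m1", group = "trained",
                             times_ms = seq(0, 2000, by = 10)) {
  stopifnot(inherits(gt, "behavior_ground_truth"))
  if (length(odor_pair) != 2L || odor_pair[1] == odor_pair[2])
    stop_invalid("odor_pair must be two distinct labels (S+ first)")
  key <- as.character(dilution_exponent)
  if (!key %in% names(gt$p_correct_by_dilution))
    stop_invalid("dilution_exponent ", key, " not in ground truth")
  p_correct <- unname(gt$p_correct_by_dilution[key])
  n <- gt$n_trials
  set.seed(gt$seed)

  # per-day balanced sequences, run constraint enforced across day joins
  odors <- character(0)
  remaining <- n
  while (remaining > 0L) {
    day_n <- min(gt$day_trials, remaining)
    odors <- c(odors,
               pseudorandom_sequence(day_n %/% 2L, day_n - day_n %/% 2L,
                                     odor_pair, prev = odors))
    remaining <- remaining - day_n
  }
  valence <- ifelse(odors == odor_pair[1], "S+", "S-")
  correct <- runif(n) < p_correct

  bins <- matrix(FALSE, n, 4L)
  n_lick <- integer(n)
  sp <- valence == "S+"
  # lick-bin counts consistent with the scoring rule for each outcome
  n_lick[sp & correct]   <- sample(3:4, sum(sp & correct),   replace = TRUE)
  n_lick[sp & !correct]  <- sample(0:2, sum(sp & !correct),  replace = TRUE)
  n_lick[!sp & correct]  <- sample(0:1, sum(!sp & correct),  replace = TRUE)
  n_lick[!sp & !correct] <- sample(2:4, sum(!sp & !correct), replace = TRUE)
  for (i in seq_len(n))
    if (n_lick[i] > 0L) bins[i, sample(4L, n_lick[i])] <- TRUE

  # beam-break: engaged trials hold the beam through the 2 s stimulus;
  # disengaging trials (correct S-, incorrect S+) retract at the programmed
  # divergence latency plus one-sided (half-normal) jitter, so that the two
  # classes are exchangeable before divergence_time_ms and diverge exactly
  # at it
  holds <- (sp & correct) | (!sp & !correct)
  traces <- matrix(TRUE, n, length(times_ms))
  retract_t <- gt$divergence_time_ms +
    abs(rnorm(n, 0, gt$divergence_jitter_ms))
  for (i in which(!holds)) traces[i, times_ms >= retract_t[i]] <- FALSE

  iti <- runif(n, 10, 20)

  trials <- data.frame(index = seq_len(n), odor = odors, valence = valence,
                       bin1 = bins[, 1], bin2 = bins[, 2],
                       bin3 = bins[, 3], bin4 = bins[, 4],
                       iti_s = iti, correct_gt = correct,
                       stringsAsFactors = FALSE)
  structure(list(mouse_id = mouse_id, odor_pair = odor_pair,
                 dilution_exponent = as.integer(dilution_exponent),
                 group = match.arg(group, c("trained", "exposed", "naive")),
                 trials = trials,
                 beam = list(times_ms = times_ms, traces = traces),
                 ground_truth = list(p_correct = p_correct,
                                     divergence_time_ms = gt$divergence_time_ms,
                                     retract_t_ms = retract_t,
                                     holds = holds)),
            class = "glom_session")
}

#' @export
print.glom_session <- function(x, ...) {
  cat("<glom_session>", x$mouse_id, paste(x$odor_pair, collapse = "/"),
      sprintf("dilution 10^%d", x$dilution_exponent),
      sprintf("(%s), %d trials\n", x$group, nrow(x$trials)))
  invisible(x)
}
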