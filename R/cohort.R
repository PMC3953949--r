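#' Simulate and analyse an imaging cohort
#'
#' End-to-end synthetic experiment: for each mouse a fresh glomerular
#' field is drawn, trial stacks are generated for every odorant x dilution
#' x repetition, the reference glomerular map is built from the lowest
#' (strongest) dilution of each odorant, repetition-averaged delta-R/R
#' maps are quantified on the reference ROIs, and activated glomeruli are
#' counted. Stacks are analysed mouse-by-mouse and discarded, so memory
#' stays bounded. Ground-truth injected amplitudes are carried alongside
#' for validation.
#'
#' @param n_per_group mice per experimental group.
#' @param groups character vector of groups to simulate.
#' @param dilution_exponents dilutions imaged for every odorant; the
#'   maximum (strongest stimulus) is used to build the reference map.
#' @param n_reps repetitions per stimulus (default 4).
#' @param activation_k activation threshold in per-ROI noise SDs.
#' @param seed master seed; per-mouse seeds are derived from it.
#' @param ... passed to \code{\link{imaging_ground_truth}} (field size,
#'   number of glomeruli, group effect scales, noise, ...).
#' @return list with \code{amplitudes} (data frame: mouse, group, odorant,
#'   dilution_exponent, roi_id, amplitude_permil, roi_noise_permil,
#'   activated) and \code{counts} (mouse, group, odorant,
#'   dilution_exponent, count), plus \code{truth} (per-mouse injected
#'   amplitude tables).
#' @export
simulate_cohort <- function(n_per_group = 3L,
                            groups = c("trained", "exposed", "naive"),
                            dilution_exponents = c(-3L, -2L, -1L, 0L),
                            n_reps = 4L,
                            activation_k = 3,
                            seed = 1L, ...) {
  ref_dil <- max(dilution_exponents)
  amps <- list(); counts <- list(); truth <- list()
  mi <- 0L
  for (g in groups) for (m in seq_len(n_per_group)) {
    mi <- mi + 1L
    mouse_id <- sprintf("%s_%02d", g, m)
    gt <- imaging_ground_truth(seed = (seed * 1013L + mi * 97L) %%
                                 .Machine$integer.max, ...)
    ref_stacks <- lapply(gt$odorants, function(od)
      lapply(seq_len(n_reps), function(r)
        generate_trial_stack(gt, od, ref_dil, r, group = g)))
    names(ref_stacks) <- gt$odorants
    gmap <- build_reference_map(ref_stacks, mouse_id = mouse_id, group = g)
    for (od in gt$odorants) for (d in sort(dilution_exponents)) {
      stacks <- if (d == ref_dil) ref_stacks[[od]] else
        lapply(seq_len(n_reps), function(r)
          generate_trial_stack(gt, od, d, r, group = g))
      avg <- average_repetitions(lapply(stacks, delta_map))
      gmap <- quantify(gmap, avg, odorant = od, dilution_exponent = d,
                       repetition = NA)
      counts[[length(counts) + 1L]] <- data.frame(
        mouse = mouse_id, group = g, odorant = od, dilution_exponent = d,
        count = count_activated(gmap, od, d, activation_k))
      truth[[length(truth) + 1L]] <- data.frame(
        mouse = mouse_id, group = g, odorant = od, dilution_exponent = d,
        glomerulus = seq_len(gt$n_glomeruli),
        amplitude_permil = injected_amplitudes(gt, od, d, g))
    }
    a <- gmap$amplitudes
    a$mouse <- mouse_id; a$group <- g
    a$activated <- abs(a$amplitude_permil) >
      activation_k * pmax(a$roi_noise_permil, 1e-12)
    amps[[mi]] <- a
  }
  list(amplitudes = do.call(rbind, amps),
       counts = do.call(rbind, counts),
       truth = do.call(rbind, truth))
}
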