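#' Frame index ranges of a trial stack
#'
#' Baseline frames lie entirely before odor onset; response frames lie
#' entirely inside the odor window (the full 5 s odor period by default).
#' @param stack a \code{glom_stack}.
#' @return list with integer vectors \code{baseline} and \code{response}.
#' @keywords internal
stack_windows <- function(stack) {
  n <- dim(stack$frames)[1]
  mid <- (seq_len(n) - 0.5) / stack$frame_rate_hz
  list(baseline = which(mid < stack$odor_window_s[1]),
       response = which(mid > stack$odor_window_s[1] &
                          mid < stack$odor_window_s[2]))
}

#' Per-pixel delta-R/R response map
#'
#' For each pixel, delta-R/R = (mean reflectance over the response window
#' minus mean reflectance over the pre-odor baseline) / baseline mean,
#' reported in permil. Odor-evoked responses appear as negative values
#' (reflectance darkening at 700 nm). Pixels with zero baseline are masked
#' to NA with a warning.
#'
#' @param stack a \code{glom_stack}.
#' @param highpass_px optional spatial high-pass: when set, a boxcar
#'   background of this half-width (pixels) is subtracted from the map to
#'   remove slow vignetting; choose it much larger than a glomerulus
#'   radius. \code{NULL} (default) disables the filter.
#' @return An object of class \code{delta_map}: \code{values} (matrix, in
#'   permil), \code{baseline_frames}, \code{response_frames},
#'   \code{noise_sd_permil} (robust per-frame pixel noise estimated from
#'   baseline frame-to-frame residuals) and \code{map_noise_permil} (the
#'   implied SD of a single map pixel).
#' @export
delta_map <- function(stack, highpass_px = NULL) {
  w <- stack_windows(stack)
  if (length(w$baseline) < 1L)
    stop_invalid("no baseline frames before odor onset")
  if (length(w$response) < 1L)
    stop_invalid("no frames inside the odor window")
  base <- colMeans(stack$frames[w$baseline, , , drop = FALSE])
  resp <- colMeans(stack$frames[w$response, , , drop = FALSE])
  zero <- base == 0
  if (any(zero)) {
    warning(sum(zero), " zero-baseline pixels masked")
    base[zero] <- NA_real_
  }
  values <- (resp - base) / base * 1000
  if (!is.null(highpass_px))
    values <- values - boxcar_background(values, highpass_px)
  sigma_f <- map_frame_noise(stack, w)
  structure(list(values = values,
                 baseline_frames = w$baseline,
                 response_frames = w$response,
                 noise_sd_permil = sigma_f,
                 map_noise_permil = sigma_f *
                   sqrt(1 / length(w$response) + 1 / length(w$baseline)),
                 meta = stack[c("odorant", "dilution_exponent",
                                "repetition", "group")]),
            class = "delta_map")
}

# separable boxcar local mean with edge renormalisation (NA-tolerant)
boxcar_background <- function(m, half) {
  k <- rep(1, 2L * half + 1L)
  smooth1 <- function(x) {
    v <- ifelse(is.na(x), 0, x)
    n <- as.numeric(!is.na(x))
    num <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), n, rep(0, half)), k, sides = 2)
    (num / pmax(den, 1))[(half + 1L):(half + length(x))]
  }
  down_cols <- apply(m, 2, smooth1)          # smooth along rows
  t(apply(down_cols, 1, smooth1))            # then along columns
}

# robust per-frame pixel noise (permil) from baseline frame-to-frame
# residuals; differencing removes the static image, /sqrt(2) undoes the
# variance doubling of the difference
map_frame_noise <- function(stack, w = stack_windows(stack)) {
  b <- w$baseline
  if (length(b) < 2L) return(NA_real_)
  ref <- colMeans(stack$frames[b, , , drop = FALSE])
  diffs <- stack$frames[b[-1], , , drop = FALSE] -
    stack$frames[b[-length(b)], , , drop = FALSE]
  rel <- sweep(diffs, c(2, 3), ref, "/") * 1000
  mad(as.numeric(rel), center = 0) / sqrt(2)
}

#' Average delta-R/R maps over stimulus repetitions
#'
#' Pixel-wise mean of per-repetition maps (four repetitions per
#' odorant/dilution in the standard protocol). All maps must share the
#' same stimulus metadata (odorant, dilution, group).
#'
#' @param maps list of \code{delta_map}s (or a list of \code{glom_stack}s,
#'   which are mapped first).
#' @return a \code{delta_map} whose \code{values} is the mean map and whose
#'   \code{map_noise_permil} is reduced by sqrt(number of repetitions).
#' @export
average_repetitions <- function(maps) {
  if (length(maps) == 0L) stop_invalid("no maps to average")
  if (inherits(maps[[1]], "glom_stack")) maps <- lapply(maps, delta_map)
  meta <- lapply(maps, function(m) m$meta[c("odorant", "dilution_exponent",
                                            "group")])
  if (length(unique(meta)) != 1L)
    stop_invalid("repetitions have mismatched stimulus metadata")
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out <- maps[[1]]
  out$values <- vals
  out$n_reps <- length(maps)
  out$map_noise_permil <- mean(vapply(maps, `[[`, numeric(1),
                                      "map_noise_permil")) /
    sqrt(length(maps))
  out$noise_sd_permil <- mean(vapply(maps, `[[`, numeric(1),
                                     "noise_sd_permil"))
  out$meta$repetition <- NA_integer_
  out
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# binary opening with the 4-neighbourhood cross: removes isolated
# supra-threshold noise pixels and 1-pixel bridges that would otherwise
# merge adjacent structures under 8-connected labelling
binary_opening <- function(mask) {
  er <- mask &
    shift_mask(mask, 1, 0) & shift_mask(mask, -1, 0) &
    shift_mask(mask, 0, 1) & shift_mask(mask, 0, -1)
  er |
    shift_mask(er, 1, 0) | shift_mask(er, -1, 0) |
    shift_mask(er, 0, 1) | shift_mask(er, 0, -1)
}

# 8-connected components of a logical mask via igraph
connected_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  nr <- nrow(mask)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]
  pos <- seq_len(nrow(idx))
  lookup <- integer(nrow(mask) * ncol(mask))
  lookup[key] <- pos
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb_r <- idx[, 1] + off[1]; nb_c <- idx[, 2] + off[2]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= ncol(mask)
    nb_key <- (nb_c - 1L) * nr + nb_r
    nb_pos <- ifelse(ok, lookup[pmax(nb_key, 1L)], 0L)
    has <- ok & nb_pos > 0L
    edges <- c(edges, rbind(pos[has], nb_pos[has]))
  }
  g <- igraph::make_graph(edges, n = nrow(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) idx[comp == k, , drop = FALSE])
}

roi_shape <- function(pixels) {
  ctr <- colMeans(pixels)
  if (nrow(pixels) < 2L)
    return(list(centroid = ctr, area = nrow(pixels), elongation = 1))
  cv <- stats::cov(pixels) + diag(1 / 12, 2)  # pixel extent regularisation
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  list(centroid = ctr, area = nrow(pixels),
       elongation = sqrt(max(ev) / max(min(ev), 1e-12)))
}

# fraction of response frames in which a component's thresholded per-frame
# mask overlaps >= overlap_frac of its pixels
frames_present <- function(stacks, pixels, k, overlap_frac = 0.5) {
  counts <- 0L
  w <- stack_windows(stacks[[1]])
  n_reps <- length(stacks)
  base <- Reduce(`+`, lapply(stacks, function(s)
    colMeans(s$frames[w$baseline, , , drop = FALSE]))) / n_reps
  sigma_f <- mean(vapply(stacks, map_frame_noise, numeric(1))) / sqrt(n_reps)
  lin <- (pixels[, 2] - 1L) * nrow(base) + pixels[, 1]
  present <- 0L
  for (f in w$response) {
    fr <- Reduce(`+`, lapply(stacks, function(s) s$frames[f, , ])) / n_reps
    dmf <- (fr - base) / base * 1000
    hit <- abs(dmf[lin]) > k * sigma_f
    if (mean(hit) >= overlap_frac) present <- present + 1L
  }
  present
}

#' Detect glomerular ROIs on reference (lowest-dilution) maps
#'
#' Thresholds the repetition-averaged delta-R/R map of each odorant at its
#' lowest (strongest) dilution at \code{k} robust noise SDs, cleans the
#' mask with a 4-neighbourhood binary opening (suppresses isolated noise
#' pixels and one-pixel bridges between structures), extracts 8-connected
#' components within the area bounds, and applies the two
#' exclusion rules: components that appear in only a single time frame
#' (transient artifacts) and components whose second-moment elongation
#' exceeds the vessel ratio (blood vessels) are discarded. Components from
#' different odorants are merged into one reference map by pixel-overlap
#' union.
#'
#' @param stacks_by_odorant named list (one element per odorant) of lists
#'   of \code{glom_stack}s (the repetitions at the lowest dilution).
#' @param k detection threshold in robust map-noise SDs (default 3).
#' @param area_range allowed component area in pixels.
#' @param vessel_ratio maximum second-moment elongation (default 4).
#' @param min_frames minimum number of response frames in which a
#'   component must appear (default 2: single-frame components are
#'   excluded).
#' @return list of ROI objects (\code{id}, \code{pixels}, \code{centroid},
#'   \code{area}, \code{elongation}, \code{n_frames_present}); empty list
#'   with a warning when nothing is detected.
#' @export
detect_rois <- function(stacks_by_odorant, k = 3,
                        area_range = c(6, 400), vessel_ratio = 4,
                        min_frames = 2L) {
  if (inherits(stacks_by_odorant, "glom_stack"))
    stacks_by_odorant <- list(list(stacks_by_odorant))
  if (inherits(stacks_by_odorant[[1]], "glom_stack"))
    stacks_by_odorant <- list(stacks_by_odorant)
  shape <- dim(stacks_by_odorant[[1]][[1]]$frames)[2:3]
  union_mask <- matrix(FALSE, shape[1], shape[2])
  dilate4 <- function(m) m |
    shift_mask(m, 1, 0) | shift_mask(m, -1, 0) |
    shift_mask(m, 0, 1) | shift_mask(m, 0, -1)
  for (stacks in stacks_by_odorant) {
    avg <- average_repetitions(lapply(stacks, delta_map))
    thr <- k * avg$map_noise_permil
    if (!is.finite(thr) || thr <= 0) thr <- k * 1e-9  # noiseless stacks
    mask <- binary_opening(!is.na(avg$values) & abs(avg$values) > thr)
    comps <- connected_components(mask)
    shapes <- lapply(comps, roi_shape)
    # vessel-like components are masked out together with their immediate
    # surroundings, so that fragments pinched off an excluded vessel do
    # not survive as spurious compact ROIs
    vessel_fp <- matrix(FALSE, shape[1], shape[2])
    for (j in seq_along(comps))
      if (shapes[[j]]$elongation > vessel_ratio) vessel_fp[comps[[j]]] <- TRUE
    for (d in 1:3) vessel_fp <- dilate4(vessel_fp)
    for (j in seq_along(comps)) {
      px <- comps[[j]]; sh <- shapes[[j]]
      if (sh$area < area_range[1] || sh$area > area_range[2]) next
      if (sh$elongation > vessel_ratio) next
      if (mean(vessel_fp[px]) >= 0.3) next
      nf <- frames_present(stacks, px, k)
      if (nf < min_frames) next
      union_mask[px] <- TRUE
    }
  }
  comps <- connected_components(union_mask)
  rois <- list()
  id <- 0L
  for (px in comps) {
    sh <- roi_shape(px)
    if (sh$area < area_range[1] || sh$area > area_range[2]) next
    if (sh$elongation > vessel_ratio) next
    id <- id + 1L
    rois[[id]] <- list(id = id, pixels = px, centroid = sh$centroid,
                       area = sh$area, elongation = sh$elongation,
                       n_frames_present = NA_integer_)
  }
  if (length(rois) == 0L) warning("no ROIs detected")
  rois
}

#' Build a per-mouse reference glomerular map
#'
#' Runs \code{\link{detect_rois}} on the lowest-dilution stacks of each
#' odorant and wraps the result with bookkeeping for amplitude
#' quantification across all dilutions of the same odorants.
#'
#' @param stacks_by_odorant as in \code{\link{detect_rois}}.
#' @param mouse_id,group metadata.
#' @param ... passed to \code{\link{detect_rois}}.
#' @return An object of class \code{glomerular_map}: \code{rois}, empty
#'   \code{amplitudes} table, and metadata.
#' @export
build_reference_map <- function(stacks_by_odorant, mouse_id = "m1",
                                group = "trained", ...) {
  rois <- detect_rois(stacks_by_odorant, ...)
  structure(list(mouse_id = mouse_id, group = group, rois = rois,
                 amplitudes = data.frame(roi_id = integer(0),
                                         odorant = character(0),
                                         dilution_exponent = integer(0),
                                         repetition = integer(0),
                                         amplitude_permil = numeric(0),
                                         roi_noise_permil = numeric(0))),
            class = "glomerular_map")
}

#' Quantify per-ROI delta-R/R amplitudes on a response map
#'
#' The reference map built at the lowest dilution is reused across all
#' dilutions of the same odorant: each ROI's amplitude is the mean
#' delta-R/R over its pixels. The per-ROI noise (map noise / sqrt(area),
#' further reduced by the number of averaged repetitions carried by the
#' map) is stored alongside for activation counting.
#'
#' @param gmap a \code{glomerular_map}.
#' @param dm a \code{delta_map} (typically repetition-averaged).
#' @param odorant,dilution_exponent,repetition stimulus labels; default to
#'   the map's metadata. Use \code{repetition = NA} for averaged maps.
#' @return the \code{glomerular_map} with rows appended to
#'   \code{$amplitudes}.
#' @export
quantify <- function(gmap, dm, odorant = dm$meta$odorant,
                     dilution_exponent = dm$meta$dilution_exponent,
                     repetition = dm$meta$repetition) {
  stopifnot(inherits(gmap, "glomerular_map"), inherits(dm, "delta_map"))
  shape <- dim(dm$values)
  for (roi in gmap$rois) {
    px <- roi$pixels
    if (any(px[, 1] < 1 | px[, 1] > shape[1] |
            px[, 2] < 1 | px[, 2] > shape[2]))
      stop_invalid("ROI ", roi$id, " outside image")
    amp <- mean(dm$values[(px[, 2] - 1L) * shape[1] + px[, 1]])
    gmap$amplitudes <- rbind(gmap$amplitudes, data.frame(
      roi_id = roi$id, odorant = odorant,
      dilution_exponent = as.integer(dilution_exponent),
      repetition = if (is.null(repetition) || is.na(repetition))
        NA_integer_ else as.integer(repetition),
      amplitude_permil = amp,
      roi_noise_permil = dm$map_noise_permil / sqrt(roi$area)))
  }
  gmap
}

#' Count activated glomeruli for one stimulus
#'
#' An ROI counts as activated when the magnitude of its (repetition-
#' averaged) amplitude exceeds \code{activation_k} times its per-ROI noise
#' SD. Counting is monotone non-increasing in \code{activation_k}.
#'
#' @param gmap a quantified \code{glomerular_map}.
#' @param odorant,dilution_exponent stimulus selector.
#' @param activation_k threshold in per-ROI noise SDs (default 3).
#' @return integer count.
#' @export
count_activated <- function(gmap, odorant, dilution_exponent,
                            activation_k = 3) {
  a <- gmap$amplitudes
  sel <- a$odorant == odorant & a$dilution_exponent == dilution_exponent
  if (!any(sel)) return(0L)
  a <- a[sel, ]
  by_roi <- split(a, a$roi_id)
  sum(vapply(by_roi, function(rr) {
    amp <- mean(rr$amplitude_permil)
    noise <- mean(rr$roi_noise_permil) / sqrt(nrow(rr))
    is.finite(amp) && abs(amp) > activation_k * max(noise, 1e-12)
  }, logical(1)))
}

#' @export
print.glomerular_map <- function(x, ...) {
  cat(sprintf("<glomerular_map> %s (%s): %d ROIs, %d amplitude rows\n",
              x$mouse_id, x$group, length(x$rois), nrow(x$amplitudes)))
  invisible(x)
}
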