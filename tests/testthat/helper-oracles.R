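# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (closed form, enumeration,
# or naive loop).

# Exhaustive two-sample permutation p-value for binary traces: the
# permutation distribution of d = mean_A - mean_B at one time point depends
# only on how many of the pooled ones land in class A, which is
# hypergeometric, so the full enumeration has a closed form.
oracle_perm_pvalues <- function(sp, sm) {
  na <- nrow(sp); n <- na + nrow(sm)
  vapply(seq_len(ncol(sp)), function(ti) {
    K <- sum(sp[, ti]) + sum(sm[, ti])
    k_obs <- sum(sp[, ti])
    stats::phyper(k_obs - 1, K, n - K, na, lower.tail = FALSE)
  }, numeric(1))
}

# Naive-loop bootstrap of P(d* <= 0): independent reimplementation of the
# package's vectorised bootstrap (different resampling code path).
oracle_boot_pvalues <- function(sp, sm, n_boot, seed) {
  set.seed(seed)
  na <- nrow(sp); nb <- nrow(sm)
  hits <- numeric(ncol(sp))
  for (b in seq_len(n_boot)) {
    da <- colSums(sp[sample(na, replace = TRUE), , drop = FALSE]) / na
    db <- colSums(sm[sample(nb, replace = TRUE), , drop = FALSE]) / nb
    hits <- hits + (da - db <= 1e-12)
  }
  pmax(hits / n_boot, 1 / (n_boot + 1))
}

# literal restatement of the published scoring rule
oracle_score <- function(valence, bins) {
  n_licked <- sum(bins)
  if (valence == "S+") n_licked >= 3 else n_licked <= 1
}

# centroid matching of detected ROIs against ground-truth blobs
oracle_match_rois <- function(rois, gt) {
  hits <- 0L
  for (i in seq_len(gt$n_glomeruli)) {
    if (length(rois) == 0L) break
    d <- vapply(rois, function(r)
      sqrt(sum((r$centroid - gt$centers[i, ])^2)), numeric(1))
    if (min(d) <= gt$radii[i]) hits <- hits + 1L
  }
  list(recall = hits / gt$n_glomeruli,
       precision = if (length(rois)) hits / length(rois) else NA_real_)
}

# realized breathing frequency from the generator's recorded cycle times
oracle_cycle_frequency <- function(trace, window_s) {
  ct <- trace$cycle_times_s
  ct <- ct[ct >= window_s[1] & ct <= window_s[2]]
  if (length(ct) < 2L) return(NA_real_)
  (length(ct) - 1L) / (ct[length(ct)] - ct[1L])
}

# four-repetition stack set for one odorant at one dilution
make_rep_stacks <- function(gt, odorant = gt$odorants[1], dil = 0L,
                            group = "trained", n_reps = 4L) {
  lapply(seq_len(n_reps), function(r)
    generate_trial_stack(gt, odorant, dil, r, group = group))
}
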