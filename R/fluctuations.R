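# Per-residue RMSF, dynamic cross-correlation maps (DCCM), and portal-region
# segment correlation statistics, including the wild-type vs mutant
# anti-correlation-loss comparison.
#
# The DCCM uses the scalar-product (isotropic) definition
#   C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)
# with fluctuations dr_i = r_i(t) - <r_i> taken about the mean structure,
# matching iterative-mean alignment upstream.

#' Drop the equilibration window of a trajectory
#'
#' Removes the leading frames of a trajectory before analysis. The default
#' fraction 1/6 mirrors discarding the first 0.5 us of a 3 us simulation and
#' analysing the remaining 2.5 us.
#'
#' @param traj A `trajectory`.
#' @param fraction Fraction of frames to discard from the start (`0 <=
#'   fraction < 1`). Ignored when `time` is given.
#' @param time Alternative cut: drop frames with time strictly below this
#'   value (requires frame times).
#' @return The truncated `trajectory`.
#' @export
discard_equilibration <- function(traj, fraction = 1 / 6, time = NULL) {
  f_n <- n_frames(traj)
  if (!is.null(time)) {
    if (is.null(traj$times)) abort("trajectory has no frame times")
    keep <- which(traj$times >= time)
  } else {
    if (fraction < 0 || fraction >= 1) abort("fraction must be in [0, 1)")
    n_drop <- floor(f_n * fraction)
    keep <- seq_len(f_n)[-seq_len(n_drop)]
    if (n_drop == 0) keep <- seq_len(f_n)
  }
  if (length(keep) < 2) abort("insufficient frames after equilibration cut")
  out <- new_trajectory(traj$topology,
                        traj$coords[keep, , , drop = FALSE],
                        traj$times[keep])
  if (inherits(traj, "aligned_trajectory")) {
    out$fit_indices <- traj$fit_indices
    out$reference <- traj$reference
    out$per_frame_rmsd <- traj$per_frame_rmsd[keep]
    class(out) <- c("aligned_trajectory", class(out))
  }
  out
}

fluct_array <- function(traj, selection) {
  if (is.null(selection)) selection <- atom_selection(name = "CA")
  idx <- atom_indices(traj$topology, selection)
  if (length(idx) == 0) abort("selection matches no atoms")
  if (n_frames(traj) < 2) abort("insufficient frames: need at least 2")
  x <- traj$coords[, idx, , drop = FALSE]
  mean_x <- apply(x, c(2, 3), mean)
  dx <- sweep(x, c(2, 3), mean_x)
  list(dx = dx, resids = traj$topology$resid[idx], idx = idx)
}

#' Per-residue root mean-square fluctuation
#'
#' Computes `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over the frames of an
#' aligned trajectory, for the selected atoms (default: all C-alpha).
#'
#' @param aligned An [align_trajectory()] result (any `trajectory` works; the
#'   caller is responsible for having aligned it).
#' @param selection [atom_selection()]; default all C-alpha atoms.
#' @return A tibble with columns `resid` and `rmsf` (Angstrom), classed
#'   `rmsf_profile`.
#' @export
rmsf <- function(aligned, selection = NULL) {
  fl <- fluct_array(aligned, selection)
  msf <- apply(fl$dx^2, 2, sum) / dim(fl$dx)[1]  # sums over frames & xyz
  out <- tibble(resid = fl$resids, rmsf = sqrt(msf))
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Dynamic cross-correlation map
#'
#' Normalized scalar-product correlations of positional fluctuations between
#' residue pairs: +1 fully correlated motion, -1 fully anti-correlated.
#' Residues with zero fluctuation give undefined (NA) entries.
#'
#' @inheritParams rmsf
#' @return An R x R matrix of class `dccm_matrix` with residue numbers as
#'   dimnames and attribute `resids`.
#' @export
dccm <- function(aligned, selection = NULL) {
  fl <- fluct_array(aligned, selection)
  f_n <- dim(fl$dx)[1]
  # cross = sum_t dr_i . dr_j, accumulated per coordinate axis
  cross <- matrix(0, length(fl$resids), length(fl$resids))
  for (k in 1:3) cross <- cross + crossprod(fl$dx[, , k])
  cross <- cross / f_n
  amp <- sqrt(diag(cross))
  denom <- outer(amp, amp)
  c_mat <- cross / denom
  c_mat[denom == 0] <- NA_real_
  c_mat[!is.na(c_mat)] <- pmin(pmax(c_mat[!is.na(c_mat)], -1), 1)
  diag(c_mat)[amp > 0] <- 1
  new_dccm(c_mat, fl$resids)
}

new_dccm <- function(c_mat, resids) {
  dimnames(c_mat) <- list(resids, resids)
  attr(c_mat, "resids") <- resids
  class(c_mat) <- c("dccm_matrix", class(c_mat))
  c_mat
}

#' @method tidy dccm_matrix
#' @export
tidy.dccm_matrix <- function(x, ...) {
  resids <- attr(x, "resids")
  tibble(resid_i = rep(resids, times = length(resids)),
         resid_j = rep(resids, each = length(resids)),
         correlation = as.vector(unclass(x)))
}

#' Default portal-region segment definitions
#'
#' Named inclusive residue ranges for the FABP portal region: helices alpha1
#' and alpha2 and the beta3-beta4 and beta5-beta6 loops. These are editable
#' defaults, not constants; every report echoes the ranges actually used.
#'
#' @param ... Additional named segments given as integer vectors, overriding
#'   or extending the defaults.
#' @return Named list of integer residue vectors, classed `segment_set`.
#' @export
default_segments <- function(...) {
  segs <- list(alpha1 = 14:22, alpha2 = 26:34,
               loop_b3b4 = 55:60, loop_b5b6 = 74:79)
  extra <- list(...)
  for (nm in names(extra)) segs[[nm]] <- as.integer(extra[[nm]])
  if (any(names(segs) == "") || anyDuplicated(names(segs))) {
    abort("segments must have unique non-empty names")
  }
  if (any(lengths(segs) == 0)) abort("segments must be non-empty")
  structure(segs, class = "segment_set")
}

#' Segment-pair correlation statistics from a DCCM
#'
#' Summarizes the DCCM block between two named segments: mean, min, max of
#' the correlations, and the count of residue pairs at or below the
#' anti-correlation threshold. Self-pairs (same residue in both segments)
#' are excluded when the segments overlap.
#'
#' @param dccm_mat A [dccm()] result.
#' @param segments A [default_segments()]-style named list.
#' @param pair Character vector of two segment names.
#' @param anticorr_threshold Correlations `<=` this count as anti-correlated
#'   (default -0.3).
#' @return A one-row tibble: `segment_a`, `segment_b`, `mean`, `min`, `max`,
#'   `n_pairs`, `n_anticorrelated`, `threshold`, plus `range_a`/`range_b`
#'   echoing the residue ranges used.
#' @export
segment_correlation <- function(dccm_mat, segments = default_segments(),
                                pair, anticorr_threshold = -0.3) {
  stopifnot(length(pair) == 2)
  for (nm in pair) {
    if (!nm %in% names(segments)) {
      abort(sprintf("unknown segment name '%s'", nm))
    }
  }
  resids <- attr(dccm_mat, "resids")
  ia <- which(resids %in% segments[[pair[1]]])
  ib <- which(resids %in% segments[[pair[2]]])
  if (length(ia) == 0 || length(ib) == 0) {
    abort("segment resolves to no residues present in the DCCM")
  }
  block <- unclass(dccm_mat)[ia, ib, drop = FALSE]
  # drop self-pairs when segments overlap
  same <- outer(resids[ia], resids[ib], "==")
  vals <- block[!same]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) abort("degenerate segment pair: empty block")
  tibble(segment_a = pair[1], segment_b = pair[2],
         mean = mean(vals), min = min(vals), max = max(vals),
         n_pairs = length(vals),
         n_anticorrelated = sum(vals <= anticorr_threshold),
         threshold = anticorr_threshold,
         range_a = paste(range(segments[[pair[1]]]), collapse = "-"),
         range_b = paste(range(segments[[pair[2]]]), collapse = "-"))
}

#' Change in segment anti-correlation between two variants
#'
#' Compares the same segment-pair correlation block between a reference
#' (e.g. wild type) and a variant (e.g. a portal mutant). On anti-correlated
#' blocks a positive `delta_mean` indicates loss of anti-correlation in the
#' variant.
#'
#' @param corr_ref,corr_var [segment_correlation()] rows for the same pair.
#' @return One-row tibble with `delta_mean = mean_var - mean_ref`,
#'   `delta_count = n_anticorrelated_var - n_anticorrelated_ref`, and the
#'   inputs' means and counts.
#' @export
anticorrelation_loss <- function(corr_ref, corr_var) {
  if (corr_ref$segment_a != corr_var$segment_a ||
      corr_ref$segment_b != corr_var$segment_b) {
    abort("segment-pair mismatch between reports")
  }
  tibble(segment_a = corr_ref$segment_a, segment_b = corr_ref$segment_b,
         mean_ref = corr_ref$mean, mean_var = corr_var$mean,
         delta_mean = corr_var$mean - corr_ref$mean,
         count_ref = corr_ref$n_anticorrelated,
         count_var = corr_var$n_anticorrelated,
         delta_count = corr_var$n_anticorrelated - corr_ref$n_anticorrelated)
}
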