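# Distance time series between atom groups and barrel-opening event
# detection. Distances are invariant under rigid motions of whole frames, so
# geometry is computed on unaligned coordinates and does not depend on
# superposition.

group_coords <- function(traj, selection, label) {
  idx <- atom_indices(traj$topology, selection)
  if (length(idx) == 0) abort(sprintf("group %s matches no atoms", label))
  idx
}

#' Distance time series between two atom groups
#'
#' Per frame, the distance between group representatives: the single
#' C-alpha of each group (`"calpha"`), the centroid of the selected atoms
#' (`"centroid"`), or the minimum over all heavy-atom pairs (`"min-heavy"`).
#'
#' @param traj A `trajectory`.
#' @param group_a,group_b [atom_selection()]s; both must be non-empty in the
#'   topology.
#' @param mode Distance mode; for `"calpha"` each group is reduced to its CA
#'   atoms (which must resolve to exactly one atom per group).
#' @return Tibble `frame` (0-indexed), `distance` (Angstrom), classed
#'   `distance_series`, with a `descriptor` attribute echoing groups + mode.
#' @export
distance_series <- function(traj, group_a, group_b,
                            mode = c("calpha", "centroid", "min-heavy")) {
  mode <- match.arg(mode)
  if (mode == "calpha") {
    group_a <- narrow_to_ca(group_a)
    group_b <- narrow_to_ca(group_b)
  }
  ia <- group_coords(traj, group_a, "A")
  ib <- group_coords(traj, group_b, "B")
  f_n <- n_frames(traj)
  d <- numeric(f_n)
  if (mode %in% c("calpha", "centroid")) {
    if (mode == "calpha" && (length(ia) != 1 || length(ib) != 1)) {
      abort("calpha mode requires exactly one CA atom per group")
    }
    for (f in seq_len(f_n)) {
      ca <- colMeans(matrix(traj$coords[f, ia, ], ncol = 3))
      cb <- colMeans(matrix(traj$coords[f, ib, ], ncol = 3))
      d[f] <- sqrt(sum((ca - cb)^2))
    }
  } else {
    for (f in seq_len(f_n)) {
      xa <- matrix(traj$coords[f, ia, ], ncol = 3)
      xb <- matrix(traj$coords[f, ib, ], ncol = 3)
      sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      d[f] <- sqrt(max(min(sq), 0))
    }
  }
  new_distance_series(d, descriptor = list(group_a = group_a,
                                           group_b = group_b, mode = mode))
}

narrow_to_ca <- function(sel) {
  sel$name <- "CA"
  sel
}

new_distance_series <- function(distances, descriptor = NULL,
                                frames = seq_along(distances) - 1L) {
  out <- tibble(frame = as.integer(frames), distance = distances)
  attr(out, "descriptor") <- descriptor
  class(out) <- c("distance_series", class(out))
  out
}

#' Detect barrel-opening events in a distance series
#'
#' An opening event is a maximal run of consecutive frames with distance
#' strictly above `threshold`, lasting at least `min_dwell` frames.
#'
#' @param series A [distance_series()] tibble (columns `frame`, `distance`).
#' @param threshold Opening distance threshold (Angstrom, > 0). The default
#'   13 A sits midway between the simulators' closed (10 A) and open (16 A)
#'   levels; tune it to the system at hand.
#' @param min_dwell Minimum event length in frames (>= 1).
#' @return An `opening_events` object: tibble of events (`start_frame`,
#'   `end_frame`, 0-indexed inclusive, `length`), with attributes
#'   `fraction_open` (frames inside events / total frames), `threshold`,
#'   `min_dwell`, `n_frames`.
#' @export
detect_opening <- function(series, threshold = 13, min_dwell = 10) {
  if (threshold <= 0) abort("threshold must be positive")
  if (min_dwell < 1) abort("min_dwell must be >= 1")
  above <- series$distance > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dwell
  events <- tibble(start_frame = series$frame[starts[keep]],
                   end_frame = series$frame[ends[keep]],
                   length = r$lengths[keep])
  out <- events
  attr(out, "fraction_open") <- sum(events$length) / nrow(series)
  attr(out, "threshold") <- threshold
  attr(out, "min_dwell") <- min_dwell
  attr(out, "n_frames") <- nrow(series)
  class(out) <- c("opening_events", class(out))
  out
}

#' @method glance opening_events
#' @export
glance.opening_events <- function(x, ...) {
  tibble(n_events = nrow(x),
         fraction_open = attr(x, "fraction_open"),
         threshold = attr(x, "threshold"),
         min_dwell = attr(x, "min_dwell"),
         n_frames = attr(x, "n_frames"))
}

#' Gate-residue to helix distance series
#'
#' Distance, per frame, between the side-chain centroid of a gate residue
#' (e.g. the portal gatekeeper Phe57) and the C-alpha centroid of a helix
#' segment. For residues without side-chain heavy atoms (Gly, Ala after
#' mutation) the C-alpha is used, with a warning.
#'
#' @param traj A `trajectory` whose topology includes the gate residue's
#'   side chain.
#' @param gate_resid Residue number of the gate residue.
#' @param helix_resids Integer vector of helix residue numbers (e.g. `26:34`
#'   for helix alpha2).
#' @param chain Optional chain restriction for both groups.
#' @return A [distance_series()] tibble.
#' @export
gate_distance <- function(traj, gate_resid, helix_resids, chain = NULL) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  gate_atoms <- select_atoms(traj$topology,
                             atom_selection(chain = chain, resid = gate_resid))
  if (nrow(gate_atoms) == 0) abort("gate residue not present in topology")
  side <- gate_atoms$name[!gate_atoms$name %in% backbone & gate_atoms$element != "H"]
  if (length(side) == 0) {
    warn("gate residue has no side-chain heavy atoms; falling back to CA")
    gate_sel <- atom_selection(chain = chain, resid = gate_resid, name = "CA")
  } else {
    gate_sel <- atom_selection(chain = chain, resid = gate_resid, name = side)
  }
  helix_sel <- atom_selection(chain = chain, resid = helix_resids, name = "CA")
  distance_series(traj, gate_sel, helix_sel, mode = "centroid")
}
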