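# Generators emulating every input the pipeline needs, with analytic ground
# truth where the downstream estimator can be checked against it:
#  - toy beta-barrel structures (Calpha + Cbeta pseudo-residues, optional
#    axial 16-carbon ligand standing in for palmitate),
#  - anisotropic elastic-network (ANM) covariances and their analytic DCCM,
#  - a factor-model covariance with engineered anti-correlated blocks,
#  - Gaussian fluctuation ensembles sampled from a given covariance,
#  - two-state (closed/open) Markov distance series with known labels,
#  - one-site binding curves with optional Gaussian noise.
# Every generator is deterministic given (parameters, seed) and embeds both
# in its output metadata.

#' Build an idealized beta-barrel test structure
#'
#' Places Calpha/Cbeta pseudo-residues on a cylinder: `n_strands` strands of
#' `residues_per_strand` residues, strand direction alternating to mimic an
#' antiparallel barrel, Cbeta pointing radially outwards. Residue numbering
#' runs sequentially along strands starting at `first_resid`, so with the
#' defaults residue 57 sits mid-barrel like the portal gatekeeper. The
#' optional ligand is a 16-carbon chain (palmitate stand-in) spiralling
#' around the cavity just inside the wall, as a hetero residue.
#'
#' @param n_strands Number of strands (>= 3), default 10.
#' @param residues_per_strand Residues per strand, default 6.
#' @param radius Barrel radius in Angstrom; the default 7.5 gives an
#'   inter-strand Calpha spacing of ~4.7 A, inside the 2.5-5 A contact
#'   window.
#' @param with_ligand Add the axial ligand (default `FALSE`).
#' @param first_resid Residue number of the first residue (default 42).
#' @return A `pdb_structure` tibble.
#' @examples
#' barrel <- build_toy_barrel()
#' nrow(dplyr::distinct(barrel, resid))  # 60 residues
#' @export
build_toy_barrel <- function(n_strands = 10, residues_per_strand = 6,
                             radius = 7.5, with_ligand = FALSE,
                             first_resid = 42) {
  if (n_strands < 3) abort("need at least 3 strands")
  spacing <- 2 * pi * radius / n_strands
  if (spacing < 2.5) {
    abort("radius too small: inter-strand spacing would clash (< 2.5 A)")
  }
  rise <- 3.3  # A per residue along the strand
  rows <- list()
  serial <- 0L
  resid <- first_resid - 1L
  for (s in seq_len(n_strands)) {
    ang <- 2 * pi * (s - 1) / n_strands
    zs <- (seq_len(residues_per_strand) - 1) * rise
    if (s %% 2 == 0) zs <- rev(zs)  # antiparallel
    for (r in seq_len(residues_per_strand)) {
      resid <- resid + 1L
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- tibble(
        serial = serial, name = "CA", element = "C", resname = "ALA",
        chain = "A", resid = resid,
        x = radius * cos(ang), y = radius * sin(ang), z = zs[r],
        is_hetero = FALSE)
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- tibble(
        serial = serial, name = "CB", element = "C", resname = "ALA",
        chain = "A", resid = resid,
        x = (radius + 1.5) * cos(ang), y = (radius + 1.5) * sin(ang),
        z = zs[r], is_hetero = FALSE)
    }
  }
  atoms <- dplyr::bind_rows(rows)
  if (with_ligand) {
    z_span <- range(atoms$z)
    zl <- seq(z_span[1], z_span[2], length.out = 16)
    # the chain spirals once around the cavity ~4 A inside the wall, so it
    # touches every strand, as a bound fatty acid lines the cavity
    angl <- 2 * pi * (seq_len(16) - 1) / 16
    rl <- radius - 4
    lig <- tibble(serial = max(atoms$serial) + seq_len(16),
                  name = paste0("C", seq_len(16)), element = "C",
                  resname = "PLM", chain = "A",
                  resid = max(atoms$resid) + 100L,
                  x = rl * cos(angl), y = rl * sin(angl), z = zl,
                  is_hetero = TRUE)
    atoms <- dplyr::bind_rows(atoms, lig)
  }
  as_structure(atoms)
}

#' Anisotropic elastic-network covariance and analytic DCCM
#'
#' Builds the anisotropic network model Hessian on the Calpha atoms of a
#' structure (springs between all Calpha pairs within `cutoff`), removes the
#' six rigid-body modes by eigenvalue truncation, and returns the thermal
#' fluctuation covariance `kT * H^+` together with the analytic DCCM it
#' implies (trace of the 3x3 cross blocks, normalized).
#'
#' @param structure A `pdb_structure`; only Calpha atoms are used.
#' @param cutoff Spring cutoff in Angstrom (default 12).
#' @param spring Uniform spring constant (energy/A^2, default 1).
#' @param kT Thermal factor in the same energy units (default 1).
#' @return List: `covariance` (3N x 3N), `dccm` (`dccm_matrix`), `resids`,
#'   `mean` (N x 3 Calpha coordinates), `params`.
#' @export
enm_covariance <- function(structure, cutoff = 12, spring = 1, kT = 1) {
  if (cutoff <= 0) abort("cutoff must be positive")
  ca <- select_atoms(structure, atom_selection(name = "CA"))
  n <- nrow(ca)
  if (n < 2) abort("need at least 2 Calpha atoms")
  xyz <- coords_matrix(ca)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  contact <- d2 <= cutoff^2 & upper.tri(d2)
  pairs <- which(contact, arr.ind = TRUE)
  if (nrow(pairs) == 0) abort("no springs: cutoff too small")
  # connectivity check on the spring graph
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    abort(sprintf("elastic network is disconnected at cutoff %.1f A (%d components)",
                  cutoff, comp$no))
  }
  h <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dv <- xyz[j, ] - xyz[i, ]
    dd <- sum(dv^2)
    blk <- -spring * tcrossprod(dv) / dd
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- h[ii, jj] + blk
    h[jj, ii] <- h[jj, ii] + blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  eig <- eigen(h, symmetric = TRUE)
  tol <- 1e-8 * max(eig$values)
  nonrigid <- eig$values > tol
  # 6 rigid-body null modes in general; 5 for collinear structures. More
  # indicates floppy internal modes the ensemble covariance cannot support.
  if (sum(!nonrigid) > 6) {
    abort(sprintf("found %d near-zero modes (> 6): network has internal zero-frequency modes",
                  sum(!nonrigid)))
  }
  v <- eig$vectors[, nonrigid, drop = FALSE]
  inv_lam <- 1 / eig$values[nonrigid]
  covariance <- kT * v %*% diag(inv_lam, nrow = length(inv_lam)) %*% t(v)
  list(covariance = covariance,
       dccm = covariance_dccm(covariance, ca$resid),
       resids = ca$resid, mean = xyz,
       params = list(cutoff = cutoff, spring = spring, kT = kT))
}

# Analytic DCCM from a 3N x 3N covariance: same scalar-product formula as
# the trajectory estimator, applied to the 3x3 blocks.
covariance_dccm <- function(covariance, resids) {
  n <- length(resids)
  tr <- matrix(0, n, n)
  for (k in 1:3) {
    sel <- seq(k, 3 * n, by = 3)
    tr <- tr + covariance[sel, sel]
  }
  amp <- sqrt(diag(tr))
  c_mat <- tr / outer(amp, amp)
  diag(c_mat) <- 1
  new_dccm(pmin(pmax(c_mat, -1), 1), resids)
}

#' Factor-model covariance with anti-correlated residue blocks
#'
#' Constructs an isotropic 3N x 3N covariance in which every residue of
#' block A loads `+sqrt(coupling)` and every residue of block B loads
#' `-sqrt(coupling)` on one shared factor, giving an exact between-block
#' DCCM of `-coupling` (within-block `+coupling`, elsewhere 0, diagonal 1).
#' With `coupling = 0` all residues fluctuate independently. This provides a
#' closed-form ground truth for segment anti-correlation analyses, e.g. an
#' engineered beta5-beta6-vs-portal contrast.
#'
#' @param resids Ordered residue numbers of the ensemble.
#' @param block_a,block_b Residue numbers of the two coupled blocks
#'   (disjoint subsets of `resids`).
#' @param coupling Shared-factor variance fraction in `[0, 1)`; default 0.5.
#' @param scale Per-axis standard deviation in Angstrom (default 0.5).
#' @return List: `covariance` (3N x 3N), `dccm` (`dccm_matrix`), `resids`,
#'   `params`.
#' @export
coupled_block_covariance <- function(resids, block_a, block_b,
                                     coupling = 0.5, scale = 0.5) {
  if (coupling < 0 || coupling >= 1) abort("coupling must be in [0, 1)")
  if (length(intersect(block_a, block_b)) > 0) {
    abort("blocks must be disjoint")
  }
  n <- length(resids)
  load <- numeric(n)
  load[resids %in% block_a] <- sqrt(coupling)
  load[resids %in% block_b] <- -sqrt(coupling)
  r <- tcrossprod(load)
  diag(r) <- 1
  covariance <- scale^2 * (r %x% diag(3))
  list(covariance = covariance,
       dccm = covariance_dccm(covariance, resids),
       resids = resids,
       params = list(coupling = coupling, scale = scale,
                     block_a = block_a, block_b = block_b))
}

#' Sample a Gaussian fluctuation ensemble
#'
#' Draws `n_frames` frames from `mean + N(0, covariance)` and packages them
#' as a trajectory over the structure's Calpha atoms. Sampling uses the
#' eigendecomposition of the covariance; eigenvalues below `-1e-8` times the
#' largest are rejected as non-PSD, small negative ones are clamped to zero.
#'
#' @param structure A `pdb_structure` supplying the Calpha topology and mean
#'   coordinates (e.g. from [build_toy_barrel()]).
#' @param covariance 3N x 3N positive-semidefinite covariance (A^2), atom
#'   order matching the structure's Calpha atoms, coordinates interleaved
#'   x1,y1,z1,x2,...
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return A `trajectory` with metadata attribute `generator` echoing
#'   parameters and seed.
#' @export
sample_ensemble <- function(structure, covariance, n_frames = 5000,
                            seed = 1) {
  if (n_frames < 2) abort("need at least 2 frames")
  ca <- select_atoms(structure, atom_selection(name = "CA"))
  n <- nrow(ca)
  if (nrow(covariance) != 3 * n) {
    abort("covariance dimension does not match 3 x number of Calpha atoms")
  }
  eig <- eigen(covariance, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1e-300)) {
    abort("covariance is not positive semidefinite")
  }
  lam <- pmax(eig$values, 0)
  half <- eig$vectors %*% diag(sqrt(lam), nrow = length(lam))
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  z <- matrix(stats::rnorm(n_frames * 3 * n), nrow = n_frames)
  draws <- z %*% t(half)  # frames x 3N
  mean_xyz <- coords_matrix(ca)
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  for (k in 1:3) {
    sel <- seq(k, 3 * n, by = 3)
    coords[, , k] <- sweep(draws[, sel, drop = FALSE], 2, mean_xyz[, k], "+")
  }
  traj <- new_trajectory(ca, coords)
  attr(traj, "generator") <- list(type = "gaussian_ensemble",
                                  n_frames = n_frames, seed = seed)
  traj
}

#' Simulate a two-state (closed/open) distance series
#'
#' Hidden two-state Markov chain (0 = closed at `d_closed`, 1 = open at
#' `d_open`) with per-frame transition probabilities and additive Gaussian
#' noise on the emitted distance. The stationary open fraction is
#' `p_open / (p_open + p_close)`. The defaults (0.02, 0.08) give a 0.2
#' stationary open fraction with mean dwell times of 50 (closed) and 12.5
#' (open) frames.
#'
#' @param n_frames Series length.
#' @param d_closed,d_open Closed and open distance levels (A, `d_open >
#'   d_closed`).
#' @param p_open P(closed -> open) per frame, in (0, 1).
#' @param p_close P(open -> closed) per frame, in (0, 1).
#' @param noise_sd Gaussian noise SD on the distance (A); default 1.2 (20%
#'   of the default level separation).
#' @param seed Integer seed.
#' @return List: `series` (a `distance_series` tibble), `states` (0/1 true
#'   labels), `stationary_open` (analytic open fraction), `params`.
#' @export
simulate_opening <- function(n_frames = 10000, d_closed = 10, d_open = 16,
                             p_open = 0.02, p_close = 0.08, noise_sd = 1.2,
                             seed = 1) {
  if (d_open <= d_closed) abort("d_open must exceed d_closed")
  if (any(c(p_open, p_close) <= 0) || any(c(p_open, p_close) >= 1)) {
    abort("transition probabilities must be in (0, 1)")
  }
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  states <- integer(n_frames)
  u <- stats::runif(n_frames)
  states[1] <- as.integer(u[1] < p_open / (p_open + p_close))  # stationary init
  for (f in 2:n_frames) {
    states[f] <- if (states[f - 1] == 0L) {
      as.integer(u[f] < p_open)
    } else {
      as.integer(u[f] >= p_close)
    }
  }
  d <- ifelse(states == 1L, d_open, d_closed)
  if (noise_sd > 0) d <- d + stats::rnorm(n_frames, sd = noise_sd)
  series <- new_distance_series(d, descriptor = list(
    type = "two_state_markov", d_closed = d_closed, d_open = d_open,
    p_open = p_open, p_close = p_close, noise_sd = noise_sd, seed = seed))
  list(series = series, states = states,
       stationary_open = p_open / (p_open + p_close),
       params = attr(series, "descriptor"))
}

#' Simulate a one-site saturation binding dataset
#'
#' Responses are `one_site_response(concentration, bmax, kd)` plus optional
#' Gaussian noise, one row per (concentration, replicate).
#'
#' @param concentrations Analyte concentrations (uM).
#' @param bmax,kd Generating parameters (R.U., uM).
#' @param noise_sd Gaussian noise SD in R.U. (default 0: exact curve).
#' @param replicates Number of replicate injections per concentration.
#' @param seed Integer seed.
#' @return Tibble `concentration`, `replicate`, `response` with a
#'   `generator` attribute echoing parameters and seed.
#' @export
simulate_binding <- function(concentrations, bmax, kd, noise_sd = 0,
                             replicates = 1, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  d <- tidyr::expand_grid(concentration = as.numeric(concentrations),
                          replicate = seq_len(replicates))
  d$response <- one_site_response(d$concentration, bmax, kd)
  if (noise_sd > 0) d$response <- d$response + stats::rnorm(nrow(d), sd = noise_sd)
  attr(d, "generator") <- list(type = "one_site_binding", bmax = bmax,
                               kd = kd, noise_sd = noise_sd, seed = seed)
  d
}

# Seed hygiene: generators set the RNG locally and restore the caller's
# state afterwards, so pipelines stay reproducible per (parameters, seed).
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
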