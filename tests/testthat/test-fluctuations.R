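make_displaced_traj <- function(base, displacements) {
  # displacements: list of F matrices (N x 3) added to the base CA coords
  ca <- select_atoms(base, atom_selection(name = "CA"))
  coords <- array(NA_real_, dim = c(length(displacements), nrow(ca), 3))
  for (f in seq_along(displacements)) {
    coords[f, , ] <- as.matrix(ca[, c("x", "y", "z")]) + displacements[[f]]
  }
  portalwatch:::new_trajectory(ca, coords)
}

test_that("rmsf is zero for identical frames and errors below 2 frames", {
  pep <- toy_peptide()
  traj <- models_to_trajectory(list(pep, pep, pep))
  expect_true(all(rmsf(traj)$rmsf == 0))
  one <- models_to_trajectory(list(pep))
  expect_error(rmsf(one), "frames")
})

test_that("rmsf recovers sigma*sqrt(3) for isotropic displacement and scales linearly", {
  barrel <- build_toy_barrel()
  iid <- coupled_block_covariance(55:114, block_a = 74:79, block_b = 55:60,
                                  coupling = 0, scale = 0.5)
  traj <- sample_ensemble(barrel, iid$covariance, n_frames = 10000, seed = 5)
  prof <- rmsf(traj)
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.02)
  # doubling displacement amplitudes doubles rmsf
  doubled <- traj
  mean_xyz <- apply(traj$coords, c(2, 3), mean)
  doubled$coords <- sweep(2 * sweep(traj$coords, c(2, 3), mean_xyz),
                          c(2, 3), mean_xyz, "+")
  expect_equal(rmsf(doubled)$rmsf, 2 * prof$rmsf, tolerance = 1e-9)
})

test_that("rmsf^2 equals the trace of the per-residue empirical covariance blocks", {
  barrel <- build_toy_barrel()
  enm <- enm_covariance(barrel)
  traj <- sample_ensemble(barrel, enm$covariance, n_frames = 200, seed = 6)
  prof <- rmsf(traj)
  x <- traj$coords
  for (i in c(1, 17, 60)) {
    dx <- sweep(x[, i, ], 2, colMeans(x[, i, ]))
    expect_equal(prof$rmsf[i]^2, sum(dx^2) / nrow(dx), tolerance = 1e-12)
  }
})

test_that("dccm reproduces hand-built perfectly correlated and anti-correlated pairs", {
  pep <- toy_peptide(resids = 1:4)
  set.seed(7)
  amp <- rnorm(20)
  disp <- lapply(amp, function(a) {
    rbind(c(a, 0, 0),   # residue 1
          c(a, 0, 0),   # residue 2: identical motion -> +1
          c(-a, 0, 0),  # residue 3: equal and opposite -> -1
          rnorm(3, sd = 0.1))
  })
  traj <- make_displaced_traj(pep, disp)
  cm <- dccm(traj)
  expect_equal(unclass(cm)[1, 2], 1, tolerance = 1e-12)
  expect_equal(unclass(cm)[1, 3], -1, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(cm), tol = 1e-12))
  expect_true(all(diag(unclass(cm)) == 1))
  expect_true(all(abs(unclass(cm)) <= 1))
})

test_that("zero-fluctuation residues yield NA off-diagonal entries", {
  pep <- toy_peptide(resids = 1:3)
  disp <- lapply(rnorm(10), function(a) {
    rbind(c(a, a, 0), c(0, 0, 0), rnorm(3, sd = 0.2))
  })
  cm <- dccm(make_displaced_traj(pep, disp))
  expect_true(is.na(unclass(cm)[1, 2]))
  expect_true(is.na(unclass(cm)[2, 3]))
})

test_that("estimated DCCM converges to the analytic elastic-network DCCM", {
  barrel <- build_toy_barrel()
  enm <- enm_covariance(barrel)
  traj <- sample_ensemble(barrel, enm$covariance, n_frames = 2000, seed = 8)
  est <- dccm(align_trajectory(traj))
  expect_lt(max(abs(unclass(est) - unclass(enm$dccm))), 0.08)
})

test_that("DCCM is invariant to a uniform rigid transform applied before alignment", {
  set.seed(48)
  barrel <- build_toy_barrel()
  enm <- enm_covariance(barrel)
  traj <- sample_ensemble(barrel, enm$covariance, n_frames = 100, seed = 9)
  cm1 <- dccm(align_trajectory(traj))
  rot <- random_rotation()
  moved <- traj
  for (f in seq_len(100)) {
    moved$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(rot), 2,
                                 c(11, -3, 8), "+")
  }
  cm2 <- dccm(align_trajectory(moved))
  expect_lt(max(abs(unclass(cm1) - unclass(cm2))), 1e-9)
})

test_that("segment correlation summarizes blocks and flags degenerate pairs", {
  resids <- 50:85
  n <- length(resids)
  c_mat <- diag(n)
  ia <- which(resids %in% 74:79); ib <- which(resids %in% 55:60)
  c_mat[ia, ib] <- -0.4; c_mat[ib, ia] <- -0.4
  cm <- portalwatch:::new_dccm(c_mat, resids)
  segs <- default_segments()
  sc <- segment_correlation(cm, segs, c("loop_b5b6", "loop_b3b4"),
                            anticorr_threshold = -0.3)
  expect_equal(sc$mean, -0.4)
  expect_equal(sc$n_anticorrelated, sc$n_pairs)
  expect_equal(sc$n_pairs, 36)
  expect_true(sc$min <= sc$mean && sc$mean <= sc$max)
  # unknown segment
  expect_error(segment_correlation(cm, segs, c("loop_b5b6", "nope")),
               "unknown segment")
  # single-residue self pair is degenerate
  segs1 <- default_segments(solo = 60)
  expect_error(segment_correlation(cm, segs1, c("solo", "solo")),
               "degenerate")
})

test_that("segment correlation is invariant to residue order within segments", {
  set.seed(49)
  resids <- 50:85
  n <- length(resids)
  r <- crossprod(matrix(rnorm(n * n), n)) / n
  d <- sqrt(diag(r)); r <- r / outer(d, d)
  cm <- portalwatch:::new_dccm(r, resids)
  pair <- c("loop_b5b6", "loop_b3b4")
  s1 <- segment_correlation(cm, default_segments(), pair)
  perm <- sample(n)
  cm_perm <- portalwatch:::new_dccm(r[perm, perm], resids[perm])
  s2 <- segment_correlation(cm_perm, default_segments(), pair)
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$min, s2$min)
  expect_equal(s1$n_anticorrelated, s2$n_anticorrelated)
})

test_that("anticorrelation loss reports the wt-vs-mutant delta", {
  resids <- 50:85
  cmat <- function(v) {
    m <- diag(length(resids))
    ia <- which(resids %in% 74:79); ib <- which(resids %in% 26:34)
    m[ia, ib] <- v; m[ib, ia] <- v
    portalwatch:::new_dccm(m, resids)
  }
  segs <- default_segments(alpha2 = 50:54)  # keep inside the toy range
  wt <- segment_correlation(cmat(-0.5), segs, c("loop_b5b6", "loop_b3b4"))
  expect_equal(anticorrelation_loss(wt, wt)$delta_mean, 0)
  expect_equal(anticorrelation_loss(wt, wt)$delta_count, 0)
  other <- segment_correlation(cmat(-0.5), segs, c("loop_b5b6", "alpha2"))
  expect_error(anticorrelation_loss(wt, other), "mismatch")
})

test_that("engineered block coupling is recovered and its removal detected", {
  barrel <- build_toy_barrel(first_resid = 42)
  coupled <- coupled_block_covariance(42:101, block_a = 74:79,
                                      block_b = 55:60, coupling = 0.5)
  uncoupled <- coupled_block_covariance(42:101, block_a = 74:79,
                                        block_b = 55:60, coupling = 0)
  segs <- default_segments()
  pair <- c("loop_b5b6", "loop_b3b4")
  sc_c <- segment_correlation(
    dccm(sample_ensemble(barrel, coupled$covariance, 3000, seed = 10)),
    segs, pair)
  sc_u <- segment_correlation(
    dccm(sample_ensemble(barrel, uncoupled$covariance, 3000, seed = 11)),
    segs, pair)
  expect_equal(sc_c$mean, -0.5, tolerance = 0.05)
  expect_equal(sc_u$mean, 0, tolerance = 0.05)
  delta <- anticorrelation_loss(sc_c, sc_u)
  expect_equal(delta$delta_mean, 0.5, tolerance = 0.07)
})

test_that("equilibration discard mirrors the 3 us -> last 2.5 us convention", {
  pep <- toy_peptide()
  traj <- models_to_trajectory(rep(list(pep), 3000))
  expect_equal(portalwatch:::n_frames(discard_equilibration(traj)), 2500)
  expect_equal(portalwatch:::n_frames(discard_equilibration(traj, 0)), 3000)
  ten <- models_to_trajectory(rep(list(pep), 10))
  expect_equal(portalwatch:::n_frames(discard_equilibration(ten, 0.5)), 5)
  expect_error(discard_equilibration(ten, 0.95), "insufficient")
})
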