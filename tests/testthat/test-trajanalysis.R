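## small hand-built trajectory helpers
two_atom_traj <- function(frames) {
  atoms <- fc_structure(data.frame(
    name = c("CA", "CA"), chain = c("A", "A"), resno = c(1L, 2L),
    resid = "GLY", x = 0, y = 0, z = 0))
  arr <- array(unlist(frames), c(2, 3, length(frames)))
  fc_trajectory(atoms, arr)
}

test_that("minimum separation picks the closest atom pair per frame", {
  atoms <- fc_structure(data.frame(
    name = c("CB", "CB", "AU"), chain = c("A", "A", "N"),
    resno = c(1L, 2L, 1L), resid = c("ALA", "ALA", "AUN"),
    x = c(3, 4, 0), y = 0, z = 0, het = c(FALSE, FALSE, TRUE)))
  tr <- fc_trajectory(atoms, array(c(3, 4, 0, 0, 0, 0, 0, 0, 0), c(3, 3, 1)))
  s <- min_separation_series(tr, 1:2, 3)
  expect_equal(s$distance, 3)
  ## selection against itself -> 0
  expect_equal(min_separation_series(tr, 1:2, 1:2)$distance, 0)
  expect_error(min_separation_series(tr, integer(0), 3), "empty")
})

test_that("minimum separation matches the exhaustive all-pairs scan", {
  dimer <- make_ch3_dimer()
  small <- dimer[1:60, ]; class(small) <- class(dimer)
  tr <- make_jitter_trajectory(small, n_frames = 20, jitter_sigma = 0.4,
                               seed = 8)
  a <- 1:25; b <- 40:60
  got <- min_separation_series(tr, a, b)$distance
  expect_equal(got, brute_min_sep(tr, a, b), tolerance = 1e-9)
})

test_that("planted adsorption contacts are recovered exactly", {
  dimer <- make_ch3_dimer()
  planted <- data.frame(chain = c("B", "B", "D"), resno = c(354, 444, 356))
  tr <- make_adsorption_trajectory(dimer, planted = planted, n_frames = 9,
                                   seed = 4)
  ct <- contact_residues(tr)
  expect_equal(paste(ct$chain, ct$resno),
               paste(planted$chain, planted$resno)[order(planted$chain,
                                                         planted$resno)])
  expect_true(all(ct$min_dist <= 5))
  ## monotonicity in the cutoff
  c3 <- contact_residues(tr, cutoff = 3.2)
  c7 <- contact_residues(tr, cutoff = 7)
  expect_true(all(paste(c3$chain, c3$resno) %in% paste(ct$chain, ct$resno)))
  expect_true(all(paste(ct$chain, ct$resno) %in% paste(c7$chain, c7$resno)))
  expect_error(contact_residues(tr, chains = "Z"), "unknown chain")
})

test_that("a distant particle produces an empty contact table", {
  dimer <- make_ch3_dimer()
  np <- build_fcc_sphere()
  far <- np
  far$positions <- sweep(far$positions, 2, c(500, 500, 500), "+")
  st <- rbind(as.data.frame(dimer), as.data.frame({
    s <- aunp_as_structure(far); s$serial <- s$serial + nrow(dimer); s
  }))
  tr <- fc_trajectory(fc_structure(st),
                      array(as.matrix(st[, c("x", "y", "z")]),
                            c(nrow(st), 3, 1)))
  expect_equal(nrow(contact_residues(tr)), 0)
})

test_that("rmsd is zero for static and rigidly moved trajectories", {
  dimer <- make_ch3_dimer()
  static <- make_jitter_trajectory(dimer, n_frames = 6, jitter_sigma = 0,
                                   seed = 1)
  expect_lt(max(rmsd_series(static)$rmsd), 1e-9)
  rigid <- make_jitter_trajectory(dimer, n_frames = 6, jitter_sigma = 0,
                                  drift_angle = 15,
                                  drift_translation = c(1, -2, 0.5), seed = 1)
  expect_true(all(rmsd_series(rigid)$rmsd <= 1e-6))
})

test_that("two-atom hand case gives rmsd sqrt(1/2) without re-fitting", {
  ## post-alignment displacements (1,0,0) and (0,0,0):
  ## sqrt((1^2 + 0^2)/2) = sqrt(1/2); use a larger anchor set so the
  ## superposition of the anchors is the identity
  atoms <- fc_structure(data.frame(
    name = "CA", chain = "A", resno = 1:5, resid = "GLY",
    x = c(0, 10, 0, 5, 2), y = c(0, 0, 10, 5, 1), z = 0))
  f1 <- coords(atoms)
  f2 <- f1; f2[1, 1] <- f2[1, 1] + 1
  tr <- fc_trajectory(atoms, array(c(f1, f2), c(5, 3, 2)))
  r <- rmsd_series(tr, atoms = 1:2, align = 2:5)
  expect_equal(r$rmsd[2], sqrt(1 / 2), tolerance = 1e-6)
})

test_that("rmsd and rmsf agree with brute-force reimplementations", {
  dimer <- make_ch3_dimer()
  small <- dimer[1:100, ]; class(small) <- class(dimer)
  tr <- make_jitter_trajectory(small, n_frames = 40, jitter_sigma = 0.6,
                               drift_angle = 2, seed = 12)
  idx <- seq_len(100)
  expect_equal(rmsd_series(tr, atoms = idx)$rmsd,
               brute_rmsd_series(tr, idx), tolerance = 1e-9)
  got <- rmsf(tr, fragment = idx, window = c(0, 1e9))
  expect_equal(got$rmsf, brute_rmsf(tr, idx), tolerance = 1e-9)
})

test_that("rmsf recovers planted isotropic jitter as sigma * sqrt(3)", {
  dimer <- make_ch3_dimer()
  for (sigma in c(0.2, 0.5, 1.0)) {
    tr <- make_jitter_trajectory(dimer, n_frames = 2000, frame_spacing = 0.05,
                                 jitter_sigma = sigma, seed = 100 + sigma * 10)
    vals <- rmsf(tr, window = c(0, 1e9))$rmsf
    expect_lt(abs(mean(vals) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  }
  ## static trajectory: all zeros
  st <- make_jitter_trajectory(dimer, n_frames = 5, jitter_sigma = 0, seed = 1)
  expect_true(all(rmsf(st, window = c(0, 1e9))$rmsf == 0))
  ## rigid drift alone vanishes after alignment
  dr <- make_jitter_trajectory(dimer, n_frames = 10, jitter_sigma = 0,
                               drift_angle = 5, drift_translation = c(1, 0, 0),
                               seed = 1)
  expect_true(all(rmsf(dr, window = c(0, 1e9))$rmsf <= 1e-6))
})

test_that("rmsf single-atom hand case: positions 0 and 2 give rmsf 1", {
  atoms <- fc_structure(data.frame(
    name = c("CA", "CA", "CA", "CB"), chain = "A", resno = c(1L, 2L, 3L, 3L),
    resid = "GLY", x = c(0, 4, 8, 9), y = c(0, 0, 4, 5), z = 0))
  f1 <- coords(atoms)
  f2 <- f1; f2[4, 1] <- f2[4, 1] + 2
  tr <- fc_trajectory(atoms, array(c(f1, f2), c(4, 3, 2)))
  ## align on the three stationary CA anchors; residue 3's CB moves 0 -> 2
  out <- rmsf(tr, fragment = 1:3, atoms = 4, window = c(0, 1e9))
  expect_equal(out$rmsf, 1, tolerance = 1e-6)
})

test_that("pair distances summarise mean and SEM over the window", {
  dimer <- make_ch3_dimer()
  static <- make_jitter_trajectory(dimer, n_frames = 10, jitter_sigma = 0,
                                   seed = 1)
  pd <- pair_distance_summary(static, c(354, 444), window = c(0, 1e9))
  expect_equal(pd$sem, c(0, 0))
  ## chain-swap symmetry of the dimer: same distance either way round
  pd_swap <- pair_distance_summary(static, c(354, 444), chains = c("D", "B"),
                                   window = c(0, 1e9))
  expect_equal(pd$mean, pd_swap$mean, tolerance = 1e-9)
  expect_error(pair_distance_summary(static, 500, window = c(0, 1e9)),
               "500")
})

test_that("alternating distances give the textbook mean and SEM", {
  frames <- list(c(0, 10, 0, 0, 0, 0), c(0, 12, 0, 0, 0, 0),
                 c(0, 10, 0, 0, 0, 0), c(0, 12, 0, 0, 0, 0))
  ## two CA atoms on chains B and D at x-separation alternating 10, 12
  atoms <- fc_structure(data.frame(
    name = "CA", chain = c("B", "D"), resno = 7L, resid = "GLY",
    x = c(0, 10), y = 0, z = 0))
  arr <- array(NA_real_, c(2, 3, 4))
  for (k in 1:4) arr[, , k] <- matrix(frames[[k]], 2, 3)
  tr <- fc_trajectory(atoms, arr)
  pd <- pair_distance_summary(tr, 7, window = c(0, 1e9))
  expect_equal(pd$mean, 11)
  expect_equal(pd$sem, sd(c(10, 12, 10, 12)) / sqrt(4))
})

test_that("rmsd is invariant under one global rigid transform of all frames", {
  dimer <- make_ch3_dimer()
  small <- dimer[1:50, ]; class(small) <- class(dimer)
  tr <- make_jitter_trajectory(small, n_frames = 8, jitter_sigma = 0.5,
                               seed = 21)
  r0 <- rmsd_series(tr, atoms = 1:50)$rmsd
  R <- random_rotation()
  moved <- tr
  for (k in seq_len(dim(tr$coords)[3]))
    moved$coords[, , k] <- sweep(tr$coords[, , k] %*% t(R), 2, c(5, 6, 7), "+")
  expect_equal(rmsd_series(moved, atoms = 1:50)$rmsd, r0, tolerance = 1e-9)
})
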