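np_default <- function() detect_surface_atoms(build_fcc_sphere())

test_that("fcc sphere atom count matches the independent lattice enumeration", {
  np <- build_fcc_sphere(diameter = 2.5, lattice_constant = 4.078)
  expect_equal(nrow(np$positions), fcc_count_oracle(2.5, 4.078))
  ## doubling the diameter scales the count roughly eightfold
  big <- build_fcc_sphere(diameter = 5, lattice_constant = 4.078)
  ratio <- nrow(big$positions) / nrow(np$positions)
  expect_gt(ratio, 8 * 0.8)
  expect_lt(ratio, 8 * 1.2)
  expect_error(build_fcc_sphere(diameter = 0.03), "lattice spacing")
  expect_error(build_fcc_sphere(diameter = -1), "positive")
})

test_that("nearest-neighbour geometry is the fcc a/sqrt(2) with coordination 12", {
  np <- np_default()
  a <- np$lattice_constant
  d <- as.matrix(dist(np$positions))
  nn <- min(d[d > 1e-9])
  expect_equal(nn, a / sqrt(2), tolerance = 1e-9)
  ## minimum-distance invariant: no pair closer than 0.9 x nn
  expect_true(all(d[d > 1e-9] >= 0.9 * nn))
  ## interior atoms all have exactly 12 nearest neighbours
  interior <- which(!np$surface)
  expect_gt(length(interior), 0)
  expect_true(all(np$coordination[interior] == 12))
})

test_that("surface atoms form a proper subset including all hull support points", {
  np <- np_default()
  ns <- sum(np$surface)
  expect_gt(ns, 0)
  expect_lt(ns, nrow(np$positions))
  ## support points (extreme along random directions) are hull vertices
  set.seed(9)
  for (i in 1:50) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    expect_true(np$surface[which.max(np$positions %*% u)])
  }
  ## a single atom is all surface
  one <- build_fcc_sphere(diameter = 0.45, lattice_constant = 4.078)
  expect_equal(nrow(one$positions), 1)
  one <- detect_surface_atoms(one)
  expect_true(all(one$surface))
  expect_error(detect_surface_atoms(np, neighbor_cutoff = -1), "positive")
})

test_that("raising the coordination threshold never shrinks the surface set", {
  np <- build_fcc_sphere()
  prev <- rep(FALSE, nrow(np$positions))
  for (thr in c(8, 10, 12, 13)) {
    cur <- detect_surface_atoms(np, coordination_threshold = thr)$surface
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("charge assignment modes conserve the configured charge", {
  np <- np_default()
  tot <- assign_charges(np, "total", -10)
  expect_equal(sum(tot$charge), -10, tolerance = 1e-9)
  expect_true(all(tot$charge[!tot$surface] == 0))
  expect_equal(length(unique(tot$charge[tot$surface])), 1L)
  per <- assign_charges(np, "per_atom", -0.05)
  expect_equal(sum(per$charge), -0.05 * sum(np$surface), tolerance = 1e-9)
  zero <- assign_charges(np, "per_atom", 0)
  expect_true(all(zero$charge == 0))
  expect_error(assign_charges(build_fcc_sphere(), "total", -10),
               "detect_surface_atoms")
})

test_that("placement reaches the requested surface gap, by exhaustive scan", {
  dimer <- make_ch3_dimer()
  np <- build_fcc_sphere()
  map <- load_base_position_map()
  base_cb <- atom_select(dimer, name = "CB", resno = map$pdb)
  placed <- place_near(np, dimer, base_cb, gap = 10)
  P <- coords(dimer)
  m <- Inf
  for (j in seq_len(nrow(placed$positions))) {
    d <- sqrt(rowSums(sweep(P, 2, placed$positions[j, ])^2))
    m <- min(m, min(d))
  }
  expect_equal(m, 10, tolerance = 1e-3)
  ## gap 0: touching (separation bounded by the closest sweep approach)
  touching <- place_near(np, dimer, base_cb, gap = 0)
  expect_lte(attr(touching, "achieved_gap"), 0.5)
  expect_error(place_near(np, dimer, integer(0), gap = 10), "empty")
})

test_that("ion-pair counts follow the closed-form solvent-volume arithmetic", {
  expect_equal(ion_pair_count(c(85, 85, 85), 0), 0L)
  avogadro <- 6.02214076e23
  hand <- round(0.05 * avogadro * 85^3 * 1e-27)
  expect_equal(ion_pair_count(c(85, 85, 85), 0.05), as.integer(hand))
  ## linearity: doubling the solvent volume doubles the count within rounding
  n1 <- ion_pair_count(c(85, 85, 85), 0.05)
  n2 <- ion_pair_count(c(170, 85, 85), 0.05)
  expect_lte(abs(n2 - 2 * n1), 1)
  expect_error(ion_pair_count(c(-1, 10, 10), 0.05), "positive")
  expect_error(ion_pair_count(c(10, 10, 10), 0.05, excluded_volume = 1e9),
               "exceeds")
})

test_that("nanoparticle export round-trips through PDB and CSV", {
  np <- assign_charges(np_default(), "total", -10)
  st <- aunp_as_structure(np)
  expect_true(all(st$het))
  expect_true(all(st$resid == "AUN"))
  f <- tempfile(fileext = ".pdb")
  write_pdb(st, f)
  back <- read_pdb(f)
  expect_equal(nrow(back), nrow(np$positions))
  expect_equal(coords(back), np$positions, tolerance = 1e-3, ignore_attr = TRUE)
  fcsv <- tempfile(fileext = ".csv")
  write_aunp_csv(np, fcsv)
  tab <- read.csv(fcsv)
  expect_equal(sum(tab$charge), -10, tolerance = 1e-9)
  expect_equal(sum(tab$surface), sum(np$surface))
})
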