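#' @title Synthetic fixtures: toy CH3 dimers, sequence families,
#'   trajectories
#' @name synthdata
#' @description Seed-deterministic generators for validation: a geometric
#'   two-chain CH3 stand-in carrying the catalogued base-position residue
#'   identities, sequence families with controlled per-position
#'   variability, adsorption trajectories with planted contact residue
#'   sets, and jitter trajectories with known fluctuation amplitude.  The
#'   dimers are topology-level stand-ins (correct chains, numbering and
#'   residue identities; one side-chain pseudo-atom per residue), not
#'   physical folds.
NULL

CH3_FIRST_RESNO <- 341L
CH3_LAST_RESNO <- 444L

rotate_z <- function(xyz, angle) {
  ca <- cos(angle); sa <- sin(angle)
  R <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  xyz %*% t(R)
}

#' The reference CH3 sequence used by the synthetic dimer
#'
#' Residues 341-444 with the 1IGT (mouse IgG2a) identity at each of the 19
#' base positions (the first-listed variant of the catalogue) and alanine
#' at all filler positions.
#'
#' @param map base-position map (default: packaged catalogue).
#' @return a one-letter amino-acid string of length 104.
#' @export
ch3_base_sequence <- function(map = load_base_position_map()) {
  n <- CH3_LAST_RESNO - CH3_FIRST_RESNO + 1L
  aa <- rep("A", n)
  vl <- base_map_variants(map)
  aa[map$pdb - CH3_FIRST_RESNO + 1L] <- vapply(vl, `[`, "", 1L)
  paste(aa, collapse = "")
}

#' Build a synthetic two-chain CH3 dimer
#'
#' Chains B and D carry residues 341-444; the 19 base positions hold the
#' 1IGT residue identities and all other residues are alanine.  Each
#' residue has backbone atoms N, CA, C, O plus one side-chain pseudo-atom
#' (CB).  Base-position CAs sit on an arc facing a fixed focal point below
#' the protein (stored as attribute `"base_focus"`), with their side-chain
#' pseudo-atoms pointing toward it, i.e. outward from the protein body at
#' the base surface; chain D is chain B rotated 180 degrees about the
#' dimer two-fold (z) axis.
#'
#' @param map base-position map (default: packaged catalogue).
#' @return an [fc_structure()] with attribute `"base_focus"` (Angstrom
#'   3-vector).
#' @export
make_ch3_dimer <- function(map = load_base_position_map()) {
  focus <- c(0, 0, -16.5)
  arc_radius <- 20.5       # base CA arc radius about the focus (x-z plane)
  resnos <- CH3_FIRST_RESNO:CH3_LAST_RESNO
  aa <- strsplit(ch3_base_sequence(map), "")[[1]]
  is_base <- resnos %in% map$pdb
  base_rank <- cumsum(is_base)     # 1..19 at base positions
  fill_rank <- cumsum(!is_base)    # 1..85 at filler positions

  ca_list <- matrix(NA_real_, length(resnos), 3)
  for (i in seq_along(resnos)) {
    if (is_base[i]) {
      theta <- (base_rank[i] - 10) * 6 * pi / 180
      ca_list[i, ] <- c(arc_radius * sin(theta), 6,
                        focus[3] + arc_radius * cos(theta))
    } else {
      q <- fill_rank[i] - 1
      ca_list[i, ] <- c(3.8 * (q %% 13) - 22.8, 6, 10 + 3.2 * (q %/% 13))
    }
  }

  build_chain <- function(chain_id, flip) {
    rows <- vector("list", length(resnos))
    for (i in seq_along(resnos)) {
      ca <- ca_list[i, ]
      if (is_base[i]) {
        u <- focus - ca
        cb <- ca + 2.0 * u / sqrt(sum(u^2))
      } else {
        cb <- ca + c(0, 1.2, 1.0)
      }
      xyz <- rbind(N = ca + c(-1.2, 0.3, 0.2),
                   CA = ca,
                   C = ca + c(1.2, 0.3, 0.2),
                   O = ca + c(1.6, 0.4, 1.3),
                   CB = cb)
      if (flip) xyz <- rotate_z(xyz, pi)
      rows[[i]] <- data.frame(
        name = rownames(xyz), chain = chain_id, resno = resnos[i],
        resid = aa_one_to_three(aa[i]),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  atoms <- rbind(build_chain("B", FALSE), build_chain("D", TRUE))
  atoms$serial <- seq_len(nrow(atoms))
  st <- fc_structure(atoms)
  attr(st, "base_focus") <- focus
  st
}

#' Generate a sequence family with controlled per-position variability
#'
#' Produces `n` copies of a base sequence where each variable position
#' draws from its variant set; every variant is guaranteed to appear at
#' least once (hence the requirement `n >=` the largest variant-set size).
#' Draws are seed-deterministic.
#'
#' @param base base sequence (string, or record with a `seq` field).
#' @param variable_positions named list: 1-based sequence position ->
#'   character vector of one-letter variants.
#' @param n number of sequences.
#' @param seed integer RNG seed.
#' @return data frame with columns `id`, `label`, `seq`.
#' @export
make_sequence_family <- function(base, variable_positions, n, seed = 1) {
  ch <- seq_chars(base)
  if (length(variable_positions)) {
    pos <- as.integer(names(variable_positions))
    if (any(is.na(pos) | pos < 1 | pos > length(ch)))
      stop("variable position outside the base sequence")
    sizes <- lengths(variable_positions)
    if (any(sizes == 0)) stop("empty variant set")
    if (n < max(sizes))
      stop(sprintf("n = %d cannot cover a variant set of size %d",
                   n, max(sizes)))
  }
  set.seed(seed)
  seqs <- matrix(rep(ch, n), nrow = n, byrow = TRUE)
  for (k in seq_along(variable_positions)) {
    vars <- variable_positions[[k]]
    draws <- c(vars, sample(vars, n - length(vars), replace = TRUE))
    seqs[, as.integer(names(variable_positions)[k])] <- sample(draws)
  }
  data.frame(id = sprintf("SYN%03d", seq_len(n)),
             label = "synthetic",
             seq = apply(seqs, 1, paste, collapse = ""),
             stringsAsFactors = FALSE)
}

#' Sequence family emulating the catalogued base-position variability
#'
#' Convenience wrapper: builds the reference CH3 sequence and varies the 15
#' non-conserved base positions over their catalogued variant sets.
#'
#' @param map base-position map (default: packaged catalogue).
#' @param n number of sequences (default 30).
#' @param seed integer RNG seed.
#' @return data frame with columns `id`, `label`, `seq`.
#' @export
make_base_family <- function(map = load_base_position_map(), n = 30,
                             seed = 1) {
  vl <- base_map_variants(map)
  vp <- setNames(vl, map$pdb - CH3_FIRST_RESNO + 1L)
  make_sequence_family(ch3_base_sequence(map), vp, n, seed)
}

#' Reference contact-residue sets of the 1IGT-AuNP simulations
#'
#' The residues of heavy chains B and D reported within 5 Angstrom of the
#' charged and uncharged 2.5 nm AuNP at the end of the 100 ns adsorption
#' trajectories, with their surface classes.
#'
#' @param condition `"charged"`, `"uncharged"`, or `NULL` for both.
#' @return data frame with columns `condition`, `chain`, `resno`, `aa`,
#'   `class`.
#' @export
reference_contact_sets <- function(condition = NULL) {
  path <- system.file("extdata", "fc_contact_reference.csv",
                      package = "fcbase", mustWork = TRUE)
  ref <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("charged", "uncharged"))
    ref <- ref[ref$condition == condition, , drop = FALSE]
    rownames(ref) <- NULL
  }
  ref
}

#' Synthesise an adsorption trajectory with a planted contact set
#'
#' The nanoparticle approaches the dimer base along the axis through the
#' dimer's base focal point, reaching it at the final frame.  Side-chain
#' pseudo-atoms of the planted residues are extended radially to a contact
#' shell `cutoff - 1.5` Angstrom above the particle surface (emulating the
#' adaptation of the base surface seen on adsorption), which guarantees at
#' the final frame that every planted residue has an atom within
#' `cutoff - 0.5` of the particle while every other residue stays beyond
#' `cutoff + 1`.  Isotropic Gaussian jitter of standard deviation
#' `jitter_sigma` per coordinate is added to all protein atoms; particle
#' atoms do not jitter.  Output is deterministic under `seed`.
#'
#' @param dimer an [fc_structure()] from [make_ch3_dimer()] (must carry the
#'   `"base_focus"` attribute).
#' @param np an `aunp_model` (default: 2.5 nm fcc sphere).
#' @param planted data frame with columns `chain`, `resno`: the residues
#'   that must be in contact at the final frame.
#' @param n_frames number of frames (default 51).
#' @param frame_spacing frame spacing in ns (default 2, i.e. 0-100 ns).
#' @param gap_start extra particle displacement at the first frame in
#'   Angstrom (the approach distance; default 30).
#' @param cutoff contact cutoff in Angstrom the margins are built for
#'   (default 5).
#' @param jitter_sigma per-coordinate Gaussian jitter in Angstrom
#'   (default 0.1).
#' @param seed integer RNG seed.
#' @return an [fc_trajectory()] over the dimer plus particle atoms (chain
#'   `"N"`, residue `AUN`).
#' @export
make_adsorption_trajectory <- function(dimer, np = NULL, planted,
                                       n_frames = 51, frame_spacing = 2,
                                       gap_start = 30, cutoff = 5,
                                       jitter_sigma = 0.1, seed = 1) {
  focus <- attr(dimer, "base_focus")
  if (is.null(focus))
    stop("dimer lacks a base_focus attribute; use make_ch3_dimer()")
  if (jitter_sigma < 0) stop("jitter_sigma must be non-negative")
  if (is.null(np)) np <- build_fcc_sphere()
  npos <- sweep(np$positions, 2, colMeans(np$positions))  # centred particle
  rmax <- max(sqrt(rowSums(npos^2)))
  contact_dist <- cutoff - 1.5
  if (contact_dist <= 0)
    stop("cutoff too small to satisfy the contact margins")

  prot <- dimer
  key <- paste(prot$chain, prot$resno)
  wanted <- paste(planted$chain, planted$resno)
  if (!all(wanted %in% key))
    stop("planted residue(s) absent from the dimer: ",
         paste(setdiff(wanted, key), collapse = ", "))

  ## extend planted side-chain pseudo-atoms to the contact shell around
  ## the particle's final position (its centre at the base focus)
  final_np <- sweep(npos, 2, focus, "+")
  P <- coords(prot)
  for (w in wanted) {
    ridx <- which(key == w)
    cb <- ridx[prot$name[ridx] == "CB"]
    if (!length(cb)) stop("planted residue lacks a side-chain pseudo-atom")
    ca <- ridx[prot$name[ridx] == "CA"]
    u <- P[ca, ] - focus
    u <- u / sqrt(sum(u^2))
    x <- focus + (rmax + contact_dist) * u
    ## correct for surface bumpiness: shift along the ray until the
    ## nearest particle atom is at contact_dist
    for (it in 1:4) {
      d0 <- min_cross_dist(matrix(x, 1), final_np)
      x <- x + (contact_dist - d0) * u
    }
    P[cb, ] <- x
  }
  coords(prot) <- P

  np_struct <- aunp_as_structure(np)
  coords(np_struct) <- final_np
  np_struct$serial <- np_struct$serial + nrow(prot)
  atoms <- fc_structure(rbind(as.data.frame(prot),
                              as.data.frame(np_struct)))

  npr <- nrow(prot); nnp <- nrow(np_struct)
  set.seed(seed)
  arr <- array(NA_real_, c(npr + nnp, 3L, n_frames))
  offsets <- seq(gap_start, 0, length.out = n_frames)
  base_coords <- coords(atoms)
  for (k in seq_len(n_frames)) {
    fr <- base_coords
    fr[seq_len(npr), ] <- fr[seq_len(npr), ] +
      matrix(rnorm(npr * 3, 0, jitter_sigma), npr, 3)
    fr[npr + seq_len(nnp), 3] <- fr[npr + seq_len(nnp), 3] - offsets[k]
    arr[, , k] <- fr
  }
  traj <- fc_trajectory(atoms, arr,
                        times = (seq_len(n_frames) - 1) * frame_spacing)

  ## verify the planted/excluded margins at the final frame
  npidx <- npr + seq_len(nnp)
  fin <- n_frames
  for (w in unique(key)) {
    ridx <- which(key == w)
    dmin <- frame_min_dist(traj, ridx, npidx, fin)
    ok <- if (w %in% wanted) dmin <= cutoff - 0.5 else dmin >= cutoff + 1
    if (!ok)
      stop(sprintf("approach schedule cannot satisfy contact margins (residue %s, min dist %.2f A)",
                   w, dmin))
  }
  traj
}

#' Synthesise a rigid-drift plus Gaussian-jitter trajectory
#'
#' Each frame applies a cumulative rigid drift (rotation about z plus
#' translation) to the structure and adds i.i.d. Gaussian displacement of
#' standard deviation `jitter_sigma` per coordinate to every atom, giving a
#' known RMSF ground truth of `jitter_sigma * sqrt(3)` after alignment.
#'
#' @param structure an [fc_structure()].
#' @param n_frames number of frames.
#' @param frame_spacing frame spacing in ns.
#' @param jitter_sigma per-coordinate Gaussian standard deviation
#'   (Angstrom).
#' @param drift_angle rotation about z per frame, degrees (default 0).
#' @param drift_translation translation per frame, Angstrom 3-vector
#'   (default none).
#' @param seed integer RNG seed.
#' @return an [fc_trajectory()].
#' @export
make_jitter_trajectory <- function(structure, n_frames = 100,
                                   frame_spacing = 0.1, jitter_sigma = 0.5,
                                   drift_angle = 0,
                                   drift_translation = c(0, 0, 0),
                                   seed = 1) {
  if (jitter_sigma < 0) stop("jitter_sigma must be non-negative")
  X <- coords(structure)
  n <- nrow(X)
  set.seed(seed)
  arr <- array(NA_real_, c(n, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    ang <- (k - 1) * drift_angle * pi / 180
    fr <- rotate_z(X, ang)
    fr <- sweep(fr, 2, (k - 1) * drift_translation, "+")
    if (jitter_sigma > 0)
      fr <- fr + matrix(rnorm(n * 3, 0, jitter_sigma), n, 3)
    arr[, , k] <- fr
  }
  fc_trajectory(structure, arr,
                times = (seq_len(n_frames) - 1) * frame_spacing)
}
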