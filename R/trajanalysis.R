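#' @title Trajectory metrics
#' @name trajanalysis
#' @description Contact residues at a distance cutoff, minimum-separation
#'   time series, backbone RMSD after rigid-body superposition, per-residue
#'   RMSF over an aligned window, and inter-chain C-alpha distances with
#'   mean and SEM.
NULL

resolve_selection <- function(traj, sel) {
  if (is.null(sel)) return(integer(0))
  if (is.list(sel) && !is.numeric(sel))
    sel <- do.call(atom_select, c(list(traj$atoms), sel))
  as.integer(sel)
}

particle_indices <- function(traj) {
  idx <- which(traj$atoms$element == "Au" | traj$atoms$resid == "AUN")
  idx
}

frame_min_dist <- function(traj, a, b, frame) {
  A <- traj$coords[a, , frame, drop = FALSE]
  B <- traj$coords[b, , frame, drop = FALSE]
  dim(A) <- c(length(a), 3L); dim(B) <- c(length(b), 3L)
  min_cross_dist(A, B)
}

#' Minimum-separation time series between two selections
#'
#' Per frame, the minimum over all atom pairs between the two selections
#' (e.g. one residue's atoms versus all nanoparticle atoms).
#'
#' @param traj an [fc_trajectory()].
#' @param a,b atom selections: integer indices or lists of
#'   [atom_select()] arguments.
#' @return data frame with columns `time` (ns) and `distance` (Angstrom).
#' @export
min_separation_series <- function(traj, a, b) {
  a <- resolve_selection(traj, a); b <- resolve_selection(traj, b)
  if (!length(a) || !length(b)) stop("empty selection")
  vals <- vapply(seq_len(n_frames(traj)),
                 function(k) frame_min_dist(traj, a, b, k), numeric(1))
  data.frame(time = traj$times, distance = vals)
}

#' Contact residues within a cutoff of the nanoparticle
#'
#' A residue is a contact when any of its atoms lies within `cutoff` of any
#' particle atom at the chosen frame (default: the final frame, matching
#' end-of-trajectory contact tables).  Residues are annotated with their
#' [classify_residue()] class and ordered by residue number within chains.
#'
#' @param traj an [fc_trajectory()] containing protein and particle atoms.
#' @param chains chain identifiers to scan (default: all non-particle
#'   chains).
#' @param cutoff contact distance in Angstrom (default 5).
#' @param frame frame index (default: final frame).
#' @param particle atom selection for the particle (default: `Au`/`AUN`
#'   atoms).
#' @param condition optional condition label stored on the result (e.g.
#'   `"charged"`).
#' @return data frame of class `fc_contact_table` with columns `chain`,
#'   `resno`, `resid`, `aa`, `class`, `min_dist`; attributes `cutoff`,
#'   `frame`, `condition`.
#' @export
contact_residues <- function(traj, chains = NULL, cutoff = 5, frame = NULL,
                             particle = NULL, condition = NA_character_) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(frame)) frame <- n_frames(traj)
  if (frame < 1 || frame > n_frames(traj)) stop("frame index out of range")
  np <- if (is.null(particle)) particle_indices(traj)
        else resolve_selection(traj, particle)
  if (!length(np)) stop("no particle atoms found")
  prot_chains <- setdiff(unique(traj$atoms$chain), traj$atoms$chain[np])
  if (is.null(chains)) chains <- sort(prot_chains)
  unknown <- setdiff(chains, prot_chains)
  if (length(unknown))
    stop("unknown chain(s): ", paste(unknown, collapse = ", "))
  rows <- list()
  for (ch in chains) {
    cidx <- setdiff(atom_select(traj$atoms, chain = ch), np)
    for (rn in sort(unique(traj$atoms$resno[cidx]))) {
      ridx <- cidx[traj$atoms$resno[cidx] == rn]
      dmin <- frame_min_dist(traj, ridx, np, frame)
      if (dmin <= cutoff) {
        resid <- traj$atoms$resid[ridx[1]]
        aa <- aa_three_to_one(resid)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch, resno = rn, resid = resid, aa = aa,
          class = classify_residue(aa), min_dist = dmin,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), resno = integer(0),
               resid = character(0), aa = character(0),
               class = character(0), min_dist = numeric(0))
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "frame") <- frame
  attr(out, "condition") <- condition
  class(out) <- c("fc_contact_table", "data.frame")
  out
}

#' Per-frame RMSD after rigid-body superposition
#'
#' For each frame, the `align` selection is superposed (Kabsch) onto the
#' reference frame and the root-mean-square deviation
#' `sqrt(sum_i |r_i - r_i(ref)|^2 / N)` is evaluated over the `atoms`
#' selection.  By default both selections are the backbone atoms
#' (N, CA, C, O), so internal deformation is measured with rigid-body
#' motion removed.
#'
#' @param traj an [fc_trajectory()].
#' @param atoms atom selection to evaluate the RMSD over (indices or
#'   [atom_select()] argument list); default: all backbone atoms.
#' @param align atom selection used for the superposition (default:
#'   `atoms`).
#' @param reference reference frame index (default 1).
#' @return data frame with columns `time` (ns) and `rmsd` (Angstrom);
#'   `rmsd` is exactly 0 at the reference frame.
#' @export
rmsd_series <- function(traj, atoms = NULL, align = NULL, reference = 1) {
  if (is.null(atoms)) atoms <- list(name = PDB_BACKBONE, het = FALSE)
  atoms <- resolve_selection(traj, atoms)
  align <- if (is.null(align)) atoms else resolve_selection(traj, align)
  if (length(atoms) < 1) stop("empty atom mask")
  if (length(align) < 3) stop("alignment selection needs at least 3 atoms")
  slice <- function(idx, k) {
    m <- traj$coords[idx, , k, drop = FALSE]
    dim(m) <- c(length(idx), 3L)
    m
  }
  ref_align <- slice(align, reference)
  ref_atoms <- slice(atoms, reference)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    if (k == reference) return(0)
    sp <- kabsch_superpose(slice(align, k), ref_align)
    moved <- apply_superposition(sp, slice(atoms, k))
    sqrt(mean(rowSums((moved - ref_atoms)^2)))
  }, numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}

#' Per-residue root-mean-square fluctuation over a trajectory window
#'
#' Frames in the window are superposed onto the first window frame using
#' the `fragment` selection (removing rigid-body and inter-domain motion),
#' the time-average position of every atom is computed, and for residue k
#' with atoms i = 1..N_k the RMSF is
#' `sqrt( <  sum_i |r_i(t) - <r_i>|^2 / N_k  > )` with `< >` the window
#' time average.
#'
#' @param traj an [fc_trajectory()].
#' @param fragment atom selection used for the alignment (indices or
#'   [atom_select()] argument list); default: all backbone atoms.
#' @param atoms atom selection whose residues are profiled (default:
#'   `fragment`).
#' @param window `c(t1, t2)` in ns; default: the trailing 20 ns.
#' @return data frame with columns `chain`, `resno`, `resid`, `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(traj, fragment = NULL, atoms = NULL, window = NULL) {
  if (is.null(fragment)) fragment <- list(name = PDB_BACKBONE, het = FALSE)
  fragment <- resolve_selection(traj, fragment)
  atoms <- if (is.null(atoms)) fragment else resolve_selection(traj, atoms)
  if (length(fragment) < 3) stop("fragment selection needs at least 3 atoms")
  if (!length(atoms)) stop("empty atom selection")
  if (is.null(window)) window <- trailing_window(traj, 20)
  frames <- window_frames(traj, window)
  if (length(frames) < 2) stop("window must contain at least 2 frames")
  slice <- function(idx, k) {
    m <- traj$coords[idx, , k, drop = FALSE]
    dim(m) <- c(length(idx), 3L)
    m
  }
  ref <- slice(fragment, frames[1])
  nf <- length(frames)
  aligned <- array(NA_real_, c(length(atoms), 3L, nf))
  for (k in seq_len(nf)) {
    sp <- kabsch_superpose(slice(fragment, frames[k]), ref)
    aligned[, , k] <- apply_superposition(sp, slice(atoms, frames[k]))
  }
  mean_pos <- apply(aligned, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf),
                 function(k) rowSums((aligned[, , k] - mean_pos)^2),
                 numeric(length(atoms)))
  dev2 <- matrix(dev2, nrow = length(atoms))
  key <- paste(traj$atoms$chain[atoms], traj$atoms$resno[atoms])
  ukey <- unique(key)
  rows <- lapply(ukey, function(k2) {
    sel <- which(key == k2)
    ## Eq: per frame, mean squared deviation over the residue's atoms,
    ## then time-average, then sqrt
    val <- sqrt(mean(colMeans(dev2[sel, , drop = FALSE])))
    i1 <- atoms[sel[1]]
    data.frame(chain = traj$atoms$chain[i1], resno = traj$atoms$resno[i1],
               resid = traj$atoms$resid[i1], rmsf = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-chain C-alpha distances with window mean and SEM
#'
#' For each residue number, measures the per-frame distance between the
#' C-alpha atoms of the two chains, and summarises the window (default:
#' trailing 20 ns) by its mean and standard error of the mean
#' (`sd / sqrt(n)` over frames).
#'
#' @param traj an [fc_trajectory()].
#' @param resno integer vector of residue numbers (one pair per number).
#' @param chains the two chain identifiers (default B and D).
#' @param window `c(t1, t2)` in ns; default: trailing 20 ns.
#' @return data frame with columns `resno`, `n`, `mean`, `sem` (Angstrom);
#'   attribute `"series"` holds the per-frame distance matrix (frames x
#'   pairs) and `"times"` the corresponding times.
#' @export
pair_distance_summary <- function(traj, resno, chains = c("B", "D"),
                                  window = NULL) {
  if (length(chains) != 2) stop("exactly two chains required")
  if (is.null(window)) window <- trailing_window(traj, 20)
  frames <- window_frames(traj, window)
  series <- matrix(NA_real_, length(frames), length(resno),
                   dimnames = list(NULL, resno))
  idx1 <- idx2 <- integer(length(resno))
  for (p in seq_along(resno)) {
    i1 <- atom_select(traj$atoms, chain = chains[1], resno = resno[p],
                      name = "CA")
    i2 <- atom_select(traj$atoms, chain = chains[2], resno = resno[p],
                      name = "CA")
    if (length(i1) != 1 || length(i2) != 1)
      stop("missing C-alpha atom for residue ", resno[p])
    idx1[p] <- i1; idx2[p] <- i2
  }
  for (k in seq_along(frames)) {
    d <- traj$coords[idx1, , frames[k], drop = FALSE] -
      traj$coords[idx2, , frames[k], drop = FALSE]
    dim(d) <- c(length(resno), 3L)
    series[k, ] <- sqrt(rowSums(d^2))
  }
  out <- data.frame(
    resno = resno,
    n = length(frames),
    mean = colMeans(series),
    sem = apply(series, 2, sd) / sqrt(nrow(series)))
  rownames(out) <- NULL
  attr(out, "series") <- series
  attr(out, "times") <- traj$times[frames]
  out
}
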