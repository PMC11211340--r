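#' Trajectory container
#'
#' A trajectory is an ordered set of coordinate frames over a shared atom
#' table, with strictly increasing frame times in ns.
#'
#' @param atoms an [fc_structure()] atom table (coordinates of the first
#'   frame are taken from `coords` if supplied, otherwise from `atoms`).
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param times numeric vector of frame times (ns); defaults to
#'   `0, 1, ...`.
#' @return object of class `fc_trajectory`: list with elements `atoms`,
#'   `coords`, `times`.
#' @export
fc_trajectory <- function(atoms, coords, times = NULL) {
  if (!inherits(atoms, "fc_structure")) atoms <- fc_structure(atoms)
  coords <- as.array(coords)
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3)
    stop("coords must be n_atoms x 3 x n_frames")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times length must equal the frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "fc_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `fc_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a structure
#'
#' @param traj an `fc_trajectory`.
#' @param frame frame index (1-based).
#' @return an `fc_structure` with that frame's coordinates.
#' @export
frame_structure <- function(traj, frame) {
  if (frame < 1 || frame > n_frames(traj)) stop("frame index out of range")
  st <- traj$atoms
  coords(st) <- traj$coords[, , frame]
  st
}

#' @export
print.fc_trajectory <- function(x, ...) {
  cat(sprintf("fc_trajectory: %d atoms x %d frames, t = %.3g..%.3g ns\n",
              nrow(x$atoms), n_frames(x), min(x$times), max(x$times)))
  invisible(x)
}

## frame indices within a [t1, t2] time window
window_frames <- function(traj, window) {
  if (is.null(window)) return(seq_len(n_frames(traj)))
  idx <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(idx)) stop("time window outside trajectory")
  idx
}

## default analysis window: trailing `span` ns of the trajectory
trailing_window <- function(traj, span = 20) {
  tmax <- max(traj$times)
  c(tmax - span, tmax)
}
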