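#' Build a spherical fcc gold nanoparticle model
#'
#' Carves a sphere out of a bulk face-centred-cubic lattice (conventional
#' cubic cell with the 4-atom basis).  All lattice points within
#' `diameter / 2` of `center` are kept.  The default lattice constant is
#' the crystallographic value for gold, 4.078 Angstrom, giving a
#' nearest-neighbour distance of `a / sqrt(2)`.
#'
#' @param diameter sphere diameter in nm (default 2.5).
#' @param lattice_constant cubic lattice constant in Angstrom.
#' @param center sphere centre (Angstrom 3-vector).
#' @return object of class `aunp_model`: list with `positions` (N x 3,
#'   Angstrom), `element`, `charge` (e), `surface` (logical, `NA` until
#'   [detect_surface_atoms()] is run), `lattice_constant`, `diameter`,
#'   `center`.
#' @export
build_fcc_sphere <- function(diameter = 2.5, lattice_constant = 4.078,
                             center = c(0, 0, 0)) {
  if (diameter <= 0) stop("diameter must be positive")
  r <- diameter * 10 / 2
  if (2 * r < lattice_constant)
    stop("diameter smaller than one lattice spacing")
  nmax <- ceiling(r / lattice_constant) + 1L
  g <- as.matrix(expand.grid(i = -nmax:nmax, j = -nmax:nmax, k = -nmax:nmax))
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  pos <- g[rep(seq_len(nrow(g)), each = 4L), , drop = FALSE] +
    basis[rep(1:4, nrow(g)), , drop = FALSE]
  pos <- pos * lattice_constant
  keep <- rowSums(pos^2) <= r^2 + 1e-9
  pos <- pos[keep, , drop = FALSE]
  pos <- sweep(pos, 2, center, "+")
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  n <- nrow(pos)
  structure(list(positions = pos, element = rep("Au", n),
                 charge = rep(0, n), surface = rep(NA, n),
                 lattice_constant = lattice_constant,
                 diameter = diameter, center = center),
            class = "aunp_model")
}

#' @export
print.aunp_model <- function(x, ...) {
  ns <- if (all(is.na(x$surface))) "not detected" else sum(x$surface)
  cat(sprintf("aunp_model: %d Au atoms, %.2f nm fcc sphere (a = %.3f A), surface atoms: %s, net charge %.4g e\n",
              nrow(x$positions), x$diameter, x$lattice_constant, ns,
              sum(x$charge)))
  invisible(x)
}

aunp_pair_dist <- function(model) {
  as.matrix(stats::dist(model$positions))
}

#' Flag nanoparticle surface atoms by coordination number
#'
#' An atom is a surface atom when it has fewer than
#' `coordination_threshold` neighbours within `neighbor_cutoff`.  Defaults
#' correspond to the fcc bulk: cutoff `1.2 * a / sqrt(2)` and threshold 12
#' (the bulk coordination number).
#'
#' @param model an `aunp_model`.
#' @param neighbor_cutoff neighbour distance cutoff in Angstrom.
#' @param coordination_threshold integer bulk coordination.
#' @return the model with its `surface` flags set.
#' @export
detect_surface_atoms <- function(model, neighbor_cutoff = NULL,
                                 coordination_threshold = 12) {
  n <- nrow(model$positions)
  if (!n) stop("empty nanoparticle model")
  if (is.null(neighbor_cutoff))
    neighbor_cutoff <- 1.2 * model$lattice_constant / sqrt(2)
  if (neighbor_cutoff <= 0) stop("neighbor cutoff must be positive")
  d <- aunp_pair_dist(model)
  ncoord <- rowSums(d > 1e-9 & d <= neighbor_cutoff)
  model$surface <- ncoord < coordination_threshold
  model$coordination <- ncoord
  model
}

#' Assign charges to a nanoparticle model
#'
#' In `"total"` mode, `value` (e) is spread uniformly over the surface
#' atoms (interior atoms stay neutral) so the net charge equals `value`
#' exactly; in `"per_atom"` mode each surface atom receives `value`.
#'
#' @param model an `aunp_model` with surface flags set.
#' @param mode `"total"` or `"per_atom"`.
#' @param value charge in e (total or per surface atom).
#' @return the model with its `charge` vector set.
#' @export
assign_charges <- function(model, mode = c("total", "per_atom"), value) {
  mode <- match.arg(mode)
  if (all(is.na(model$surface)))
    stop("run detect_surface_atoms() before assigning charges")
  ns <- sum(model$surface)
  model$charge <- rep(0, nrow(model$positions))
  if (mode == "total") {
    if (ns == 0) stop("total-charge mode requires a non-empty surface set")
    model$charge[model$surface] <- value / ns
  } else {
    model$charge[model$surface] <- value
  }
  model
}

min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Place a nanoparticle at a given surface-to-surface gap from a protein
#'
#' The particle is moved along the ray from the protein centroid through
#' the centroid of `target` atoms until the minimum atom-atom distance
#' between particle and protein equals `gap` (bisection to `1e-4`
#' Angstrom).  With the default 10 Angstrom gap this reproduces the
#' unbiased starting geometry used for adsorption simulations.
#'
#' @param model an `aunp_model`.
#' @param structure an `fc_structure`.
#' @param target integer atom indices (or a list of [atom_select()]
#'   arguments) defining the approach direction.
#' @param gap required minimum separation in Angstrom (`>= 0`).
#' @return the translated model, with attribute `"achieved_gap"`.
#' @export
place_near <- function(model, structure, target, gap = 10) {
  if (gap < 0) stop("gap must be non-negative")
  if (is.list(target) && !is.numeric(target))
    target <- do.call(atom_select, c(list(structure), target))
  target <- as.integer(target)
  if (!length(target)) stop("empty target selection")
  P <- coords(structure)
  pcent <- colMeans(P)
  tcent <- colMeans(P[target, , drop = FALSE])
  dir <- tcent - pcent
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9)
    stop("target centroid coincides with the protein centroid; direction undefined")
  dir <- dir / nd
  np0 <- sweep(model$positions, 2, colMeans(model$positions))
  fgap <- function(t) min_cross_dist(P, sweep(np0, 2, tcent + t * dir, "+")) - gap
  rnp <- max(sqrt(rowSums(np0^2)))
  rpr <- max(sqrt(rowSums(sweep(P, 2, tcent)^2)))
  hi <- rnp + rpr + gap + 10
  if (fgap(hi) < 0) stop("cannot bracket the requested gap")
  lo <- 0
  while (fgap(lo) > 0 && lo > -(rnp + rpr)) lo <- lo - 5
  if (fgap(lo) < 0) {
    root <- stats::uniroot(fgap, c(lo, hi), tol = 1e-6)$root
  } else {
    ## separations are bounded below by the closest sweep approach (relevant
    ## only for near-zero gaps); take the best attainable point on the ray
    root <- stats::optimize(function(t) abs(fgap(t)), c(lo, hi),
                            tol = 1e-6)$minimum
  }
  newpos <- sweep(np0, 2, tcent + root * dir, "+")
  achieved <- min_cross_dist(P, newpos)
  tol <- if (fgap(lo) < 0) 1e-3 else 0.5
  if (abs(achieved - gap) > tol)
    stop(sprintf("placement failed: achieved gap %.4f A vs requested %.4f A",
                 achieved, gap))
  model$positions <- newpos
  model$center <- colMeans(newpos)
  attr(model, "achieved_gap") <- achieved
  model
}

#' Ion pairs needed for a target ionic strength
#'
#' Number of monovalent salt pairs (e.g. NaCl) to reach ionic strength `I`
#' in the solvent-accessible volume of a simulation box:
#' `round(I * N_A * (V_box - V_excluded))` with volumes converted to
#' litres.
#'
#' @param box_dimensions box edge lengths in Angstrom (length-3 vector).
#' @param ionic_strength mol/L.
#' @param excluded_volume solute-excluded volume in cubic Angstrom.
#' @return integer number of ion pairs.
#' @export
ion_pair_count <- function(box_dimensions, ionic_strength,
                           excluded_volume = 0) {
  if (length(box_dimensions) != 3 || any(box_dimensions <= 0))
    stop("box dimensions must be three positive lengths")
  if (ionic_strength < 0) stop("ionic strength must be non-negative")
  v <- prod(box_dimensions) - excluded_volume
  if (v <= 0) stop("excluded volume exceeds the box volume")
  avogadro <- 6.02214076e23
  as.integer(round(ionic_strength * avogadro * v * 1e-27))
}

#' Convert a nanoparticle model to an `fc_structure`
#'
#' Atoms are written as HETATM records with residue name `AUN` on chain
#' `"N"`, so nanoparticle atoms are selectable by element or residue name
#' in trajectory analyses.
#'
#' @param model an `aunp_model`.
#' @param chain chain identifier for the particle.
#' @return an `fc_structure`.
#' @export
aunp_as_structure <- function(model, chain = "N") {
  n <- nrow(model$positions)
  fc_structure(data.frame(
    serial = seq_len(n), name = "AU", element = "Au",
    chain = chain, resno = seq_len(n), icode = "", resid = "AUN",
    x = model$positions[, 1], y = model$positions[, 2],
    z = model$positions[, 3],
    occ = 1, b = 0, het = TRUE, stringsAsFactors = FALSE))
}

#' Export a nanoparticle charge table as CSV
#'
#' Columns: `serial, x, y, z, charge, surface`.
#'
#' @param model an `aunp_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aunp_csv <- function(model, path) {
  df <- data.frame(serial = seq_len(nrow(model$positions)),
                   x = model$positions[, 1], y = model$positions[, 2],
                   z = model$positions[, 3], charge = model$charge,
                   surface = model$surface)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
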