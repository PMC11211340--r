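#' @title Structure container and PDB/XYZ input/output
#' @name structio
#' @description Atomic structures are stored as a data frame of atom records
#'   (one row per atom) with class `fc_structure`.  Columns: `serial`,
#'   `name` (atom name, e.g. `"CA"`), `element`, `chain`, `resno`, `icode`,
#'   `resid` (3-letter residue name), `x`, `y`, `z` (Angstrom), `occ`, `b`,
#'   `het` (logical, HETATM record).
NULL

## backbone atom set used for RMSD-style analyses
PDB_BACKBONE <- c("N", "CA", "C", "O")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

#' Convert 3-letter residue names to 1-letter codes
#'
#' Non-standard residue names map to `"X"`.
#'
#' @param resid character vector of 3-letter residue names.
#' @return character vector of 1-letter codes.
#' @export
aa_three_to_one <- function(resid) {
  out <- AA3TO1[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Convert 1-letter amino-acid codes to 3-letter residue names
#'
#' @param aa character vector of 1-letter codes.
#' @return character vector of 3-letter names (`"UNK"` for unknown codes).
#' @export
aa_one_to_three <- function(aa) {
  out <- AA1TO3[toupper(aa)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

fc_structure_cols <- c("serial", "name", "element", "chain", "resno",
                       "icode", "resid", "x", "y", "z", "occ", "b", "het")

#' Construct an `fc_structure` atom table
#'
#' @param atoms data frame with at least `name`, `chain`, `resno`, `resid`,
#'   `x`, `y`, `z`; missing bookkeeping columns are filled with defaults.
#' @return data frame of class `fc_structure`.
#' @export
fc_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "chain", "resno", "resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  atoms <- atoms[, fc_structure_cols]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, atoms$het)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, icode, name) atom identifiers")
  rownames(atoms) <- NULL
  class(atoms) <- c("fc_structure", "data.frame")
  atoms
}

guess_element <- function(name) {
  el <- sub("^([A-Za-z]).*$", "\\1", name)
  el[toupper(name) %in% c("AU")] <- "Au"
  toupper(substr(el, 1, 1))
}

#' @export
print.fc_structure <- function(x, ...) {
  cat(sprintf("fc_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x),
              length(unique(paste(x$chain, x$resno, x$icode))),
              paste(sort(unique(x$chain)), collapse = " ")))
  invisible(x)
}

#' Extract the coordinate matrix of a structure
#'
#' @param structure an `fc_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

`coords<-` <- function(structure, value) {
  structure$x <- value[, 1]
  structure$y <- value[, 2]
  structure$z <- value[, 3]
  structure
}

#' Select atoms from an atom table
#'
#' Returns the integer indices of atoms matching every supplied filter.
#'
#' @param atoms an `fc_structure` or atom data frame.
#' @param chain,resno,name,element,resid optional filters; each keeps atoms
#'   whose field is in the supplied set.
#' @param het if not `NULL`, keep only HETATM (`TRUE`) or ATOM (`FALSE`)
#'   records.
#' @return integer vector of row indices.
#' @export
atom_select <- function(atoms, chain = NULL, resno = NULL, name = NULL,
                        element = NULL, resid = NULL, het = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  if (!is.null(element)) keep <- keep & atoms$element %in% element
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(het)) keep <- keep & atoms$het == het
  which(keep)
}

## -- PDB reading ------------------------------------------------------------

validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    bad <- nchar(ln) < 54
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bad <- any(is.na(xyz))
    }
    if (bad)
      stop(sprintf("malformed ATOM/HETATM record at line %d of '%s'", i, path))
  }
  invisible(length(idx))
}

bio3d_to_fc <- function(pdb) {
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  chain <- a$chain
  chain[is.na(chain)] <- " "
  icode <- a$insert
  icode[is.na(icode)] <- ""
  fc_structure(data.frame(
    serial = a$eleno, name = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "", guess_element(a$elety),
                     a$elesy),
    chain = chain, resno = a$resno, icode = icode, resid = a$resid,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM", stringsAsFactors = FALSE
  ))
}

#' Read a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records (via the bio3d parser) into an
#' [fc_structure()].  Only the blank or `'A'` alternate-location indicator is
#' kept.  `MODEL`/`ENDMDL` blocks beyond the first are ignored here; use
#' [read_trajectory_pdb()] for multi-model trajectories.
#'
#' @param path file path.
#' @return an `fc_structure`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^(ATOM|HETATM)", lines)))
    stop("no ATOM/HETATM records in '", path, "'")
  validate_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  bio3d_to_fc(pdb)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame over the shared atom table
#' of the first model.
#'
#' @param path file path.
#' @param times optional numeric vector of frame times in ns; defaults to
#'   `0, 1, 2, ...`.
#' @return an [fc_trajectory()].
#' @export
read_trajectory_pdb <- function(path, times = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^(ATOM|HETATM)", lines)))
    stop("no ATOM/HETATM records in '", path, "'")
  validate_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  atoms <- bio3d_to_fc(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  arr <- array(NA_real_, c(na, 3L, nf))
  for (k in seq_len(nf))
    arr[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  ## bio3d xyz covers all parsed atoms incl. discarded alt-locs; re-read only
  ## if counts disagree
  if (na != nrow(atoms))
    stop("alternate locations in multi-model files are not supported")
  fc_trajectory(atoms, arr, times = times)
}

## -- PDB writing ------------------------------------------------------------

format_pdb_atoms <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) < 4,
                  sprintf(" %-3s", atoms$name), atoms$name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$het, "HETATM", "ATOM"),
          atoms$serial %% 100000L, name4, "",
          atoms$resid, atoms$chain, atoms$resno, atoms$icode,
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
          toupper(atoms$element))
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' Trajectories are written as one `MODEL`/`ENDMDL` block per frame.
#'
#' @param x an `fc_structure` or `fc_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "fc_trajectory")) {
    for (k in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      fr <- frame_structure(x, k)
      writeLines(format_pdb_atoms(fr), con)
      writeLines("ENDMDL", con)
    }
  } else {
    writeLines(format_pdb_atoms(x), con)
  }
  writeLines("END", con)
  invisible(path)
}

## -- XYZ --------------------------------------------------------------------

#' Write coordinates in XYZ format
#'
#' One block per frame: atom count, comment line, then `element x y z`.
#'
#' @param x an `fc_structure`, `fc_trajectory`, `aunp_model`, or a numeric
#'   matrix (with `elements`).
#' @param path output file path.
#' @param elements per-atom element symbols when `x` is a bare matrix.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, elements = NULL, comment = "fcbase") {
  blocks <- list()
  if (inherits(x, "fc_trajectory")) {
    elements <- x$atoms$element
    for (k in seq_len(n_frames(x))) blocks[[k]] <- x$coords[, , k]
  } else if (inherits(x, "aunp_model")) {
    elements <- x$element
    blocks[[1]] <- x$positions
  } else if (inherits(x, "fc_structure")) {
    elements <- x$element
    blocks[[1]] <- coords(x)
  } else {
    if (is.null(elements)) stop("elements required for a bare matrix")
    blocks[[1]] <- as.matrix(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (m in blocks) {
    writeLines(as.character(nrow(m)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path file path.
#' @return a list with `elements` (character vector, from the first frame)
#'   and `frames` (list of coordinate matrices).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty XYZ file '", path, "'")
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || i + 1L + n > length(lines))
      stop("malformed XYZ header at line ", i, " of '", path, "'")
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    el <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(is.na(xyz))) stop("malformed XYZ coordinates near line ", i + 2L)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = elements, frames = frames)
}

## -- extraction and superposition -------------------------------------------

#' Extract a residue range from one chain
#'
#' @param structure an `fc_structure`.
#' @param chain chain identifier.
#' @param first,last inclusive residue-number bounds (`first <= last`).
#' @return an `fc_structure` with atom order preserved.
#' @export
extract_residue_range <- function(structure, chain, first, last) {
  if (first > last) stop("reversed bounds: first > last")
  idx <- atom_select(structure, chain = chain)
  idx <- idx[structure$resno[idx] >= first & structure$resno[idx] <= last]
  if (!length(idx))
    stop(sprintf("no atoms for chain %s residues %d-%d (wrong chain or numbering?)",
                 chain, first, last))
  out <- structure[idx, , drop = FALSE]
  class(out) <- c("fc_structure", "data.frame")
  out
}

as_coord_matrix <- function(x, mask = NULL) {
  if (inherits(x, "fc_structure")) {
    if (!is.null(mask)) x <- x[x$name %in% mask, , drop = FALSE]
    return(as.matrix(x[, c("x", "y", "z")]))
  }
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("coordinates must be an n x 3 matrix")
  m
}

#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile and a reference point set (SVD solution with the standard sign
#' correction, so a reflection is never returned).
#'
#' @param mobile,reference n x 3 coordinate matrices or `fc_structure`s
#'   with matching atom order.
#' @param mask optional atom-name filter applied to `fc_structure` inputs
#'   (e.g. `c("N","CA","C","O")`).
#' @return object of class `fc_superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3), and `rmsd` (Angstrom).  The fitted
#'   map is `x %*% t(rotation) + translation` for row-vector coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  P <- as_coord_matrix(mobile, mask)
  Q <- as_coord_matrix(reference, mask)
  if (nrow(P) != nrow(Q)) stop("point counts differ after masking")
  if (nrow(P) < 3) stop("need at least 3 points to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Qc)$d[2] < 1e-8 * (svd(Qc)$d[1] + 1e-30) ||
      svd(Pc)$d[2] < 1e-8 * (svd(Pc)$d[1] + 1e-30))
    stop("degenerate (collinear) point set")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd),
            class = "fc_superposition")
}

#' @export
print.fc_superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition: rmsd = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sp an `fc_superposition`.
#' @param x n x 3 matrix or `fc_structure`.
#' @return transformed object of the same kind.
#' @export
apply_superposition <- function(sp, x) {
  if (inherits(x, "fc_structure")) {
    coords(x) <- apply_superposition(sp, coords(x))
    return(x)
  }
  sweep(as_coord_matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
}
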