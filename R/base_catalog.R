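#' Load the Fc-base position map
#'
#' The base of the IgG Fc region comprises 19 amino-acid positions per heavy
#' chain at the CH3/CH3 interface.  The packaged map lists, for each
#' position, its Kabat number, the corresponding residue number in PDB
#' files, the variants observed across the analysed IgG sequences
#' (species and subclasses), and whether the position is conserved
#' (a single observed variant: P354, W418, K440 and S443 in PDB numbering).
#'
#' @param path CSV file with columns `index,kabat,pdb,variants,conserved`;
#'   defaults to the packaged catalogue.
#' @return data frame of class `fc_base_map` with columns `index`, `kabat`,
#'   `pdb`, `variants` ("/"-separated one-letter codes), `conserved`.
#' @export
load_base_position_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fc_base_positions.csv",
                        package = "fcbase", mustWork = TRUE)
  map <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "kabat", "pdb", "variants", "conserved")
  if (!all(need %in% names(map)))
    stop("base-position fixture lacks column(s): ",
         paste(setdiff(need, names(map)), collapse = ", "))
  vl <- strsplit(map$variants, "/", fixed = TRUE)
  for (i in seq_len(nrow(map))) {
    row_ok <- !is.na(map$index[i]) && map$index[i] == i &&
      map$index[i] >= 1 && map$index[i] <= 19 &&
      length(vl[[i]]) >= 1 && all(vl[[i]] %in% names(AA1TO3)) &&
      !is.na(map$conserved[i]) &&
      map$conserved[i] == (length(unique(vl[[i]])) == 1)
    if (!row_ok)
      stop(sprintf("corrupt base-position fixture at row %d (index '%s')",
                   i, map$index[i]))
  }
  if (any(diff(map$kabat) <= 0) || any(diff(map$pdb) <= 0))
    stop("corrupt base-position fixture: Kabat/PDB numbers not strictly increasing")
  class(map) <- c("fc_base_map", "data.frame")
  map
}

#' Variant sets of a base-position map
#'
#' @param map an `fc_base_map`.
#' @return named list (by PDB number) of character vectors of one-letter
#'   codes.
#' @export
base_map_variants <- function(map) {
  setNames(strsplit(map$variants, "/", fixed = TRUE), map$pdb)
}

#' Export a base-position map as CSV
#'
#' @param map an `fc_base_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_base_map_csv <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## -- residue classification -------------------------------------------------

RESIDUE_CLASS <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  P = "hydrophobic", M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
  K = "positive", R = "positive", H = "positive",
  E = "negative", D = "negative",
  G = "hydrophilic", S = "hydrophilic", C = "hydrophilic", N = "hydrophilic",
  Q = "hydrophilic", Y = "hydrophilic", T = "hydrophilic"
)

#' Classify amino acids by surface character
#'
#' Partitions the 20 standard residues into the four classes used to
#' describe the Fc-base surface: hydrophobic (A, V, L, I, P, M, F, W),
#' positively charged (K, R, H), negatively charged (E, D) and the
#' remaining hydrophilic residues (G, S, C, N, Q, Y, T).  His is counted
#' positive despite only partial protonation at pH 7, matching the surface
#' colouring convention this scheme reproduces.
#'
#' @param aa character vector of one-letter codes.
#' @return character vector with values `"hydrophobic"`, `"hydrophilic"`,
#'   `"positive"`, `"negative"` or `"unknown"`.
#' @export
classify_residue <- function(aa) {
  out <- RESIDUE_CLASS[toupper(aa)]
  out[is.na(out)] <- "unknown"
  unname(out)
}

#' Per-chain classification of the Fc-base positions of a structure
#'
#' Looks up each mapped PDB residue number on the given chains, records the
#' residue found there and its [classify_residue()] class, and warns (does
#' not fail) when the residue differs from the catalogued variants.
#'
#' @param structure an `fc_structure` containing the CH3 chains.
#' @param map an `fc_base_map` (default: packaged catalogue).
#' @param chains character vector of chain identifiers (default B and D,
#'   the heavy chains of the 1IGT numbering convention).
#' @return data frame with columns `chain`, `index`, `kabat`, `pdb`, `resid`,
#'   `aa`, `class`, `in_variants` (19 rows per chain).
#' @export
base_motif_summary <- function(structure, map = load_base_position_map(),
                               chains = c("B", "D")) {
  variants <- base_map_variants(map)
  out <- list()
  for (ch in chains) {
    missing <- integer(0)
    rows <- list()
    for (i in seq_len(nrow(map))) {
      p <- map$pdb[i]
      idx <- atom_select(structure, chain = ch, resno = p)
      if (!length(idx)) { missing <- c(missing, p); next }
      resid <- structure$resid[idx[1]]
      aa <- aa_three_to_one(resid)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, index = map$index[i], kabat = map$kabat[i], pdb = p,
        resid = resid, aa = aa, class = classify_residue(aa),
        in_variants = aa %in% variants[[as.character(p)]],
        stringsAsFactors = FALSE)
    }
    if (length(missing))
      stop(sprintf("chain %s lacks residue(s) at mapped PDB number(s): %s",
                   ch, paste(missing, collapse = ", ")))
    out[[ch]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!res$in_variants))
    warning("residues outside the catalogued variant sets: ",
            paste(sprintf("%s%d %s", res$chain[!res$in_variants],
                          res$pdb[!res$in_variants],
                          res$aa[!res$in_variants]), collapse = ", "))
  res
}

## -- sequence records and FASTA ---------------------------------------------

#' Read amino-acid sequences from FASTA
#'
#' The description line is parsed as `"id label..."`.
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `label`, `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  desc <- names(set)
  id <- sub("\\s.*$", "", desc)
  label <- ifelse(grepl("\\s", desc), sub("^\\S+\\s+", "", desc), "")
  data.frame(id = id, label = label, seq = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records to FASTA
#'
#' @param records data frame with columns `id`, `label`, `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$seq)
  names(set) <- trimws(paste(records$id, records$label))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## -- isoelectric point and molecular weight ---------------------------------

#' Default pKa table for net-charge and pI calculations
#'
#' Values: N-terminus 9.0, C-terminus 2.0, Asp 3.65, Glu 4.25, Cys 8.3,
#' Tyr 10.07, His 6.0, Lys 10.53, Arg 12.48.
#'
#' @return named numeric vector with entries `nterm`, `cterm`, `D`, `E`,
#'   `C`, `Y`, `H`, `K`, `R`.
#' @export
default_pka <- function() {
  c(nterm = 9.0, cterm = 2.0, D = 3.65, E = 4.25, C = 8.3, Y = 10.07,
    H = 6.0, K = 10.53, R = 12.48)
}

seq_chars <- function(seq) {
  if (is.list(seq) || is.data.frame(seq)) seq <- seq$seq
  strsplit(toupper(seq), "")[[1]]
}

#' Henderson-Hasselbalch net charge of a sequence at a given pH
#'
#' Positive groups (N-terminus, K, R, H) contribute
#' `1 / (1 + 10^(pH - pKa))`; negative groups (C-terminus, D, E, C, Y)
#' contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param seq amino-acid string (or record with a `seq` field).
#' @param pH numeric pH.
#' @param pka pKa table as from [default_pka()].
#' @return net charge in elementary units.
#' @export
net_charge <- function(seq, pH, pka = default_pka()) {
  ch <- seq_chars(seq)
  if (!length(ch)) stop("empty sequence")
  counts <- table(ch)
  pos <- c(nterm = 1, K = 0, R = 0, H = 0)
  neg <- c(cterm = 1, D = 0, E = 0, C = 0, Y = 0)
  for (a in intersect(names(counts), names(pos))) pos[a] <- counts[[a]]
  for (a in intersect(names(counts), names(neg))) neg[a] <- counts[[a]]
  q_pos <- sum(pos / (1 + 10^(pH - pka[names(pos)])))
  q_neg <- sum(neg / (1 + 10^(pka[names(neg)] - pH)))
  q_pos - q_neg
}

#' Isoelectric point of a sequence by net-charge bisection
#'
#' Bisects the monotone net-charge curve on pH (0, 14) until the interval is
#' narrower than `tol`.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units (default `1e-3`).
#' @return pH at which the modeled net charge is zero.
#' @export
isoelectric_point <- function(seq, pka = default_pka(), tol = 1e-3) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## average residue masses (Da); peptide-bond water subtracted
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
WATER_MASS <- 18.0153

#' Average molecular weight of a peptide sequence
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq amino-acid string (or record with a `seq` field).
#' @return mass in Da.
#' @export
molecular_weight <- function(seq) {
  ch <- seq_chars(seq)
  if (!length(ch)) stop("empty sequence")
  bad <- setdiff(unique(ch), names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  sum(RESIDUE_MASS[ch]) + WATER_MASS
}
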