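#' BLOSUM62 substitution matrix
#'
#' Convenience accessor for the BLOSUM62 scoring matrix shipped with
#' Biostrings, the default substitution model for [align_sequences()].
#'
#' @return integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

aa_alphabet <- function() c(names(AA1TO3), "X")

## Affine-gap (Gotoh) global alignment of a gapped profile against one
## sequence.  A gap of length L costs open + L * ext.  Profile columns are
## scored against a residue by the mean substitution score over the
## column's non-gap residues (all-gap columns score 0).
gotoh_align <- function(profile, b, S, open, ext) {
  m <- ncol(profile); n <- length(b)
  ## per-column residue counts -> profile/residue score matrix
  alpha <- rownames(S)
  Cmat <- matrix(0, m, length(alpha), dimnames = list(NULL, alpha))
  for (i in seq_len(m)) {
    col <- profile[, i]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(col)
      Cmat[i, names(tb)] <- as.numeric(tb)
    }
  }
  denom <- pmax(rowSums(Cmat), 1)
  sub <- (Cmat %*% S[alpha, b, drop = FALSE]) / denom   # m x n

  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  pM <- matrix(NA_character_, m + 1, n + 1); pX <- pM; pY <- pM
  M[1, 1] <- 0
  for (i in seq_len(m)) { X[i + 1, 1] <- -(open + i * ext); pX[i + 1, 1] <- "X" }
  pX[2, 1] <- "M"
  for (j in seq_len(n)) { Y[1, j + 1] <- -(open + j * ext); pY[1, j + 1] <- "Y" }
  pY[1, 2] <- "M"
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      k <- which.max(prev)
      M[i + 1, j + 1] <- prev[k] + sub[i, j]
      pM[i + 1, j + 1] <- names(prev)[k]
      cand <- c(M = M[i, j + 1] - open - ext,
                X = X[i, j + 1] - ext,
                Y = Y[i, j + 1] - open - ext)
      k <- which.max(cand)
      X[i + 1, j + 1] <- cand[k]; pX[i + 1, j + 1] <- names(cand)[k]
      cand <- c(M = M[i + 1, j] - open - ext,
                X = X[i + 1, j] - open - ext,
                Y = Y[i + 1, j] - ext)
      k <- which.max(cand)
      Y[i + 1, j + 1] <- cand[k]; pY[i + 1, j + 1] <- names(cand)[k]
    }
  }
  fin <- c(M = M[m + 1, n + 1], X = X[m + 1, n + 1], Y = Y[m + 1, n + 1])
  state <- names(fin)[which.max(fin)]
  score <- max(fin)

  ## traceback: build the new column sequence from the end
  prof_cols <- integer(0)  # 0 = gap column
  b_out <- character(0)
  i <- m; j <- n
  while (i > 0 || j > 0) {
    if (state == "M") {
      prof_cols <- c(i, prof_cols); b_out <- c(b[j], b_out)
      state <- pM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == "X") {
      prof_cols <- c(i, prof_cols); b_out <- c("-", b_out)
      state <- pX[i + 1, j + 1]; i <- i - 1
    } else {
      prof_cols <- c(0L, prof_cols); b_out <- c(b[j], b_out)
      state <- pY[i + 1, j + 1]; j <- j - 1
    }
  }
  newprof <- matrix("-", nrow(profile), length(prof_cols))
  keep <- prof_cols > 0
  newprof[, keep] <- profile[, prof_cols[keep], drop = FALSE]
  list(profile = rbind(newprof, b_out), score = score)
}

#' Progressive global multiple sequence alignment
#'
#' Aligns sequences progressively in input order: each sequence is aligned
#' to the growing profile with an affine-gap (Gotoh) global dynamic
#' program.  A gap of length L costs `gap_open + L * gap_extend`; profile
#' columns score against a residue by the mean substitution score over the
#' column's non-gap residues.
#'
#' @param records data frame with columns `id`, `label`, `seq`, or a
#'   character vector of sequences.
#' @param substitution substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return object of class `fc_alignment`: list with `id`, `label`, `aln`
#'   (equal-length gapped sequences) and `score` (sum of progressive
#'   alignment scores).
#' @export
align_sequences <- function(records, substitution = NULL, gap_open = 10,
                            gap_extend = 0.5) {
  if (is.character(records))
    records <- data.frame(id = paste0("seq", seq_along(records)),
                          label = "", seq = records, stringsAsFactors = FALSE)
  if (!nrow(records)) stop("no sequences to align")
  if (!all(is.finite(c(gap_open, gap_extend))))
    stop("gap penalties must be finite")
  if (is.null(substitution)) substitution <- blosum62()
  seqs <- lapply(records$seq, function(s) strsplit(toupper(s), "")[[1]])
  for (k in seq_along(seqs)) {
    bad <- which(!(seqs[[k]] %in% aa_alphabet()))
    if (length(bad))
      stop(sprintf("non-amino-acid character '%s' at position %d of sequence '%s'",
                   seqs[[k]][bad[1]], bad[1], records$id[k]))
    if (!length(seqs[[k]])) stop("empty sequence '", records$id[k], "'")
  }
  profile <- matrix(seqs[[1]], nrow = 1)
  total <- 0
  if (length(seqs) > 1) {
    for (k in 2:length(seqs)) {
      res <- gotoh_align(profile, seqs[[k]], substitution,
                         gap_open, gap_extend)
      profile <- res$profile
      total <- total + res$score
    }
  }
  structure(list(id = records$id, label = records$label,
                 aln = unname(apply(profile, 1, paste, collapse = "")),
                 score = total),
            class = "fc_alignment")
}

#' @export
print.fc_alignment <- function(x, ...) {
  cat(sprintf("fc_alignment: %d sequences, width %d\n",
              length(x$aln), nchar(x$aln[1])))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param alignment an `fc_alignment`, character matrix, or character
#'   vector of equal-length gapped sequences.
#' @return character matrix (rows = sequences, columns = alignment
#'   columns).
#' @export
alignment_matrix <- function(alignment) {
  if (inherits(alignment, "fc_alignment")) alignment <- alignment$aln
  if (is.matrix(alignment)) return(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("aligned sequences must have equal length")
  do.call(rbind, strsplit(alignment, ""))
}

#' Per-position conservation profile of an alignment
#'
#' For each profiled column, records the set of residues observed (gaps are
#' counted separately and never listed as variants) and flags the column
#' conserved when exactly one residue is observed.
#'
#' @param alignment an `fc_alignment` (or gapped sequence vector/matrix).
#' @param map optional [load_base_position_map()]-style map restricting the
#'   profile to the base positions and annotating them with PDB numbers.
#' @param columns optional integer vector of alignment columns to profile
#'   (parallel to `map` rows if both given).  Without `columns`, an
#'   alignment whose width equals `nrow(map)` is profiled column-by-column;
#'   otherwise supply `first_resno` to resolve the map's PDB numbers
#'   against ungapped positions of the first row.
#' @param first_resno residue number of the first (ungapped) position of
#'   the first alignment row.
#' @return data frame of class `fc_conservation` with columns `column`,
#'   `pdb` (if mapped), `variants`, `n_variants`, `n_gaps`, `conserved`;
#'   attributes `conserved_count` and `variable_count`.
#' @export
conservation_profile <- function(alignment, map = NULL, columns = NULL,
                                 first_resno = NULL) {
  aln <- alignment_matrix(alignment)
  width <- ncol(aln)
  pdb <- NA_integer_
  if (is.null(columns)) {
    if (is.null(map)) {
      columns <- seq_len(width)
    } else if (width == nrow(map)) {
      columns <- seq_len(width)
    } else if (!is.null(first_resno)) {
      ungapped <- which(aln[1, ] != "-")
      offs <- map$pdb - first_resno + 1L
      if (any(offs < 1 | offs > length(ungapped)))
        stop("mapped position outside the alignment")
      columns <- ungapped[offs]
    } else {
      stop("cannot resolve map positions: supply `columns` or `first_resno`")
    }
  }
  if (any(columns < 1 | columns > width))
    stop("profiled column outside the alignment")
  if (!is.null(map)) pdb <- map$pdb
  rows <- lapply(seq_along(columns), function(k) {
    col <- aln[, columns[k]]
    vars <- sort(unique(col[col != "-"]))
    data.frame(column = columns[k],
               pdb = if (!is.null(map)) map$pdb[k] else NA_integer_,
               variants = paste(vars, collapse = "/"),
               n_variants = length(vars),
               n_gaps = sum(col == "-"),
               conserved = length(vars) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "conserved_count") <- sum(out$conserved)
  attr(out, "variable_count") <- sum(!out$conserved)
  class(out) <- c("fc_conservation", "data.frame")
  out
}

#' @export
print.fc_conservation <- function(x, ...) {
  cat(sprintf("conservation profile: %d positions, %d conserved, %d variable\n",
              nrow(x), attr(x, "conserved_count"),
              attr(x, "variable_count")))
  print.data.frame(x)
  invisible(x)
}
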