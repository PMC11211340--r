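## Independent brute-force oracles used across the suite.  These stay free
## of the package's own code paths: plain loops, exhaustive enumeration,
## and bio3d's least-squares fit as the second route for superposition.

## exhaustive affine-gap global alignment score: enumerate every monotone
## alignment path; a gap run of length L costs open + L * ext
brute_align_score <- function(a, b, S, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, score + S[a[i], b[j]], "M")
    if (i <= length(a))
      rec(i + 1, j, score - ext - if (prev == "X") 0 else open, "X")
    if (j <= length(b))
      rec(i, j + 1, score - ext - if (prev == "Y") 0 else open, "Y")
  }
  rec(1, 1, 0, "S")
  best
}

## alignment score of an fc_alignment with the same affine convention,
## summed over row pairs is not needed; for 2 rows score the single pair
score_pairwise_alignment <- function(row_a, row_b, S, open, ext) {
  a <- strsplit(row_a, "")[[1]]; b <- strsplit(row_b, "")[[1]]
  score <- 0; run_a <- FALSE; run_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      score <- score + S[a[k], b[k]]; run_a <- run_b <- FALSE
    } else if (a[k] == "-") {
      score <- score - ext - if (run_a) 0 else open
      run_a <- TRUE; run_b <- FALSE
    } else {
      score <- score - ext - if (run_b) 0 else open
      run_b <- TRUE; run_a <- FALSE
    }
  }
  score
}

euler_rotation <- function(ang) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(ang[1]) %*% ry(ang[2]) %*% rz(ang[3])
}

## rotation-grid + local-refinement oracle for the minimal RMSD over
## proper rigid transforms (translations optimal at the centroids)
grid_min_rmsd <- function(P, Q, coarse_deg = 10) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(ang) {
    R <- euler_rotation(ang)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  step <- coarse_deg * pi / 180
  g1 <- seq(0, 2 * pi - step, by = step)
  g2 <- seq(0, pi, by = step)
  best <- Inf; bang <- c(0, 0, 0)
  for (a1 in g1) for (a2 in g2) for (a3 in g1) {
    v <- f(c(a1, a2, a3))
    if (v < best) { best <- v; bang <- c(a1, a2, a3) }
  }
  opt <- stats::optim(bang, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

## per-frame minimum cross distance by explicit double loop
brute_min_sep <- function(traj, a, b) {
  vapply(seq_len(dim(traj$coords)[3]), function(k) {
    m <- Inf
    for (i in a) for (j in b) {
      d <- sqrt(sum((traj$coords[i, , k] - traj$coords[j, , k])^2))
      if (d < m) m <- d
    }
    m
  }, numeric(1))
}

## independent superposition route: bio3d least-squares fit
bio3d_fit_frame <- function(mobile, reference) {
  inds <- seq_len(3 * nrow(reference))
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(reference)),
                        mobile = matrix(as.numeric(t(mobile)), nrow = 1),
                        fixed.inds = inds, mobile.inds = inds)
  matrix(fit[1, ], ncol = 3, byrow = TRUE)
}

brute_rmsd_series <- function(traj, idx, reference = 1) {
  ref <- traj$coords[idx, , reference]
  vapply(seq_len(dim(traj$coords)[3]), function(k) {
    moved <- bio3d_fit_frame(traj$coords[idx, , k], ref)
    s <- 0
    for (i in seq_len(nrow(ref))) s <- s + sum((moved[i, ] - ref[i, ])^2)
    sqrt(s / nrow(ref))
  }, numeric(1))
}

brute_rmsf <- function(traj, idx, frames = seq_len(dim(traj$coords)[3])) {
  ref <- traj$coords[idx, , frames[1]]
  aligned <- lapply(frames, function(k)
    bio3d_fit_frame(traj$coords[idx, , k], ref))
  mean_pos <- Reduce(`+`, aligned) / length(aligned)
  key <- paste(traj$atoms$chain[idx], traj$atoms$resno[idx])
  out <- numeric(0)
  for (k2 in unique(key)) {
    sel <- which(key == k2)
    acc <- 0
    for (fr in aligned) {
      s <- 0
      for (i in sel) s <- s + sum((fr[i, ] - mean_pos[i, ])^2)
      acc <- acc + s / length(sel)
    }
    out <- c(out, sqrt(acc / length(aligned)))
  }
  out
}

## independent fcc enumeration: all points (i,j,k) * a/2 with i+j+k even
fcc_count_oracle <- function(diameter_nm, a) {
  r <- diameter_nm * 10 / 2
  nmax <- ceiling(2 * r / a) + 1L
  g <- expand.grid(i = -nmax:nmax, j = -nmax:nmax, k = -nmax:nmax)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]
  pos <- as.matrix(g) * a / 2
  sum(rowSums(pos^2) <= r^2 + 1e-9)
}

random_rotation <- function() {
  euler_rotation(c(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi)))
}
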