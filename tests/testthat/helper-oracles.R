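# Independent oracles used by the unit and acceptance tests. These never call
# the code paths they check.

# Affine-gap global alignment score by Gotoh dynamic programming.
# Gap of length L costs open + L * ext (both <= 0), matching align_global().
nw_score_oracle <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # last pair aligned
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a residue vs gap)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + i * ext
  for (j in seq_len(m)) Y[1, j + 1] <- open + j * ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, Y[i + 1, j] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every global alignment (move sequences), scoring
# maximal gap runs as open + len * ext. Only feasible for very short strings;
# used to validate the Gotoh oracle itself at tiny n.
nw_enumerate_oracle <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last_move, run_open) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + mat[av[i], bv[j]], "d", FALSE)
    }
    if (i <= length(av)) {
      extra <- if (identical(last_move, "x")) ext else open + ext
      rec(i + 1, j, score + extra, "x", TRUE)
    }
    if (j <= length(bv)) {
      extra <- if (identical(last_move, "y")) ext else open + ext
      rec(i, j + 1, score + extra, "y", TRUE)
    }
  }
  rec(1, 1, 0, "", FALSE)
  best
}

random_aa_string <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# Numerical brute-force rigid-fit oracle: minimize RMSD of Q onto P over
# Euler angles + translation with multi-start BFGS. Independent of the
# closed-form SVD route.
euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

rigid_fit_oracle <- function(P, Q, n_restarts = 30) {
  msd <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    D <- P - sweep(Q %*% t(R), 2, p[4:6], `+`)
    mean(rowSums(D^2))
  }
  best <- Inf
  starts <- c(list(rep(0, 6)),
              lapply(seq_len(n_restarts - 1), function(i) {
                c(runif(3, -pi, pi), colMeans(P) - colMeans(Q) +
                    rnorm(3, sd = 5))
              }))
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, msd, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit)) best <- min(best, fit$value)
  }
  sqrt(best)
}

random_proper_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Hand-built minimal structures for parser-independent geometry tests.
tiny_structure <- function(coords, resno = seq_len(nrow(coords)),
                           chain = "A", aa = "A", atom = "CA", id = "tiny") {
  dicerruler:::new_structure(tibble::tibble(
    chain = chain, resno = as.integer(resno), ins = "", aa = aa,
    atom = atom, elem = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], o = 1, b = 0), id = id)
}

tiny_sites <- function(id, site, resno, chain = "A", aa = "A",
                       resolved = TRUE) {
  n <- max(length(site), length(resno))
  resolved <- rep_len(resolved, n)
  resno <- rep_len(as.integer(resno), n)
  resno[!resolved] <- NA_integer_
  dicerruler:::new_site_map(tibble::tibble(
    structure_id = id, site = rep_len(site, n), chain = chain,
    resno = resno, expected_aa = rep_len(aa, n), resolved = resolved))
}
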