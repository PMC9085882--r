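# Internal numerical helpers shared across modules.

# Symmetrize a square matrix (guards against round-off asymmetry).
symmetrize <- function(M) (M + t(M)) / 2

is_symmetric <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# Eigenvalue floor used when inverting covariance matrices.  Eigenvalues
# below the floor are clamped (with a warning) so that near-singular P
# matrices produced by round-off do not abort a long integration.
.EIG_FLOOR <- 1e-12

# Symmetric eigendecomposition-based inverse with eigenvalue clamping.
solve_psd <- function(M, floor = .EIG_FLOOR, warn = TRUE) {
  if (length(M) == 1L) {
    m <- as.numeric(M)
    if (m < floor) {
      if (warn) warning("covariance eigenvalue below ", floor, "; clamped")
      m <- floor
    }
    return(matrix(1 / m, 1L, 1L))
  }
  e <- eigen(symmetrize(M), symmetric = TRUE)
  v <- e$values
  if (any(v < floor)) {
    if (warn) warning("covariance eigenvalue below ", floor, "; clamped")
    v <- pmax(v, floor)
  }
  e$vectors %*% (t(e$vectors) / v)
}

# Log-determinant of a symmetric positive (semi)definite matrix, with the
# same eigenvalue floor as solve_psd.
logdet_psd <- function(M, floor = .EIG_FLOOR) {
  if (length(M) == 1L) return(log(max(as.numeric(M), floor)))
  sum(log(pmax(eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values,
               floor)))
}

# Project a symmetric matrix onto the PSD cone.  Eigenvalues in
# (-tol, 0) are clamped to 0; anything more negative is a genuine
# violation and raises an error.
psd_project <- function(M, tol = 1e-8) {
  if (length(M) == 1L) {
    m <- as.numeric(M)
    if (m < -tol) stop("matrix eigenvalue ", m, " below -", tol, "; not PSD")
    return(matrix(max(m, 0), 1L, 1L))
  }
  e <- eigen(symmetrize(M), symmetric = TRUE)
  if (any(e$values < -tol))
    stop("matrix eigenvalue ", min(e$values), " below -", tol, "; not PSD")
  symmetrize(e$vectors %*% (pmax(e$values, 0) * t(e$vectors)))
}

min_eigen <- function(M) {
  if (length(M) == 1L) return(as.numeric(M))
  min(eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values)
}

# Multivariate normal density evaluated at the rows of X (n x L matrix).
dmvn <- function(X, mean, cov) {
  X <- as.matrix(X)
  L <- ncol(X)
  R <- chol(symmetrize(as.matrix(cov)))
  q <- backsolve(R, t(X) - mean, transpose = TRUE)
  exp(-0.5 * colSums(q^2) - sum(log(diag(R))) - 0.5 * L * log(2 * pi))
}

# Draw a Haar-uniform random orthogonal matrix (QR of a Gaussian matrix
# with the sign convention that makes the distribution exactly uniform).
rhaar_orthogonal <- function(L) {
  if (L == 1L) return(matrix(sample(c(-1, 1), 1L), 1L, 1L))
  qr_ <- qr(matrix(stats::rnorm(L * L), L, L))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q %*% diag(d, L)
}

# Deterministic, order-independent per-run seed stream: maps a master seed
# and a run counter to a 31-bit seed (R set.seed() takes 32-bit integers).
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + as.double(index) * 1013904223) %%
               2147483647)
}
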