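# Independent numerical oracles used across the test files.
#
# The 1-D resource-utilization machinery is integrated by adaptive
# quadrature directly from its defining integrals (never via the
# package's closed forms); 2-D checks use pracma::integral2 and Monte
# Carlo. These anchor the correctness of every closed-form Gaussian
# reduction in the package.

# Resource utilization function u(z, y) and saturation concentration
# R0(y) in one dimension: W = omega^2/4, normalization (pi omega^2)^(1/4).
u_fn <- function(z, y, omega) {
  (pi * omega^2)^(1 / 4) * stats::dnorm(z, y, omega / 2)
}
R0_fn <- function(omega) (pi * omega^2)^(-1 / 4)

# Resource intake of phenotype z: integral of u(z, y) R0(y) over y.
intake_quad <- function(z, omega) {
  stats::integrate(function(y) u_fn(z, y, omega) * R0_fn(omega),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Competition kernel between fixed phenotypes z and zp: the overlap
# integral of their utilization functions.
kernel_quad <- function(z, zp, omega) {
  stats::integrate(function(y) u_fn(z, y, omega) * u_fn(zp, y, omega),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Kernel smoothed over a 1-D Gaussian phenotype distribution N(mu, P):
# double integral over resources y and phenotypes z'.
smoothed_kernel_quad <- function(z, mu, P, omega) {
  inner <- Vectorize(function(zp) kernel_quad(z, zp, omega))
  s <- sqrt(P)
  stats::integrate(function(zp) inner(zp) * stats::dnorm(zp, mu, s),
                   mu - 10 * s, mu + 10 * s, rel.tol = 1e-9)$value
}

# Species-pair competition coefficient by double quadrature.
pairwise_quad <- function(mu_a, Pa, mu_b, Pb, omega) {
  sa <- sqrt(Pa)
  outer_f <- Vectorize(function(z) {
    if (Pb == 0) kernel_quad(z, mu_b, omega)
    else smoothed_kernel_quad(z, mu_b, Pb, omega)
  })
  if (Pa == 0) return(outer_f(mu_a))
  stats::integrate(function(z) outer_f(z) * stats::dnorm(z, mu_a, sa),
                   mu_a - 10 * sa, mu_a + 10 * sa, rel.tol = 1e-8)$value
}

# Fitness landscape r(z) assembled from quadrature pieces only (1-D).
r_quad <- function(comm, z) {
  p <- comm$params
  r <- intake_quad(z, p$omega) - mortality(p, z)
  for (sp in comm$species) {
    P <- as.numeric(sp$G + sp$E)
    r <- r - sp$N * smoothed_kernel_quad(z, sp$mu, P, p$omega)
  }
  r
}

# The three fitness moments by adaptive quadrature (1-D), with r(z)
# evaluated through the package's fitness_landscape (itself checked
# against r_quad at sample points).
moments_quad <- function(comm, i, rel.tol = 1e-10) {
  sp <- comm$species[[i]]
  P <- as.numeric(sp$G + sp$E)
  s <- sqrt(P)
  mu <- sp$mu
  rfun <- function(z) vapply(z, function(zz) fitness_landscape(comm, zz),
                             numeric(1))
  qi <- function(f) stats::integrate(f, mu - 12 * s, mu + 12 * s,
                                     rel.tol = rel.tol,
                                     abs.tol = 1e-12)$value
  m0 <- qi(function(z) rfun(z) * stats::dnorm(z, mu, s))
  m1 <- qi(function(z) (z - mu) * rfun(z) * stats::dnorm(z, mu, s))
  M2 <- qi(function(z) 0.5 * ((z - mu)^2 - P) * rfun(z) *
             stats::dnorm(z, mu, s))
  list(m0 = m0, m1 = m1, M2 = M2)
}

# Vectorized multivariate normal density for the Monte Carlo oracle
# (independent of the package's internal helper).
oracle_dmvn <- function(X, mean, cov) {
  L <- ncol(X)
  R <- chol(cov)
  q <- backsolve(R, t(X) - mean, transpose = TRUE)
  exp(-0.5 * colSums(q^2)) / ((2 * pi)^(L / 2) * prod(diag(R)))
}

# r(z) at the rows of Z (n x L), assembled independently from the model
# definition: intake 1, mortality, and the density-smoothed Gaussian
# kernel written out directly.
r_direct <- function(comm, Z) {
  p <- comm$params
  L <- p$L
  zz <- rowSums(Z^2)
  m <- if (p$mortality_shape == "quadratic") zz / p$theta^2
       else zz^2 / p$theta^4
  r <- 1 - m
  for (sp in comm$species) {
    A <- diag(p$omega^2 / 2, L) + sp$G + sp$E
    k <- sqrt((p$omega^2 / 2)^L / det(A)) *
      oracle_dmvn(Z, sp$mu, A) * sqrt((2 * pi)^L * det(A))
    r <- r - sp$N * k
  }
  r
}

# Monte Carlo fitness moments for L >= 2: sample z ~ N(mu_i, P_i),
# average r and its centered products; returns estimates and standard
# errors.
moments_mc <- function(comm, i, n = 1e5) {
  sp <- comm$species[[i]]
  L <- comm$params$L
  P <- sp$G + sp$E
  X <- matrix(stats::rnorm(n * L), n, L) %*% chol(P)
  Z <- sweep(X, 2, sp$mu, "+")
  r <- r_direct(comm, Z)
  se <- function(v) stats::sd(v) / sqrt(n)
  m1_hat <- colMeans(X * r)
  m1_se <- apply(X * r, 2, se)
  ut <- which(upper.tri(diag(L), diag = TRUE))
  M2s <- matrix(0, n, length(ut))
  for (k in seq_along(ut)) {
    a <- ((ut[k] - 1) %% L) + 1
    b <- ((ut[k] - 1) %/% L) + 1
    M2s[, k] <- 0.5 * (X[, a] * X[, b] - P[a, b]) * r
  }
  list(m0 = mean(r), m0_se = se(r),
       m1 = m1_hat, m1_se = m1_se,
       M2 = colMeans(M2s), M2_se = apply(M2s, 2, se), ut = ut)
}

# Random valid community builder shared by the property tests.
rand_community <- function(S, L = 1, omega = NULL,
                           shape = c("quadratic", "quartic")) {
  shape <- if (length(shape) > 1) sample(shape, 1) else shape
  if (is.null(omega)) omega <- stats::runif(1, 0.08, 0.45)
  params <- model_params(L = L, omega = omega, mortality_shape = shape)
  species <- lapply(seq_len(S), function(i) {
    A <- matrix(stats::rnorm(L * L, sd = 0.1), L, L)
    G <- crossprod(A) + diag(stats::runif(L, 0, 0.02), L)
    species_state(N = stats::runif(1, 0.05, 2),
                  mu = stats::runif(L, -0.6, 0.6),
                  G = G,
                  E = diag(stats::runif(L, 0.004, 0.03), L))
  })
  community(params, species)
}
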