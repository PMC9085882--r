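#' Model parameters for the competition-in-trait-space model
#'
#' Bundles the global constants of the fitness landscape: the dimensionality
#' of trait space, the Gaussian competition width, the resource-utilization
#' covariance, and the intrinsic mortality function.
#'
#' Each phenotype `z` (a point in L-dimensional trait space) consumes
#' resources through a Gaussian utilization function with covariance
#' `W = (omega^2/4) I`, competes with other phenotypes through the kernel
#' `exp(-|z - z'|^2 / omega^2)`, and suffers intrinsic mortality
#' `m(z) = (z.z)/theta^2` (quadratic) or `(z.z)^2/theta^4` (quartic).
#' The resource supply is tuned so that the per-capita resource intake of
#' every phenotype equals 1, so the intrinsic growth rate is `1 - m(z)`.
#'
#' @param L Integer dimensionality of trait space (>= 1).
#' @param omega Competition width \eqn{\omega > 0}, in trait units.
#' @param theta Mortality scale \eqn{\theta > 0}, in trait units
#'   (default 1/2).
#' @param mortality_shape `"quadratic"` or `"quartic"`.
#'
#' @return An object of class `eed_params` with fields `L`, `omega`,
#'   `theta`, `mortality_shape` and the derived utilization covariance `W`.
#' @examples
#' p <- model_params(L = 1, omega = 0.1)
#' mortality(p, 0.5)         # equals 1 at |z| = theta
#' competition_kernel(p, 0.1) # equals exp(-1) at |d| = omega
#' @export
model_params <- function(L = 1L, omega, theta = 0.5,
                         mortality_shape = c("quadratic", "quartic")) {
  mortality_shape <- match.arg(mortality_shape)
  L <- as.integer(L)
  stopifnot(length(L) == 1L, L >= 1L,
            length(omega) == 1L, is.finite(omega), omega > 0,
            length(theta) == 1L, is.finite(theta), theta > 0)
  structure(list(L = L, omega = as.numeric(omega), theta = as.numeric(theta),
                 mortality_shape = mortality_shape,
                 W = diag(omega^2 / 4, L)),
            class = "eed_params")
}

#' @export
print.eed_params <- function(x, ...) {
  cat("Model parameters: L =", x$L, ", omega =", x$omega,
      ", theta =", x$theta, ",", x$mortality_shape, "mortality\n")
  invisible(x)
}

#' One species' state: density, trait mean and covariance components
#'
#' A species is described by its population density `N`, trait mean vector
#' `mu`, genetic covariance matrix `G` and environmental covariance matrix
#' `E`. Its phenotype distribution is multivariate normal with mean `mu`
#' and total phenotypic covariance `P = G + E`; `G` is the heritable part
#' that responds to selection, `E` the non-heritable part.
#'
#' @param N Nonnegative population density.
#' @param mu Trait mean vector (length L).
#' @param G L x L symmetric positive semidefinite genetic covariance. A
#'   scalar is interpreted as `G * I`.
#' @param E L x L symmetric positive semidefinite environmental
#'   covariance. A scalar is interpreted as `E * I`. Dynamics require a
#'   positive definite `E` (so `P` stays invertible); the semidefinite
#'   case is allowed for static quantities with a finite point-phenotype
#'   limit, such as [pairwise_competition()].
#'
#' @return An object of class `eed_species`.
#' @examples
#' species_state(N = 1, mu = 0, G = 0.02, E = 0.005)
#' @export
species_state <- function(N, mu, G, E) {
  mu <- as.numeric(mu)
  L <- length(mu)
  if (length(G) == 1L) G <- diag(as.numeric(G), L)
  if (length(E) == 1L) E <- diag(as.numeric(E), L)
  G <- as.matrix(G); E <- as.matrix(E)
  stopifnot(length(N) == 1L, is.finite(N), N >= 0,
            all(is.finite(mu)), all(dim(G) == L), all(dim(E) == L))
  if (!is_symmetric(G) || !is_symmetric(E))
    stop("G and E must be symmetric ", L, " x ", L, " matrices")
  if (min_eigen(G) < -1e-10)
    stop("G must be positive semidefinite")
  if (min_eigen(E) < -1e-10)
    stop("E must be positive semidefinite (minimum eigenvalue ",
         format(min_eigen(E)), ")")
  structure(list(N = as.numeric(N), mu = mu, G = symmetrize(G),
                 E = symmetrize(E)),
            class = "eed_species")
}

#' Total phenotypic covariance P = G + E of a species
#' @param species An `eed_species` object.
#' @return The L x L phenotypic covariance matrix.
#' @export
phenotypic_cov <- function(species) species$G + species$E

#' @export
print.eed_species <- function(x, ...) {
  cat("Species: N =", format(x$N, digits = 4),
      " mu = (", paste(format(x$mu, digits = 4), collapse = ", "), ")",
      " tr(G) =", format(sum(diag(x$G)), digits = 4),
      " tr(E) =", format(sum(diag(x$E)), digits = 4), "\n")
  invisible(x)
}

#' A community: shared parameters plus an ordered set of species
#'
#' @param params An `eed_params` object.
#' @param species A list of `eed_species` objects (possibly empty), all of
#'   the same trait dimensionality as `params$L`. Species identity is the
#'   list position, which is stable across the dynamics (species are never
#'   removed, only tagged as extinct by a density threshold).
#'
#' @return An object of class `eed_community`.
#' @examples
#' p <- model_params(L = 1, omega = 0.15)
#' comm <- community(p, list(
#'   species_state(1, -0.2, 0.02, 0.006),
#'   species_state(1,  0.2, 0.02, 0.006)))
#' fitness_landscape(comm, 0)
#' @export
community <- function(params, species = list()) {
  stopifnot(inherits(params, "eed_params"), is.list(species))
  for (sp in species) {
    if (!inherits(sp, "eed_species"))
      stop("all community members must be eed_species objects")
    if (length(sp$mu) != params$L)
      stop("species trait dimension ", length(sp$mu),
           " does not match params$L = ", params$L)
  }
  structure(list(params = params, species = species),
            class = "eed_community")
}

#' Number of species in a community
#' @param comm An `eed_community`.
#' @return Integer species count.
#' @export
n_species <- function(comm) length(comm$species)

#' Densities, relative frequencies and trait means of a community
#'
#' @param comm An `eed_community`.
#' @return `densities()` returns the vector of population densities;
#'   `rel_frequencies()` the relative frequencies `f_i = N_i / sum(N)`;
#'   `trait_means()` an S x L matrix of trait means.
#' @export
densities <- function(comm) vapply(comm$species, `[[`, numeric(1), "N")

#' @rdname densities
#' @export
rel_frequencies <- function(comm) {
  N <- densities(comm)
  tot <- sum(N)
  if (tot <= 0) stop("community has zero total density")
  N / tot
}

#' @rdname densities
#' @export
trait_means <- function(comm) {
  S <- n_species(comm)
  matrix(unlist(lapply(comm$species, `[[`, "mu")), nrow = S,
         ncol = comm$params$L, byrow = TRUE)
}

#' @export
print.eed_community <- function(x, ...) {
  cat("Community of", n_species(x), "species in", x$params$L,
      "trait dimension(s); omega =", x$params$omega, "\n")
  if (n_species(x) > 0) {
    N <- densities(x)
    cat("  total density", format(sum(N), digits = 4),
        "; density range [", format(min(N), digits = 3), ",",
        format(max(N), digits = 3), "]\n")
  }
  invisible(x)
}

.check_z <- function(params, z) {
  z <- as.numeric(z)
  if (length(z) != params$L)
    stop("trait vector has length ", length(z), "; expected L = ", params$L)
  z
}

#' Intrinsic mortality rate of a phenotype
#'
#' `m(z) = (z.z)/theta^2` (quadratic) or `(z.z)^2/theta^4` (quartic), an
#' increasing function of distance from the trait-space origin, where
#' resources are most abundant.
#'
#' @param params An `eed_params` object.
#' @param z Trait vector of length `params$L`.
#' @return Nonnegative mortality rate.
#' @export
mortality <- function(params, z) {
  z <- .check_z(params, z)
  zz <- sum(z^2)
  if (params$mortality_shape == "quadratic") zz / params$theta^2
  else zz^2 / params$theta^4
}

#' Intrinsic per-capita growth rate of a phenotype (no competition)
#'
#' Equals `1 - m(z)`: with the resource supply scaled as in this model, the
#' resource-intake integral of every phenotype is identically 1 (the
#' utilization function and the saturation resource concentration are
#' mutually normalized), so growth in an empty community is intake minus
#' mortality. Positive inside a ball of radius `theta` around the origin
#' (quadratic and quartic mortality alike), negative outside.
#'
#' @inheritParams mortality
#' @return Growth rate, at most 1, with equality only at `z = 0`.
#' @export
intrinsic_growth <- function(params, z) 1 - mortality(params, z)

#' Gaussian competition kernel between two phenotypes
#'
#' The competitive effect of one phenotype on another separated by trait
#' displacement `d`: the overlap integral of their resource utilization
#' functions, which reduces to `exp(-|d|^2 / omega^2)`.
#'
#' @param params An `eed_params` object.
#' @param d Trait displacement vector (length L).
#' @return Kernel value in (0, 1]; 1 iff `d = 0`.
#' @export
competition_kernel <- function(params, d) {
  d <- .check_z(params, d)
  exp(-sum(d^2) / params$omega^2)
}

#' Competition coefficient between two species
#'
#' The competition kernel averaged over both species' phenotype
#' distributions: a Gaussian convolution with closed form
#' \deqn{\alpha_{ab} = \sqrt{\det(2W)/\det(C)} \exp(-\tfrac12 \Delta\mu^T
#' C^{-1} \Delta\mu), \quad C = 2W + P_a + P_b.}
#' In one dimension this is
#' \eqn{\omega/\sqrt{\omega^2 + 2P_a + 2P_b}\,
#' \exp(-\Delta\mu^2/(\omega^2 + 2P_a + 2P_b))}.
#'
#' @param params An `eed_params` object.
#' @param a,b `eed_species` objects (their `G + E` may be positive
#'   semidefinite; a zero matrix is the point-phenotype limit).
#' @return Symmetric coefficient in (0, 1], decreasing in mean separation
#'   and in total phenotypic variance.
#' @export
pairwise_competition <- function(params, a, b) {
  Pa <- a$G + a$E; Pb <- b$G + b$E
  if (min_eigen(Pa) < -1e-10 || min_eigen(Pb) < -1e-10)
    stop("phenotypic covariances must be positive semidefinite")
  L <- params$L
  C <- diag(params$omega^2 / 2, L) + Pa + Pb
  d <- a$mu - b$mu
  ld2W <- L * log(params$omega^2 / 2)
  exp(0.5 * (ld2W - logdet_psd(C)) -
        0.5 * drop(crossprod(d, solve_psd(C, warn = FALSE) %*% d)))
}

# Density-smoothed kernel of species j evaluated at phenotype z:
# int kernel(z - z') p_j(z') dz'  =  sqrt(det(2W)/det(2W + P_j)) *
# exp(-1/2 (z - mu_j)' (2W + P_j)^{-1} (z - mu_j)).
.smoothed_kernel <- function(params, z, mu_j, P_j) {
  L <- params$L
  A <- diag(params$omega^2 / 2, L) + P_j
  d <- z - mu_j
  exp(0.5 * (L * log(params$omega^2 / 2) - logdet_psd(A)) -
        0.5 * drop(crossprod(d, solve_psd(A, warn = FALSE) %*% d)))
}

#' Per-capita fitness landscape over phenotypes
#'
#' The growth rate `r(z)` of a phenotype `z` irrespective of species
#' identity, given the current community:
#' `r(z) = 1 - m(z) - sum_j N_j <kernel>_j(z)`, where `<kernel>_j(z)` is
#' the competition kernel smoothed over species j's phenotype distribution
#' (closed Gaussian form). An empty community gives the intrinsic growth
#' rate.
#'
#' @param comm An `eed_community`.
#' @param z Trait vector of length L.
#' @return The per-capita growth rate (any real number).
#' @export
fitness_landscape <- function(comm, z) {
  params <- comm$params
  z <- .check_z(params, z)
  r <- intrinsic_growth(params, z)
  for (sp in comm$species)
    r <- r - sp$N * .smoothed_kernel(params, z, sp$mu, sp$G + sp$E)
  r
}

# Gaussian expectations of the mortality function under N(mu, P):
# returns E[m], E[x m] and E[x x' m] with x = z - mu.
.mortality_moments <- function(params, mu, P) {
  th2 <- params$theta^2
  trP <- sum(diag(P))
  mumu <- sum(mu^2)
  if (params$mortality_shape == "quadratic") {
    Em <- (mumu + trP) / th2
    Em1 <- 2 * drop(P %*% mu) / th2
    Exxm <- (mumu * P + trP * P + 2 * P %*% P) / th2
  } else {
    th4 <- th2^2
    Pmu <- drop(P %*% mu)
    P2 <- P %*% P
    muPmu <- sum(mu * Pmu)
    trP2 <- sum(P * P)
    Em <- ((trP + mumu)^2 + 2 * trP2 + 4 * muPmu) / th4
    Em1 <- (4 * (mumu + trP) * Pmu + 8 * drop(P2 %*% mu)) / th4
    Exxm <- (mumu^2 * P + 4 * muPmu * P + 8 * tcrossprod(Pmu) +
               2 * mumu * (trP * P + 2 * P2) +
               (trP^2 + 2 * trP2) * P + 4 * trP * P2 + 8 * P2 %*% P) / th4
  }
  list(Em = Em, Em1 = Em1, Exxm = Exxm)
}

#' Fitness moments of a focal species
#'
#' The three integrals that drive the dynamics — the mean fitness
#' `m0 = E[r(z)]`, the selection differential `m1 = E[(z - mu) r(z)]`, and
#' the (co)variance selection term
#' `M2 = (1/2) E[((z - mu)(z - mu)' - P) r(z)]` — all taken over the focal
#' species' phenotype distribution and evaluated in closed Gaussian form.
#'
#' @param comm An `eed_community`.
#' @param i Index of the focal species.
#' @return A list with components `m0` (scalar), `m1` (length-L vector)
#'   and `M2` (L x L symmetric matrix).
#' @export
fitness_moments <- function(comm, i) {
  params <- comm$params
  S <- n_species(comm)
  if (i < 1L || i > S) stop("species index ", i, " out of range 1..", S)
  sp <- comm$species[[i]]
  P <- sp$G + sp$E
  if (min_eigen(P) <= .EIG_FLOOR)
    stop("phenotypic covariance P of species ", i, " is singular; ",
         "ensure E has eigenvalues above ", .EIG_FLOOR)
  mm <- .mortality_moments(params, sp$mu, P)
  m0 <- 1 - mm$Em
  m1 <- -mm$Em1
  M2 <- -0.5 * (mm$Exxm - P * mm$Em)
  L <- params$L
  ld2W <- L * log(params$omega^2 / 2)
  for (j in seq_len(S)) {
    spj <- comm$species[[j]]
    if (spj$N == 0) next
    C <- diag(params$omega^2 / 2, L) + P + spj$G + spj$E
    Cinv <- solve_psd(C, warn = FALSE)
    dmu <- sp$mu - spj$mu
    a <- exp(0.5 * (ld2W - logdet_psd(C)) -
               0.5 * drop(crossprod(dmu, Cinv %*% dmu)))
    d <- -drop(P %*% Cinv %*% dmu)        # posterior mean shift
    Vs <- P - P %*% Cinv %*% P            # posterior covariance
    m0 <- m0 - spj$N * a
    m1 <- m1 - spj$N * a * d
    M2 <- M2 - spj$N * a * 0.5 * (Vs + tcrossprod(d) - P)
  }
  list(m0 = m0, m1 = m1, M2 = symmetrize(M2))
}

#' Read and write communities as JSON
#'
#' Serializes an `eed_community` (or `eed_params`) to JSON with keys `L`,
#' `omega`, `theta`, `mortality_shape` and `species`, the latter an array
#' of objects with keys `N`, `mu`, `G`, `E` (matrices as nested row-major
#' arrays).
#'
#' @param comm An `eed_community`.
#' @param path File path.
#' @return `read_community_json()` returns an `eed_community`;
#'   `write_community_json()` invisibly returns `path`.
#' @export
write_community_json <- function(comm, path) {
  obj <- list(L = comm$params$L, omega = comm$params$omega,
              theta = comm$params$theta,
              mortality_shape = comm$params$mortality_shape,
              species = lapply(comm$species, function(sp)
                list(N = sp$N, mu = sp$mu,
                     G = apply(sp$G, 1L, identity, simplify = FALSE),
                     E = apply(sp$E, 1L, identity, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_community_json
#' @export
read_community_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  params <- model_params(L = obj$L, omega = obj$omega, theta = obj$theta,
                         mortality_shape = obj$mortality_shape)
  L <- params$L
  to_mat <- function(m) matrix(as.numeric(unlist(m)), L, L, byrow = TRUE)
  species <- list()
  if (!is.null(obj$species) && length(obj$species)) {
    if (is.data.frame(obj$species)) {
      species <- lapply(seq_len(nrow(obj$species)), function(k)
        species_state(N = obj$species$N[k],
                      mu = as.numeric(unlist(obj$species$mu[k])),
                      G = to_mat(obj$species$G[k]),
                      E = to_mat(obj$species$E[k])))
    } else {
      species <- lapply(obj$species, function(sp)
        species_state(N = sp$N, mu = as.numeric(unlist(sp$mu)),
                      G = to_mat(sp$G), E = to_mat(sp$E)))
    }
  }
  community(params, species)
}
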