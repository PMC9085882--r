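# Right-hand sides of the coupled density / trait-mean / G-matrix dynamics,
# the ODE driver, and the frozen-covariance null model.

#' Integrator options
#'
#' @param t_end Integration horizon in model time units (default `1e10`,
#'   long enough for eco-evolutionary equilibrium; scaled-down studies
#'   typically use `1e6` together with equilibrium early stopping).
#' @param rel_tol,abs_tol Solver tolerances.
#' @param equilibrium_tol Early-stopping threshold: integration stops once
#'   the max-norm of the full right-hand side falls below this value.
#' @param extinction_threshold Density below which a species is reported
#'   extinct. Species are never removed from the state; the threshold is
#'   bookkeeping only.
#' @param freeze_G If `TRUE`, `dG/dt` is forced to zero (the
#'   frozen-covariance null model): densities and trait means still evolve
#'   but every `G` (hence `P`) keeps its initial value.
#' @param n_snapshots Number of logarithmically spaced output times.
#' @param seed Optional integer recorded with the run (the dynamics are
#'   deterministic; the seed documents how the initial state was drawn).
#' @return An object of class `eed_options`.
#' @export
integrator_options <- function(t_end = 1e10, rel_tol = 1e-8, abs_tol = 1e-10,
                               equilibrium_tol = 1e-10,
                               extinction_threshold = 1e-6,
                               freeze_G = FALSE, n_snapshots = 50L,
                               seed = NULL) {
  stopifnot(t_end > 0, rel_tol > 0, abs_tol > 0, equilibrium_tol > 0,
            extinction_threshold >= 0, n_snapshots >= 2L)
  structure(list(t_end = t_end, rel_tol = rel_tol, abs_tol = abs_tol,
                 equilibrium_tol = equilibrium_tol,
                 extinction_threshold = extinction_threshold,
                 freeze_G = isTRUE(freeze_G),
                 n_snapshots = as.integer(n_snapshots), seed = seed),
            class = "eed_options")
}

# Fitness moments for every species at once, on raw state arrays.
# N: length-S densities; mu: S x L matrix; Pv: for L = 1 a length-S vector
# of phenotypic variances, otherwise a list of S L x L matrices.
# Returns m0 (length S), m1 (S x L), M2 (L = 1: length S; else list).
.community_moments <- function(params, N, mu, Pv) {
  S <- length(N)
  L <- params$L
  Nc <- pmax(N, 0)
  if (L == 1L) {
    mu <- as.numeric(mu)
    P <- as.numeric(Pv)
    th2 <- params$theta^2
    if (params$mortality_shape == "quadratic") {
      Em <- (mu^2 + P) / th2
      Em1 <- 2 * P * mu / th2
      EM2 <- P^2 / th2
    } else {
      th4 <- th2^2
      Em <- ((P + mu^2)^2 + 2 * P^2 + 4 * mu^2 * P) / th4
      Em1 <- (4 * (mu^2 + P) * P * mu + 8 * P^2 * mu) / th4
      Exxm <- (mu^4 * P + 18 * mu^2 * P^2 + 15 * P^3) / th4
      EM2 <- 0.5 * (Exxm - P * Em)
    }
    w2h <- params$omega^2 / 2
    C <- outer(P, P, "+") + w2h          # C_ij = omega^2/2 + P_i + P_j
    D <- outer(mu, mu, "-")              # D_ij = mu_i - mu_j
    A <- sqrt(w2h / C) * exp(-0.5 * D^2 / C)
    Dd <- -(P * D) / C                   # posterior mean shift, row i
    Vs <- P - P^2 / C                    # posterior variance, row i
    m0 <- 1 - Em - drop(A %*% Nc)
    m1 <- -Em1 - drop((A * Dd) %*% Nc)
    M2 <- -EM2 - drop((A * 0.5 * (Vs + Dd^2 - P)) %*% Nc)
    return(list(m0 = m0, m1 = matrix(m1, S, 1L), M2 = M2))
  }
  w2h <- params$omega^2 / 2
  ld2W <- L * log(w2h)
  m0 <- numeric(S)
  m1 <- matrix(0, S, L)
  M2 <- vector("list", S)
  for (i in seq_len(S)) {
    Pi <- Pv[[i]]
    mm <- .mortality_moments(params, mu[i, ], Pi)
    m0i <- 1 - mm$Em
    m1i <- -mm$Em1
    M2i <- -0.5 * (mm$Exxm - Pi * mm$Em)
    for (j in seq_len(S)) {
      if (Nc[j] == 0) next
      C <- Pi + Pv[[j]] + diag(w2h, L)
      Cinv <- solve_psd(C, warn = FALSE)
      dmu <- mu[i, ] - mu[j, ]
      a <- exp(0.5 * (ld2W - logdet_psd(C)) -
                 0.5 * drop(crossprod(dmu, Cinv %*% dmu)))
      d <- -drop(Pi %*% Cinv %*% dmu)
      Vs <- Pi - Pi %*% Cinv %*% Pi
      m0i <- m0i - Nc[j] * a
      m1i <- m1i - Nc[j] * a * d
      M2i <- M2i - Nc[j] * a * 0.5 * (Vs + tcrossprod(d) - Pi)
    }
    m0[i] <- m0i
    m1[i, ] <- m1i
    M2[[i]] <- symmetrize(M2i)
  }
  list(m0 = m0, m1 = m1, M2 = M2)
}

#' Right-hand side of the eco-evolutionary dynamics
#'
#' Evaluates the instantaneous rates of change of every species' density,
#' trait mean and genetic covariance:
#' `dN_i/dt = N_i m0_i`, `dmu_i/dt = G_i P_i^{-1} m1_i`,
#' `dG_i/dt = G_i P_i^{-1} M2_i P_i^{-1} G_i`, with the fitness moments
#' `(m0, m1, M2)` of [fitness_moments()]. Because `G` premultiplies both
#' evolutionary equations, a species with `G = 0` has frozen mean and
#' covariance; with `freeze_G = TRUE` every `dG` is forced to zero.
#'
#' @param comm An `eed_community`.
#' @param freeze_G Logical; if `TRUE` return `dG = 0` (null model).
#' @return A list with `dN` (length S), `dmu` (S x L matrix) and `dG`
#'   (list of S symmetric L x L matrices).
#' @export
community_rhs <- function(comm, freeze_G = FALSE) {
  params <- comm$params
  S <- n_species(comm)
  L <- params$L
  N <- densities(comm)
  mu <- trait_means(comm)
  Glist <- lapply(comm$species, `[[`, "G")
  Plist <- lapply(comm$species, function(sp) sp$G + sp$E)
  Pv <- if (L == 1L) vapply(Plist, as.numeric, numeric(1)) else Plist
  mom <- .community_moments(params, N, mu, Pv)
  dN <- N * mom$m0
  dmu <- matrix(0, S, L)
  dG <- vector("list", S)
  for (i in seq_len(S)) {
    Pinv <- solve_psd(Plist[[i]])
    GPinv <- Glist[[i]] %*% Pinv
    M2i <- if (L == 1L) matrix(mom$M2[i], 1L, 1L) else mom$M2[[i]]
    dmu[i, ] <- drop(GPinv %*% mom$m1[i, ])
    dG[[i]] <- if (freeze_G) matrix(0, L, L)
               else symmetrize(GPinv %*% M2i %*% t(GPinv))
  }
  list(dN = dN, dmu = dmu, dG = dG)
}

# --- state packing -------------------------------------------------------

.ut_index <- function(L) which(upper.tri(diag(L), diag = TRUE))

.pack_state <- function(comm) {
  L <- comm$params$L
  ut <- .ut_index(L)
  c(densities(comm), as.vector(trait_means(comm)),
    unlist(lapply(comm$species, function(sp) sp$G[ut])))
}

# Rebuild a community from a packed state vector (clamping round-off).
.unpack_state <- function(y, params, E_list, psd_tol = 1e-8) {
  L <- params$L
  ut <- .ut_index(L)
  K <- length(ut)
  S <- length(E_list)
  N <- pmax(y[seq_len(S)], 0)
  mu <- matrix(y[S + seq_len(S * L)], S, L)
  species <- vector("list", S)
  for (i in seq_len(S)) {
    Gm <- matrix(0, L, L)
    Gm[ut] <- y[S + S * L + (i - 1L) * K + seq_len(K)]
    Gm <- Gm + t(Gm) - diag(diag(Gm), L)
    Gm <- psd_project(Gm, tol = psd_tol)
    species[[i]] <- species_state(N = N[i], mu = mu[i, ], G = Gm,
                                  E = E_list[[i]])
  }
  community(params, species)
}

# deSolve derivative function over the packed state.
.make_deriv <- function(params, S, E_list, freeze_G) {
  L <- params$L
  ut <- .ut_index(L)
  K <- length(ut)
  Ev <- if (L == 1L) vapply(E_list, as.numeric, numeric(1)) else E_list
  if (L == 1L) {
    function(t, y, parms) {
      N <- y[seq_len(S)]
      mu <- y[S + seq_len(S)]
      g <- pmax(y[2L * S + seq_len(S)], 0)
      P <- g + Ev
      mom <- .community_moments(params, N, mu, P)
      ratio <- g / P
      list(c(N * mom$m0, ratio * mom$m1[, 1L],
             if (freeze_G) numeric(S) else ratio^2 * mom$M2))
    }
  } else {
    function(t, y, parms) {
      N <- y[seq_len(S)]
      mu <- matrix(y[S + seq_len(S * L)], S, L)
      Plist <- vector("list", S)
      Glist <- vector("list", S)
      for (i in seq_len(S)) {
        Gm <- matrix(0, L, L)
        Gm[ut] <- y[S + S * L + (i - 1L) * K + seq_len(K)]
        Gm <- Gm + t(Gm) - diag(diag(Gm), L)
        ev <- eigen(Gm, symmetric = TRUE)
        Gm <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
        Glist[[i]] <- Gm
        Plist[[i]] <- Gm + E_list[[i]]
      }
      mom <- .community_moments(params, N, mu, Plist)
      dmu <- matrix(0, S, L)
      dg <- numeric(S * K)
      for (i in seq_len(S)) {
        Pinv <- solve_psd(Plist[[i]], warn = FALSE)
        GPinv <- Glist[[i]] %*% Pinv
        dmu[i, ] <- drop(GPinv %*% mom$m1[i, ])
        if (!freeze_G) {
          dGi <- symmetrize(GPinv %*% mom$M2[[i]] %*% t(GPinv))
          dg[(i - 1L) * K + seq_len(K)] <- dGi[ut]
        }
      }
      list(c(N * mom$m0, as.vector(dmu), dg))
    }
  }
}

#' Integrate a community to eco-evolutionary equilibrium
#'
#' Integrates the coupled density / trait-mean / G-matrix ODE system with
#' an adaptive solver (`deSolve::lsodar`), stopping early once the
#' max-norm of the right-hand side falls below `equilibrium_tol` or when
#' `t_end` is reached. Snapshots are taken at logarithmically spaced
#' times. Positivity of densities and positive semidefiniteness of the
#' `G` matrices are enforced at every snapshot (round-off-level
#' eigenvalue clamping; larger violations raise an error).
#'
#' @param comm An `eed_community` (every species must have positive
#'   definite `E`).
#' @param options An `eed_options` object from [integrator_options()].
#' @return An object of class `eed_trajectory`: a list with `times`,
#'   `states` (a community snapshot per time), `converged` (did the
#'   derivative norm drop below `equilibrium_tol`?) and `t_final`.
#' @examples
#' p <- model_params(L = 1, omega = 0.1)
#' comm <- community(p, list(species_state(0.1, 0, G = 0, E = 1e-6)))
#' tr <- integrate_community(comm, integrator_options(t_end = 100))
#' final_state(tr)$species[[1]]$N   # logistic growth to N* = 1
#' @export
integrate_community <- function(comm, options = integrator_options()) {
  stopifnot(inherits(comm, "eed_community"), inherits(options, "eed_options"))
  S <- n_species(comm)
  if (S == 0L) stop("cannot integrate an empty community")
  params <- comm$params
  E_list <- lapply(comm$species, `[[`, "E")
  for (E in E_list)
    if (min_eigen(E) <= .EIG_FLOOR)
      stop("every species needs positive definite E for integration")
  y0 <- .pack_state(comm)
  deriv <- .make_deriv(params, S, E_list, options$freeze_G)
  times <- unique(c(0, 10^seq(0, log10(options$t_end),
                              length.out = options$n_snapshots - 1L)))
  rootfun <- function(t, y, parms)
    max(abs(unlist(deriv(t, y, parms)))) - options$equilibrium_tol
  out <- tryCatch(
    deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                 method = "lsodar", rtol = options$rel_tol,
                 atol = options$abs_tol, rootfunc = rootfun,
                 maxsteps = 50000),
    error = function(e) stop("solver failure: ", conditionMessage(e),
                             call. = FALSE))
  tt <- out[, 1L]
  states <- lapply(seq_len(nrow(out)), function(k)
    .unpack_state(out[k, -1L], params, E_list))
  t_final <- tt[length(tt)]
  final_deriv <- max(abs(unlist(deriv(t_final, out[nrow(out), -1L], NULL))))
  structure(list(times = tt, states = states,
                 converged = final_deriv <= options$equilibrium_tol * 1.01 ||
                   t_final < options$t_end * (1 - 1e-9),
                 t_final = t_final, options = options),
            class = "eed_trajectory")
}

#' Frozen-covariance null model run
#'
#' Identical to [integrate_community()] except that the trait covariances
#' are not allowed to evolve: `dG/dt = 0`, so every species keeps its
#' initial `G` (hence `P`) while densities and trait means still respond
#' to selection and competition. Used as the null against which the
#' effect of trait-variance evolution is judged.
#'
#' @inheritParams integrate_community
#' @return An `eed_trajectory` with `options$freeze_G = TRUE`.
#' @export
run_null <- function(comm, options = integrator_options()) {
  options$freeze_G <- TRUE
  integrate_community(comm, options)
}

#' Final state of a trajectory
#' @param traj An `eed_trajectory`.
#' @return The last community snapshot.
#' @export
final_state <- function(traj) traj$states[[length(traj$states)]]

#' @export
print.eed_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "snapshots to t =",
      format(x$t_final, digits = 4),
      if (x$converged) "(equilibrium reached)" else "(horizon reached)", "\n")
  print(final_state(x))
  invisible(x)
}
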