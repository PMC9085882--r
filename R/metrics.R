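# Species diversity (Hill numbers), trait-probability-density functional
# diversity on a regular grid, and ecosystem-function measures.

#' Regular evaluation grid over trait space
#'
#' Trait space is divided into `bins_per_dim^L` congruent (hyper-)cubes;
#' densities are evaluated at cell centers. The default 101 bins on
#' \[-1, 1\] per dimension is the resolution used for model output.
#'
#' @param bins_per_dim Number of bins per trait dimension (>= 2).
#' @param lo,hi Per-dimension range (scalars are recycled to length `L`).
#' @param L Trait-space dimensionality.
#' @return An object of class `eed_grid` with fields `bins_per_dim`,
#'   `lo`, `hi`, `L`, and `C` (total cell count).
#' @export
grid_spec <- function(bins_per_dim = 101L, lo = -1, hi = 1, L = 1L) {
  L <- as.integer(L)
  bins_per_dim <- as.integer(bins_per_dim)
  lo <- rep_len(as.numeric(lo), L)
  hi <- rep_len(as.numeric(hi), L)
  stopifnot(bins_per_dim >= 2L, L >= 1L, all(lo < hi))
  structure(list(bins_per_dim = bins_per_dim, lo = lo, hi = hi, L = L,
                 C = bins_per_dim^L),
            class = "eed_grid")
}

#' @export
print.eed_grid <- function(x, ...) {
  cat("Grid:", x$bins_per_dim, "bins per dimension on [",
      paste(x$lo, collapse = ","), "] .. [", paste(x$hi, collapse = ","),
      "], L =", x$L, "(", x$C, "cells )\n")
  invisible(x)
}

#' Cell centers of an evaluation grid
#' @param grid An `eed_grid`.
#' @return A `C x L` matrix of cell-center coordinates.
#' @export
grid_centers <- function(grid) {
  axes <- lapply(seq_len(grid$L), function(k) {
    w <- (grid$hi[k] - grid$lo[k]) / grid$bins_per_dim
    grid$lo[k] + w * (seq_len(grid$bins_per_dim) - 0.5)
  })
  as.matrix(expand.grid(axes))
}

#' Hill number (effective number of species) of order q
#'
#' `(sum_i f_i^q)^(1/(1-q))` for a frequency vector `f`; the order-1 case
#' is the analytic limit `exp(Shannon entropy)`, order 2 the inverse
#' Simpson index, order 0 richness.
#'
#' @param f Nonnegative frequencies summing to 1 (renormalized with a
#'   warning if the sum deviates by more than 1e-9).
#' @param q Diversity order, a real number >= 0.
#' @return The Hill number, between 1 and `length(f)`.
#' @examples
#' hill_number(c(0.5, 0.5), q = 2)          # 2 effective species
#' hill_number(c(0.5, 0.25, 0.25), q = 1)   # 2^1.5
#' @export
hill_number <- function(f, q = 2) {
  if (any(f < 0)) stop("frequencies must be nonnegative")
  if (any(!is.finite(f))) stop("frequencies must be finite")
  tot <- sum(f)
  if (tot <= 0) stop("frequencies sum to zero")
  if (abs(tot - 1) > 1e-9) {
    warning("frequencies sum to ", format(tot), "; renormalizing")
  }
  f <- f / tot
  f <- f[f > 0]
  if (q == 1) return(exp(-sum(f * log(f))))
  sum(f^q)^(1 / (1 - q))
}

#' Community-wide trait probability density
#'
#' The abundance-weighted mixture of the species' phenotype distributions,
#' `D(z) = sum_i f_i p_i(z)` with `f_i = N_i / sum_j N_j`; a proper
#' probability density over trait space.
#'
#' @param comm An `eed_community` with positive total density.
#' @param z A trait vector, or an `n x L` matrix of evaluation points.
#' @return Density value(s) at `z`.
#' @export
community_trait_density <- function(comm, z) {
  f <- rel_frequencies(comm)   # errors on zero total density
  z <- if (is.matrix(z)) z else matrix(as.numeric(z), ncol = comm$params$L)
  if (ncol(z) != comm$params$L)
    stop("evaluation points must have ", comm$params$L, " columns")
  out <- numeric(nrow(z))
  for (i in seq_along(f)) {
    if (f[i] == 0) next
    sp <- comm$species[[i]]
    out <- out + f[i] * dmvn(z, sp$mu, sp$G + sp$E)
  }
  out
}

# Regularized Hill number of gridded relative densities: the core of the
# functional-diversity measure. `values` are (unnormalized) densities at
# the C cell centers.
.fd_from_values <- function(values, q, C) {
  if (all(values == 0)) stop("density is zero on every grid cell; ",
                             "the community lies outside the grid")
  Dhat <- values / sum(values)
  Dhat <- Dhat[Dhat > 0]
  if (q == 1) exp(-sum(Dhat * log(Dhat))) / C
  else sum(Dhat^q)^(1 / (1 - q)) / C
}

#' Functional diversity of a community over a trait-space grid
#'
#' Evaluates the community trait probability density at the centers of the
#' grid cells, normalizes the values to a discrete relative density, and
#' returns the Hill number of order `q` of that relative density divided
#' by the cell count `C`. The 1/C regularization makes the value finite as
#' the grid is refined and scales it so that a community whose density is
#' uniform over the whole grid scores exactly 1; a density concentrated in
#' a single cell scores 1/C.
#'
#' @param x An `eed_community`, or a numeric vector of cell densities
#'   (one per grid cell).
#' @param q Diversity order (default 2).
#' @param grid An `eed_grid`; its `L` must match the community's.
#' @param ... Passed between methods.
#' @return Functional diversity in (0, 1].
#' @examples
#' p <- model_params(L = 1, omega = 0.1)
#' comm <- community(p, list(species_state(1, 0, G = 0, E = 0.01)))
#' functional_diversity(comm, q = 2)   # ~ sigma * sqrt(pi) = 0.177
#' @export
functional_diversity <- function(x, q = 2, ...) UseMethod("functional_diversity")

#' @rdname functional_diversity
#' @export
functional_diversity.eed_community <- function(x, q = 2,
                                               grid = grid_spec(L = x$params$L),
                                               ...) {
  if (grid$L != x$params$L)
    stop("grid dimensionality ", grid$L, " does not match community L = ",
         x$params$L)
  vals <- community_trait_density(x, grid_centers(grid))
  .fd_from_values(vals, q, grid$C)
}

#' @rdname functional_diversity
#' @export
functional_diversity.numeric <- function(x, q = 2, grid = NULL, ...) {
  C <- if (is.null(grid)) length(x) else grid$C
  if (!is.null(grid) && length(x) != grid$C)
    stop("expected ", grid$C, " cell values, got ", length(x))
  if (any(x < 0)) stop("cell densities must be nonnegative")
  .fd_from_values(x, q, C)
}

#' Total biomass of a community
#'
#' The summed population density over all species, one of the two
#' ecosystem-function measures reported by the experiment harness.
#'
#' @param comm An `eed_community`.
#' @return `sum(N_i)` (0 for an empty community).
#' @export
total_biomass <- function(comm) sum(densities(comm))

#' Integrated resource depletion of a community
#'
#' The community's total draw-down of the resource continuum: the integral
#' over resource space of the difference between the saturation resource
#' concentration and its depleted equilibrium level. In closed form this
#' is `(pi * omega^2)^(L/4) * sum(N_i)` — under the Gaussian utilization
#' and flat saturation profile of this model, resource use is exactly
#' proportional to total biomass (reported separately all the same, as the
#' two functions answer different questions when the model is extended).
#'
#' @param comm An `eed_community`.
#' @return Nonnegative depletion (0 for an empty community).
#' @export
resource_depletion <- function(comm) {
  (pi * comm$params$omega^2)^(comm$params$L / 4) * sum(densities(comm))
}

#' Species- and functional diversity of a community, bundled
#'
#' @param comm An `eed_community`.
#' @param q Diversity order.
#' @param grid An `eed_grid` for the functional-diversity evaluation.
#' @return An object of class `eed_diversity`: a list with `q`,
#'   `species_diversity`, `functional_diversity` and `grid`.
#' @export
community_diversity <- function(comm, q = 2,
                                grid = grid_spec(L = comm$params$L)) {
  structure(list(q = q,
                 species_diversity = hill_number(rel_frequencies(comm), q),
                 functional_diversity = functional_diversity(comm, q, grid),
                 grid = grid),
            class = "eed_diversity")
}

#' @export
print.eed_diversity <- function(x, ...) {
  cat("Diversity (q =", x$q, "): species",
      format(x$species_diversity, digits = 5), ", functional",
      format(x$functional_diversity, digits = 5), "\n")
  invisible(x)
}
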