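# Factorial simulation protocol: design construction, seeded
# initial-condition sampling, and batch execution of paired full/null runs.

.G_LEVELS <- list(low = c(0.01, 0.05), high = c(0.05, 0.1))
.E_LEVELS <- list(low = c(0.005, 0.008), medium = c(0.015, 0.018),
                  high = c(0.025, 0.028))
.OMEGA_LEVELS <- list(`1` = c(low = 0.1, high = 0.15),
                      `2` = c(low = 0.25, high = 0.3),
                      `3` = c(low = 0.4, high = 0.45))

#' Full factorial simulation design
#'
#' Crosses trait-space dimensionality `L` in \{1, 2, 3\}, initial species
#' number `S0` in \{2, ..., 25\}, initial genetic-covariance level
#' \{low, high\}, environmental-covariance level \{low, medium, high\},
#' competition-width level \{low, high\} (the width itself depends on `L`:
#' 0.1/0.15 for L = 1, 0.25/0.3 for L = 2, 0.4/0.45 for L = 3, chosen so
#' higher-dimensional trait spaces hold comparable species numbers) and
#' mortality shape \{quadratic, quartic\} — 1728 unique parameter
#' combinations, in deterministic lexicographic order.
#'
#' @param L,S0,g_init_level,e_level,omega_level,mortality_shape Optional
#'   restrictions of each factor to a subset of its levels (defaults: the
#'   full factor).
#' @return A data.frame with one row per parameter combination and an
#'   `omega` column resolved from `(L, omega_level)`.
#' @examples
#' nrow(build_design())             # 1728
#' nrow(build_design(L = 1))        # the 1-dimensional slice
#' @export
build_design <- function(L = 1:3, S0 = 2:25,
                         g_init_level = c("low", "high"),
                         e_level = c("low", "medium", "high"),
                         omega_level = c("low", "high"),
                         mortality_shape = c("quadratic", "quartic")) {
  stopifnot(all(L %in% 1:3), all(S0 %in% 2:25),
            all(g_init_level %in% c("low", "high")),
            all(e_level %in% c("low", "medium", "high")),
            all(omega_level %in% c("low", "high")),
            all(mortality_shape %in% c("quadratic", "quartic")))
  d <- expand.grid(mortality_shape = mortality_shape,
                   omega_level = omega_level, e_level = e_level,
                   g_init_level = g_init_level, S0 = as.integer(S0),
                   L = as.integer(L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("L", "S0", "g_init_level", "e_level", "omega_level",
             "mortality_shape")]
  d$omega <- vapply(seq_len(nrow(d)), function(i)
    .OMEGA_LEVELS[[as.character(d$L[i])]][[d$omega_level[i]]], numeric(1))
  rownames(d) <- NULL
  d
}

#' Expand a design with seeded replicates
#'
#' Adds `n` replicate rows per design point, each with a deterministic
#' 31-bit seed derived from `(master_seed, row counter)`; replicates
#' differ in their initial trait means and (by default) in their sampled
#' `G` and `E` matrices.
#'
#' @param design A data.frame from [build_design()].
#' @param n Replicates per design point (default 10).
#' @param master_seed Integer master seed.
#' @return The design with `replicate` and `seed` columns,
#'   `nrow(design) * n` rows.
#' @examples
#' nrow(add_replicates(build_design(), 10))   # 17280
#' @export
add_replicates <- function(design, n = 10L, master_seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  idx <- rep(seq_len(nrow(design)), each = n)
  out <- design[idx, , drop = FALSE]
  out$replicate <- rep(seq_len(n), times = nrow(design))
  counter <- (idx - 1L) * n + out$replicate
  out$seed <- vapply(counter, function(k) derive_seed(master_seed, k),
                     integer(1))
  rownames(out) <- NULL
  out
}

#' Sample a random initial genetic covariance matrix
#'
#' `G = U B U'` with `U` Haar-uniform orthogonal and `B` diagonal with
#' entries drawn uniformly from the level's interval (\[0.01, 0.05\] low,
#' \[0.05, 0.1\] high), so the eigenvalues of `G` are exactly the sampled
#' diagonal entries.
#'
#' @param L Trait dimensionality.
#' @param level `"low"` or `"high"`.
#' @return An L x L symmetric PSD matrix. Uses the global RNG.
#' @export
sample_initial_G <- function(L, level = c("low", "high")) {
  level <- match.arg(level)
  b <- stats::runif(L, .G_LEVELS[[level]][1], .G_LEVELS[[level]][2])
  U <- rhaar_orthogonal(L)
  symmetrize(U %*% (b * t(U)))
}

#' Sample an initial community for one design point
#'
#' `S0` species with density 1 each, trait means uniform on
#' \[-0.5, 0.5\] per dimension, `G` from [sample_initial_G()], and
#' diagonal `E` with entries uniform in the environmental level's interval.
#'
#' @param point A single-row data.frame (one row of a design), with
#'   columns `L`, `S0`, `g_init_level`, `e_level`, `omega`,
#'   `mortality_shape`.
#' @return An `eed_community`. Uses the global RNG; seed it (e.g. with the
#'   row's `seed`) for reproducibility.
#' @export
sample_initial_community <- function(point) {
  L <- as.integer(point$L)
  params <- model_params(L = L, omega = point$omega,
                         mortality_shape = point$mortality_shape)
  e_int <- .E_LEVELS[[point$e_level]]
  species <- lapply(seq_len(point$S0), function(i)
    species_state(N = 1,
                  mu = stats::runif(L, -0.5, 0.5),
                  G = sample_initial_G(L, point$g_init_level),
                  E = diag(stats::runif(L, e_int[1], e_int[2]), L)))
  community(params, species)
}

.result_row <- function(point, model, traj, grid, q,
                        extinction_threshold) {
  base <- as.data.frame(point, stringsAsFactors = FALSE)
  if (is.null(traj)) {
    return(cbind(base, data.frame(model = model, t_final = NA_real_,
                                  converged = FALSE,
                                  species_diversity = NA_real_,
                                  functional_diversity = NA_real_,
                                  total_biomass = NA_real_,
                                  resource_depletion = NA_real_,
                                  n_extant = NA_integer_)))
  }
  fs <- final_state(traj)
  cbind(base, data.frame(
    model = model, t_final = traj$t_final, converged = traj$converged,
    species_diversity = hill_number(rel_frequencies(fs), q),
    functional_diversity = functional_diversity(fs, q, grid),
    total_biomass = total_biomass(fs),
    resource_depletion = resource_depletion(fs),
    n_extant = sum(densities(fs) > extinction_threshold)))
}

#' Run a batch of paired full/null simulations
#'
#' For every design row: seed the RNG with the row's seed, draw one
#' initial community, integrate it under the full model and (from the
#' bit-identical initial state) under the frozen-covariance null model,
#' and summarize both equilibria (Hill q = 2 species diversity,
#' functional diversity on the standard grid, biomass, resource depletion,
#' extant species count). A failed run yields a row with `converged =
#' FALSE` and missing metrics; it never aborts the batch. Identical
#' inputs reproduce the table exactly.
#'
#' @param design A data.frame from [add_replicates()] (must carry a
#'   `seed` column; [build_design()] output is accepted and given one
#'   replicate with `master_seed`).
#' @param options An `eed_options`; defaults to a desk-scale horizon of
#'   `1e6` time units with equilibrium early stopping.
#' @param master_seed Used only if `design` lacks a `seed` column.
#' @param models Which of `"full"`, `"null"` to run.
#' @param q Diversity order for the summaries.
#' @param grid Optional `eed_grid`; defaults to 101 bins on \[-1,1\]^L
#'   per design row.
#' @param verbose Print a progress line per design row.
#' @return A data.frame with one row per (design row, model).
#' @export
run_batch <- function(design,
                      options = integrator_options(t_end = 1e6,
                                                   equilibrium_tol = 1e-10),
                      master_seed = 1L, models = c("full", "null"),
                      q = 2, grid = NULL, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(design$seed)) design <- add_replicates(design, 1L, master_seed)
  rows <- vector("list", nrow(design) * length(models))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    point <- design[i, , drop = FALSE]
    g <- if (is.null(grid)) grid_spec(L = point$L) else grid
    set.seed(point$seed)
    comm0 <- sample_initial_community(point)
    for (model in models) {
      traj <- tryCatch({
        if (model == "full") integrate_community(comm0, options)
        else run_null(comm0, options)
      }, error = function(e) {
        warning("run failed (row ", i, ", ", model, "): ",
                conditionMessage(e))
        NULL
      })
      k <- k + 1L
      rows[[k]] <- .result_row(point, model, traj, g, q,
                               options$extinction_threshold)
    }
    if (verbose)
      message(sprintf("[%d/%d] S0=%d omega=%.2f done", i, nrow(design),
                      point$S0, point$omega))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
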