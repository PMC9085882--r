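# Individual-level trait-table pipeline: cleaning, per-species density
# estimation, subcommunity diversity summaries, abundance randomization,
# and a synthetic trait-table generator.

#' Individual-level trait table with host-plant counts
#'
#' Wraps a table of individuals — species identity, subcommunity
#' membership (island code plus arid/humid vegetation zone) and a
#' two-dimensional trait vector (shell centroid size and shape PC1 in the
#' snail application) — together with the number of potential host-plant
#' species per subcommunity, the normalizer used for species diversity.
#' Zones form separate communities: species ranges never span both zones
#' of an island, so an (island, zone) pair is the unit of analysis.
#'
#' @param records A data.frame with columns `species`, `island`, `zone`
#'   (`"arid"` or `"humid"`), `size`, `shapePC1`.
#' @param host_plants A data.frame with columns `island`, `zone`,
#'   `n_hostplants` (positive integers), covering every (island, zone)
#'   present in `records`.
#' @return An object of class `eed_traittable`.
#' @export
trait_table <- function(records, host_plants) {
  need <- c("species", "island", "zone", "size", "shapePC1")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  need_h <- c("island", "zone", "n_hostplants")
  if (!all(need_h %in% names(host_plants)))
    stop("host_plants needs columns: ", paste(need_h, collapse = ", "))
  if (!all(records$zone %in% c("arid", "humid")))
    stop("zone must be 'arid' or 'humid'")
  if (!all(is.finite(records$size)) || !all(is.finite(records$shapePC1)))
    stop("trait values must be finite")
  if (any(host_plants$n_hostplants <= 0))
    stop("host-plant counts must be positive")
  key_r <- unique(paste(records$island, records$zone, sep = "/"))
  key_h <- paste(host_plants$island, host_plants$zone, sep = "/")
  missing <- setdiff(key_r, key_h)
  if (length(missing))
    stop("no host-plant count for subcommunity: ",
         paste(missing, collapse = ", "))
  structure(list(records = as.data.frame(records,
                                         stringsAsFactors = FALSE),
                 host_plants = as.data.frame(host_plants,
                                             stringsAsFactors = FALSE)),
            class = "eed_traittable")
}

#' @export
print.eed_traittable <- function(x, ...) {
  cat("Trait table:", nrow(x$records), "individuals,",
      length(unique(x$records$species)), "species,",
      length(unique(paste(x$records$island, x$records$zone))),
      "subcommunities\n")
  invisible(x)
}

#' Clean a trait table
#'
#' Drops records from excluded islands (by default the three small
#' satellite islands CH, ED and GA) and species sampled fewer than
#' `min_individuals` times in the whole table (the minimum for a
#' covariance fit; in the snail data this removes one two-specimen
#' species).
#'
#' @param table An `eed_traittable`.
#' @param excluded_islands Character vector of island codes to drop.
#' @param min_individuals Minimum total specimens per retained species.
#' @return A list with `table` (the cleaned `eed_traittable`) and
#'   `report` (a data.frame of records dropped per rule).
#' @export
clean_trait_table <- function(table, excluded_islands = c("CH", "ED", "GA"),
                              min_individuals = 3L) {
  stopifnot(inherits(table, "eed_traittable"))
  rec <- table$records
  drop_island <- rec$island %in% excluded_islands
  rec2 <- rec[!drop_island, , drop = FALSE]
  counts <- table(rec2$species)
  rare <- names(counts)[counts < min_individuals]
  drop_rare <- rec2$species %in% rare
  rec3 <- rec2[!drop_rare, , drop = FALSE]
  if (nrow(rec3) == 0L) stop("no records remain after cleaning")
  hp <- table$host_plants
  keep_hp <- paste(hp$island, hp$zone) %in% unique(paste(rec3$island,
                                                         rec3$zone))
  report <- data.frame(
    rule = c("excluded_island", "rare_species"),
    records_dropped = c(sum(drop_island), sum(drop_rare)),
    stringsAsFactors = FALSE)
  list(table = trait_table(rec3, hp[keep_hp, , drop = FALSE]),
       report = report)
}

#' Fit a species-level trait density
#'
#' Estimates a two-dimensional trait density for one species, either as a
#' binormal (maximum-likelihood mean and 1/n covariance) or by Gaussian
#' product-kernel density estimation with a per-axis plug-in bandwidth.
#'
#' @param traits An `n x 2` matrix or data.frame of trait values.
#' @param method `"binormal_mle"` (needs n >= 3 and a nonsingular sample
#'   covariance) or `"kde"` (needs n >= 2).
#' @param bandwidth Optional length-2 kernel bandwidth for `"kde"`;
#'   defaults to `stats::bw.nrd0` per axis.
#' @return An object of class `eed_density`; evaluate it with
#'   [predict.eed_density()].
#' @export
fit_species_density <- function(traits, method = c("binormal_mle", "kde"),
                                bandwidth = NULL) {
  method <- match.arg(method)
  X <- as.matrix(traits)
  if (ncol(X) != 2L) stop("traits must have two columns")
  n <- nrow(X)
  if (method == "binormal_mle") {
    if (n < 3L) stop("binormal_mle needs at least 3 individuals")
    m <- colMeans(X)
    Xc <- sweep(X, 2L, m)
    S <- crossprod(Xc) / n           # maximum-likelihood (1/n) covariance
    if (min_eigen(S) <= 1e-12)
      stop("sample covariance is singular; try method = 'kde'")
    out <- list(method = method, n = n, mean = m, cov = S)
  } else {
    if (n < 2L) stop("kde needs at least 2 individuals")
    if (is.null(bandwidth))
      bandwidth <- c(stats::bw.nrd0(X[, 1L]), stats::bw.nrd0(X[, 2L]))
    if (any(bandwidth <= 0))
      stop("kde bandwidth must be positive (degenerate trait values?)")
    out <- list(method = method, n = n, data = X,
                bandwidth = as.numeric(bandwidth))
  }
  structure(out, class = "eed_density")
}

#' Evaluate a fitted species density
#'
#' @param object An `eed_density`.
#' @param newdata An `m x 2` matrix of trait points.
#' @param ... Unused.
#' @return Density values at the rows of `newdata`.
#' @export
predict.eed_density <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (ncol(Z) != 2L) stop("newdata must have two columns")
  if (object$method == "binormal_mle")
    return(dmvn(Z, object$mean, object$cov))
  h <- object$bandwidth
  X <- object$data
  out <- numeric(nrow(Z))
  for (k in seq_len(nrow(X)))
    out <- out + stats::dnorm(Z[, 1L], X[k, 1L], h[1L]) *
      stats::dnorm(Z[, 2L], X[k, 2L], h[2L])
  out / nrow(X)
}

#' @export
print.eed_density <- function(x, ...) {
  cat("Species trait density (", x$method, "), n =", x$n, "\n")
  invisible(x)
}

# Linear map of each trait axis to [-1, 1] using the pooled range of the
# whole table: one shared frame keeps functional diversity comparable
# across subcommunities.
.pooled_rescale <- function(records) {
  lo <- c(min(records$size), min(records$shapePC1))
  hi <- c(max(records$size), max(records$shapePC1))
  w <- hi - lo
  w[w == 0] <- 1
  cbind(2 * (records$size - lo[1]) / w[1] - 1,
        2 * (records$shapePC1 - lo[2]) / w[2] - 1)
}

# Per-subcommunity species densities on the grid, computed once and
# shared by subcommunity_summary() and abundance_randomization().
# Returns a list per subcommunity: island, zone, species, counts,
# n_hostplants, and the species x cells matrix of density values.
.subcommunity_densities <- function(table, grid, method, min_individuals) {
  rec <- table$records
  Xs <- .pooled_rescale(rec)
  centers <- grid_centers(grid)
  hp <- table$host_plants
  hp_key <- paste(hp$island, hp$zone)
  sub_key <- paste(rec$island, rec$zone)
  out <- list()
  for (key in sort(unique(sub_key))) {
    sel <- sub_key == key
    counts <- table(rec$species[sel])
    ok <- counts >= min_individuals
    if (any(!ok))
      warning("subcommunity ", key, ": dropping ", sum(!ok),
              " species with fewer than ", min_individuals, " individuals")
    counts <- counts[ok]
    if (length(counts) == 0L) {
      warning("subcommunity ", key, " excluded: no species with at least ",
              min_individuals, " individuals")
      next
    }
    dens <- matrix(0, length(counts), nrow(centers))
    for (s in seq_along(counts)) {
      rows <- sel & rec$species == names(counts)[s]
      fit <- fit_species_density(Xs[rows, , drop = FALSE], method)
      dens[s, ] <- predict(fit, centers)
    }
    isl <- rec$island[sel][1L]
    zn <- rec$zone[sel][1L]
    out[[key]] <- list(island = isl, zone = zn,
                       species = names(counts),
                       counts = as.integer(counts),
                       n_hostplants =
                         hp$n_hostplants[match(paste(isl, zn), hp_key)],
                       density_matrix = dens)
  }
  out
}

.summaries_from_densities <- function(subs, grid, q,
                                      weights = NULL) {
  rows <- lapply(seq_along(subs), function(k) {
    sc <- subs[[k]]
    f <- if (is.null(weights)) sc$counts / sum(sc$counts) else weights[[k]]
    sd_q <- hill_number(f, q)
    fd <- .fd_from_values(drop(f %*% sc$density_matrix), q, grid$C)
    data.frame(island = sc$island, zone = sc$zone,
               S = length(sc$species), n_individuals = sum(sc$counts),
               species_diversity_q2 = sd_q,
               n_hostplants = sc$n_hostplants,
               normalized_diversity = sd_q / sc$n_hostplants,
               functional_diversity = fd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subcommunity diversity summaries
#'
#' For each (island, zone) subcommunity: Hill species diversity of the
#' sampled relative abundances, the same diversity normalized by the
#' local host-plant count (an index of ecological opportunity), and
#' functional diversity of the abundance-weighted mixture of fitted
#' species trait densities, evaluated on a shared grid. Trait axes are
#' first rescaled to \[-1, 1\] by the pooled range of the whole table so
#' all subcommunities share one frame. Zones are never pooled.
#'
#' @param table An `eed_traittable` (clean it first with
#'   [clean_trait_table()]).
#' @param grid An `eed_grid` with `L = 2` (default 101 bins per axis on
#'   \[-1, 1\]).
#' @param method Density estimation method, see [fit_species_density()].
#' @param q Diversity order (default 2).
#' @param min_individuals Minimum individuals per species within a
#'   subcommunity for a density fit; rarer species are dropped with a
#'   warning, and a subcommunity with no fittable species is excluded.
#' @return A data.frame with one row per subcommunity: `island`, `zone`,
#'   `S`, `n_individuals`, `species_diversity_q2`, `n_hostplants`,
#'   `normalized_diversity`, `functional_diversity`.
#' @export
subcommunity_summary <- function(table, grid = grid_spec(101L, -1, 1, 2L),
                                 method = c("binormal_mle", "kde"), q = 2,
                                 min_individuals = 3L) {
  stopifnot(inherits(table, "eed_traittable"), grid$L == 2L)
  method <- match.arg(method)
  subs <- .subcommunity_densities(table, grid, method, min_individuals)
  if (length(subs) == 0L) stop("no subcommunity could be summarized")
  .summaries_from_densities(subs, grid, q)
}

#' Regression of functional diversity on normalized species diversity
#'
#' Ordinary least squares of subcommunity functional diversity on
#' host-plant-normalized species diversity, with a two-sided t test on
#' the slope.
#'
#' @param summaries A data.frame from [subcommunity_summary()] (columns
#'   `functional_diversity` and `normalized_diversity`).
#' @return A list with `slope`, `slope_se`, `p_value`, `n` and the
#'   underlying `lm` fit.
#' @export
sd_fd_regression <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 3L)
  if (stats::var(summaries$normalized_diversity) == 0)
    stop("normalized species diversity has zero variance")
  fit <- stats::lm(functional_diversity ~ normalized_diversity,
                   data = summaries)
  co <- summary(fit)$coefficients
  list(slope = co[2L, 1L], slope_se = co[2L, 2L], p_value = co[2L, 4L],
       n = nrow(summaries), fit = fit)
}

#' Sensitivity of the diversity relationship to sampled abundances
#'
#' The recorded per-species specimen counts need not reflect true
#' abundances. This randomizes the relative abundances within each
#' subcommunity (the species' trait densities are untouched), recomputes
#' species- and functional diversity and the regression slope per trial,
#' and reports the fraction of trials with a negative slope.
#'
#' @param table An `eed_traittable`.
#' @param trials Number of randomization trials (>= 1).
#' @param grid,method,q,min_individuals As in [subcommunity_summary()].
#' @param scheme `"dirichlet"` resamples frequencies uniformly on the
#'   simplex (symmetric Dirichlet with concentration `alpha`);
#'   `"multinomial"` resamples the specimen counts with equal species
#'   probabilities at the observed subcommunity sample size.
#' @param alpha Dirichlet concentration (default 1: uniform).
#' @return A list with `fraction_negative`, the vector `slopes`, and
#'   `trials`.
#' @export
abundance_randomization <- function(table, trials = 1000L,
                                    grid = grid_spec(101L, -1, 1, 2L),
                                    method = c("binormal_mle", "kde"),
                                    q = 2, min_individuals = 3L,
                                    scheme = c("dirichlet", "multinomial"),
                                    alpha = 1) {
  stopifnot(trials >= 1L)
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  subs <- .subcommunity_densities(table, grid, method, min_individuals)
  if (length(subs) < 3L) stop("need at least 3 subcommunities")
  slopes <- numeric(trials)
  for (t in seq_len(trials)) {
    weights <- lapply(subs, function(sc) {
      S <- length(sc$species)
      if (scheme == "dirichlet") {
        g <- stats::rgamma(S, shape = alpha)
        while (sum(g) == 0) g <- stats::rgamma(S, shape = alpha)
        g / sum(g)
      } else {
        drop(stats::rmultinom(1L, sum(sc$counts), rep(1 / S, S))) /
          sum(sc$counts)
      }
    })
    sm <- .summaries_from_densities(subs, grid, q, weights)
    x <- sm$normalized_diversity
    y <- sm$functional_diversity
    slopes[t] <- stats::cov(x, y) / stats::var(x)
  }
  list(fraction_negative = mean(slopes < 0), slopes = slopes,
       trials = trials)
}

#' Generate a synthetic trait table with a controlled diversity gradient
#'
#' Builds an individual-level table that mimics the structure of the
#' snail data: isolated (island, zone) subcommunities, each a mixture of
#' per-species binormal trait clusters. Species counts increase across
#' subcommunities, and within-species trait spread is co-varied with
#' species number so that the realized relationship between species
#' diversity and functional diversity has the requested sign: under
#' `"negative"`, richer subcommunities hold narrower, more tightly packed
#' clusters (trait sd scaling like 1/S); under `"positive"`, clusters
#' keep their width and richer subcommunities cover more trait space.
#'
#' @param n_subcommunities Number of (island, zone) subcommunities.
#' @param species_per_subcommunity Species counts, recycled to
#'   `n_subcommunities` (default `2, 3, ...`).
#' @param n_per_species Individuals sampled per species.
#' @param sd_fd_slope_sign `"negative"` or `"positive"`.
#' @param sigma0 Base within-species trait standard deviation (trait
#'   units of the synthetic plane).
#' @param n_hostplants Host-plant count attached to every subcommunity.
#' @return An `eed_traittable` whose `"truth"` attribute records the
#'   generating parameters per species (means, variances) for
#'   parameter-recovery checks. Uses the global RNG.
#' @examples
#' set.seed(1)
#' tab <- simulate_trait_table(6, n_per_species = 40)
#' nrow(tab$records)   # 6 subcommunities x (2+3+...+7) species x 40
#' @export
simulate_trait_table <- function(n_subcommunities = 10L,
                                 species_per_subcommunity = NULL,
                                 n_per_species = 30L,
                                 sd_fd_slope_sign = c("negative",
                                                      "positive"),
                                 sigma0 = 0.1, n_hostplants = 4L) {
  sd_fd_slope_sign <- match.arg(sd_fd_slope_sign)
  stopifnot(n_subcommunities >= 1L, n_per_species >= 1L, sigma0 > 0)
  Svec <- if (is.null(species_per_subcommunity))
    1L + seq_len(n_subcommunities)
  else rep_len(as.integer(species_per_subcommunity), n_subcommunities)
  stopifnot(all(Svec >= 1L))
  recs <- list()
  truth <- list()
  for (k in seq_len(n_subcommunities)) {
    S <- Svec[k]
    island <- sprintf("I%02d", (k + 1L) %/% 2L)
    zone <- if (k %% 2L == 1L) "arid" else "humid"
    if (sd_fd_slope_sign == "negative") {
      span <- 1.6                       # fixed occupied span
      sigma <- sigma0 * min(Svec) / S   # richer => narrower clusters
    } else {
      span <- 0.3 * (S - 1L)            # richer => wider coverage
      sigma <- sigma0 / 2
    }
    centers <- if (S == 1L) 0 else seq(-span / 2, span / 2, length.out = S)
    for (s in seq_len(S)) {
      m <- c(centers[s], centers[s])
      v <- c(sigma^2, (0.8 * sigma)^2)
      X <- cbind(stats::rnorm(n_per_species, m[1], sqrt(v[1])),
                 stats::rnorm(n_per_species, m[2], sqrt(v[2])))
      sp_id <- sprintf("sp_%02d_%02d", k, s)
      recs[[length(recs) + 1L]] <- data.frame(
        species = sp_id, island = island, zone = zone,
        size = X[, 1L], shapePC1 = X[, 2L], stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        island = island, zone = zone, species = sp_id,
        mean_size = m[1], mean_shape = m[2],
        var_size = v[1], var_shape = v[2], stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  hp <- unique(records[, c("island", "zone")])
  hp$n_hostplants <- as.integer(n_hostplants)
  out <- trait_table(records, hp)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
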