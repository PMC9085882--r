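toy_table <- function() {
  recs <- rbind(
    data.frame(species = "a", island = "SC", zone = "arid",
               size = rnorm(10, 0), shapePC1 = rnorm(10, 0)),
    data.frame(species = "b", island = "SC", zone = "arid",
               size = rnorm(8, 2), shapePC1 = rnorm(8, 1)),
    data.frame(species = "c", island = "CH", zone = "humid",
               size = rnorm(5, 1), shapePC1 = rnorm(5, 0)),
    data.frame(species = "d", island = "SF", zone = "humid",
               size = rnorm(2, 1), shapePC1 = rnorm(2, 0)),
    data.frame(species = "e", island = "SF", zone = "humid",
               size = rnorm(12, -1), shapePC1 = rnorm(12, 2)))
  hp <- data.frame(island = c("SC", "CH", "SF"),
                   zone = c("arid", "humid", "humid"),
                   n_hostplants = c(4L, 2L, 5L))
  trait_table(recs, hp)
}

test_that("trait tables validate their structure", {
  set.seed(111)
  tab <- toy_table()
  expect_s3_class(tab, "eed_traittable")
  bad <- tab$records; bad$zone[1] <- "alpine"
  expect_error(trait_table(bad, tab$host_plants), "arid")
  expect_error(trait_table(tab$records, tab$host_plants[1:2, ]),
               "no host-plant count")
  bad2 <- tab$records; bad2$size[1] <- NA
  expect_error(trait_table(bad2, tab$host_plants), "finite")
})

test_that("cleaning drops excluded islands and under-sampled species", {
  set.seed(112)
  tab <- toy_table()
  cl <- clean_trait_table(tab)
  rec <- cl$table$records
  expect_false(any(rec$island == "CH"))
  expect_false(any(rec$species == "d"))   # two specimens only
  expect_true(all(c("a", "b", "e") %in% rec$species))
  expect_equal(cl$report$records_dropped[cl$report$rule == "excluded_island"],
               5)
  expect_equal(cl$report$records_dropped[cl$report$rule == "rare_species"], 2)
  # an already-clean table passes through unchanged with an all-zero report
  cl2 <- clean_trait_table(cl$table)
  expect_equal(cl2$table$records, cl$table$records)
  expect_true(all(cl2$report$records_dropped == 0))
})

test_that("binormal fit returns ML mean and 1/n covariance", {
  X <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  fit <- fit_species_density(X, "binormal_mle")
  expect_equal(fit$mean, c(0, 0))
  expect_equal(fit$cov, diag(2))
  # degenerate data is rejected with a pointer to kde
  expect_error(fit_species_density(rbind(c(1, 2), c(1, 2), c(1, 2)),
                                   "binormal_mle"), "kde")
  expect_error(fit_species_density(X[1:2, ], "binormal_mle"), "at least 3")
  # parameter recovery on a large synthetic sample
  set.seed(113)
  n <- 2000
  Sig <- matrix(c(0.04, 0.01, 0.01, 0.02), 2)
  Z <- matrix(rnorm(2 * n), n) %*% chol(Sig)
  Z <- sweep(Z, 2, c(0.3, -0.2), "+")
  big <- fit_species_density(Z, "binormal_mle")
  se_mean <- sqrt(diag(Sig) / n)
  expect_true(all(abs(big$mean - c(0.3, -0.2)) < 3 * se_mean))
  se_var <- sqrt(2) * diag(Sig) / sqrt(n)
  expect_true(all(abs(diag(big$cov) - diag(Sig)) < 3 * se_var))
})

test_that("fitted densities integrate to one over a wide grid", {
  set.seed(114)
  X <- cbind(rnorm(60, 0, 0.15), rnorm(60, 0, 0.1))
  g <- grid_spec(161, -1, 1, 2)
  w <- (2 / 161)^2
  for (m in c("binormal_mle", "kde")) {
    fit <- fit_species_density(X, m)
    mass <- sum(predict(fit, grid_centers(g))) * w
    expect_equal(mass, 1, tolerance = 0.01)
  }
})

test_that("subcommunity summaries compute the documented quantities", {
  set.seed(115)
  # one subcommunity, one species
  rec1 <- data.frame(species = "a", island = "AA", zone = "arid",
                     size = rnorm(20), shapePC1 = rnorm(20))
  hp1 <- data.frame(island = "AA", zone = "arid", n_hostplants = 3L)
  s1 <- subcommunity_summary(trait_table(rec1, hp1))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$species_diversity_q2, 1)
  expect_equal(s1$normalized_diversity, 1 / 3)
  # two equally sampled species: SD = 2, host plants 4 -> 0.5
  rec2 <- rbind(rec1,
                data.frame(species = "b", island = "BB", zone = "humid",
                           size = rnorm(20, 2), shapePC1 = rnorm(20, 1)),
                data.frame(species = "c", island = "BB", zone = "humid",
                           size = rnorm(20, -2), shapePC1 = rnorm(20, -1)))
  hp2 <- rbind(hp1, data.frame(island = "BB", zone = "humid",
                               n_hostplants = 4L))
  s2 <- subcommunity_summary(trait_table(rec2, hp2))
  bb <- s2[s2$island == "BB", ]
  expect_equal(bb$species_diversity_q2, 2)
  expect_equal(bb$normalized_diversity, 0.5)
  expect_equal(bb$n_individuals, 40)
  # zones are never pooled
  expect_equal(nrow(s2), 2)
  # species below the local minimum are dropped with a warning
  rec3 <- rbind(rec2, data.frame(species = "tiny", island = "BB",
                                 zone = "humid", size = 0.5,
                                 shapePC1 = 0.5))
  expect_warning(s3 <- subcommunity_summary(trait_table(rec3, hp2)),
                 "fewer than")
  expect_equal(s3[s3$island == "BB", ]$S, 2)
})

test_that("plug-in functional diversity is consistent with the truth", {
  set.seed(116)
  tab <- simulate_trait_table(4, species_per_subcommunity = 3,
                              n_per_species = 500)
  truth <- attr(tab, "truth")
  sm <- subcommunity_summary(tab)
  g <- grid_spec(101, -1, 1, 2)
  centers <- grid_centers(g)
  # the same pooled [-1,1] rescale the pipeline applies, on the truth side
  lo <- c(min(tab$records$size), min(tab$records$shapePC1))
  hi <- c(max(tab$records$size), max(tab$records$shapePC1))
  rel_err <- vapply(seq_len(nrow(sm)), function(k) {
    tk <- truth[truth$island == sm$island[k] & truth$zone == sm$zone[k], ]
    vals <- 0
    for (s in seq_len(nrow(tk))) {
      m_sc <- 2 * (c(tk$mean_size[s], tk$mean_shape[s]) - lo) / (hi - lo) - 1
      v_sc <- c(tk$var_size[s], tk$var_shape[s]) * (2 / (hi - lo))^2
      vals <- vals + dnorm(centers[, 1], m_sc[1], sqrt(v_sc[1])) *
        dnorm(centers[, 2], m_sc[2], sqrt(v_sc[2])) / nrow(tk)
    }
    fd_true <- functional_diversity(vals, q = 2, grid = g)
    abs(sm$functional_diversity[k] - fd_true) / fd_true
  }, numeric(1))
  expect_lt(mean(rel_err), 0.02)
  expect_lt(max(rel_err), 0.05)
})

test_that("binormal and kde functional diversity agree on clean clusters", {
  set.seed(117)
  tab <- simulate_trait_table(5, species_per_subcommunity = 3,
                              n_per_species = 400)
  sb <- subcommunity_summary(tab, method = "binormal_mle")
  sk <- subcommunity_summary(tab, method = "kde")
  expect_true(all(abs(sk$functional_diversity - sb$functional_diversity) /
                    sb$functional_diversity < 0.10))
})

test_that("the diversity regression recovers exact linear relationships", {
  sm <- data.frame(normalized_diversity = c(0.2, 0.5, 0.8, 1.1),
                   functional_diversity = 2 * c(0.2, 0.5, 0.8, 1.1) + 1)
  # suppress lm's "essentially perfect fit" note on the exact line
  fit <- suppressWarnings(sd_fd_regression(sm))
  expect_equal(fit$slope, 2)
  expect_lt(fit$p_value, 1e-10)
  expect_equal(fit$n, 4)
  sm$functional_diversity <- 0.4
  expect_equal(suppressWarnings(sd_fd_regression(sm))$slope, 0)
  sm$normalized_diversity <- 1
  expect_error(sd_fd_regression(sm), "zero variance")
})

test_that("the fixture generator realizes the requested diversity gradient", {
  set.seed(118)
  neg <- simulate_trait_table(8, n_per_species = 60)
  expect_equal(nrow(neg$records), 60 * sum(2:9))
  expect_lt(sd_fd_regression(subcommunity_summary(neg))$slope, 0)
  pos <- simulate_trait_table(8, n_per_species = 60,
                              sd_fd_slope_sign = "positive")
  expect_gt(sd_fd_regression(subcommunity_summary(pos))$slope, 0)
})

test_that("abundance randomization is seeded and sign-faithful", {
  set.seed(119)
  tab <- simulate_trait_table(6, n_per_species = 40)
  # determinism under a shared seed
  set.seed(1); r1 <- abundance_randomization(tab, trials = 5)
  set.seed(1); r2 <- abundance_randomization(tab, trials = 5)
  expect_identical(r1$slopes, r2$slopes)
  # a strongly negative construction keeps its sign under randomization
  set.seed(2)
  rn <- abundance_randomization(tab, trials = 60)
  expect_gt(rn$fraction_negative, 0.9)
  # multinomial scheme works and respects sample sizes
  set.seed(3)
  rm_ <- abundance_randomization(tab, trials = 10, scheme = "multinomial")
  expect_true(all(is.finite(rm_$slopes)))
})

test_that("randomized slopes are centred when trait structure is shared", {
  set.seed(120)
  # every subcommunity: same species count, same trait distribution for
  # all species, so functional diversity cannot track species diversity
  recs <- do.call(rbind, lapply(1:6, function(k)
    do.call(rbind, lapply(1:3, function(s)
      data.frame(species = sprintf("sp%d_%d", k, s),
                 island = sprintf("I%d", k), zone = "arid",
                 size = rnorm(30, 0, 0.3), shapePC1 = rnorm(30, 0, 0.3))))))
  hp <- unique(recs[, c("island", "zone")])
  hp$n_hostplants <- 4L
  tab <- trait_table(recs, hp)
  set.seed(4)
  rr <- abundance_randomization(tab, trials = 100)
  expect_lt(abs(mean(rr$slopes)), 0.05)
  expect_gt(rr$fraction_negative, 0.1)
  expect_lt(rr$fraction_negative, 0.9)
})
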