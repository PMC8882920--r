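test_that("Spearman correlation: ranks, ties, monotone invariance", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  # invariance under strictly monotone transforms
  withr::with_seed(8, {
    a <- rnorm(30); b <- a + rnorm(30)
    expect_equal(spearman_rho(exp(a), b)$rho, spearman_rho(a, b)$rho)
  })
  # independent oracle: Pearson correlation of average ranks, computed from
  # the definition (no cor() shortcut), on a tie-containing fixture
  xs <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  ys <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  rx <- rank(xs); ry <- rank(ys)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(xs, ys)$rho, oracle, tolerance = 1e-12)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "voweldisp_domain_error")
  expect_error(spearman_rho(1:2, 1:2), class = "voweldisp_domain_error")
})

test_that("log-log OLS recovers an exact power law perfectly", {
  ede <- c(0.1, 0.3, 0.7, 1.2, 2.5)
  fe <- 10 * ede^(-1)
  fit <- fit_loglog_ols(tibble::tibble(effective_de = ede, fe = fe))
  expect_equal(fit$slope_k, -1, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  expect_error(fit_loglog_ols(tibble::tibble(effective_de = c(1, 2),
                                             fe = c(1, 2))),
               class = "voweldisp_domain_error")
  expect_error(fit_loglog_ols(tibble::tibble(effective_de = c(1, -2, 3),
                                             fe = c(1, 2, 3))),
               class = "voweldisp_domain_error")
})

test_that("OLS slope lands within sampling error of a simulated exponent", {
  typ <- simulate_typology(n_systems = 500, n_languages = 300,
                           n_families = 30, exponent = -1, seed = 101)
  fit <- fit_loglog_ols(typ$profiles)
  expect_lt(abs(fit$slope_k + 1), 3 * fit$se_slope)
})

test_that("mixed model collapses to OLS when grouping is uninformative", {
  typ <- simulate_typology(n_systems = 120, n_languages = 120,
                           exponent = -1, family_sd = 0.15,
                           region_sd = 0.1, seed = 31)
  prof <- typ$profiles
  # single grouping level with one group: term dropped, OLS path
  prof1 <- dplyr::mutate(prof, family = "only", region = "only",
                         iso = "only")
  m1 <- fit_mixed_model(prof1)
  ols <- fit_loglog_ols(prof1)
  expect_null(m1$model)
  expect_equal(m1$slope_k, ols$slope_k, tolerance = 1e-12)
  # exactly zero between-group variance: three families holding identical
  # copies of the same points, so the variance estimate hits the boundary
  # and the model collapses onto OLS
  base <- withr::with_seed(32, tibble::tibble(
    effective_de = exp(rnorm(20, -1, 0.4))))
  base$fe <- withr::with_seed(33, 10^(-1 * log10(base$effective_de) +
                                        rnorm(20, 0, 0.1)))
  prof0 <- dplyr::bind_rows(
    dplyr::mutate(base, family = "A"),
    dplyr::mutate(base, family = "B"),
    dplyr::mutate(base, family = "C"))
  prof0$iso <- paste0("l", seq_len(nrow(prof0)))
  prof0$region <- "R"
  m0 <- fit_mixed_model(prof0, random = "family")
  ols0 <- fit_loglog_ols(prof0)
  expect_equal(m0$slope_k, ols0$slope_k, tolerance = 1e-6)
  expect_true(m0$singular) # variance component on the boundary
})

test_that("mixed model recovers slope and variance components", {
  # a single draw of a 30-family variance component has ~26% relative
  # sampling error, so the component check averages over 5 replicates
  fam_vars <- numeric(5)
  for (i in 1:5) {
    typ <- simulate_typology(n_systems = 300, n_languages = 300,
                             n_families = 30, n_regions = 8,
                             exponent = -1, family_sd = 0.2,
                             region_sd = 0.1, resid_sd = 0.05,
                             seed = 76 + i)
    m <- fit_mixed_model(typ$profiles)
    if (i == 1) {
      expect_true(m$converged)
      expect_lt(abs(m$slope_k + 1), 3 * m$se_slope)
      expect_gt(m$adj_r2, m$marginal_r2 - 1e-12)
    }
    fam_vars[i] <- m$varcor$variance[m$varcor$group == "family"]
  }
  expect_lt(abs(mean(fam_vars) - 0.2^2), 0.3 * 0.2^2)
})

test_that("stratified fits keep the complementary nesting and skip small strata", {
  typ <- simulate_typology(n_systems = 400, n_languages = 250,
                           n_families = 10, n_regions = 4, exponent = -1,
                           seed = 55)
  prof <- typ$profiles
  st <- stratified_fits(prof, "region", min_n = 11)
  expect_s3_class(st, "vowel_stratified")
  expect_true(all(st$summary$slope_k < 0))
  expect_true(all(abs(st$summary$slope_k + 1) < 3 * st$summary$se_slope))
  # a tiny stratum is skipped with a reason
  small <- dplyr::bind_rows(prof, dplyr::mutate(prof[1:5, ],
                                                region = "Rtiny",
                                                sample_id = paste0("x", 1:5)))
  st2 <- stratified_fits(small, "region", min_n = 11)
  expect_true("Rtiny" %in% st2$skipped$stratum)
  expect_false("Rtiny" %in% st2$summary$stratum)
})

test_that("single-stratum report equals the global complementary fit", {
  typ <- simulate_typology(n_systems = 80, n_languages = 60, n_regions = 1,
                           exponent = -1, seed = 66)
  prof <- typ$profiles
  st <- stratified_fits(prof, "region", min_n = 11)
  expect_equal(nrow(st$summary), 1)
  global <- fit_mixed_model(prof, random = "family/iso")
  expect_equal(st$summary$slope_k, global$slope_k, tolerance = 1e-10)
})

test_that("group-mean regression fits over stratum means of the logs", {
  # three single-sample strata whose log pairs lie exactly on slope -0.8
  lx <- c(-1, -0.5, 0)
  prof <- tibble::tibble(
    sample_id = paste0("s", 1:3), iso = paste0("l", 1:3),
    family = "F", region = c("R1", "R2", "R3"),
    effective_de = 10^lx, fe = 10^(0.2 - 0.8 * lx))
  g <- group_mean_regression(prof, "region")
  expect_equal(g$slope_k, -0.8, tolerance = 1e-10)
  expect_equal(g$adj_r2, 1, tolerance = 1e-9)
  # single-member strata keep their point but report no spread
  expect_true(all(is.na(g$points$se_y)))
  expect_error(group_mean_regression(prof[1:2, ], "region"),
               class = "voweldisp_domain_error")
})

test_that("mean-of-logs and log-of-means genuinely differ on skewed data", {
  withr::with_seed(9, {
    prof <- tibble::tibble(
      sample_id = paste0("s", 1:60), iso = paste0("l", 1:60),
      family = "F", region = rep(c("R1", "R2", "R3"), each = 20),
      effective_de = exp(rnorm(60, 0, 1)), fe = exp(rnorm(60, 0, 1)))
    a <- group_mean_regression(prof, "region", log_first = TRUE)
    b <- group_mean_regression(prof, "region", log_first = FALSE)
    expect_false(isTRUE(all.equal(a$points$x, b$points$x)))
  })
})

test_that("weighted aggregation collapses samples to languages", {
  prof <- tibble::tibble(
    sample_id = c("a1", "a2", "b1"), iso = c("aaa", "aaa", "bbb"),
    family = "F", region = "R",
    effective_de = c(1, 3, 2), fe = c(4, 2, 5))
  # hand-computed weighted mean: (1*1 + 3*3) / 4 = 2.5
  agg <- aggregate_language_samples(prof,
                                    c(a1 = 1, a2 = 3, b1 = 7))
  expect_equal(agg$effective_de[agg$iso == "aaa"], 2.5)
  # single sample per language -> identity
  expect_equal(agg$effective_de[agg$iso == "bbb"], 2)
  # equal weights -> arithmetic mean
  agg2 <- aggregate_language_samples(prof)
  expect_equal(agg2$effective_de[agg2$iso == "aaa"], 2)
  # log means are averaged separately, not recomputed from raw means
  expect_equal(agg2$log10_effective_de[agg2$iso == "aaa"],
               mean(log10(c(1, 3))))
  expect_error(aggregate_language_samples(prof, c(a1 = 0, a2 = 0, b1 = 1)),
               class = "voweldisp_domain_error")
})

test_that("regressions are invariant to row order", {
  typ <- simulate_typology(n_systems = 100, n_languages = 80,
                           exponent = -1, seed = 21)
  prof <- typ$profiles
  perm <- withr::with_seed(1, sample(nrow(prof)))
  expect_equal(fit_loglog_ols(prof[perm, ])$slope_k,
               fit_loglog_ols(prof)$slope_k, tolerance = 1e-12)
  expect_equal(spearman_rho(prof$effective_de[perm], prof$fe[perm])$rho,
               spearman_rho(prof$effective_de, prof$fe)$rho)
})
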