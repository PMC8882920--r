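test_that("dependent bivariate BM estimates the evolutionary correlation", {
  tr <- simulate_yule_tree(200, seed = 17)
  tt <- simulate_bivariate_traits(tr, "BM", rates = c(1, 2), rho = 0.8,
                                  seed = 18)
  dep <- fit_bivariate_bm(tt, tr, traits = c("x", "y"), model = "dependent")
  expect_lt(abs(dep$rho - 0.8), 0.1)
  ind <- fit_bivariate_bm(tt, tr, traits = c("x", "y"),
                          model = "independent")
  expect_equal(ind$rho, 0)
  expect_gte(dep$logL, ind$logL)
})

test_that("the dependent model never fits worse than the independent one", {
  for (seed in c(1, 2, 3, 4, 5)) {
    tr <- simulate_yule_tree(25, seed = seed)
    tt <- simulate_bivariate_traits(tr, "BM", rho = 0, seed = seed + 100)
    dep <- fit_bivariate_bm(tt, tr, c("x", "y"), "dependent")
    ind <- fit_bivariate_bm(tt, tr, c("x", "y"), "independent")
    expect_gte(dep$logL, ind$logL - 1e-9)
  }
})

test_that("a perfect trait copy drives the correlation to the boundary", {
  tr <- simulate_yule_tree(30, seed = 8)
  tt <- simulate_bivariate_traits(tr, "BM", seed = 9)
  tt$y <- tt$x
  dep <- fit_bivariate_bm(tt, tr, c("x", "y"), "dependent")
  expect_equal(dep$rho, 1, tolerance = 1e-10)
  expect_true(dep$degenerate)
})

test_that("model comparison: zero evidence when the fits coincide", {
  # 4-tip star with equal branches: whitening is a scalar, so traits
  # orthogonal after centering give a cross-rate of exactly zero
  star <- ape::stree(4, "star"); star$edge.length <- rep(1, 4)
  d <- tibble::tibble(tip = star$tip.label,
                      x = c(1, -1, 0, 0), y = c(0, 0, 1, -1))
  dep <- fit_bivariate_bm(d, star, c("x", "y"), "dependent")
  ind <- fit_bivariate_bm(d, star, c("x", "y"), "independent")
  cmp <- compare_models(ind, dep)
  expect_equal(cmp$statistic, 0, tolerance = 1e-10)
  expect_equal(cmp$p_value, 1, tolerance = 1e-8)
  expect_equal(cmp$support, "weak")
})

test_that("model comparison refuses fits from different data", {
  tr <- simulate_yule_tree(10, seed = 1)
  t1 <- simulate_bivariate_traits(tr, "BM", seed = 2)
  t2 <- simulate_bivariate_traits(tr, "BM", seed = 3)
  dep <- fit_bivariate_bm(t1, tr, c("x", "y"), "dependent")
  ind <- fit_bivariate_bm(t2, tr, c("x", "y"), "independent")
  expect_error(compare_models(ind, dep), class = "voweldisp_config_error")
  expect_error(compare_models(dep, dep), class = "voweldisp_config_error")
})

test_that("strong simulated correlation earns decisive support", {
  tr <- simulate_yule_tree(100, seed = 41)
  tt <- simulate_bivariate_traits(tr, "BM", rho = 0.95, seed = 42)
  dep <- fit_bivariate_bm(tt, tr, c("x", "y"), "dependent")
  ind <- fit_bivariate_bm(tt, tr, c("x", "y"), "independent")
  cmp <- compare_models(ind, dep)
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$support, "decisive")
})

test_that("PGLS equals OLS on a star phylogeny", {
  star <- ape::stree(12, "star"); star$edge.length <- rep(1, 12)
  withr::with_seed(20, {
    x <- rnorm(12); y <- -0.9 * x + rnorm(12, 0, 0.3)
  })
  d <- tibble::tibble(tip = star$tip.label, effective_de = x, fe = y)
  fit <- pgls_fit(d, star, fe ~ effective_de, "BM")
  ref <- stats::lm(y ~ x)
  expect_equal(fit$beta, unname(stats::coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(stats::coef(ref)[1]),
               tolerance = 1e-10)
})

test_that("PGLS slope equals the dense-inversion GLS oracle", {
  for (seed in c(6, 7)) {
    tr <- simulate_yule_tree(50, seed = seed)
    tt <- simulate_bivariate_traits(tr, "BM", rho = -0.6, seed = seed + 50)
    d <- tibble::tibble(tip = tt$tip, effective_de = tt$x, fe = tt$y)
    fit <- pgls_fit(d, tr, fe ~ effective_de, "BM")
    V <- phylo_vcv(tr, "BM")
    ord <- match(tr$tip.label, d$tip)
    expect_equal(fit$beta,
                 oracle_gls_slope(V, d$effective_de[ord], d$fe[ord]),
                 tolerance = 1e-8)
    # OU at a fixed alpha against the same oracle
    fit_ou <- pgls_fit(d, tr, fe ~ effective_de, "OU", alpha = 0.5)
    V_ou <- suppressWarnings(phylo_vcv(tr, "OU", alpha = 0.5))
    expect_equal(fit_ou$beta,
                 oracle_gls_slope(V_ou, d$effective_de[ord], d$fe[ord]),
                 tolerance = 1e-8)
  }
})

test_that("PGLS agrees with the nlme reference implementation", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule_tree(40, seed = 23)
  tt <- simulate_bivariate_traits(tr, "BM", rho = -0.7, seed = 24)
  d <- as.data.frame(tibble::tibble(tip = tt$tip, effective_de = tt$x,
                                    fe = tt$y))
  rownames(d) <- d$tip
  mine <- pgls_fit(d, tr, fe ~ effective_de, "BM")
  ref <- nlme::gls(fe ~ effective_de, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~tip),
                   method = "ML")
  expect_equal(mine$beta, unname(stats::coef(ref)[2]), tolerance = 1e-6)
  expect_equal(mine$logL, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  ou <- pgls_fit(d, tr, fe ~ effective_de, "OU")
  ref_ou <- nlme::gls(fe ~ effective_de, data = d,
                      correlation = ape::corMartins(ou$alpha, tr,
                                                    form = ~tip,
                                                    fixed = TRUE),
                      method = "ML")
  expect_equal(ou$beta, unname(stats::coef(ref_ou)[2]), tolerance = 1e-6)
  expect_equal(ou$logL, as.numeric(stats::logLik(ref_ou)), tolerance = 1e-5)
})

test_that("PGLS recovers a simulated regression slope within sampling error", {
  tr <- simulate_yule_tree(100, seed = 29)
  withr::with_seed(30, {
    V <- phylo_vcv(tr, "BM")
    L <- t(chol(V))
    x <- as.numeric(L %*% rnorm(100))
    y <- 1 - 0.9 * x + as.numeric(L %*% rnorm(100, 0, 0.5))
  })
  d <- tibble::tibble(tip = tr$tip.label, effective_de = x, fe = y)
  fit <- pgls_fit(d, tr, fe ~ effective_de, "BM")
  expect_lt(abs(fit$beta + 0.9), 3 * fit$se_beta)
})

test_that("OU fitted on BM data collapses toward the BM limit", {
  tr <- simulate_yule_tree(60, seed = 33)
  tt <- simulate_bivariate_traits(tr, "BM", rho = -0.5, seed = 34)
  d <- tibble::tibble(tip = tt$tip, effective_de = tt$x, fe = tt$y)
  bm <- pgls_fit(d, tr, fe ~ effective_de, "BM")
  ou <- pgls_fit(d, tr, fe ~ effective_de, "OU")
  expect_gte(ou$logL, bm$logL - 0.05)
})

test_that("likelihood-ratio test compares BM against OU", {
  tr <- simulate_yule_tree(80, seed = 35)
  depth <- max(ape::node.depth.edgelength(tr))
  tt <- simulate_bivariate_traits(tr, "OU", rates = c(1, 1), rho = 0,
                                  alpha = 5 / depth, seed = 36)
  d <- tibble::tibble(tip = tt$tip, effective_de = tt$x, fe = tt$y)
  bm <- pgls_fit(d, tr, fe ~ effective_de, "BM")
  ou <- pgls_fit(d, tr, fe ~ effective_de, "OU")
  out <- likelihood_ratio_test(bm, ou)
  expect_equal(out$statistic, 2 * (ou$logL - bm$logL))
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(likelihood_ratio_test(ou, bm),
               class = "voweldisp_config_error")
  # equal likelihoods: statistic 0, p = 1
  fake_bm <- bm; fake_ou <- ou
  fake_ou$logL <- bm$logL
  expect_equal(likelihood_ratio_test(fake_bm, fake_ou)$p_value, 1)
})

test_that("across_trees summarises per-tree estimates", {
  trees <- lapply(1:4, function(s) simulate_yule_tree(15, seed = s))
  tt <- simulate_bivariate_traits(trees[[1]], "BM", rho = -0.6, seed = 99)
  d <- tibble::tibble(tip = tt$tip, effective_de = tt$x, fe = tt$y)
  res <- across_trees(trees, function(tr) {
    f <- pgls_fit(d, tr, fe ~ effective_de, "BM")
    tibble::tibble(beta = f$beta)
  })
  expect_equal(nrow(res$per_tree), 4)
  expect_equal(res$summary$mean[res$summary$quantity == "beta"],
               mean(res$per_tree$beta))
})
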