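# Likelihood-based comparative models: dependent vs independent bivariate
# Brownian motion, and phylogenetic generalized least squares under BM or
# OU covariance. All fits are exact-algebra maximum likelihood; nothing is
# iterative except the one-dimensional profile over the OU alpha.

# Whiten X and y by the Cholesky factor of V and return GLS quantities.
# logL is the ML Gaussian log-likelihood with sigma^2 profiled out; it is
# invariant to rescaling V, so BM (branch-length units) and OU (unit
# diagonal) likelihoods are directly comparable.
gls_core <- function(V, X, y) {
  U <- tryCatch(chol(V), error = function(e) {
    vd_abort(sprintf("GLS: covariance not positive definite (%s).",
                     conditionMessage(e)), "voweldisp_degenerate_error")
  })
  kappa_est <- kappa(U, exact = FALSE)
  if (!is.finite(kappa_est) || kappa_est > 1e10) {
    vd_abort(sprintf(
      "GLS: covariance ill-conditioned (condition number ~ %.2e).",
      kappa_est^2), "voweldisp_degenerate_error")
  }
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  n <- length(y); p <- ncol(X)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  logL <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(XtX_inv) * rss / (n - p))
  list(beta = as.numeric(beta), se = se, sigma2 = sigma2_ml,
       logL = logL, rss = rss, n = n, p = p)
}

#' Phylogenetic generalized least squares under BM or OU covariance
#'
#' Regresses one trait on another across the tips of a phylogeny with the
#' residual covariance implied by an evolutionary process: Brownian motion
#' (covariance proportional to shared branch length) or Ornstein-Uhlenbeck
#' in its Martins-Hansen correlation form (`exp(-alpha * patristic
#' distance)`, modeling stabilizing selection: correlation between relatives
#' decays with divergence time at rate alpha). For OU, alpha is profiled by
#' maximum likelihood over a log-spaced grid spanning `[1e-4, 1e2] / tree
#' depth` and then refined by one-dimensional optimization. The residual
#' scale is profiled out analytically in both cases, making the BM and OU
#' log-likelihoods directly comparable via [likelihood_ratio_test()].
#'
#' @param data Data frame with a `tip` column naming tree tips, plus the
#'   trait columns referenced by `formula`.
#' @param tree A `phylo` covering every row's tip.
#' @param formula Two-sided formula, e.g. `fe ~ effective_de` (the default
#'   response convention) or `log10_fe ~ log10_effective_de`.
#' @param process `"BM"` or `"OU"`.
#' @param alpha Optional fixed OU alpha; `NULL` (default) profiles it.
#' @return Object of class `pgls_fit`: `beta` (slope) and `intercept` with
#'   SEs, `sigma2`, `logL`, `alpha` (OU only), `process`, `n`, `formula`.
#' @export
pgls_fit <- function(data, tree, formula = fe ~ effective_de,
                     process = c("BM", "OU"), alpha = NULL) {
  process <- match.arg(process)
  validate_phylogeny(tree)
  vd_require_columns(data, "tip", "pgls_fit")
  data <- tibble::as_tibble(data)
  missing <- setdiff(tree$tip.label, data$tip)
  if (length(missing)) {
    vd_abort(sprintf("pgls_fit: no trait row for tip(s): %s",
                     paste(missing, collapse = ", ")),
             "voweldisp_config_error")
  }
  data <- data[match(tree$tip.label, data$tip), , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula), mf)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    vd_abort("pgls_fit: non-finite trait values.", "voweldisp_domain_error")
  }
  fit_at <- function(a) {
    V <- if (process == "BM") phylo_vcv(tree, "BM") else
      suppressWarnings(phylo_vcv(tree, "OU", alpha = a))
    gls_core(V, X, y)
  }
  alpha_hat <- NULL
  if (process == "BM") {
    core <- fit_at(NULL)
  } else if (!is.null(alpha)) {
    alpha_hat <- alpha
    core <- fit_at(alpha)
  } else {
    depth <- max(ape::node.depth.edgelength(tree))
    grid <- 10^seq(-4, 2, length.out = 25) / depth
    prof <- vapply(grid, function(a) fit_at(a)$logL, numeric(1))
    best <- which.max(prof)
    lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
    opt <- stats::optimize(function(la) fit_at(exp(la))$logL,
                           interval = log(c(lo, hi)), maximum = TRUE,
                           tol = 1e-8)
    alpha_hat <- exp(opt$maximum)
    core <- fit_at(alpha_hat)
  }
  structure(list(
    process = process,
    beta = core$beta[2], se_beta = core$se[2],
    intercept = core$beta[1], se_intercept = core$se[1],
    alpha = alpha_hat, sigma2 = core$sigma2, logL = core$logL,
    n = core$n, formula = formula
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s): %s\n", x$process, deparse(x$formula)))
  cat(sprintf("  beta = %.4f (SE %.4f), intercept = %.4f (SE %.4f)\n",
              x$beta, x$se_beta, x$intercept, x$se_intercept))
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %.5g\n", x$alpha))
  cat(sprintf("  logL = %.4f, n = %d\n", x$logL, x$n))
  invisible(x)
}

#' Likelihood-ratio comparison of BM and OU PGLS fits
#'
#' Compares `2 * (logL_OU - logL_BM)` against a chi-squared distribution
#' with 1 df. Two caveats are inherent to the stationary (Martins-Hansen)
#' OU correlation: alpha sits on the boundary of its space under the null,
#' making the chi-squared reference conservative; and the structure only
#' approximately nests BM, so on data that genuinely favour BM the best OU
#' fit can have a slightly *lower* likelihood. A negative statistic is
#' therefore evidence for BM, not an error: it is reported truncated at 0
#' with p = 1, and the untruncated value is kept in `raw_statistic`.
#'
#' @param bm_fit,ou_fit `pgls_fit` objects for the same data and tree.
#' @return One-row tibble with `statistic`, `df`, `p_value`,
#'   `raw_statistic`.
#' @export
likelihood_ratio_test <- function(bm_fit, ou_fit) {
  if (bm_fit$process != "BM" || ou_fit$process != "OU") {
    vd_abort("likelihood_ratio_test: pass (BM fit, OU fit) in that order.",
             "voweldisp_config_error")
  }
  if (bm_fit$n != ou_fit$n) {
    vd_abort("likelihood_ratio_test: fits use different data.",
             "voweldisp_config_error")
  }
  raw <- 2 * (ou_fit$logL - bm_fit$logL)
  stat <- max(raw, 0)
  tibble::tibble(statistic = stat, df = 1,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 raw_statistic = raw)
}

#' Dependent vs independent bivariate Brownian motion
#'
#' Maximum-likelihood fit of two traits evolving by Brownian motion on the
#' same tree, with covariance `R %x% C` (2x2 trait rate matrix, Kronecker
#' with the BM tree matrix). The dependent model estimates the evolutionary
#' correlation rho between the traits' changes; the independent model fixes
#' rho = 0. Both have closed-form ML estimates (GLS ancestral states, then
#' the ML rate matrix), so the dependent log-likelihood is never below the
#' independent one.
#'
#' @param data Data frame with a `tip` column and the two trait columns
#'   named in `traits`.
#' @param tree A `phylo` covering every tip.
#' @param traits Character vector of the two trait column names.
#' @param model `"dependent"` (rho estimated) or `"independent"` (rho = 0).
#' @return Object of class `bivariate_bm_fit`: `rates` (per-trait BM rate),
#'   `rho`, `ancestral` (root state per trait), `logL`, `aic`, `n_params`,
#'   `model`, `n`, `degenerate` flag (TRUE when |rho| = 1 makes the rate
#'   matrix singular and the likelihood unbounded).
#' @export
fit_bivariate_bm <- function(data, tree, traits = c("effective_de", "fe"),
                             model = c("dependent", "independent")) {
  model <- match.arg(model)
  validate_phylogeny(tree)
  vd_require_columns(data, c("tip", traits), "fit_bivariate_bm")
  data <- tibble::as_tibble(data)
  missing <- setdiff(tree$tip.label, data$tip)
  if (length(missing)) {
    vd_abort(sprintf("fit_bivariate_bm: no trait row for tip(s): %s",
                     paste(missing, collapse = ", ")),
             "voweldisp_config_error")
  }
  data <- data[match(tree$tip.label, data$tip), , drop = FALSE]
  X <- as.matrix(data[traits])
  if (any(!is.finite(X))) {
    vd_abort("fit_bivariate_bm: non-finite trait values.",
             "voweldisp_domain_error")
  }
  C <- phylo_vcv(tree, "BM")
  U <- chol(C)
  ones <- matrix(1, nrow(X), 1)
  Xw <- backsolve(U, X, transpose = TRUE)
  onesw <- backsolve(U, ones, transpose = TRUE)
  # GLS ancestral state per trait (shared design: a column of ones)
  a_hat <- as.numeric(crossprod(onesw, Xw) / sum(onesw^2))
  Ew <- Xw - onesw %*% t(a_hat)
  n <- nrow(X)
  R_full <- crossprod(Ew) / n # ML rate matrix of the dependent model
  R <- if (model == "dependent") R_full else diag(diag(R_full), 2)
  logdetC <- 2 * sum(log(diag(U)))
  detR <- R[1, 1] * R[2, 2] - R[1, 2] * R[2, 1]
  degenerate <- detR <= .Machine$double.eps * R[1, 1] * R[2, 2]
  logL <- if (degenerate) Inf else {
    -n * log(2 * pi) - logdetC - (n / 2) * log(detR) - n
  }
  n_params <- if (model == "dependent") 5 else 4
  structure(list(
    model = model,
    rates = stats::setNames(diag(R_full), traits),
    rho = if (model == "dependent") {
      R_full[1, 2] / sqrt(R_full[1, 1] * R_full[2, 2])
    } else 0,
    ancestral = stats::setNames(a_hat, traits),
    logL = logL, aic = 2 * n_params - 2 * logL, n_params = n_params,
    n = n, traits = traits, degenerate = degenerate,
    data_fingerprint = c(n, sum(X))
  ), class = "bivariate_bm_fit")
}

#' @export
print.bivariate_bm_fit <- function(x, ...) {
  cat(sprintf("Bivariate Brownian motion (%s model)\n", x$model))
  cat(sprintf("  traits: %s\n", paste(x$traits, collapse = ", ")))
  cat(sprintf("  rates: %.5g, %.5g;  rho = %.4f\n",
              x$rates[1], x$rates[2], x$rho))
  cat(sprintf("  root state: %.4f, %.4f\n", x$ancestral[1], x$ancestral[2]))
  cat(sprintf("  logL = %.4f, AIC = %.4f, n = %d\n", x$logL, x$aic, x$n))
  if (x$degenerate) cat("  note: |rho| = 1; likelihood unbounded\n")
  invisible(x)
}

#' Compare dependent and independent bivariate BM fits
#'
#' Likelihood-ratio test of correlated evolution: the independent model
#' (rho = 0) is nested in the dependent one, so `2 * (logL_dep - logL_ind)`
#' is referred to chi-squared with 1 df; the AIC difference and a
#' descriptive evidence label (on the decimal log-likelihood-ratio scale:
#' < 2 weak, 2-5 positive, 5-10 strong, > 10 decisive) are reported
#' alongside.
#'
#' @param fit_independent,fit_dependent `bivariate_bm_fit` objects for the
#'   same data and tree.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `delta_aic`
#'   (AIC_independent - AIC_dependent), `log10_lr`, `support`.
#' @export
compare_models <- function(fit_independent, fit_dependent) {
  if (fit_independent$model != "independent" ||
      fit_dependent$model != "dependent") {
    vd_abort("compare_models: pass (independent, dependent) in that order.",
             "voweldisp_config_error")
  }
  if (!isTRUE(all.equal(fit_independent$data_fingerprint,
                        fit_dependent$data_fingerprint))) {
    vd_abort("compare_models: fits come from different data.",
             "voweldisp_config_error")
  }
  d <- fit_dependent$logL - fit_independent$logL
  if (is.finite(d) && d < -1e-6) {
    vd_abort("compare_models: dependent logL < independent logL; the nested ",
             "inequality is violated, signalling a numerical failure.",
             "voweldisp_degenerate_error")
  }
  d <- max(d, 0)
  stat <- 2 * d
  log10_lr <- d / log(10)
  support <- if (log10_lr < 2) "weak" else if (log10_lr < 5) "positive"
  else if (log10_lr <= 10) "strong" else "decisive"
  tibble::tibble(
    statistic = stat, df = 1,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    delta_aic = fit_independent$aic - fit_dependent$aic,
    log10_lr = log10_lr, support = support)
}

#' Summarise a comparative analysis over a sample of trees
#'
#' Phylogenetic uncertainty is commonly carried by re-running an analysis
#' over a posterior sample of trees. `across_trees()` maps a fitting
#' function over a list of trees, binds the one-row results, and reports the
#' mean and standard deviation of every numeric column.
#'
#' @param trees List of `phylo` objects (or an ape `multiPhylo`).
#' @param fn Function taking a tree and returning a one-row data frame.
#' @param ... Passed on to `fn`.
#' @return List with `per_tree` (bound results, one row per tree) and
#'   `summary` (tibble of column, mean, sd).
#' @export
across_trees <- function(trees, fn, ...) {
  per_tree <- purrr::map_dfr(unclass(trees), function(tr) {
    tibble::as_tibble(fn(tr, ...))
  })
  num <- names(per_tree)[vapply(per_tree, is.numeric, logical(1))]
  summary <- tibble::tibble(
    quantity = num,
    mean = vapply(per_tree[num], mean, numeric(1), USE.NAMES = FALSE),
    sd = vapply(per_tree[num], stats::sd, numeric(1), USE.NAMES = FALSE))
  list(per_tree = per_tree, summary = summary)
}
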