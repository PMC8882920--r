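# Synchronic analysis of the dependence between effective dispersion and
# focalization: rank correlation, log-log OLS (the power-law exponent),
# nested random-intercept mixed models, stratified fits, group-mean
# regression, and weighted per-language aggregation.

#' Spearman rank correlation between two statistics
#'
#' Rank correlation with average ranks for ties, invariant under strictly
#' monotone transforms of either variable. The p-value uses the asymptotic
#' t approximation (ties-safe).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  vd_check_numeric(x, "x"); vd_check_numeric(y, "y")
  if (length(x) != length(y)) {
    vd_abort("spearman_rho: x and y differ in length.",
             "voweldisp_domain_error")
  }
  if (length(x) < 3) {
    vd_abort("spearman_rho: need n >= 3.", "voweldisp_domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    vd_abort("spearman_rho: correlation undefined for a constant vector.",
             "voweldisp_domain_error")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Log-log ordinary least squares: the power-law exponent
#'
#' Fits `log10(fe) ~ log10(effective_de)` by OLS. Under a power law
#' `fe = c * effective_de^K` the slope estimates the exponent K directly.
#'
#' @param profiles A `vowel_profiles` tibble (or any data frame with positive
#'   `effective_de` and `fe` columns).
#' @return Object of class `vowel_ols` with elements `slope_k`, `intercept`,
#'   `se_slope`, `se_intercept`, `p_slope`, `adj_r2`, `n`, and the underlying
#'   `lm` fit in `$model`. Supports [generics::tidy()], [generics::glance()],
#'   and [ggplot2::autoplot()].
#' @export
fit_loglog_ols <- function(profiles) {
  vd_require_columns(profiles, c("effective_de", "fe"), "fit_loglog_ols")
  vd_check_numeric(profiles$effective_de, "effective_de", positive = TRUE)
  vd_check_numeric(profiles$fe, "fe", positive = TRUE)
  if (nrow(profiles) < 3) {
    vd_abort("fit_loglog_ols: need n >= 3.", "voweldisp_domain_error")
  }
  df <- tibble::tibble(x = log10(profiles$effective_de),
                       y = log10(profiles$fe))
  fit <- stats::lm(y ~ x, data = df)
  sm <- summary(fit)
  structure(list(
    slope_k = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    se_slope = sm$coefficients[2, 2],
    se_intercept = sm$coefficients[1, 2],
    p_slope = sm$coefficients[2, 4],
    adj_r2 = sm$adj.r.squared,
    n = nrow(df),
    data = df,
    model = fit
  ), class = "vowel_ols")
}

#' @export
print.vowel_ols <- function(x, ...) {
  cat("Log-log OLS (power-law fit): log10(FE) ~ log10(Effective DE)\n")
  cat(sprintf("  slope K = %.4f (SE %.4f, p = %.3g)\n",
              x$slope_k, x$se_slope, x$p_slope))
  cat(sprintf("  intercept = %.4f (SE %.4f)\n", x$intercept, x$se_intercept))
  cat(sprintf("  adj. R^2 = %.4f, n = %d\n", x$adj_r2, x$n))
  invisible(x)
}

# Expand "a/b" nesting shorthand into lme4 random-intercept terms:
# "family/iso" -> (1|family) + (1|family:iso).
expand_random_spec <- function(random) {
  terms <- character(0)
  for (r in random) {
    parts <- strsplit(r, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      terms <- c(terms, sprintf("(1|%s)", parts))
    } else if (length(parts) == 2) {
      terms <- c(terms, sprintf("(1|%s)", parts[1]),
                 sprintf("(1|%s:%s)", parts[1], parts[2]))
    } else {
      vd_abort("random spec supports at most one level of nesting (a/b).",
               "voweldisp_config_error")
    }
  }
  unique(terms)
}

#' Nested random-intercept mixed model of the power-law dependence
#'
#' Fits `log10(fe) ~ log10(effective_de)` with random intercepts for the
#' grouping structure of cross-linguistic samples. The default reproduces the
#' full nesting of language identity in both language family and geographic
#' region: `(1|family) + (1|family:iso) + (1|region) + (1|region:iso)`.
#' Grouping factors with fewer than two levels in the data are dropped (with
#' a note); if none remain the model collapses to OLS. Estimation is REML by
#' default; slope p-values use the Satterthwaite approximation via lmerTest,
#' falling back to a normal approximation if that fails.
#'
#' The headline `adj_r2` is the conditional R-squared (variance explained by
#' fixed plus random effects, Nakagawa-style); `marginal_r2` isolates the
#' fixed effect.
#'
#' @param profiles Data frame with `effective_de`, `fe` (positive) and the
#'   grouping columns named in `random`.
#' @param random Character vector of random-intercept specs; `"a/b"` denotes
#'   b nested in a and expands to `(1|a) + (1|a:b)`.
#' @param reml Logical; REML (default) or ML estimation.
#' @return Object of class `vowel_lmm`: fixed `slope_k`/`intercept` with SEs
#'   and p-values, `varcor` tibble of variance components, `adj_r2`
#'   (conditional), `marginal_r2`, `converged`, `singular`, `dropped_terms`,
#'   `p_method`, `n`, and the lme4 fit in `$model` (NULL when collapsed to
#'   OLS).
#' @export
fit_mixed_model <- function(profiles,
                            random = c("family/iso", "region/iso"),
                            reml = TRUE) {
  vd_require_columns(profiles, c("effective_de", "fe"), "fit_mixed_model")
  vd_check_numeric(profiles$effective_de, "effective_de", positive = TRUE)
  vd_check_numeric(profiles$fe, "fe", positive = TRUE)
  terms <- expand_random_spec(random)
  groups <- unique(unlist(strsplit(gsub("[()1|]", "", terms), ":")))
  vd_require_columns(profiles, groups, "fit_mixed_model")
  df <- tibble::as_tibble(profiles)
  df$.y <- log10(df$fe)
  df$.x <- log10(df$effective_de)
  # drop random terms whose grouping factor is degenerate: fewer than two
  # levels, or one level per observation (an observation-level intercept,
  # unidentifiable alongside the residual)
  usable <- vapply(terms, function(tm) {
    fac <- gsub("[()1|]", "", tm)
    vars <- strsplit(fac, ":")[[1]]
    key <- do.call(paste, c(df[vars], sep = ":"))
    nl <- length(unique(key))
    nl >= 2 && nl < nrow(df)
  }, logical(1))
  dropped <- terms[!usable]
  terms <- terms[usable]
  if (!length(terms)) {
    ols <- fit_loglog_ols(df)
    return(structure(list(
      slope_k = ols$slope_k, intercept = ols$intercept,
      se_slope = ols$se_slope, se_intercept = ols$se_intercept,
      p_slope = ols$p_slope, p_intercept = summary(ols$model)$coefficients[1, 4],
      varcor = tibble::tibble(group = character(), variance = numeric()),
      resid_var = summary(ols$model)$sigma^2,
      adj_r2 = ols$adj_r2, marginal_r2 = ols$adj_r2,
      converged = TRUE, singular = FALSE, dropped_terms = dropped,
      p_method = "t (OLS collapse)", n = nrow(df), model = NULL,
      reml = reml
    ), class = "vowel_lmm"))
  }
  fml <- stats::as.formula(paste(".y ~ .x +", paste(terms, collapse = " + ")))
  warn_msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = df, REML = reml),
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  converged <- !any(grepl("failed to converge", warn_msgs))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  p_method <- "Satterthwaite"
  if (is.null(co) || ncol(co) < 5) {
    co <- summary(fit, ddf = "lme4")$coefficients
    z <- co[, "Estimate"] / co[, "Std. Error"]
    pvals <- 2 * stats::pnorm(-abs(z))
    p_method <- "normal approximation"
  } else {
    pvals <- co[, "Pr(>|t|)"]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f <- stats::var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  tot <- var_f + var_r + var_e
  structure(list(
    slope_k = unname(lme4::fixef(fit)[".x"]),
    intercept = unname(lme4::fixef(fit)["(Intercept)"]),
    se_slope = co[".x", "Std. Error"],
    se_intercept = co["(Intercept)", "Std. Error"],
    p_slope = unname(pvals[".x"]),
    p_intercept = unname(pvals["(Intercept)"]),
    varcor = tibble::tibble(group = vc$grp[vc$grp != "Residual"],
                            variance = vc$vcov[vc$grp != "Residual"]),
    resid_var = var_e,
    adj_r2 = (var_f + var_r) / tot,
    marginal_r2 = var_f / tot,
    converged = converged, singular = singular, dropped_terms = dropped,
    p_method = p_method, n = nrow(df), model = fit, reml = reml
  ), class = "vowel_lmm")
}

#' @export
print.vowel_lmm <- function(x, ...) {
  cat("Mixed model: log10(FE) ~ log10(Effective DE) + random intercepts\n")
  cat(sprintf("  slope K = %.4f (SE %.4f, p = %.3g [%s])\n",
              x$slope_k, x$se_slope, x$p_slope, x$p_method))
  cat(sprintf("  intercept = %.4f (SE %.4f)\n", x$intercept, x$se_intercept))
  cat(sprintf("  conditional R^2 = %.4f, marginal R^2 = %.4f, n = %d\n",
              x$adj_r2, x$marginal_r2, x$n))
  if (nrow(x$varcor)) {
    cat("  variance components:\n")
    for (i in seq_len(nrow(x$varcor))) {
      cat(sprintf("    %s: %.5f\n", x$varcor$group[i], x$varcor$variance[i]))
    }
  }
  cat(sprintf("  residual variance: %.5f\n", x$resid_var))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$singular) cat("  note: singular fit (some variance component ~ 0)\n")
  if (length(x$dropped_terms)) {
    cat("  dropped random terms (<2 levels):",
        paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-stratum mixed-model fits of the power-law dependence
#'
#' Refits the dependence separately within each geographic region (or each
#' language family), keeping the complementary nesting as the random
#' structure: region-stratified models retain language identity nested in
#' family, family-stratified models retain language identity nested in
#' region. Strata with fewer than `min_n` samples are skipped with a recorded
#' reason (the default 11 mirrors a "more than 10 samples" inclusion rule).
#'
#' @param profiles A `vowel_profiles` tibble with `region`/`family`/`iso`.
#' @param stratum `"region"` or `"family"`.
#' @param min_n Minimum samples per fitted stratum.
#' @return Object of class `vowel_stratified`: a summary tibble (one row per
#'   fitted stratum with slope, SE, p, conditional R2, n, and per-stratum
#'   means/SEs of the log10 statistics), `$fits` (named list of `vowel_lmm`),
#'   and `$skipped`.
#' @export
stratified_fits <- function(profiles, stratum = c("region", "family"),
                            min_n = 11) {
  stratum <- match.arg(stratum)
  vd_require_columns(profiles, c(stratum, "iso", "effective_de", "fe"),
                     "stratified_fits")
  complement <- if (stratum == "region") "family/iso" else "region/iso"
  df <- tibble::as_tibble(profiles)
  levels <- unique(df[[stratum]])
  fits <- list(); rows <- list(); skipped <- list()
  for (lev in levels) {
    sub <- df[df[[stratum]] == lev, , drop = FALSE]
    if (nrow(sub) < min_n) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        stratum = lev,
        reason = sprintf("n = %d < min_n = %d", nrow(sub), min_n))
      next
    }
    fit <- fit_mixed_model(sub, random = complement)
    fits[[lev]] <- fit
    lx <- log10(sub$effective_de); ly <- log10(sub$fe)
    rows[[length(rows) + 1]] <- tibble::tibble(
      stratum = lev, n = nrow(sub),
      slope_k = fit$slope_k, se_slope = fit$se_slope, p_slope = fit$p_slope,
      adj_r2 = fit$adj_r2,
      mean_log10_ede = mean(lx), se_log10_ede = stats::sd(lx) / sqrt(nrow(sub)),
      mean_log10_fe = mean(ly), se_log10_fe = stats::sd(ly) / sqrt(nrow(sub)))
  }
  structure(list(
    stratum = stratum,
    summary = dplyr::bind_rows(rows),
    fits = fits,
    skipped = dplyr::bind_rows(skipped)
  ), class = "vowel_stratified")
}

#' @export
print.vowel_stratified <- function(x, ...) {
  cat(sprintf("Stratified power-law fits by %s (%d fitted, %d skipped)\n",
              x$stratum, nrow(x$summary), nrow(x$skipped)))
  print(x$summary, ...)
  invisible(x)
}

#' Regression over stratum means of the log statistics
#'
#' Aggregates to one point per stratum and regresses the mean
#' `log10(fe)` on the mean `log10(effective_de)` across strata, with
#' per-point standard errors for plotting. Means are taken on the log scale
#' by default (mean of logs, matching an analysis that plots log-transformed
#' means with error bars); `log_first = FALSE` instead logs the arithmetic
#' means of the raw statistics.
#'
#' @param profiles A `vowel_profiles` tibble.
#' @param stratum `"region"` or `"family"`.
#' @param min_strata Minimum number of strata (default 3).
#' @param log_first Mean-of-logs (default) vs log-of-means.
#' @param spread `"se"` (default) or `"sd"` for the per-point error bars.
#' @return Object of class `vowel_grouped`: `$points` tibble (stratum, n,
#'   x, y, se_x, se_y) and the OLS fields `slope_k`, `intercept`, `se_slope`,
#'   `p_slope`, `adj_r2`, `n`.
#' @export
group_mean_regression <- function(profiles, stratum = c("region", "family"),
                                  min_strata = 3, log_first = TRUE,
                                  spread = c("se", "sd")) {
  stratum <- match.arg(stratum)
  spread <- match.arg(spread)
  vd_require_columns(profiles, c(stratum, "effective_de", "fe"),
                     "group_mean_regression")
  df <- tibble::as_tibble(profiles)
  df$.s <- df[[stratum]]
  pts <- dplyr::group_by(df, .data$.s)
  pts <- dplyr::summarise(
    pts,
    n = dplyr::n(),
    x = if (log_first) mean(log10(.data$effective_de)) else
      log10(mean(.data$effective_de)),
    y = if (log_first) mean(log10(.data$fe)) else log10(mean(.data$fe)),
    sd_x = stats::sd(log10(.data$effective_de)),
    sd_y = stats::sd(log10(.data$fe)),
    .groups = "drop")
  denom <- if (spread == "se") sqrt(pts$n) else 1
  pts$se_x <- pts$sd_x / denom
  pts$se_y <- pts$sd_y / denom
  pts <- dplyr::rename(pts, stratum = ".s")
  if (nrow(pts) < min_strata) {
    vd_abort(sprintf("group_mean_regression: %d strata < min_strata = %d.",
                     nrow(pts), min_strata), "voweldisp_domain_error")
  }
  fit <- stats::lm(y ~ x, data = pts)
  sm <- summary(fit)
  structure(list(
    stratum = stratum, points = pts,
    slope_k = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    se_slope = sm$coefficients[2, 2],
    p_slope = sm$coefficients[2, 4],
    adj_r2 = sm$adj.r.squared,
    n = nrow(pts), model = fit
  ), class = "vowel_grouped")
}

#' @export
print.vowel_grouped <- function(x, ...) {
  cat(sprintf("Regression over %s means (n = %d strata)\n", x$stratum, x$n))
  cat(sprintf("  slope K = %.4f (SE %.4f, p = %.3g), adj. R^2 = %.4f\n",
              x$slope_k, x$se_slope, x$p_slope, x$adj_r2))
  invisible(x)
}

#' Weighted aggregation of samples to one profile per language
#'
#' Languages sampled more than once (dialects, elicitation variants) are
#' collapsed to a single pair of statistics per ISO code by weighted
#' averaging, e.g. with speaker counts as weights. Raw statistics and their
#' base-10 logs are averaged separately (the weighted mean of logs is not the
#' log of the weighted mean).
#'
#' @param profiles A `vowel_profiles` tibble.
#' @param weights Named numeric vector (names = `sample_id`) or data frame
#'   with columns `sample_id`, `weight`; missing samples default to weight 1.
#'   Weights must be non-negative with a positive total per language.
#' @return Tibble with one row per `iso`: weighted means of `effective_de`,
#'   `fe`, `log10_effective_de`, `log10_fe`, plus `n_samples` and metadata
#'   (first family/region seen).
#' @export
aggregate_language_samples <- function(profiles, weights = NULL) {
  vd_require_columns(profiles, c("sample_id", "iso", "effective_de", "fe"),
                     "aggregate_language_samples")
  df <- tibble::as_tibble(profiles)
  if (is.null(weights)) {
    w <- rep(1, nrow(df))
  } else {
    if (is.data.frame(weights)) {
      vd_require_columns(weights, c("sample_id", "weight"),
                         "aggregate_language_samples")
      w <- weights$weight[match(df$sample_id, weights$sample_id)]
    } else {
      w <- unname(weights[df$sample_id])
    }
    w[is.na(w)] <- 1
  }
  vd_check_numeric(w, "weights", nonneg = TRUE)
  df$.w <- w
  tot <- tapply(df$.w, df$iso, sum)
  if (any(tot == 0)) {
    vd_abort(sprintf("aggregate_language_samples: all-zero weights for %s.",
                     paste(names(tot)[tot == 0], collapse = ", ")),
             "voweldisp_domain_error")
  }
  out <- dplyr::group_by(df, .data$iso)
  # log means are weighted means *of the logs*, so they are computed before
  # the raw statistics are overwritten by their aggregates
  out <- dplyr::summarise(
    out,
    family = dplyr::first(.data$family),
    region = dplyr::first(.data$region),
    n_samples = dplyr::n(),
    log10_effective_de = sum(.data$.w * log10(.data$effective_de)) /
      sum(.data$.w),
    log10_fe = sum(.data$.w * log10(.data$fe)) / sum(.data$.w),
    effective_de = sum(.data$.w * .data$effective_de) / sum(.data$.w),
    fe = sum(.data$.w * .data$fe) / sum(.data$.w),
    .groups = "drop")
  dplyr::relocate(out, "effective_de", "fe",
                  .before = "log10_effective_de")
}
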