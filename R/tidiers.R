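# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.vowel_ols <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "log10_effective_de"),
    estimate = c(x$intercept, x$slope_k),
    std.error = c(x$se_intercept, x$se_slope),
    p.value = c(summary(x$model)$coefficients[1, 4], x$p_slope))
}

#' @export
glance.vowel_ols <- function(x, ...) {
  tibble::tibble(adj.r.squared = x$adj_r2, slope_k = x$slope_k,
                 p.value = x$p_slope, nobs = x$n)
}

#' @export
tidy.vowel_lmm <- function(x, ...) {
  fixed <- tibble::tibble(
    effect = "fixed",
    term = c("(Intercept)", "log10_effective_de"),
    estimate = c(x$intercept, x$slope_k),
    std.error = c(x$se_intercept, x$se_slope),
    p.value = c(x$p_intercept, x$p_slope))
  random <- tibble::tibble(
    effect = "ran_pars",
    term = c(x$varcor$group, "Residual"),
    estimate = c(x$varcor$variance, x$resid_var),
    std.error = NA_real_, p.value = NA_real_)
  dplyr::bind_rows(fixed, random)
}

#' @export
glance.vowel_lmm <- function(x, ...) {
  tibble::tibble(slope_k = x$slope_k, conditional.r2 = x$adj_r2,
                 marginal.r2 = x$marginal_r2, converged = x$converged,
                 singular = x$singular, nobs = x$n)
}

#' @export
tidy.vowel_grouped <- function(x, ...) x$points

#' @export
glance.vowel_grouped <- function(x, ...) {
  tibble::tibble(slope_k = x$slope_k, adj.r.squared = x$adj_r2,
                 p.value = x$p_slope, n_strata = x$n)
}

#' @export
tidy.vowel_stratified <- function(x, ...) x$summary

#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$beta),
    std.error = c(x$se_intercept, x$se_beta))
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(process = x$process, logLik = x$logL, sigma2 = x$sigma2,
                 alpha = ifelse(is.null(x$alpha), NA_real_, x$alpha),
                 nobs = x$n)
}

#' @export
tidy.bivariate_bm_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("rate_", x$traits), "rho",
             paste0("ancestral_", x$traits)),
    estimate = c(unname(x$rates), x$rho, unname(x$ancestral)))
}

#' @export
glance.bivariate_bm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logL, AIC = x$aic,
                 rho = x$rho, nobs = x$n)
}
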