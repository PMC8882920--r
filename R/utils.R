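# Internal helpers shared across modules.

# Errors carry a package-specific class so callers can condition on them:
#   voweldisp_domain_error      -- invalid numeric input (out of domain)
#   voweldisp_config_error      -- bad configuration / missing columns
#   voweldisp_degenerate_error  -- geometry too degenerate for the statistic
vd_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "voweldisp_error"))
}

vd_check_numeric <- function(x, name, finite = TRUE, positive = FALSE,
                             nonneg = FALSE) {
  if (!is.numeric(x)) {
    vd_abort(sprintf("`%s` must be numeric.", name), "voweldisp_domain_error")
  }
  if (finite && any(!is.finite(x))) {
    vd_abort(sprintf("`%s` contains non-finite values.", name),
             "voweldisp_domain_error")
  }
  if (positive && any(x <= 0)) {
    vd_abort(sprintf("`%s` must be strictly positive.", name),
             "voweldisp_domain_error")
  }
  if (nonneg && any(x < 0)) {
    vd_abort(sprintf("`%s` must be non-negative.", name),
             "voweldisp_domain_error")
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the RNG alone.
vd_with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

vd_require_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    vd_abort(sprintf("%s: missing required column(s): %s", where,
                     paste(missing, collapse = ", ")),
             "voweldisp_config_error")
  }
  invisible(data)
}
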