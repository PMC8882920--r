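#' Convert frequency in Hz to the Bark psychoacoustic scale
#'
#' The Bark scale approximates the critical-band frequency resolution of human
#' hearing: it stretches the low-frequency region, where listeners discriminate
#' small frequency differences well, and compresses the high-frequency region,
#' where they do not. The conversion used here is
#' \deqn{Bark = 13\,\arctan(0.00076\,f) + 3.5\,\arctan\big((f/7500)^2\big)}
#' with the arctangent in radians. It is strictly increasing, so it preserves
#' the ordering of formants (F2 > F1 in Hz implies B2 > B1 in Bark).
#'
#' @param freq Numeric vector of frequencies in Hz; must be finite and
#'   non-negative.
#' @return Numeric vector of Bark values, in (0, ~27) for speech frequencies.
#' @examples
#' hz_to_bark(c(500, 1000, 2000))
#' @seealso [bark_to_hz()] for the numeric inverse, [add_bark()] to transform
#'   a formant table.
#' @export
hz_to_bark <- function(freq) {
  vd_check_numeric(freq, "freq", finite = TRUE, nonneg = TRUE)
  13 * atan(0.00076 * freq) + 3.5 * atan((freq / 7500)^2)
}

#' Convert Bark back to Hz
#'
#' Numeric inverse of [hz_to_bark()] by monotone root finding. Used when
#' synthetic vowels are jittered on the perceptual (Bark) scale and must be
#' written back out as Hz formant values.
#'
#' @param bark Numeric vector of Bark values in `[0, hz_to_bark(upper)]`.
#' @param upper Upper bracket for the search, in Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
bark_to_hz <- function(bark, upper = 25000) {
  vd_check_numeric(bark, "bark", finite = TRUE, nonneg = TRUE)
  max_bark <- hz_to_bark(upper)
  if (any(bark > max_bark)) {
    vd_abort(sprintf("`bark` exceeds hz_to_bark(%g) = %.3f.", upper, max_bark),
             "voweldisp_domain_error")
  }
  # vectorized Newton iteration; the map is smooth and strictly increasing,
  # so a coarse-grid start plus a handful of steps converges to ~1e-12 Bark
  grid_f <- seq(0, upper, length.out = 512)
  grid_b <- hz_to_bark(grid_f)
  f <- stats::approx(grid_b, grid_f, xout = bark, rule = 2)$y
  dbark <- function(f) {
    13 * 0.00076 / (1 + (0.00076 * f)^2) +
      3.5 * (2 * f / 7500^2) / (1 + (f / 7500)^4)
  }
  for (i in 1:8) {
    step <- (hz_to_bark(f) - bark) / dbark(f)
    f <- pmin(pmax(f - step, 0), upper)
    if (max(abs(step)) < 1e-9) break
  }
  f[bark == 0] <- 0
  f
}

#' Add Bark-transformed formant columns to a formant table
#'
#' Appends `b1` and `b2` columns (Bark transforms of `f1` and `f2`) to a
#' long-format formant table, after checking the per-token invariant
#' `f2 > f1`. Because the Bark map is strictly increasing this guarantees
#' `b2 > b1` for every token.
#'
#' @param data Data frame with numeric columns `f1` and `f2` in Hz.
#' @return The input as a tibble with added `b1`, `b2` columns.
#' @examples
#' add_bark(tibble::tibble(vowel = c("i", "a"), f1 = c(280, 710),
#'                         f2 = c(2250, 1100)))
#' @export
add_bark <- function(data) {
  vd_require_columns(data, c("f1", "f2"), "add_bark")
  vd_check_numeric(data$f1, "f1", positive = TRUE)
  vd_check_numeric(data$f2, "f2", positive = TRUE)
  bad <- which(data$f2 <= data$f1)
  if (length(bad)) {
    vd_abort(sprintf(
      "add_bark: %d token(s) violate f2 > f1 (rows: %s).",
      length(bad), paste(utils::head(bad, 10), collapse = ", ")),
      "voweldisp_domain_error")
  }
  dplyr::mutate(tibble::as_tibble(data),
                b1 = hz_to_bark(.data$f1),
                b2 = hz_to_bark(.data$f2))
}
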