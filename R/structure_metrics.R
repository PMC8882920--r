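# Per-system structural statistics of vowel inventories, all computed on the
# Bark scale: dispersion estimate (DE), convex-hull acoustic space estimate
# (ASE), effective dispersion per unit area (Effective DE = DE / ASE), and
# the focalization estimate (FE).

#' Dispersion estimate of a vowel inventory
#'
#' The default (`geometric_mean`) is the geometric mean of all n(n-1)/2
#' pairwise perceptual (Euclidean Bark) distances: inventories whose vowels
#' crowd together have small DE. The `inverse_square_sum` variant instead
#' accumulates the reciprocal squared distances (a Liljencrants-Lindblom
#' style crowdedness energy); it grows when vowels crowd. Exactly coincident
#' points make the geometric mean identically zero, so they raise an error
#' under the default variant rather than silently degenerating.
#'
#' @param b1,b2 Bark coordinates of the vowels.
#' @param variant `"geometric_mean"` (default) or `"inverse_square_sum"`.
#' @return A single positive number (Bark for the default variant).
#' @examples
#' # pairwise distances {1, 2, 4} -> geometric mean 2
#' dispersion_estimate(c(0, 1, 0), c(0, 0, 4))
#' @export
dispersion_estimate <- function(b1, b2,
                                variant = c("geometric_mean",
                                            "inverse_square_sum")) {
  variant <- match.arg(variant)
  vd_check_numeric(b1, "b1"); vd_check_numeric(b2, "b2")
  if (length(b1) < 2) {
    vd_abort("dispersion_estimate: need >= 2 points.",
             "voweldisp_domain_error")
  }
  d <- pairwise_distances(b1, b2)
  if (variant == "geometric_mean") {
    if (any(d == 0)) {
      vd_abort(paste0("dispersion_estimate: exactly coincident points make ",
                      "the geometric-mean DE zero; deduplicate or perturb."),
               "voweldisp_degenerate_error")
    }
    exp(mean(log(d)))
  } else {
    if (any(d == 0)) {
      vd_abort("dispersion_estimate: coincident points give infinite 1/d^2.",
               "voweldisp_degenerate_error")
    }
    sum(1 / d^2)
  }
}

#' Effective dispersion estimate
#'
#' Dispersion per unit of acoustic space: `de / ase`. Normalizing by the hull
#' area removes the confound that, at a given inventory size, a larger vowel
#' space mechanically inflates mean pairwise distance.
#'
#' @param de Dispersion estimate (> 0).
#' @param ase Acoustic space estimate, the hull area in Bark^2 (> 0).
#' @return Effective DE in Bark^-1 (for the geometric-mean DE).
#' @export
effective_de <- function(de, ase) {
  vd_check_numeric(de, "de", positive = TRUE)
  if (!is.numeric(ase) || any(!is.finite(ase)) || any(ase <= 0)) {
    vd_abort("effective_de: `ase` must be a finite positive area.",
             "voweldisp_degenerate_error")
  }
  de / ase
}

#' Focalization estimate of a vowel inventory
#'
#' Sum over vowels of the inverse squared Bark distance between the first two
#' formants: \eqn{FE = \sum_i 1/(B2_i - B1_i)^2}. Vowels whose adjacent
#' formants lie close together (focal vowels, e.g. a cardinal /u/) contribute
#' large terms; every added vowel strictly increases FE.
#'
#' @param b1,b2 Bark values of F1 and F2 per vowel; requires `b2 > b1`.
#' @param label Optional vowel labels used in error messages.
#' @return FE in Bark^-2.
#' @examples
#' focalization_estimate(1, 3) # single vowel with gap 2 -> 0.25
#' @export
focalization_estimate <- function(b1, b2, label = NULL) {
  vd_check_numeric(b1, "b1"); vd_check_numeric(b2, "b2")
  bad <- which(b2 <= b1)
  if (length(bad)) {
    who <- if (is.null(label)) paste("token", bad) else label[bad]
    vd_abort(sprintf("focalization_estimate: b2 <= b1 for %s.",
                     paste(who, collapse = ", ")),
             "voweldisp_domain_error")
  }
  sum(1 / (b2 - b1)^2)
}

#' Structural profile of every vowel system in a formant table
#'
#' The workhorse of the synchronic analysis. For each `sample_id` the Hz
#' formants are Bark-transformed, then four statistics are computed: `de`
#' (dispersion estimate over all tokens), `ase` (convex-hull area over
#' deduplicated points), `effective_de = de / ase`, and `fe` (focalization
#' over all tokens), plus their base-10 logs. Systems that cannot support the
#' geometry (fewer than `min_vowels` vowels, collinear configurations, or
#' exactly duplicated points under the geometric-mean DE) are skipped, and
#' the skips are recorded in `attr(, "skipped")` rather than silently lost.
#'
#' @param data Formant tibble with columns `sample_id, iso, family, region,
#'   vowel, f1, f2` (Hz), e.g. from [read_formant_table()] or
#'   [simulate_typology()].
#' @param variant Dispersion variant, see [dispersion_estimate()].
#' @param min_vowels Minimum inventory size profiled (default 3, the hull
#'   floor).
#' @return Tibble of class `vowel_profiles`, one row per profiled system:
#'   `sample_id, iso, family, region, n_vowels, de, ase, effective_de, fe,
#'   log10_effective_de, log10_fe`. Skipped systems in `attr(, "skipped")`
#'   (see [skipped_systems()]).
#' @export
profile_systems <- function(data, variant = c("geometric_mean",
                                              "inverse_square_sum"),
                            min_vowels = 3) {
  variant <- match.arg(variant)
  vd_require_columns(data, c("sample_id", "f1", "f2"), "profile_systems")
  data <- tibble::as_tibble(data)
  if (!"iso" %in% names(data)) data$iso <- NA_character_
  if (!"family" %in% names(data)) data$family <- NA_character_
  if (!"region" %in% names(data)) data$region <- NA_character_
  bark <- add_bark(data)
  groups <- split(bark, bark$sample_id)
  rows <- vector("list", length(groups))
  skipped <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    sid <- g$sample_id[[1]]
    if (nrow(g) < min_vowels) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(sample_id = sid,
                       reason = sprintf("%d vowel(s) < min_vowels = %d",
                                        nrow(g), min_vowels))
      next
    }
    res <- tryCatch({
      de <- dispersion_estimate(g$b1, g$b2, variant = variant)
      ase <- polygon_area(convex_hull(g$b1, g$b2))
      fe <- focalization_estimate(g$b1, g$b2, label = g$vowel)
      ede <- effective_de(de, ase)
      tibble::tibble(sample_id = sid, iso = g$iso[[1]],
                     family = g$family[[1]], region = g$region[[1]],
                     n_vowels = nrow(g), de = de, ase = ase,
                     effective_de = ede, fe = fe,
                     log10_effective_de = log10(ede), log10_fe = log10(fe))
    }, voweldisp_error = function(e) {
      tibble::tibble(sample_id = sid, reason = conditionMessage(e))
    })
    if ("reason" %in% names(res)) {
      skipped[[length(skipped) + 1]] <- res
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  # restore input encounter order of samples
  first_seen <- unique(data$sample_id)
  out <- out[order(match(out$sample_id, first_seen)), , drop = FALSE]
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  class(out) <- c("vowel_profiles", class(out))
  out
}

#' Systems skipped by [profile_systems()]
#'
#' @param profiles A `vowel_profiles` tibble.
#' @return Tibble with columns `sample_id`, `reason` (zero rows if nothing
#'   was skipped).
#' @export
skipped_systems <- function(profiles) {
  s <- attr(profiles, "skipped")
  if (is.null(s) || !nrow(s)) {
    tibble::tibble(sample_id = character(), reason = character())
  } else {
    s
  }
}

#' Write a structural profile table as delimited text
#'
#' @param profiles A `vowel_profiles` tibble.
#' @param file Output path.
#' @param delim Field delimiter (default tab).
#' @return `file`, invisibly.
#' @export
write_profile_table <- function(profiles, file, delim = "\t") {
  readr::write_delim(tibble::as_tibble(profiles), file, delim = delim)
  invisible(file)
}
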