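#' Describe the column layout of a formant table
#'
#' Export dialects of cross-linguistic formant databases differ in their header
#' names, so the reader takes an explicit mapping from the canonical fields to
#' the column names present in the file. Metadata fields mapped to `NULL` are
#' filled with `NA`.
#'
#' @param sample_id,iso,family,region,vowel,f1,f2 Column names in the source
#'   file for each canonical field.
#' @param elicitation,quantity_class Optional metadata columns (`NULL` to
#'   skip).
#' @return A named list of class `formant_columns`.
#' @export
formant_columns <- function(sample_id = "sample_id", iso = "iso",
                            family = "family", region = "region",
                            vowel = "vowel", f1 = "f1", f2 = "f2",
                            elicitation = NULL, quantity_class = NULL) {
  structure(list(sample_id = sample_id, iso = iso, family = family,
                 region = region, vowel = vowel, f1 = f1, f2 = f2,
                 elicitation = elicitation, quantity_class = quantity_class),
            class = "formant_columns")
}

#' Read a delimited formant table into a vowel-system tibble
#'
#' Reads one vowel token per row, maps columns via a [formant_columns()]
#' configuration, coerces formants to numeric, and enforces the per-token
#' invariants (`f1 > 0`, `f2 > f1`, both finite). Offending rows are dropped,
#' not fatal: the parse report attached to the result records every dropped
#' row and its reason. Row order within each sample is preserved.
#'
#' @param file Path to a delimited text file (UTF-8), or a literal string of
#'   its contents via `I()`.
#' @param columns A [formant_columns()] mapping.
#' @param delim Field delimiter; `NULL` guesses between tab and comma.
#' @return A tibble with columns `sample_id, iso, family, region, elicitation,
#'   quantity_class, vowel, f1, f2`, one row per retained token, with the
#'   parse report in `attr(, "parse_report")` (see [parse_report()]).
#' @export
read_formant_table <- function(file, columns = formant_columns(),
                               delim = NULL) {
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  required <- unlist(columns[c("sample_id", "iso", "family", "region",
                               "vowel", "f1", "f2")])
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    vd_abort(sprintf("read_formant_table: column(s) not found in file: %s",
                     paste(missing, collapse = ", ")),
             "voweldisp_config_error")
  }
  pick <- function(field) {
    nm <- columns[[field]]
    if (is.null(nm)) rep(NA_character_, nrow(raw)) else raw[[nm]]
  }
  out <- tibble::tibble(
    sample_id = pick("sample_id"),
    iso = pick("iso"),
    family = pick("family"),
    region = pick("region"),
    elicitation = pick("elicitation"),
    quantity_class = pick("quantity_class"),
    vowel = pick("vowel"),
    f1 = suppressWarnings(as.numeric(pick("f1"))),
    f2 = suppressWarnings(as.numeric(pick("f2")))
  )
  reason <- dplyr::case_when(
    is.na(out$f1) | is.na(out$f2) ~ "non-numeric or missing formant",
    out$f1 <= 0 | out$f2 <= 0 ~ "non-positive formant",
    out$f2 <= out$f1 ~ "F2 <= F1",
    TRUE ~ NA_character_
  )
  dropped <- tibble::tibble(row = which(!is.na(reason)),
                            sample_id = out$sample_id[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  kept <- out[is.na(reason), , drop = FALSE]
  report <- list(rows_read = nrow(raw),
                 rows_kept = nrow(kept),
                 systems_built = dplyr::n_distinct(kept$sample_id),
                 dropped = dropped)
  attr(kept, "parse_report") <- report
  kept
}

#' Retrieve the parse report attached by [read_formant_table()]
#'
#' @param data A tibble returned by [read_formant_table()].
#' @return A list with `rows_read`, `rows_kept`, `systems_built`, and a
#'   `dropped` tibble of per-row drop reasons.
#' @export
parse_report <- function(data) {
  attr(data, "parse_report")
}

#' Write a formant table as delimited text
#'
#' Inverse of [read_formant_table()] with canonical column names; reading the
#' written file back reproduces the same systems.
#'
#' @param data Formant tibble (canonical columns).
#' @param file Output path.
#' @param delim Field delimiter (default tab).
#' @return `file`, invisibly.
#' @export
write_formant_table <- function(data, file, delim = "\t") {
  vd_require_columns(data, c("sample_id", "iso", "family", "region",
                             "vowel", "f1", "f2"), "write_formant_table")
  readr::write_delim(data, file, delim = delim)
  invisible(file)
}

#' Flag vowel systems with structural problems
#'
#' A reporting pass over a formant table: flags systems that cannot support
#' hull-based statistics (< 3 vowels), systems containing tokens at exactly
#' coincident (f1, f2) coordinates (which make the geometric-mean dispersion
#' degenerate), and systems with missing language metadata. Nothing is
#' filtered here; acting on the flags is the caller's explicit choice.
#'
#' @param data Formant tibble (canonical columns).
#' @return Tibble with columns `sample_id`, `flag`, `detail`; zero rows if
#'   every system is clean.
#' @export
validate_vowel_systems <- function(data) {
  vd_require_columns(data, c("sample_id", "f1", "f2"),
                     "validate_vowel_systems")
  per <- dplyr::group_by(tibble::as_tibble(data), .data$sample_id)
  flags <- dplyr::summarise(
    per,
    insufficient = dplyr::n() < 3,
    duplicates = anyDuplicated(cbind(.data$f1, .data$f2)) > 0,
    missing_meta = any(is.na(.data$iso) | is.na(.data$family) |
                         is.na(.data$region)),
    n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(
    tibble::tibble(sample_id = flags$sample_id[flags$insufficient],
                   flag = "insufficient for hull",
                   detail = sprintf("%d vowel(s); >= 3 required",
                                    flags$n[flags$insufficient])),
    tibble::tibble(sample_id = flags$sample_id[flags$duplicates],
                   flag = "duplicate coordinates",
                   detail = "two or more tokens share exact (f1, f2)"),
    tibble::tibble(sample_id = flags$sample_id[flags$missing_meta],
                   flag = "missing metadata",
                   detail = "iso, family, or region is NA")
  )
  dplyr::arrange(out, .data$sample_id, .data$flag)
}
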