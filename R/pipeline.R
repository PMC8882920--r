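# Stage runners: compose the modules end-to-end and write their outputs as
# delimited text plus a machine-readable JSON run manifest (configuration,
# seed, package version, input checksums) for provenance. These are the
# package's orchestration surface; each returns its results invisibly so
# the stages also compose in R without touching disk twice.

write_manifest <- function(dir, stage, config, inputs = character(0)) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(
    stage = stage,
    package = "voweldisp",
    version = as.character(utils::packageVersion("voweldisp")),
    config = config,
    input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the simulation stage: emit a full synthetic dataset bundle
#'
#' Writes a formant table (`formants.tsv`), a Yule tree (`tree.nwk`), a
#' tip-trait table evolved on it (`traits.tsv`), the truth records
#' (`truth.json`), and a run manifest to `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving every random draw.
#' @param n_systems,n_tips Scale of the typology and the tree.
#' @param ... Further arguments to [simulate_typology()].
#' @return Invisibly, a list with the typology, tree, and traits.
#' @export
run_simulate <- function(out_dir, seed, n_systems = 532, n_tips = 33, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  typ <- simulate_typology(n_systems = n_systems, seed = seed, ...)
  tree <- simulate_yule_tree(n_tips = n_tips, seed = seed + 1)
  traits <- simulate_bivariate_traits(tree, process = "BM",
                                      rates = c(1, 1), rho = -0.7,
                                      seed = seed + 2)
  write_formant_table(typ$formants, file.path(out_dir, "formants.tsv"))
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  readr::write_delim(traits, file.path(out_dir, "traits.tsv"), delim = "\t")
  jsonlite::write_json(list(typology = typ$truth,
                            traits = attr(traits, "truth")),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 list(seed = seed, n_systems = n_systems, n_tips = n_tips))
  invisible(list(typology = typ, tree = tree, traits = traits))
}

#' Run the profiling stage: formant table in, profile table out
#'
#' Reads and validates a delimited formant table, profiles every system, and
#' writes `profiles.tsv`, `skipped.tsv` (systems excluded from hull-based
#' statistics, with reasons), and a manifest.
#'
#' @param input Path to a delimited formant table.
#' @param out_dir Output directory.
#' @param columns A [formant_columns()] mapping.
#' @param variant Dispersion variant (see [dispersion_estimate()]).
#' @return Invisibly, the `vowel_profiles` tibble.
#' @export
run_profile <- function(input, out_dir, columns = formant_columns(),
                        variant = "geometric_mean") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_formant_table(input, columns = columns)
  profiles <- profile_systems(data, variant = variant)
  write_profile_table(profiles, file.path(out_dir, "profiles.tsv"))
  readr::write_delim(skipped_systems(profiles),
                     file.path(out_dir, "skipped.tsv"), delim = "\t")
  write_manifest(out_dir, "profile",
                 list(input = input, variant = variant,
                      rows_read = parse_report(data)$rows_read,
                      rows_dropped = nrow(parse_report(data)$dropped)),
                 inputs = input)
  invisible(profiles)
}

#' Run the dependence stage: correlation, regressions, stratified reports
#'
#' Computes the global Spearman correlation, the log-log OLS, the nested
#' random-intercept mixed model, stratified per-region and per-family fits,
#' and group-mean regressions, writing each as delimited text in `out_dir`.
#'
#' @param profiles A `vowel_profiles` tibble or a path to `profiles.tsv`.
#' @param out_dir Output directory.
#' @param min_n Minimum samples for a stratum to be fitted.
#' @return Invisibly, a list of all fitted objects.
#' @export
run_dependence <- function(profiles, out_dir, min_n = 11) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_path <- character(0)
  if (is.character(profiles)) {
    input_path <- profiles
    profiles <- readr::read_delim(profiles, delim = "\t",
                                  show_col_types = FALSE, progress = FALSE)
  }
  rho <- spearman_rho(profiles$effective_de, profiles$fe)
  ols <- fit_loglog_ols(profiles)
  lmm <- fit_mixed_model(profiles)
  by_region <- stratified_fits(profiles, "region", min_n = min_n)
  by_family <- stratified_fits(profiles, "family", min_n = min_n)
  gm_region <- tryCatch(group_mean_regression(profiles, "region"),
                        voweldisp_error = function(e) NULL)
  gm_family <- tryCatch(group_mean_regression(profiles, "family"),
                        voweldisp_error = function(e) NULL)
  global <- dplyr::bind_rows(
    tibble::tibble(quantity = "spearman_rho", value = rho$rho),
    tibble::tibble(quantity = "spearman_p", value = rho$p_value),
    tibble::tibble(quantity = "ols_slope_k", value = ols$slope_k),
    tibble::tibble(quantity = "ols_adj_r2", value = ols$adj_r2),
    tibble::tibble(quantity = "mixed_slope_k", value = lmm$slope_k),
    tibble::tibble(quantity = "mixed_conditional_r2", value = lmm$adj_r2),
    tibble::tibble(quantity = "n", value = ols$n))
  readr::write_delim(global, file.path(out_dir, "global.tsv"), delim = "\t")
  readr::write_delim(by_region$summary,
                     file.path(out_dir, "stratified_region.tsv"),
                     delim = "\t")
  readr::write_delim(by_family$summary,
                     file.path(out_dir, "stratified_family.tsv"),
                     delim = "\t")
  if (!is.null(gm_region)) {
    readr::write_delim(gm_region$points,
                       file.path(out_dir, "group_means_region.tsv"),
                       delim = "\t")
  }
  write_manifest(out_dir, "dependence", list(min_n = min_n),
                 inputs = input_path)
  invisible(list(spearman = rho, ols = ols, mixed = lmm,
                 by_region = by_region, by_family = by_family,
                 gm_region = gm_region, gm_family = gm_family))
}

#' Run the phylogenetic stage: contrasts, bivariate models, PGLS
#'
#' For a tree (or a list of trees carrying posterior uncertainty) and a
#' tip-trait table of (effective_de, fe) pairs: independent-contrast
#' correlations (raw and log10), the dependent-vs-independent bivariate BM
#' comparison, and PGLS under BM and OU with their likelihood-ratio test.
#' Results are written to `phylo_report.tsv`; with multiple trees an
#' across-tree mean/SD summary is written instead.
#'
#' @param tree A `phylo`, a list of them, or a path to a Newick file.
#' @param traits Data frame with `tip`, `effective_de`, `fe` columns, or a
#'   path to such a delimited file.
#' @param out_dir Output directory.
#' @param response `"fe"` (default) or `"effective_de"`: the PGLS response.
#' @return Invisibly, the per-tree report tibble (plus the across-tree
#'   summary when several trees are given).
#' @export
run_phylo <- function(tree, traits, out_dir, response = c("fe",
                                                          "effective_de")) {
  response <- match.arg(response)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(tree)) {
    inputs <- c(inputs, tree)
    tree <- read_newick(tree)
  }
  if (is.character(traits)) {
    inputs <- c(inputs, traits)
    traits <- readr::read_delim(traits, delim = "\t",
                                show_col_types = FALSE, progress = FALSE)
  }
  vd_require_columns(traits, c("tip", "effective_de", "fe"), "run_phylo")
  predictor <- setdiff(c("fe", "effective_de"), response)
  fml <- stats::as.formula(paste(response, "~", predictor))
  traits <- dplyr::mutate(traits,
                          log10_effective_de = log10(.data$effective_de),
                          log10_fe = log10(.data$fe))
  lfml <- stats::as.formula(paste0("log10_", response, " ~ log10_",
                                   predictor))
  analyse <- function(tr) {
    tr <- resolve_polytomies(tr)
    pic_x <- independent_contrasts(tr, traits[c("tip", "effective_de")])
    pic_y <- independent_contrasts(tr, traits[c("tip", "fe")])
    pic_lx <- independent_contrasts(tr, traits[c("tip",
                                                 "log10_effective_de")])
    pic_ly <- independent_contrasts(tr, traits[c("tip", "log10_fe")])
    ind <- fit_bivariate_bm(traits, tr, model = "independent")
    dep <- fit_bivariate_bm(traits, tr, model = "dependent")
    cmp <- compare_models(ind, dep)
    bm <- pgls_fit(traits, tr, fml, process = "BM")
    ou <- pgls_fit(traits, tr, fml, process = "OU")
    lrt <- likelihood_ratio_test(bm, ou)
    tibble::tibble(
      pic_rho_raw = contrast_correlation(pic_x, pic_y),
      pic_rho_log10 = contrast_correlation(pic_lx, pic_ly),
      bm_rho = dep$rho,
      bm_lrt_stat = cmp$statistic, bm_lrt_p = cmp$p_value,
      pgls_bm_beta = bm$beta, pgls_bm_logL = bm$logL,
      pgls_ou_beta = ou$beta, pgls_ou_alpha = ou$alpha,
      pgls_ou_logL = ou$logL,
      bm_ou_lr_stat = lrt$statistic, bm_ou_lr_p = lrt$p_value)
  }
  if (inherits(tree, "phylo")) {
    report <- analyse(tree)
    readr::write_delim(report, file.path(out_dir, "phylo_report.tsv"),
                       delim = "\t")
    write_manifest(out_dir, "phylo",
                   list(response = response, n_trees = 1), inputs = inputs)
    invisible(report)
  } else {
    res <- across_trees(tree, analyse)
    readr::write_delim(res$per_tree,
                       file.path(out_dir, "phylo_per_tree.tsv"),
                       delim = "\t")
    readr::write_delim(res$summary,
                       file.path(out_dir, "phylo_report.tsv"), delim = "\t")
    write_manifest(out_dir, "phylo",
                   list(response = response, n_trees = length(tree)),
                   inputs = inputs)
    invisible(res)
  }
}
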