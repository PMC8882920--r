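# Synthetic-data generators: vowel systems and typologies with hierarchical
# grouping structure, Yule trees, and bivariate traits evolved along trees
# under BM or OU with known parameters. Every generator is a pure function
# of its configuration and seed, and every latent parameter is returned in a
# truth record so estimators can be scored against ground truth.

#' Canonical vowel prototype anchors
#'
#' Fourteen cardinal-style vowel qualities with typical (F1, F2) values in
#' Hz, used as anchors by the prototype-jitter generator. Labels are ASCII
#' stand-ins for IPA symbols (E = open-mid front, ae = near-open front,
#' A = open back, V = wedge, O = open-mid back, U = near-close back,
#' @ = schwa, I = near-close front). The specific numbers matter only in
#' their qualitative layout: front vowels with high F2, back rounded vowels
#' with low, close formants, and F2 > F1 throughout.
#'
#' @return Tibble with columns `vowel`, `f1`, `f2`.
#' @export
vowel_prototypes <- function() {
  path <- system.file("extdata", "vowel_prototypes.csv",
                      package = "voweldisp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Speech-plausible formant bounds used by both generation modes (Hz).
f1_range <- c(150, 1100)
f2_range <- c(450, 3200)

#' Simulate one vowel system
#'
#' `prototype_jitter` (default) draws `n_vowels` anchors from
#' [vowel_prototypes()] (without replacement unless `replace = TRUE`), adds
#' Gaussian jitter of SD `jitter_sd` on the Bark scale (where perceptual
#' distance is uniform), and maps the result back to Hz by numeric inversion
#' of the Bark transform. `uniform_trapezoid` draws points uniformly from a
#' trapezoidal F1 x F2 region that narrows as F1 rises, mimicking the shape
#' of the acoustic vowel space. Both modes enforce F2 > F1 and the plausible
#' frequency ranges by rejection.
#'
#' @param n_vowels Inventory size (>= 3 for downstream geometry).
#' @param mode `"prototype_jitter"` or `"uniform_trapezoid"`.
#' @param jitter_sd Jitter SD in Bark (prototype mode).
#' @param prototypes Anchor table; defaults to [vowel_prototypes()].
#' @param replace Sample anchors with replacement (needed when `n_vowels`
#'   exceeds the number of anchors).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Tibble with columns `vowel`, `f1`, `f2` (Hz).
#' @export
simulate_vowel_system <- function(n_vowels,
                                  mode = c("prototype_jitter",
                                           "uniform_trapezoid"),
                                  jitter_sd = 0.3,
                                  prototypes = vowel_prototypes(),
                                  replace = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (n_vowels < 1) {
    vd_abort("simulate_vowel_system: n_vowels must be >= 1.",
             "voweldisp_config_error")
  }
  vd_with_seed(seed, {
    if (mode == "prototype_jitter") {
      if (!replace && n_vowels > nrow(prototypes)) {
        vd_abort(sprintf(
          paste0("simulate_vowel_system: n_vowels = %d exceeds the %d ",
                 "anchors; use replace = TRUE to jitter with replacement."),
          n_vowels, nrow(prototypes)), "voweldisp_config_error")
      }
      idx <- sample.int(nrow(prototypes), n_vowels, replace = replace)
      base <- prototypes[idx, , drop = FALSE]
      b1 <- hz_to_bark(base$f1); b2 <- hz_to_bark(base$f2)
      lo1 <- hz_to_bark(f1_range[1]); hi1 <- hz_to_bark(f1_range[2])
      lo2 <- hz_to_bark(f2_range[1]); hi2 <- hz_to_bark(f2_range[2])
      j1 <- b1 + stats::rnorm(n_vowels, 0, jitter_sd)
      j2 <- b2 + stats::rnorm(n_vowels, 0, jitter_sd)
      for (k in 1:100) { # rejection: keep b2 > b1 and bounds
        bad <- which(j2 <= j1 + 1e-6 | j1 < lo1 | j1 > hi1 |
                       j2 < lo2 | j2 > hi2)
        if (!length(bad)) break
        j1[bad] <- b1[bad] + stats::rnorm(length(bad), 0, jitter_sd)
        j2[bad] <- b2[bad] + stats::rnorm(length(bad), 0, jitter_sd)
      }
      tibble::tibble(vowel = base$vowel,
                     f1 = bark_to_hz(j1), f2 = bark_to_hz(j2))
    } else {
      f1 <- numeric(n_vowels); f2 <- numeric(n_vowels)
      for (i in seq_len(n_vowels)) {
        repeat {
          a <- stats::runif(1, f1_range[1], 850)
          # upper F2 edge slopes down as F1 rises (front-to-back taper)
          upper <- 2500 - 1.8 * (a - f1_range[1])
          lower <- a + 250
          if (upper <= lower) next
          b <- stats::runif(1, lower, upper)
          if (b > a) break
        }
        f1[i] <- a; f2[i] <- b
      }
      tibble::tibble(vowel = sprintf("v%d", seq_len(n_vowels)),
                     f1 = f1, f2 = f2)
    }
  })
}

#' Simulate a cross-linguistic vowel typology
#'
#' Generates a sample collection shaped like a worldwide formant database:
#' systems grouped into languages, languages into families and regions, with
#' inventory sizes drawn uniformly from `size_range`. Defaults emulate the
#' scale of a large cross-linguistic survey: 532 samples over ~357 languages,
#' 39 families, and 8 regions.
#'
#' Two regimes:
#' \itemize{
#'   \item Emergent (`exponent = NULL`, default): every system's vowels are
#'     simulated via [simulate_vowel_system()] and the structural statistics
#'     are whatever the geometry produces; no dependence is imposed.
#'   \item Imposed power law (`exponent = k`): per-sample
#'     `log10(effective_de)` is drawn Normal(`ede_mean`, `ede_sd`) and
#'     `log10(fe) = intercept + k * log10(effective_de) + family effect +
#'     region effect + noise`, with Normal(0, `family_sd`) and
#'     Normal(0, `region_sd`) intercepts; the pairs are reported directly in
#'     `$profiles`, ready for the regression and mixed-model estimators.
#' }
#'
#' @param n_systems,n_languages,n_families,n_regions Sizes of the hierarchy.
#' @param size_range Inventory size range, inclusive (default 3-15).
#' @param mode,jitter_sd Passed to [simulate_vowel_system()] (emergent mode).
#' @param exponent Imposed power-law exponent k, or `NULL` for emergent.
#' @param intercept,ede_mean,ede_sd Log-scale location parameters of the
#'   imposed regime.
#' @param family_sd,region_sd,resid_sd Random-intercept and residual SDs on
#'   the log10 scale (imposed regime).
#' @param seed Integer seed (required: generators are pure functions of
#'   configuration and seed).
#' @return List of class `vowel_typology`: `$samples` (per-sample metadata),
#'   `$formants` (long token table, emergent mode only), `$profiles`
#'   (imposed mode only: sample-level effective_de/fe pairs), and `$truth`
#'   (every latent parameter, including the drawn family/region effects).
#' @export
simulate_typology <- function(n_systems = 532, n_languages = 357,
                              n_families = 39, n_regions = 8,
                              size_range = c(3, 15),
                              mode = "prototype_jitter", jitter_sd = 0.3,
                              exponent = NULL, intercept = -0.5,
                              ede_mean = -0.5, ede_sd = 0.25,
                              family_sd = 0.2, region_sd = 0.1,
                              resid_sd = 0.05, seed) {
  if (missing(seed)) {
    vd_abort("simulate_typology: a seed is required.",
             "voweldisp_config_error")
  }
  if (n_languages > n_systems) n_languages <- n_systems
  vd_with_seed(seed, {
    lang_family <- sample.int(n_families, n_languages, replace = TRUE)
    lang_region <- sample.int(n_regions, n_languages, replace = TRUE)
    # every language gets one sample; the surplus is assigned at random
    lang_of <- c(seq_len(n_languages),
                 sample.int(n_languages, n_systems - n_languages,
                            replace = TRUE))
    samples <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n_systems)),
      iso = sprintf("L%03d", lang_of),
      family = sprintf("F%02d", lang_family[lang_of]),
      region = sprintf("R%d", lang_region[lang_of]),
      n_vowels = sample(seq(size_range[1], size_range[2]), n_systems,
                        replace = TRUE))
    truth <- list(n_systems = n_systems, n_languages = n_languages,
                  n_families = n_families, n_regions = n_regions,
                  size_range = size_range, mode = mode,
                  jitter_sd = jitter_sd, exponent = exponent, seed = seed)
    if (is.null(exponent)) {
      protos <- vowel_prototypes()
      formants <- purrr::map_dfr(seq_len(n_systems), function(i) {
        nv <- samples$n_vowels[i]
        sys <- simulate_vowel_system(nv, mode = mode, jitter_sd = jitter_sd,
                                     prototypes = protos,
                                     replace = nv > nrow(protos))
        dplyr::bind_cols(samples[i, c("sample_id", "iso", "family",
                                      "region")][rep(1, nv), ], sys)
      })
      structure(list(samples = samples, formants = formants,
                     profiles = NULL, truth = truth),
                class = "vowel_typology")
    } else {
      fam_eff <- stats::setNames(stats::rnorm(n_families, 0, family_sd),
                                 sprintf("F%02d", seq_len(n_families)))
      reg_eff <- stats::setNames(stats::rnorm(n_regions, 0, region_sd),
                                 sprintf("R%d", seq_len(n_regions)))
      lx <- stats::rnorm(n_systems, ede_mean, ede_sd)
      ly <- unname(intercept + exponent * lx + fam_eff[samples$family] +
                     reg_eff[samples$region] +
                     stats::rnorm(n_systems, 0, resid_sd))
      profiles <- dplyr::mutate(
        samples,
        effective_de = 10^lx, fe = 10^ly,
        log10_effective_de = lx, log10_fe = ly)
      truth <- c(truth, list(intercept = intercept, ede_mean = ede_mean,
                             ede_sd = ede_sd, family_sd = family_sd,
                             region_sd = region_sd, resid_sd = resid_sd,
                             family_effects = fam_eff,
                             region_effects = reg_eff))
      structure(list(samples = samples, formants = NULL,
                     profiles = profiles, truth = truth),
                class = "vowel_typology")
    }
  })
}

#' Simulate a Yule (pure-birth) tree
#'
#' Stand-in phylogenies for comparative analyses. With `n_tips` given the
#' tree is conditioned on its present-day tip count; with `time` given
#' instead, lineages branch at rate `birth_rate` for a fixed duration and
#' the realized tip count is random with expectation `exp(birth_rate *
#' time)`.
#'
#' @param n_tips Number of tips (ignored when `time` is given).
#' @param birth_rate Speciation rate (> 0).
#' @param time Fixed simulation duration (alternative to `n_tips`).
#' @param rescale_depth If `TRUE`, rescale branch lengths to unit tree
#'   depth.
#' @param seed Integer seed.
#' @return A `phylo` with tips labeled `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips = NULL, birth_rate = 1, time = NULL,
                               rescale_depth = FALSE, seed = NULL) {
  if (birth_rate <= 0) {
    vd_abort("simulate_yule_tree: birth_rate must be > 0.",
             "voweldisp_config_error")
  }
  if (is.null(n_tips) && is.null(time)) {
    vd_abort("simulate_yule_tree: give n_tips or time.",
             "voweldisp_config_error")
  }
  vd_with_seed(seed, {
    tree <- if (!is.null(time)) {
      yule_forward(birth_rate, time)
    } else {
      if (n_tips < 2) {
        vd_abort("simulate_yule_tree: n_tips must be >= 2.",
                 "voweldisp_config_error")
      }
      ape::rphylo(n_tips, birth = birth_rate, death = 0)
    }
    tree$tip.label <- sprintf("t%d", seq_along(tree$tip.label))
    if (rescale_depth) {
      tree$edge.length <- tree$edge.length /
        max(ape::node.depth.edgelength(tree))
    }
    tree
  })
}

# Forward Yule simulation from a single ancestral lineage for a fixed
# duration: waiting times Exp(k * lambda), a uniformly chosen lineage splits
# at each event, so the tip count at time T has expectation exp(lambda * T).
# Returns an ape phylo (a one-tip stub when no split happens).
yule_forward <- function(birth_rate, time) {
  # active lineages: parent node id (0 = root stub) and birth time
  parent <- c(0); born <- c(0)
  splits <- list() # per internal node: (parent, born)
  t_now <- 0
  repeat {
    k <- length(parent)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    if (t_now >= time) break
    i <- sample.int(k, 1)
    # record the new internal node as (parent node id, split time)
    splits[[length(splits) + 1]] <- c(parent[i], t_now)
    node_id <- length(splits) # index into internal-node table
    parent <- c(parent[-i], node_id, node_id)
    born <- c(born[-i], t_now, t_now)
  }
  n <- length(parent)
  if (n == 1) {
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          edge.length = time, tip.label = "t1",
                          Nnode = 1L), class = "phylo"))
  }
  n_int <- length(splits)
  # phylo numbering: tips 1..n, then internals; internal i -> n + 1 + ...
  # splits[[1]] is the first split = the root
  node_num <- function(id) if (id == 0) NA_integer_ else n + id
  edges <- matrix(0L, 0, 2); lens <- numeric(0)
  for (i in seq_along(splits)) {
    p <- splits[[i]][1]; b <- splits[[i]][2]
    if (p != 0) {
      edges <- rbind(edges, c(node_num(p), n + i))
      lens <- c(lens, b - splits[[p]][2])
    }
  }
  for (i in seq_len(n)) {
    edges <- rbind(edges, c(node_num(parent[i]), i))
    lens <- c(lens, time - born[i])
  }
  storage.mode(edges) <- "integer"
  structure(list(edge = edges, edge.length = lens,
                 tip.label = sprintf("t%d", seq_len(n)),
                 Nnode = n_int),
            class = "phylo")
}

# 2x2 trait rate matrix from per-trait rates and a correlation.
rate_matrix <- function(rates, rho) {
  if (length(rates) != 2 || any(rates < 0)) {
    vd_abort("rates must be two non-negative numbers.",
             "voweldisp_config_error")
  }
  if (abs(rho) > 1) {
    vd_abort("|rho| must be <= 1.", "voweldisp_config_error")
  }
  R <- diag(rates)
  R[1, 2] <- R[2, 1] <- rho * sqrt(rates[1] * rates[2])
  R
}

# Draw one bivariate normal increment with covariance S (possibly singular).
mvn_draw <- function(mean, S) {
  if (max(abs(S)) == 0) return(mean)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  mean + as.numeric(eg$vectors %*% (sqrt(ev) * stats::rnorm(2)))
}

#' Simulate two correlated traits along a phylogeny
#'
#' Recursive simulation from the root toward the tips. Brownian motion adds
#' increments with covariance `branch length * R` where `R` is the 2x2 rate
#' matrix built from `rates` and `rho`. The Ornstein-Uhlenbeck process uses
#' the exact transition moments with per-trait attraction `alpha` toward
#' `optimum`: over a branch of length t, trait i moves to
#' `optimum_i + exp(-alpha_i t) * (x_i - optimum_i)` in expectation, with
#' transition covariance `R_ij (1 - exp(-(alpha_i + alpha_j) t)) /
#' (alpha_i + alpha_j)` (the stationary variance of trait i is
#' `R_ii / (2 alpha_i)`).
#'
#' @param tree A `phylo` object.
#' @param process `"BM"` or `"OU"`.
#' @param rates Per-trait rate (diffusion) parameters, length 2.
#' @param rho Evolutionary correlation of the traits' changes.
#' @param alpha OU attraction strength(s): scalar or length 2 (> 0).
#' @param optimum OU optimum per trait, length 2.
#' @param root Root state per trait, length 2.
#' @param seed Integer seed.
#' @return Tibble with columns `tip`, `x`, `y`; the full configuration is
#'   attached as `attr(, "truth")`.
#' @export
simulate_bivariate_traits <- function(tree, process = c("BM", "OU"),
                                      rates = c(1, 1), rho = 0,
                                      alpha = NULL, optimum = c(0, 0),
                                      root = c(0, 0), seed = NULL) {
  process <- match.arg(process)
  validate_phylogeny(tree)
  R <- rate_matrix(rates, rho)
  if (process == "OU") {
    if (is.null(alpha) || any(alpha <= 0)) {
      vd_abort("simulate_bivariate_traits: OU requires alpha > 0.",
               "voweldisp_config_error")
    }
    alpha <- rep(alpha, length.out = 2)
  }
  vd_with_seed(seed, {
    n <- length(tree$tip.label)
    n_nodes <- n + tree$Nnode
    states <- matrix(NA_real_, n_nodes, 2)
    root_node <- n + 1
    states[root_node, ] <- root
    ord <- ape::reorder.phylo(tree, "postorder")
    edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE] # preorder
    lens <- rev(ord$edge.length)
    for (i in seq_len(nrow(edges))) {
      parent <- edges[i, 1]; child <- edges[i, 2]; t <- lens[i]
      x0 <- states[parent, ]
      if (process == "BM") {
        states[child, ] <- mvn_draw(x0, R * t)
      } else {
        m <- optimum + exp(-alpha * t) * (x0 - optimum)
        asum <- outer(alpha, alpha, "+")
        S <- R * (1 - exp(-asum * t)) / asum
        states[child, ] <- mvn_draw(m, S)
      }
    }
    out <- tibble::tibble(tip = tree$tip.label,
                          x = states[seq_len(n), 1],
                          y = states[seq_len(n), 2])
    attr(out, "truth") <- list(process = process, rates = rates, rho = rho,
                               alpha = alpha, optimum = optimum,
                               root = root, seed = seed)
    out
  })
}
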