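# voweldisp

Structure and evolution of vowel systems: dispersion, focalization, and
their power-law dependence across languages.

## The scientific problem

Vowel inventories differ enormously across languages, but their internal
geometry is constrained. Two summary statistics capture a system's layout
in perceptual (Bark) space, computed from per-vowel F1/F2 formant
frequencies:

- **Effective dispersion** — the geometric mean of all pairwise perceptual
  distances (DE), divided by the convex-hull area of the inventory (ASE):

  EffectiveDE = DE / ASE

  a measure of crowdedness per unit of acoustic space.

- **Focalization** — FE = Σᵢ 1/(B2ᵢ − B1ᵢ)², the summed spectral salience
  of the vowels; vowels whose first two formants lie close together (a
  cardinal /u/) are focal and contribute large terms.

Across languages, log₁₀(FE) falls roughly linearly in
log₁₀(EffectiveDE) — a power law FE ∝ EffectiveDEᴷ with negative
exponent. This package measures both statistics per system, quantifies
the dependence (Spearman correlation, log–log OLS, nested
random-intercept mixed models, per-region / per-family stratification),
and tests whether the two properties *evolve* together on a language
phylogeny: Felsenstein independent contrasts, maximum-likelihood
dependent-vs-independent bivariate Brownian motion, and PGLS under
Brownian-motion and Ornstein–Uhlenbeck covariance with a
likelihood-ratio comparison. A synthetic-data module generates vowel
typologies, Yule trees, and traits evolved under known parameters so
every estimator can be scored against ground truth.

## Worked example

```r
library(voweldisp)

# a synthetic cross-linguistic survey: 200 samples, 140 languages
typ <- simulate_typology(n_systems = 200, n_languages = 140, seed = 42)
profiles <- profile_systems(typ$formants)
profiles[1:3, ]
#>   sample_id iso   family region n_vowels    de   ase effective_de    fe
#> 1 s001      L001  F37    R2            4  3.04  1.49        2.03  0.557
#> 2 s002      L002  F01    R1           12  3.29 22.8         0.144 6.58
#> 3 s003      L003  F25    R5            6  4.11 19.2         0.214 0.850

spearman_rho(profiles$effective_de, profiles$fe)
#>      rho  p_value     n
#> 1 -0.695 3.72e-30   200

fit_loglog_ols(profiles)
#> Log-log OLS (power-law fit): log10(FE) ~ log10(Effective DE)
#>   slope K = -0.8893 (SE 0.0649, p = 1.6e-30)
#>   intercept = -0.6743 (SE 0.0477)
#>   adj. R^2 = 0.4845, n = 200
```

The 4-vowel system `s001` packs few vowels into a small hull (large
effective dispersion, low focalization); the 12-vowel `s002` crowds a
large hull (small effective dispersion) and accumulates focal vowels —
that trade-off, repeated across systems, is the negative dependence: rank
correlation −0.695, fitted exponent K ≈ −0.89.

The same question asked diachronically, with trait pairs evolved along a
33-tip tree under correlated Brownian motion (true evolutionary
correlation −0.7):

```r
tree <- simulate_yule_tree(33, seed = 43, rescale_depth = TRUE)
ev <- simulate_bivariate_traits(tree, "BM", rates = c(0.1, 0.1),
                                rho = -0.7, root = c(-0.5, 0), seed = 44)
traits <- tibble::tibble(tip = ev$tip,
                         log10_effective_de = ev$x, log10_fe = ev$y)

cx <- independent_contrasts(tree, traits[c("tip", "log10_effective_de")])
cy <- independent_contrasts(tree, traits[c("tip", "log10_fe")])
contrast_correlation(cx, cy)
#> [1] -0.7659

dep <- fit_bivariate_bm(traits, tree,
                        c("log10_effective_de", "log10_fe"), "dependent")
ind <- fit_bivariate_bm(traits, tree,
                        c("log10_effective_de", "log10_fe"), "independent")
compare_models(ind, dep)
#>   statistic    df      p_value delta_aic log10_lr support
#> 1      29.1     1 0.0000000671      27.1     6.33 strong

pgls_fit(traits, tree, log10_fe ~ log10_effective_de, "BM")
#> PGLS (BM): log10_fe ~ log10_effective_de
#>   beta = -0.7995 (SE 0.1206), intercept = -0.3567 (SE 0.1417)
#>   logL = 22.0065, n = 33
```

The contrast correlation (−0.77) and PGLS slope (−0.80 ± 0.12) recover
the planted correlated evolution after shared ancestry is accounted for,
and the dependent model is preferred decisively over the independent one
(likelihood ratio 29.1 on 1 df).

Real formant tables enter through `read_formant_table()` (delimited text,
configurable column mapping) and real trees through `read_newick()`; the
`run_profile()` / `run_dependence()` / `run_phylo()` / `run_simulate()`
stage runners write delimited reports plus a JSON manifest for
provenance. Fitted objects support `tidy()`, `glance()`, and
`autoplot()`.

See the methods vignette (`vignettes/vowel-structure-methods.Rmd`) for
the model definitions, numerical choices, and known limitations.

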