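---
title: "Measuring vowel-system structure and its correlated evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vowel-system structure and its correlated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voweldisp)
```

## The problem

Across the world's languages, vowel inventories range from three qualities
to well over a dozen, yet they are not arbitrary scatter: perceptual
pressures shape where vowels sit in the acoustic space. Two structural
properties summarise a system. *Dispersion* is global: how far apart the
vowels sit from one another in perceptual space. *Focalization* is local:
how spectrally salient individual vowels are, which for the first two
formants means how close F1 and F2 lie to each other (a cardinal /u/, with
both formants low and adjacent, is highly focal). This package measures
both properties per system, quantifies how they covary across languages,
and asks — with phylogenetic comparative methods — whether they *evolve*
together rather than merely co-occurring through common descent.

## From formants to statistics

All measurement happens on the Bark psychoacoustic scale,

$$\mathrm{Bark}(f) = 13\arctan(0.00076 f) + 3.5\arctan\!\big((f/7500)^2\big),$$

(arctangent in radians; the expression is only dimensionally coherent that
way), which stretches the low-frequency region where hearing discriminates
finely. `hz_to_bark()` is strictly increasing, so the token invariant
F2 > F1 survives the transform.

For a system of $n$ vowels at Bark points $(B1_i, B2_i)$:

* **DE**, the dispersion estimate, is the *geometric mean* of the
  $n(n-1)/2$ pairwise Euclidean Bark distances. The literature also uses a
  reciprocal-of-distances crowdedness energy; both readings circulate, and
  the package keeps the reciprocal-square sum behind
  `dispersion_estimate(..., variant = "inverse_square_sum")`. The
  geometric mean is the default because it is the reading under which
  "dispersion per unit area" behaves as a crowdedness measure with the
  negative dependence on focalization that motivates the analysis: crowded
  systems have small mean pairwise distance and large FE.
* **ASE**, the acoustic space estimate, is the area of the convex hull of
  the (deduplicated) Bark points, computed by a first-principles monotone
  chain and the shoelace formula so the geometry is itself a tested
  component.
* **Effective DE** $= \mathrm{DE}/\mathrm{ASE}$, dispersion per unit area.
  Under coordinate scaling by $c$: DE scales as $c$, ASE as $c^2$,
  Effective DE as $1/c$, FE as $1/c^2$ — asserted numerically in the tests.
* **FE** $= \sum_i 1/(B2_i - B1_i)^2$, the focalization estimate; every
  added vowel adds a positive term.

Degenerate geometry is refused, never silently patched: systems with fewer
than 3 vowels, collinear configurations (zero hull area would make
Effective DE undefined), and exactly coincident points under the
geometric-mean DE (which would be identically zero) are skipped by
`profile_systems()` with logged reasons, available via
`skipped_systems()`. Duplicated points are excluded from the hull but kept
for FE, which is a per-token sum.

A note on the canonical five-vowel fixture used in examples and tests: the
claim "u is more focal than o" requires cardinal formant values for /u/
(F1 300, F2 600 Hz), with a genuinely low second formant. Because the Bark
map is steepest at low frequencies, a fronted /u/ with F2 near 760 Hz
spans *more* Bark than a mid /o/ and the ordering flips; the fixture
therefore uses cardinal values.

## The synchronic dependence

With one profile row per sample, the dependence between Effective DE and
FE is quantified on the $\log_{10}$ scale throughout (both statistics are
positive and the hypothesis is a power law $FE \propto
\mathrm{EffectiveDE}^K$, linear in the logs):

* `spearman_rho()` — rank correlation, monotone-transform invariant;
* `fit_loglog_ols()` — the power-law exponent $K$ as an OLS slope;
* `fit_mixed_model()` — the same fixed effect with nested random
  intercepts for language identity within language family and within
  geographic region, `(1|family) + (1|family:iso) + (1|region) +
  (1|region:iso)`, because cross-linguistic samples are unbalanced and
  repeated across dialects. Estimation is REML via lme4; slope p-values
  use the Satterthwaite approximation (lmerTest), falling back to a normal
  approximation with the method recorded in the result. Random slopes are
  deliberately not fitted — with these group sizes they routinely fail to
  converge and the scientific question concerns the common exponent.
  Grouping factors with fewer than two levels, or one level per
  observation, are dropped and recorded; with no usable grouping the model
  collapses to OLS, which is also the correct limiting behaviour when
  variance components hit zero.
* The headline fit quality for the mixed model is the *conditional*
  R² (fixed plus random variance over total, Nakagawa-style); the marginal
  R² (fixed only) is reported alongside. OLS fits report the classical
  adjusted R².
* `stratified_fits()` refits per region (keeping family nesting) or per
  family (keeping region nesting); strata under `min_n` samples are
  skipped with a reason. The default `min_n = 11` operationalises a
  "more than 10 samples" inclusion rule.
* `group_mean_regression()` collapses each stratum to a point and
  regresses across strata. Means are taken on the log scale
  (mean-of-logs), the convention matching plots of log-transformed means
  with standard-error bars; `log_first = FALSE` gives log-of-means, which
  genuinely differs on skewed data, and `spread = "sd"` swaps the error
  bars.
* `aggregate_language_samples()` collapses repeated samples of a language
  (dialects, elicitation variants) into one profile by weighted means,
  e.g. with speaker counts as weights; raw and log statistics are averaged
  separately.

## The diachronic question

A cross-linguistic correlation can be manufactured by common descent alone
(Galton's problem). Three complementary analyses address it, all taking a
rooted tree with branch lengths plus a tip table of (Effective DE, FE)
pairs — analysed both raw and log10-transformed:

**Independent contrasts.** `independent_contrasts()` implements the
Felsenstein pruning pass; `contrast_correlation()` correlates two contrast
sets through the origin (contrasts have arbitrary sign). Polytomies must
be resolved explicitly (`resolve_polytomies()`, new branches at `1e-8` of
tree depth by default — small enough not to move estimates, large enough
to keep the recursion defined).

**Dependent vs independent bivariate Brownian motion.**
`fit_bivariate_bm()` fits two traits under BM with covariance
$R \otimes C$ ($R$ the 2×2 trait rate matrix, $C$ the BM tree matrix).
Both models have closed-form maximum-likelihood estimates — GLS ancestral
states, then the ML rate matrix, with the independent model zeroing the
off-diagonal — so the dependent likelihood can never fall below the
independent one, and `compare_models()` reports the likelihood-ratio
statistic, its $\chi^2_1$ p-value, the AIC difference, and a descriptive
evidence label (weak / positive / strong / decisive on the decimal
log-likelihood-ratio scale). This ML comparison replaces MCMC-based
marginal-likelihood machinery by design: the scientific contrast — does
the correlation parameter earn its keep? — is the same, but the
likelihood values are not comparable to stepping-stone marginal
likelihoods.

**PGLS under BM vs OU.** `pgls_fit()` runs exact generalized least
squares with residual covariance from `phylo_vcv()`: BM shared branch
lengths, or the stationary Ornstein-Uhlenbeck correlation
$\exp(-\alpha\, d_{ij})$ in patristic distance $d$ (the Martins-Hansen
form, recommended on ultrametric trees; a warning is issued otherwise).
The residual scale is profiled out analytically, making the log-likelihood
invariant to rescaling the covariance and hence directly comparable
between the two processes; $\alpha$ is profiled over a log-spaced grid
spanning $[10^{-4}, 10^2]$ per unit tree depth and refined by
one-dimensional optimization. The default response convention is
`fe ~ effective_de`, with the formula exposed so either direction can be
fitted. `likelihood_ratio_test()` compares the processes on $\chi^2_1$.
Two numerical caveats are documented rather than hidden: under the null
the attraction parameter sits on its boundary, making the test
conservative; and the stationary OU correlation only *approximately*
nests BM (as $\alpha \to 0$ it tends to an equicorrelated, not a
Brownian, structure), so on data genuinely favouring BM the best OU
likelihood can fall slightly below the BM one. A negative statistic is
therefore reported truncated at zero with p = 1 — evidence for BM — with
the raw value kept alongside; it is not treated as an optimizer failure.

Phylogenetic uncertainty is carried by `across_trees()`, which maps any
fitting function over a collection (e.g. a posterior sample) of trees and
summarises each numeric quantity as mean ± SD. Tree inference itself is
out of scope; trees are inputs.

## What the synthetic data emulate

`simulate_typology()` is the package's stand-in for a worldwide formant
survey, and its defaults are the study conditions the tests run under:
532 samples over 357 languages, 39 families, 8 regions, inventory sizes
uniform on 3–15. Vowels are generated by `prototype_jitter`: anchors from
a 14-quality cardinal chart, jittered with SD 0.3 Bark — roughly the
within-language token variability of careful citation speech — in the
perceptually uniform space, then mapped back to Hz by Newton inversion of
the Bark transform. Under these defaults no dependence is imposed, yet
Spearman's rho between Effective DE and FE is reliably negative: larger
inventories pack a bounded space (smaller mean pairwise distance, larger
hull, hence smaller Effective DE) while FE accumulates one positive term
per vowel. The acceptance suite checks the sign, not a magnitude, because
the magnitude depends on generator details real data need not share.

With `exponent = k`, the generator instead draws
$\log_{10}\mathrm{EffectiveDE} \sim N(-0.5, 0.25)$ and builds
$\log_{10}FE = a + k\,\log_{10}\mathrm{EffectiveDE} + u_{family} +
u_{region} + \varepsilon$ with intercept SDs 0.2 and 0.1 and residual SD
0.05 on the log scale — exactly the hierarchy the mixed model assumes —
and stores every latent draw in the truth record, so each estimator has a
stored truth to be scored against. What passing these tests shows is that
the estimators recover what the generators planted; they cannot show that
real vowel databases satisfy the generators' assumptions (independent
Gaussian jitter, single family/region membership per language, no
elicitation effects, no inventory-frequency realism).

`simulate_yule_tree()` provides pure-birth trees (fixed tip count via
`ape::rphylo`, or fixed duration via a forward simulation from a single
lineage so the expected tip count is exactly $e^{\lambda t}$), and
`simulate_bivariate_traits()` evolves trait pairs along a tree under BM or
OU using exact transition moments (for OU with per-trait attraction
$\alpha_i$, cross-covariances use
$R_{ij}(1 - e^{-(\alpha_i+\alpha_j)t})/(\alpha_i+\alpha_j)$).

## Numerical choices and problem sizes

Simulation-backed tests use fixed seeds and sizes chosen so each check is
a ≥3-standard-error statement: 20 replicates of 500-sample typologies for
exponent recovery (variance components judged on the replicate mean, since
a single 30-group variance estimate carries ~26% sampling error), 100
seeds for the emergent sign, 500 replicates on 50 tips for the type-I
calibration of the correlated-evolution test, 300 replicates on 200 tips
for correlation recovery, and 100 replicates on 100 tips for the BM-vs-OU
test's size and power. Exact algebra (hand examples, hull and GLS oracles,
contrast fixtures) is asserted at 1e-8–1e-9.

## Known limitations

* Only F1/F2 enter the metrics; no effective-second-formant synthesis, no
  F3, no audio processing.
* The OU machinery assumes (and warns outside) ultrametric trees; the
  LRT's boundary conservatism is documented, not corrected.
* The bivariate BM comparison shares one tree matrix across both traits;
  separate trait-specific tree transformations are out of scope.
* The generators make no attempt to imitate real cross-linguistic
  inventory frequency distributions; they provide controlled truth, not
  typological realism.
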