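---
title: "Measuring gloss constancy behind transparent layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gloss constancy behind transparent layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glosstrans)
```

## The problem

A glossy object seen through a partially transmissive layer — smoke, a
tinted pane, a scrim — reaches the eye with its luminance histogram shifted
and compressed. The brightest image regions are the specular highlights, and
the contrast between highlight and surround is one of the strongest cues to
how glossy a surface looks. If the visual system fully discounted the layer,
perceived gloss would be invariant to it (gloss constancy); if not, the
layer contaminates the judgment. This package provides the computational
chain for studying that question with simulated observers: image formation
under a transparency model, two psychophysical scaling methods for
quantifying the contamination, and an error analysis for asymmetric
matching.

## Image formation: the episcotister model

A transparent layer is parameterized by its transmittance $\alpha \in [0,1]$
and its reflectance when opaque $t \in [0,1]$. A background pixel of
luminance $b$ appears through the layer as the convex combination

$$p = \alpha\, b + t\,(1 - \alpha).$$

`apply_filter()` applies this map pixelwise. Its consequences, all verified
numerically in the test suite, structure every downstream diagnostic:

* pixels at $b = t$ are fixed points for every $\alpha$; pixels above $t$
  darken, pixels below lighten (`fraction_darkened()`);
* the luminance range scales by $\alpha$, so Michelson contrast
  $(L_{\max} - L_{\min})/(L_{\max} + L_{\min})$ never increases, with
  equality exactly when $t = 0$ (pure scaling) or $\alpha = 1$ (identity);
* two stacked layers compose into a single layer with
  $\alpha' = \alpha_1\alpha_2$.

Histogram summaries (`histogram_stats()`) use the population skewness
estimator, the convention for moment-based image statistics; zero-variance
regions return skewness 0 rather than NaN, and an all-black region returns
Michelson contrast 0 with a warning, so degenerate masks do not poison
summary tables.

Two layer parameterizations ship as defaults: the paired-comparison
configuration uses four reflectances $t \in \{0, 0.33, 0.66, 1\}$ at fixed
$\alpha = 0.5$ (layers from black to white at half transmittance), and the
matching configuration fixes $t = 0.5$ and varies
$\alpha \in \{0.2, 0.4, 0.6, 0.8\}$ (one gray at four transmittances). Both
are plain config entries and can be swapped freely.

## Conjoint measurement: three nested observer models

In the paired-comparison task the observer sees two stimuli, each a
(specularity level $i$, layer level $j$) combination, and reports which
looks glossier. The Thurstonian decision model assigns each stimulus a
latent value and compares them with a single draw of Gaussian judgment
noise:

$$\Delta = (\psi^g_i + \psi^r_j + \psi^{gr}_{ij}) -
           (\psi^g_k + \psi^r_l + \psi^{gr}_{kl}) + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, \sigma^2),$$

so the left stimulus is chosen with probability $\Phi(\Delta_{\det}/\sigma)$
(probit link; no lapse parameter). Three nested restrictions are fitted by
`mlcm_fit()`:

* **independent** — only the attended dimension matters
  ($\psi^r \equiv 0$, $\psi^{gr} \equiv 0$); a gloss-constant observer;
* **additive** — the layer shifts perceived gloss by a level-dependent
  constant ($\psi^{gr} \equiv 0$);
* **full** — an interaction term per cell.

Identifiability follows the standard conjoint-measurement convention:
$\sigma \equiv 1$, so scales are in noise-SD ($d'$-like) units, and the
first level of each dimension (and the first row and column of the
interaction) is anchored at 0. The free-parameter counts are then
$n_g - 1$, $(n_g - 1) + (n_f - 1)$ and $n_g n_f - 1$, which fixes the
degrees of freedom of the likelihood-ratio tests `lr_test()` computes
(3 and 9 on a 4×4 grid). Model selection per observer uses the
Bonferroni-corrected level `bonferroni_level(0.05, n_observers)` — 0.00625
for a cohort of eight.

### Numerical choices

Estimation is penalized maximum likelihood: the Bernoulli log-likelihood
plus a tiny ridge $10^{-6}\|\psi\|^2$. Four-repetition designs regularly
produce empirical choice proportions of exactly 0 or 1, under which the
unpenalized MLE diverges (complete separation); the ridge keeps estimates
finite, and any fit with $|\psi| > 8$ is flagged via `separation` rather
than failing. Optimization is BFGS with an analytic gradient (relative
tolerance $10^{-8}$, 500 iterations), started from zeros and from one
random perturbation, keeping the better optimum. The reported
log-likelihood is the unpenalized value at the optimum. The tests verify the
optimizer against two independent routes: an exhaustive two-stage lattice
search on 2×2 problems (agreement to $10^{-3}$ in log-likelihood) and a
probit regression fitted by `glm()` on the same design matrix.

### Aggregation

Scales are comparable across observers only after removing the arbitrary
per-observer unit, so `aggregate_scales()` divides each observer's
estimates by that observer's maximum over both dimensions, then averages;
the spread is the SEM across observers of the *normalized* values
(normalization first, then averaging). Observers with no positive estimate
cannot be normalized and are excluded with a warning.

## Difference scaling for stimulus spacing

Matching experiments want lattice steps that are perceptually, not
physically, equal. `fit_mlds()` implements maximum-likelihood difference
scaling from quadruple judgments ($a < b \le c < d$; which pair differs
more?), with $P(\text{choose } (a,b)) =
\Phi\!\big(((\psi_b - \psi_a) - (\psi_d - \psi_c))/\sigma\big)$, anchors
$\psi_1 = 0$, $\psi_n = 1$, and $\sigma$ estimated on a log scale. The
quadruple protocol was chosen as the common default for this method.
When responses are uninformative (all choice rates at ½) the likelihood is
flat in the interior scale values; a vanishing quadratic tie-break
($10^{-6}$) toward the equally spaced scale selects the linear solution in
that degenerate case and is otherwise negligible against the likelihood
curvature. `equal_step_levels()` inverts a fitted scale — isotonic
projection first, because sampling noise can produce local non-monotonicity,
then linear interpolation — returning physical values with equally spaced
perceptual images (for $\psi = x^2$ and 7 steps: $x_k = \sqrt{k/6}$).

## Matching errors and the condition-3 prediction

Matching data live on a 7×7 albedo × gloss lattice. The error is
matched minus true level, so overestimation is positive.
`matching_errors()` summarizes per design cell;
`contrast_error_table()` joins the per-filter gloss error with the
Michelson contrast of the object behind each layer, the diagnostic that
exposes contrast-driven overshoot (largest error behind the most
contrast-compressing layer). `predict_condition3()` asks whether the error
made when matching both attributes at once is just the vector combination
of the single-attribute errors: per (material, filter) cell the predicted
deviation is $\sqrt{e_1^2 + e_2^2}$ (albedo-only and gloss-only errors, in
lattice steps), the observed deviation is the Euclidean distance from the
true material to the mean joint match, and observed is regressed on
predicted by OLS with a t-test of the slope against 1 (df $= n - 2$; with
2×2 materials and 4 filters, 16 cells and df 14). An exactly additive error
structure gives slope 1 and $r = 1$; when the regression is degenerate
(no variance in either distance) it is flagged instead of reporting an
undefined correlation. Routine repeated-measures ANOVA is deliberately not
reimplemented; the long-format error table feeds any standard ANOVA
tooling.

## What the simulators emulate — and what they do not

The package is validated end-to-end on synthetic data, so the generators
define the study conditions:

* `conjoint_design()` enumerates all unordered stimulus pairs
  (120 for a 4×4 grid) and replicates them (480 trials at 4 repetitions);
  left/right position is randomized per trial under the seed, and no
  position bias is modelled, matching the decision model which has none.
* `simulate_conjoint()` draws responses from the same probit model the
  fitting assumes. The default cohort truth is an additive observer with
  $\psi^g = (0,1,2,3)$, $\psi^r = (0,-0.2,-0.4,-0.6)$, $\sigma = 1$: a
  strong gloss scale with a moderate, monotone penalty from lighter layers.
* `simulate_matching()` adds a per-filter bias and Gaussian noise to the
  target, then quantizes by round-half-away-from-zero and clips to 1..7,
  because observers chose from a discrete 7-step set. The default biases
  (albedo 0.6/0.3/0.15/0.1 and gloss 1.0/0.7/0.4/0.2 lattice steps, layers
  ordered from least to most transmissive) emulate the qualitative pattern
  of interest — gloss overshoot growing as the layer compresses contrast,
  albedo overcompensation behind strongly darkening layers — at magnitudes
  a matching task on a 7-step lattice can express. They are a chosen
  synthetic truth, not fitted values.
* `glossy_image()` builds a 128×128 image (8×8-check background, smoothly
  shaded blob, Gaussian highlights growing with the gloss parameter) —
  small enough for fast tests, rich enough for contrast and histogram
  statistics.

Passing tests on these simulators demonstrate that the estimators recover
the generating model and that the analysis chain is internally consistent.
They cannot show that human observers obey the additive model, that real
rendered stimuli have these image statistics, or that matching biases take
these values — those are empirical claims requiring human data and physical
rendering, both outside this package's scope (no physically based renderer
is included, and the procedural images make no claim to shape-from-shading
realism).

## Problem sizes

The shipped configurations are the sizes the analysis is designed around: a
4×4 grid at 4 repetitions (480 trials) per conjoint observer with cohorts
of 8; 1000 quadruples for difference-scaling recovery; 1000 replicates for
the likelihood-ratio test's type-I error; 16 cells for the condition-3
regression. All are computed in seconds to a couple of minutes on a single
CPU.

## A worked run

```{r exp1, eval = FALSE}
res1 <- run_experiment1(exp1_config(seed = 1), out_dir = "exp1")
subset(res1$lr_table, full_model == "additive")
aggregate_scales(lapply(res1$fits, `[[`, "additive"))

res2 <- run_experiment2(exp2_config(seed = 1), out_dir = "exp2")
res2$contrast_table
glance(res2$prediction)
```

Both runs write their artifact bundles (trial CSVs, summaries, LR tables,
regression JSON) plus a manifest carrying the configuration hash and seeds;
reruns with the same configuration are byte-identical.

## Known limitations

* Scales are estimated per observer with $\sigma \equiv 1$; no pooled joint
  fit or random-effects structure across observers is offered (aggregation
  is average-of-normalized-estimates by design).
* No lapse-rate or position-bias parameters; data from observers with
  substantial lapses will inflate the apparent noise.
* The interaction (full) model's parameter count grows as $n_g n_f$, and
  small designs will frequently flag separation in it.
* Chromatic (3-channel) transparency is out of scope; images are luminance
  only, and the ratio-based perceptual transmittance models from the
  lightness literature are not computed.
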