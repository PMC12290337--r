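# glosstrans

Tools for studying **gloss constancy through transparency**: does perceived
gloss survive an intervening transmissive layer, and if not, by how much is
it contaminated? The package is aimed at visual psychophysicists who need
the full computational chain — image formation under a transparency model,
conjoint measurement of two-dimensional perceptual scales, difference
scaling for perceptually uniform stimulus spacing, and asymmetric-matching
error analysis — runnable end to end on simulated observers.

## The models at the core

**Image formation.** A transparent layer with transmittance α and
reflectance-when-opaque *t* composites a background pixel *b* as the convex
combination (Metelli's episcotister model)

> p = α·b + t·(1 − α)

which shifts and compresses the luminance histogram. `apply_filter()`
implements it; `michelson_contrast()`, `histogram_stats()` and
`fraction_darkened()` compute the diagnostics that quantify the compression
(a layer never increases Michelson contrast; equality holds exactly when
t = 0 or α = 1).

**Conjoint measurement.** In a paired-comparison task each stimulus is a
(gloss level *i*, layer level *j*) combination with latent value
ψᵍᵢ + ψʳⱼ (+ ψᵍʳᵢⱼ), and the probability of choosing the left stimulus is
Φ(Δ/σ) with a single Gaussian judgment error on the difference Δ.
`mlcm_fit()` fits the **independent** (ψʳ ≡ 0), **additive**, and **full**
(interaction) observer models by penalized maximum likelihood (probit link,
σ ≡ 1, first levels anchored at 0, ridge 10⁻⁶ against complete
separation); `lr_test()` compares them with nested χ² likelihood-ratio
tests, and `aggregate_scales()` averages per-observer max-normalized
scales with SEM across observers.

**Difference scaling.** `fit_mlds()` estimates a perceptual scale from
quadruple judgments (anchors ψ₁ = 0, ψₙ = 1, σ estimated) and
`equal_step_levels()` inverts it into physically specified, perceptually
equal steps.

**Matching analysis.** `matching_errors()` summarizes matched-minus-true
errors on the 7-step lattice (overestimation positive),
`contrast_error_table()` relates gloss error to the Michelson contrast
behind each layer, and `predict_condition3()` tests whether joint
(albedo + gloss) matching errors equal the Euclidean combination of the
single-attribute errors via an OLS slope tested against 1.

Simulators (`conjoint_design()`, `simulate_conjoint()`,
`simulate_matching()`, `simulate_mlds()`, `glossy_image()`) generate every
input the pipeline needs, bit-reproducibly under explicit seeds.

## Worked example

```r
library(glosstrans)

# a mid-gray image behind a white half-transmissive layer
apply_filter(matrix(0.4, 2, 2), metelli_filter(t = 1, alpha = 0.5))
#>      [,1] [,2]
#> [1,]  0.7  0.7
#> [2,]  0.7  0.7

# paired-comparison study: 8 simulated additive observers,
# 4x4 grid, 480 trials each
res1 <- run_experiment1(exp1_config(seed = 1), out_dir = "exp1")
subset(res1$lr_table, full_model == "additive")[, c("observer", "statistic", "p_value", "significant")]
#>   observer statistic  p_value significant
#> 1        1      16.0 1.11e-03        TRUE
#> 2        2      21.4 8.64e-05        TRUE
#> ...
#> 8        8      25.0 1.55e-05        TRUE
```

Seven of the eight simulated observers reject the independent
(gloss-constant) model at the Bonferroni-corrected level 0.00625 — the
transparent layer's contribution to the gloss judgment is detected. The
aggregated normalized scales show the monotone gloss scale and the layer's
negative contribution:

```r
aggregate_scales(lapply(res1$fits, `[[`, "additive"))
#>   dimension level    mean    sem
#>   filter        1  0      0
#>   filter        2 -0.0557 0.0185
#>   filter        3 -0.123  0.0214
#>   filter        4 -0.207  0.0101
#>   gloss         1  0      0
#>   gloss         2  0.350  0.0182
#>   gloss         3  0.701  0.0220
#>   gloss         4  1      0
```

The matching study relates gloss-matching error to image contrast and
tests the additivity of joint matching errors:

```r
res2 <- run_experiment2(exp2_config(seed = 1), out_dir = "exp2")
res2$contrast_table
#>   filter_id contrast mean_error    sem
#>           1    0.198      0.977 0.0477   <- lowest contrast, largest overshoot
#>           2    0.395      0.641 0.0452
#>           3    0.592      0.391 0.0575
#>           4    0.788      0.180 0.0503

glance(res2$prediction)
#>   slope intercept     r t_vs_1    df p_value
#>    1.03    0.0198 0.933  0.266    14   0.794
```

The joint-matching deviation is predicted by the single-attribute errors
(r = 0.93 over 16 material × filter cells) with a slope statistically
indistinguishable from 1 — the errors combine additively.

## Documentation

The methods vignette (`vignettes/gloss-through-transparency.Rmd`) describes
the decision models, identifiability conventions, numerical choices and
what the simulators do and do not emulate.
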