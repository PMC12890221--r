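# spatsic

Hierarchical Bayesian estimation of **directional spatial interaction
curves** between cell types in multiplexed-imaging point patterns.

## The problem

Multiplexed imaging (mIF, CODEX, IMC, ...) yields classified cell
centroids per tissue image. How one cell type arranges itself around
another — T cells accumulating near tumor cells, granulocytes avoiding
fibroblast-rich stroma — is directional: the effect of A's positions on
B's density is not the effect of B on A. Classical per-image summaries
(G-cross, K-cross envelope tests) are computed image by image and
cannot share strength across the images, patients and cohorts a study
contains.

`spatsic` is for analysts of such studies who want, per directed
source → target pair: a smooth distance-indexed effect estimate with
honest joint uncertainty, pooled hierarchically across the study, plus
detection calls, prioritization summaries, and a heterogeneity
decomposition.

## The model

The target type is an inhomogeneous Poisson process given the source
patterns, with log-linear conditional intensity

    log λ(v) = β₀ + z(v)ᵀβ + Σₖ q_k(v)ᵀ δ_k,
    q_{k,p}(v) = Σ_{x ∈ X_k} φ_p(‖v − x‖),

where φ₁…φ_P are compact distance-basis functions (cubic B-splines on
[0, 150] µm by default). The **spatial interaction curve**
SIC_k(s) = Σ_p δ_k⁽ᵖ⁾ φ_p(s) is the additive log-intensity
contribution of one source cell at distance s; `exp(SIC)` is a density
fold-change (0.2 → ≈ 1.22×, −0.3 → ≈ 0.74×). Coefficients are pooled
over cohort (ψ) → patient (γ) → image (δ) Gaussian levels with
half-Normal scale hyperpriors; the Poisson likelihood is fit by the
standard dummy-point logistic approximation; posterior sampling is
adaptive Hamiltonian Monte Carlo. Inference products are simultaneous
(joint-coverage) credible bands, band-based detection, peak /
persistence / strength summaries, and between- vs within-patient MAD
heterogeneity. A full simulator with known ground truth and classical
G-/K-cross global envelope tests support validation and benchmarking.

See the methods vignette (`vignettes/interaction-curves.Rmd`) for the
model, priors, band construction and design choices.

## Worked example

Simulate a small study with a known attraction bump (peak 0.8 at
40 µm), fit the hierarchical model, and summarize the cohort curve:

```r
library(spatsic)

cfg <- sic_sim_config(n_patients = 4, images_per_patient = 2,
                      source_count = 150, target_count = 50)
sim <- simulate_study(cfg, seed = 7)
sim$study
#> <sic_study> 1585 cells, 2 types, 8 images, 4 patients, 1 cohorts

dat <- build_sic_data(sim$study, target = "target", sources = "source",
                      basis = cfg$basis, seed = 7)
fit <- fit_sic_hier(dat, sim$study$hierarchy, seed = 7)
glance(fit)
#> # A tibble: 1 × 9
#>   model   n_images n_patients n_cohorts n_draws accept_rate divergences max_rhat
#>   <chr>      <int>      <int>     <int>   <int>       <dbl>       <int>    <dbl>
#> 1 hierar…        8          4         1    4000       0.912           5     1.02

band <- sic_band(fit, "cohort", grid = seq(25, 150, by = 5))
head(band, 4)
#> # A tibble: 4 × 8
#>   level  unit    source target distance  mean lower upper
#>   <chr>  <chr>   <chr>  <chr>     <dbl> <dbl> <dbl> <dbl>
#> 1 cohort cohort1 source target       25 0.615 0.298 0.932
#> 2 cohort cohort1 source target       30 0.663 0.362 0.965
#> 3 cohort cohort1 source target       35 0.700 0.420 0.980
#> 4 cohort cohort1 source target       40 0.725 0.465 0.985

detect_interaction(band, c(25, 75))[c("detected", "sign")]
#> $detected
#> [1] TRUE
#> $sign
#> [1] "positive"

sic_summary_measures(band, c(25, 150))
#> # A tibble: 1 × 4
#>   peak_distance peak_value persistence strength
#>           <dbl>      <dbl>       <dbl>    <dbl>
#> 1            45      0.736        0.82     51.9

sic_heterogeneity(fit, grid = seq(25, 150, by = 5))
#> # A tibble: 1 × 4
#>   source target between_patient_mad within_patient_mad
#>   <chr>  <chr>                <dbl>              <dbl>
#> 1 source target              0.0402            0.00997
```

Reading the output: the simultaneous 95% band stays above zero from
25 µm outward, so a positive interaction is detected; the posterior
mean curve peaks at 45 µm with value 0.74 (truth: 40 µm, 0.8), i.e.
about an `exp(0.74) ≈ 2.1×` local density increase; the band excludes
zero over 82% of the 25–150 µm range; and patient-level curves deviate
from the cohort curve by a median 0.04 log-intensity units — modest
heterogeneity, consistent with the generating σ values. `autoplot(fit)`
draws the band; `plot_study(sim$study)` shows the patterns.

Real data enter the same way via `read_cells("cells.csv")` (columns
x, y, cell_type, image_id, patient_id, cohort_id; optional window CSV)
instead of `simulate_study()`.

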