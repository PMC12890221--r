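---
title: "Directional spatial interaction curves: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional spatial interaction curves: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Multiplexed imaging reduces a tissue section to a marked point pattern:
cell centroids in micrometres with a cell-type label per centroid.
Questions about tissue organization — do cytotoxic T cells accumulate
near tumor cells? do granulocytes avoid fibroblast-rich regions? — are
questions about *directional* spatial dependence between types: the
effect of type A on where type B sits is not the effect of B on A.
Classical summaries (G-cross, K-cross) are symmetric in spirit,
computed per image, and hard to pool across the images, patients and
cohorts that a study actually contains.

`spatsic` models one *target* type conditionally on one or more
*source* types, estimates smooth distance-indexed effects with full
posterior uncertainty, and pools them hierarchically.

# The model

Given the source patterns, target cells are modelled as an
inhomogeneous Poisson process with log-linear conditional intensity

$$\log \lambda(v) = \beta_0 + z(v)^\top \beta +
  \sum_k q_k(v)^\top \delta_k, \qquad
  q_{k,p}(v) = \sum_{x \in X_k} \phi_p(\lVert v - x\rVert),$$

where the $\phi_p$ are `P` nonnegative distance-basis functions on
`[0, r_max]` (clamped cubic B-splines by default, Gaussian kernels as
an alternative). The scientific object is the **spatial interaction
curve** for source type $k$,

$$\mathrm{SIC}_k(s) = \sum_p \delta_k^{(p)} \phi_p(s),$$

the additive contribution of one source cell at distance $s$ to the
target log-intensity. `exp(SIC)` is a density fold-change: a value of
0.2 at 30 µm means a cell 30 µm from a source cell sees about a 22%
higher expected target density. Curves can be positive (attraction) or
negative (repulsion), and the per-image intercept normalizes out
baseline density so curves are comparable across images.

Coefficients are pooled over three levels. With cohort curves $\psi$,
patient curves $\gamma$ and image curves $\delta$, elementwise per
basis index:

$$\psi \sim N(0, \sigma^2_{\text{cohort}}), \quad
  \gamma \sim N(\psi_{g(n)}, \sigma^2_{\text{patient}}), \quad
  \delta \sim N(\gamma_{n(m)}, \sigma^2_{\text{image}}).$$

Partial pooling shares strength across replicates while leaving room
for real patient- and image-level heterogeneity, which the package
quantifies explicitly (`sic_heterogeneity()`).

## Likelihood approximation

The Poisson likelihood integral is replaced by the standard logistic
device: sample dummy points from a homogeneous Poisson process with
intensity $\lambda_d$, label target cells 1 and dummies 0, and fit a
Bernoulli-logit model with offset $-\log \lambda_d$; then
$\mathrm{logit}\, P(y=1 \mid v) = \log\lambda(v) - \log\lambda_d$.
Default $\lambda_d$ is four times the observed per-image target
density, a standard quadrature choice; the approximation error decays
as $\lambda_d$ grows (tested against a pixel-grid Poisson oracle).

## Priors and their rationale

All defaults live on the log-intensity scale, where interaction values
beyond ±2 (a 7-fold density change) are biologically extreme:

* intercepts and covariate coefficients: Normal(0, 5²) — effectively
  flat over plausible densities;
* $\sigma_{\text{cohort}}, \sigma_{\text{patient}},
  \sigma_{\text{image}}$: half-Normal(0, 1);
* flat (unpooled) model: Normal(0, 5²) per image coefficient, chosen
  so the ablation differs from the hierarchical model only by
  replacing learned pooling scales with one fixed weak scale. A
  tighter choice (e.g. sd 1) would itself act as pooling-to-zero and
  blur the comparison.

Sensitivity to the hyperprior scales is most visible in
single-image or single-patient studies, where the scales are barely
identified; with two or more images per patient and a handful of
patients the interaction curves are dominated by the likelihood.

## Reporting cutoff

Below roughly one or two cell diameters, segmentation artifacts and
physical crowding make curve values uninterpretable, so summaries are
reported on `[r_min, r_max]` with `r_min = 25` µm by default. The
model is still *fit* with all distances; only reporting masks them.

# Posterior inference

Fitting uses an adaptive Hamiltonian Monte Carlo sampler implemented
in the package (leapfrog integration, dual-averaging step size
targeting 0.8 acceptance, diagonal mass matrix estimated over two
warmup windows, trajectory lengths jittered uniformly). Defaults are 4
chains of 1000 warmup + 1000 kept iterations; split-R-hat above 1.05
on any interaction coefficient triggers a warning, never an error.

One geometry decision matters: the cohort level is *centered* (the
$\psi$ are sampled directly) while patient and image deviations are
non-centered (standardized offsets scaled by their $\sigma$). The
cohort level aggregates every patient and is well identified, so the
centered form avoids the $\sigma_{\text{cohort}}$ funnel that the
fully non-centered model exhibits; the sparsely informed lower levels
keep the non-centered form that suits weak likelihoods.

# Bands, detection and prioritization

Simultaneous credible bands use the max-standardized-deviation
construction: with posterior mean $m(s)$ and sd $\sigma(s)$ per grid
point, the multiplier $c^\*$ is the posterior level-quantile of
$\max_s |f(s) - m(s)|/\sigma(s)$ and the band is $m \pm c^\*\sigma$.
Grid points with zero posterior spread get zero width. Joint coverage
is calibrated (tested at 5000 draws on a 50-point grid) and the band
is never narrower than the pointwise interval.

Detection on an interval: the band excludes zero at some grid point.
Prioritization summaries use the posterior mean curve: peak location
and signed magnitude; persistence (fraction of the interval where the
band excludes zero); strength (trapezoidal integral of `|mean|` over
the excluded region). A draw-wise variant of persistence/strength —
integrating each posterior draw rather than the mean — is possible and
would propagate more uncertainty, but the mean-curve convention is
simpler and is what the package implements.

Heterogeneity decomposes as median absolute deviations of
posterior-mean curves: between patients (patient vs cohort curve) and
within patients (image vs patient curve), pooled over the reporting
grid.

# The simulator

`simulate_study()` generates studies with known truth: homogeneous
Poisson sources; hierarchical true coefficients drawn exactly as the
model assumes; targets by rejection (thinning) against an intensity
bound from a 256×256 evaluation grid with a 1.2 safety factor — runs
abort rather than silently truncate if the bound is violated. The
default truth is a single nonnegative bump peaking near 40 µm with
height 0.8, detectable but not trivial; the default window is
1500×1500 µm².

Because attraction inflates realized counts multiplicatively, the
baseline is calibrated: `sic_sim_config()` subtracts the expected
Campbell inflation $\lambda_{\text{src}} \int (e^{\mathrm{SIC}(s)}-1)
\, 2\pi s\, ds$ from $\beta_0$, so "target count 50" produces on the
order of 50 cells per image whether or not a curve is active.
Per-image counts still fluctuate around the nominal value (roughly
1–2×) through source realizations and hierarchical coefficient noise.

What the simulator does *not* emulate — so passing tests do not speak
to these features of real data: segmentation and classification
errors, non-rectangular tissue masks, target–target dependence beyond
the conditional Poisson assumption, and marker-intensity information.
Compartment confounding *is* emulated (Voronoi fields with
tiered log-intensity offsets: weak 0.3, moderate 0.7, strong 1.2,
centred to zero), and a kernel-density compartment covariate is
available to adjust for it.

# Baselines and the benchmark

G-cross uses the reduced-sample (border) correction; K-cross uses
translation weights and is reported on the L scale. Envelope tests
redraw the *to*-type uniformly at its observed count with the
*from*-type fixed — the standard conditioning for cross-type CSR
tests — and use extreme-rank-length (ERL) global envelopes at
$\alpha = 0.05$: each curve is ranked by its sorted vector of
two-sided pointwise ranks, which yields calibrated type-I error
(measured 2–9% at `n_sim = 99`) where naive pointwise min/max
envelopes are badly liberal (~15%).

`run_benchmark()` scores image-level detection, simultaneous
coverage, and type-I error on paired alternative/null studies, fully
seeded per (condition, replicate) so results are independent of
execution order and any replicate can be reproduced alone.

# Problem sizes

The shipped tests and the acceptance script run at reduced scale,
chosen as the smallest sizes at which each qualitative conclusion is
stable: benchmark conditions use 10 patients × 2 images with 10 (tests)
or 6 (script) replicates and 2-chain, 300+300-iteration fits; recovery
experiments use 4 patients with paired seeds across the
images-per-patient arms; envelope calibration uses 200 null patterns.
Full-scale runs (40 patients, 50 replicates, 4×1000+1000 sampling) use
the same code paths through the exported functions.

# Known limitations

* Curves are predictive associations, not causal effects; unmodelled
  architecture (compartments) biases them when both densities are
  high — use the compartment covariate when such structure is
  suspected.
* One target type per fit; cross-target dependence is out of scope.
* With a single image per patient the hierarchy scales are weakly
  identified and inference leans on the half-Normal hyperpriors;
  cohort curves are then conservative (shrunken toward zero).
* The HMC sampler is adequate for the model sizes the package targets
  (hundreds of images, a few sources); it is not a general-purpose
  probabilistic-programming backend.
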