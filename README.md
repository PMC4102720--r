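# multidm

Multisensory drift-diffusion modelling of reaction-time heading
discrimination.

## The problem

In a two-alternative heading task, observers judge whether self-motion is
directed left or right of straight ahead from optic flow (visual), inertial
motion (vestibular), or both. Classical cue-integration theory predicts the
combined discrimination threshold

σ²_pred = σ²_vis σ²_vest / (σ²_vis + σ²_vest) ≤ min(σ_vis, σ_vest),

but that prediction assumes the observer uses the whole stimulus. When the
observer chooses *when* to respond, a faster decision in the combined
condition can raise the measured threshold even if every sample of evidence
is used optimally. `multidm` implements the extended drift-diffusion model
that makes this precise, for researchers in perceptual decision-making and
multisensory integration.

## The model

Momentary evidence about sin(h) arrives with time-varying reliability:
visual sensitivity follows the stimulus velocity profile v(t) (a Gaussian
bump, peak 0.403 m/s, displacement 0.3 m in ≤ 2 s), vestibular sensitivity
follows the acceleration magnitude |a(t)|. Optimal accumulation weights
each increment by its momentary sensitivity; the weighted accumulator

dX = w(t)² μ dt + w(t) dW,  μ = k·sin(h − bias)/σ(c)

is a constant-drift unit-variance diffusion in the effective-time clock
s(t) = ∫ w(u)² du, absorbed at ±θ/σ(c). Across cues, sensitivities add in
squares (Fisher information is additive):

k_comb(c) = √(k_vis(c)² + k_vest²),  k_vis(c) = a_vis c^γ,

and the combined weighting profile satisfies
d(t)² = (k_vis² v(t)² + k_vest² |a(t)|²)/k_comb². Twelve core parameters
(sensitivities, bounds, variance scalings 1 + b c^γ, non-decision times)
plus per-condition biases and one lapse rate predict choice fractions and
mean reaction times of correct and error responses for every
modality × coherence × heading condition.

First-passage distributions are computed two independent ways: a spectral
series in effective time (fast path) and second-kind Volterra integral
equations for arbitrary drift/diffusion profiles (validator, and the
likelihood kernel for model variants that break the time-change structure).

## Worked example

```r
library(multidm)

params   <- multidm_params()                 # generative ground truth
nuisance <- multidm_nuisance(lapse = 0.03)
design   <- experiment_design(coherences = c(25, 37, 70),
                              trials_per_condition = 300)
trials   <- simulate_trials(params, nuisance, design, seed = 1)

fit <- multidm(trials, seed = 2, budget = list(mcmc = 400))
print(fit)
#> Extended diffusion model fit (variant: optimal)
#>   20 parameters, 16800 trials, 168 data points
#>   log-likelihood -6741.68, adjusted R2 0.986 (psych 0.993, chron 0.978)

psy <- fit_psychometric(trials)
th  <- setNames(psy$conditions$threshold, psy$conditions$condition)
round(th[c("visual:70", "vestibular", "combined:70")], 2)
#>  visual:70 vestibular combined:70
#>       3.70       2.53        2.60
predict_combined_threshold(th[["visual:70"]], th[["vestibular"]])
#> [1] 2.086226
```

The fitted model explains ~99% of the variance in the 168 per-condition
choice fractions and mean RTs it was fit to (the log-likelihood's scale is
dominated by the per-trial Bernoulli choice terms). The psychometric
thresholds (degrees) show the package's central phenomenon: the measured
combined threshold (2.60°) sits near the faster vestibular condition, well
above the classical fixed-duration prediction of 2.09° — even though the
generative accumulation is exactly optimal. Decisions in the combined
condition simply terminate sooner, so less evidence is integrated.

Model variants (`separate_k`, `no_cue_weighting`, `weight_by_acceleration`,
`weight_by_velocity`, `no_temporal_weighting`,
`no_cue_temporal_weighting`) are compared with
`multidm_compare()`, which pools −BIC/2 log-evidence over datasets into
log10 Bayes factors (|log10 BF| > 2 flagged decisive). Model-free analyses
include parametric-bootstrap threshold CIs (`bootstrap_thresholds`) and
Miller/Grice race-bound tests (`race_bound_tests`). A thin CLI over these
functions lives at `inst/cli/multidm.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — simulates a
three-coherence experiment from the default generative parameters, fits
the optimal model at a reduced sampling budget, runs the psychometric
analysis and the optimal-threshold prediction — and writes the JSON
report to `--out`.

See `vignettes/extended-diffusion-model.Rmd` for the model's assumptions,
parameter conventions, numerical choices and known limitations.
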