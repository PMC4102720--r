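---
title: "The extended multisensory diffusion model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended multisensory diffusion model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidm)
```

## The model and its assumptions

`multidm` models two-alternative heading discrimination under free response
timing. A diffusing decision variable accumulates momentary evidence about
sin(h) (h the heading angle, sign = direction) until it reaches one of two
symmetric bounds; bound identity gives the choice, crossing time plus a
modality-specific non-decision time gives the reaction time.

Three assumptions carry all of the model's structure:

1. **Time-varying sensitivity.** The stimulus follows a Gaussian velocity
   profile (peak 0.403 m/s, total displacement 0.3 m inside a 2 s window),
   so the information delivered per unit time is not constant. Visual
   (optic-flow) sensitivity is assumed proportional to stimulus velocity
   v(t); vestibular sensitivity to the acceleration magnitude |a(t)|,
   because the otolith organs transduce acceleration. Optimal accumulation
   then requires weighting each evidence increment by its momentary
   sensitivity. The weighted accumulator is a constant-drift,
   unit-variance diffusion in the *effective time* s(t) = ∫ w(u)² du,
   which is both the statistical statement of sufficiency (the posterior
   over sin(h) depends only on X(t) and s(t)) and the computational basis
   of the package's fast first-passage solver.
2. **Optimal cue combination.** Independent cues add Fisher information,
   so combined sensitivity is k_comb(c) = √(k_vis(c)² + k_vest²), and the
   combined weighting profile obeys
   d(t)² = (k_vis² v(t)² + k_vest² a(t)²)/k_comb². The package fixes d(t)
   by this information-consistency identity (posterior precision of the
   combined accumulator = sum of unimodal precisions at every t), which
   the test suite asserts to 1e-10.
3. **Coherence scaling.** Visual sensitivity follows
   k_vis(c) = a_vis·c^γ_vis with coherence c stored as a fraction in
   [0, 1], and the diffusion variance scales as 1 + b·c^γ (γ shared with
   the sensitivity exponent within the visual condition; the combined
   condition has its own b, γ). The variance scaling is motivated by a
   population code in which neural variance grows with total activity,
   and it is what lets the model produce coherence-dependent decision
   times even at h ≈ 0. Bounds θ are coherence-independent; the
   coherence-dependent diffusion SD is implemented exactly by rescaling
   to a unit-variance process with drift k·sin(h − bias)/σ(c) and bound
   θ/σ(c). The "0%" coherence display (actually 0.1%) is modelled as
   c = 0, the zero-information limit.

Twelve core parameters result: a_vis, γ_vis, b_vis, θ_vis; b_comb,
γ_comb, θ_comb; k_vest, θ_vest; and one non-decision time per modality.
Nuisance parameters are one heading bias per modality/coherence
combination (a horizontal psychometric shift, entering as sin(h − bias))
and a single lapse rate: the probability a choice is replaced by a fair
coin flip. Lapse trials keep the accumulator's reaction time — the data
attach lapsing to choices only, and any other convention would be an
unsupported assumption.

## Tunable parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| grid step (prediction) | s | 0.001 | RT precision far below fitted SEMs |
| grid step (fitting) | s | 0.005 | identical predictions to ~1e-4; 5× cheaper |
| trial deadline | s | 2 | experiment's maximum trial length |
| Euler step (simulation) | s | 0.001 (2.5e-4 for oracle runs) | discretization bias below 1 binomial SE |
| MCMC samples | — | 44000 | three-stage fitting default; reducible via `budget` |
| bootstrap samples | — | 5000 full analysis / ≥ a few hundred for CIs | percentile CIs |
| prior box | — | θ ∈ (0,10], k ∈ [0,50], γ ∈ (0,3], b ∈ [0,100], t_nd ∈ [0,1] s, lapse ∈ [0,0.2], |bias| ≤ 5° | uniform bounded prior of the sampler |

## First-passage computation

Two independent engines compute choice probabilities and RT densities:

* `fpt_time_change()` solves the constant-drift two-boundary problem in
  effective time with the classical series solution — a method-of-images
  representation below s/a² = 0.09 (a = bound separation) and a spectral
  representation above, both truncated far below 1e-8 relative error —
  then maps densities to real time with Jacobian w(t)². Absorption
  probabilities at the deadline come from exact term-wise integration of
  the spectral tail (with a direct quadrature fallback when the deadline
  is far shorter than the diffusion scale and essentially nothing is
  absorbed).
* `fpt_volterra()` discretizes the two-boundary second-kind Volterra
  integral equations for arbitrary drift/SD profiles, after reduction to
  a standard Brownian motion in variance time with curved boundaries
  (compiled kernel). The discrete boundary slope makes the diagonal
  kernel vanish, so the trapezoidal scheme is explicit.

On the Gaussian-profile model the two engines agree to total-variation
distance ~1e-8 at the 1 ms grid; the test suite enforces < 0.01 and also
checks both against Euler–Maruyama simulation. Variants whose drift and
diffusion profiles are not proportional (the equal-weight cue average)
cannot use the time change and are fitted through the Volterra engine; in
fitting loops that O(n²) solve runs on a grid decimated to ≤ 121 points,
which changes predicted summaries by far less than one empirical SEM.

**Deadline closure.** The task never states how non-responses at 2 s were
handled. Trials still undecided at the deadline are forced to the choice
given by the sign of the accumulated evidence (ties at random), reported
as `p_undecided_at_T`, and excluded from fitted RT means. With the default
generative parameters the forced mass is a few percent in most conditions,
rising to tens of percent only in the hardest low-coherence visual cells —
mirroring the long visual RTs near h = 0.

## The synthetic-data generator

`simulate_trials()` is the package's data generator (there is no deposited
human data): Euler–Maruyama paths of the unit-variance-normalized weighted
accumulator with a Brownian-bridge boundary-crossing correction — at each
step, paths whose endpoints remain inside the bounds are absorbed with the
bridge crossing probability exp(−2(θ − X_i)(θ − X_{i+1})/(σ_i²Δ)), which
removes the O(√Δ) widening of the effective bounds that a naive
discrete-time crossing check produces — per condition cell of the stated
design (headings ±0.686°,
±1.96°, ±5.6°, ±16°; coherences {25,37,70}% or {0,12,25,37,51,70}%; 2 s
deadline). The default ground truth — a_vis = 50, γ_vis = 1, b_vis = 1,
θ_vis = 0.7, b_comb = 1, γ_comb = 1, θ_comb = 0.8, k_vest = 25,
θ_vest = 0.8, t_nd = 0.35/0.30/0.30 s, lapse = 0.03 — was chosen once to
land in the experiment's observed regime: thresholds of roughly 2–6°
falling with coherence, mean RTs 0.9–1.4 s, the vestibular condition
faster than the visual one (acceleration information arrives earlier than
velocity information), and sensitivities inside the fitting box k ≤ 50.
θ_vis was lowered from an initial 0.85 to 0.7 during development because
the hardest visual cell otherwise left ~40% of trials undecided at the
deadline, which is unrealistic for this task.

What a green test on synthetic data does establish: the estimation
machinery recovers the generating process, the two first-passage routes
agree, and model comparison points at the generating model. What it does
not establish: anything about real observers — real data have sequential
dependencies, non-stationary lapsing, RT contaminants and
between-session drift that the generator deliberately omits.

## Fitting

`multidm()` follows a three-stage maximum-likelihood procedure: local
ascent from a data-driven start, 44,000 random-walk Metropolis samples of
the posterior under the uniform box prior (per-parameter steps adapted to
20–40% acceptance during the 20% burn-in), then local ascent from the
best sample. The likelihood treats per-condition rightward counts as a
Bernoulli product at the predicted choice probability (probabilities
clipped at 1e-12, with a warning) and the empirical mean RTs of correct
and error responses as Gaussian around the predicted means with the
empirical SEMs (degenerate SEMs floored at the dataset median, with a
warning; correctness classes with no trials contribute nothing; a
predicted class with vanishing probability but observed trials is scored
at the latest attainable RT, keeping the objective finite and bounded).

The ascent stages use Nelder–Mead with a simplex restart rather than a
gradient method: a numerical gradient costs ~2×dim likelihood
evaluations, each of which solves ~100 first-passage problems. The
data-driven start converts model-free psychometric fits into parameter
guesses — the psychometric slope pins the product k·θ/σ², the
chronometric intercept at the smallest heading pins θ through the
effective-time clock, and the fastest responses minus the profile's gate
time pin the non-decision times. Posterior samples are thinned to ≤ 2000
and exposed for interval summaries (`summary()`); note that short chains
in 20+ dimensions report local, badly over-narrow intervals — `vcov()`
computes the observed-information (Laplace) covariance at the optimum,
which is the better-calibrated uncertainty estimate under reduced
budgets and is what the package's own consistency checks use.

Goodness of fit is the average of observation-count-weighted adjusted R²
over choice fractions and over correct/error mean RTs, with the standard
1 − (1 − R²)(n − 1)/(n − p − 1) adjustment (the adjustment formula is a
documented package choice; only "adjusted for the number of parameters"
is stated for the original analysis).

## Model variants

`separate_k` frees k_comb at each coherence (one parameter per coherence;
it nests the optimal model). `no_cue_weighting` replaces the
information-weighted combination by the equal-weight average — implemented
as (Ẋ_vis + Ẋ_vest)/√2, so that the noise stays unit variance and equal
sensitivities reproduce the optimal model exactly; the alternative 1/2
scaling differs only by a factor absorbed into the free bound.
`weight_by_acceleration` / `weight_by_velocity` force both modalities'
weighting profiles to a(t) / v(t); `no_temporal_weighting` uses a constant
profile; `no_cue_temporal_weighting` combines the last two removals.
Variants are compared by BIC-approximated log evidence
(ln p(M|s) ≈ −BIC/2, BIC = −2 ln L + k ln N with N the number of trials),
pooled over datasets into base-10 log Bayes factors; |log10 BF| > 2 is
flagged decisive.

## Psychophysics

Psychometric functions are cumulative Gaussians in signed heading
(proportion rightward, not folded), one threshold and bias per
modality/coherence plus a single shared lapse, fitted jointly by profiling
the lapse over per-condition 2-parameter MLEs. Parametric bootstrap
(simulate counts from the fitted curves, refit) gives percentile 95% CIs;
the shared lapse is held at its point estimate during resampling for
speed, which leaves threshold CIs essentially unchanged. Threshold
comparisons are one-tailed bootstrap-difference tests, Bonferroni-corrected
across an explicitly declared comparison family (the original family size
is not enumerated anywhere, so it is a config choice here). The optimal
combined threshold prediction σ_pred is propagated through the same
bootstrap samples.

Race-model diagnostics compare the combined-condition RT CDF with
Miller's upper bound F_vis + F_vest and Grice's lower bound
max(F_vis, F_vest) per coherence/heading cell. Significance uses
permutation of modality labels (distribution-free and self-contained;
the analytic tests in the literature are external procedures). A
significant Grice violation is reported as "slower than parallel race" —
the signature of an elevated combined bound — and a significant Miller
violation as "faster than parallel race".

## Numerical choices and degenerate inputs

* Series truncation: image terms |k| ≤ 5, spectral terms k ≤ 21 (41 for
  tail integrals); switching point s/a² = 0.09; all beyond 1e-8 relative
  accuracy in their regime.
* Effective-time accumulation is trapezoidal, so a constant unit profile
  gives E(t) = t exactly on the grid.
* Exponentials are evaluated on combined log scales, so large drift ×
  bound products do not overflow.
* All-zero profiles, nonpositive bounds, empty designs, negative RTs,
  unknown modalities and missing seeds are rejected with errors; every
  stochastic entry point requires an explicit seed.
* Perfect psychometric separation pins the threshold at 0.01° and flags
  the condition.

## Known limitations

* The likelihood uses per-condition mean RTs (correct/error), not full RT
  distributions, matching the original analysis; the FPT densities would
  support full-distribution likelihoods but that is deliberately out of
  scope.
* Bounds are constant within a trial; collapsing bounds are out of scope.
* Short MCMC budgets give optimistic posterior intervals; the defaults
  (44,000 samples) are the reference, and every reduced budget is an
  explicit `budget` argument.
* The race-bound permutation tests exchangeability of all three modality
  samples, which is conservative in cells where one modality barely
  responds before the deadline.
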