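#' Core model parameters
#'
#' The 12 core parameters of the optimal multisensory diffusion model:
#' visual sensitivity scale and coherence exponent (`a_vis`, `gamma_vis`,
#' giving k_vis(c) = a_vis * c^gamma_vis with coherence c as a fraction in
#' \[0, 1\]), visual diffusion-variance scaling `b_vis` (variance
#' 1 + b_vis * c^gamma_vis, sharing the exponent with the sensitivity),
#' visual bound `theta_vis`; combined-condition variance scaling `b_comb`,
#' `gamma_comb` and bound `theta_comb`; vestibular sensitivity `k_vest` and
#' bound `theta_vest` (coherence-independent); and one non-decision time per
#' modality (`tnd_vis`, `tnd_vest`, `tnd_comb`, in seconds).
#'
#' Bounds are expressed in evidence units of the unit-variance baseline
#' process; the coherence-dependent diffusion SD is implemented by rescaling
#' to a unit-variance process with drift k*sin(h - bias)/sigma(c) and bound
#' theta/sigma(c), which is mathematically identical.
#'
#' @param a_vis,gamma_vis,b_vis,theta_vis visual-condition parameters.
#' @param b_comb,gamma_comb,theta_comb combined-condition parameters.
#' @param k_vest,theta_vest vestibular-condition parameters.
#' @param tnd_vis,tnd_vest,tnd_comb non-decision times (s).
#' @return An object of class `multidm_params` (a named list of 12 numbers).
#' @export
multidm_params <- function(a_vis = 50, gamma_vis = 1, b_vis = 1,
                           theta_vis = 0.7,
                           b_comb = 1, gamma_comb = 1, theta_comb = 0.8,
                           k_vest = 25, theta_vest = 0.8,
                           tnd_vis = 0.35, tnd_vest = 0.30, tnd_comb = 0.30) {
  p <- list(a_vis = a_vis, gamma_vis = gamma_vis, b_vis = b_vis,
            theta_vis = theta_vis, b_comb = b_comb, gamma_comb = gamma_comb,
            theta_comb = theta_comb, k_vest = k_vest, theta_vest = theta_vest,
            tnd_vis = tnd_vis, tnd_vest = tnd_vest, tnd_comb = tnd_comb)
  validate_params(p)
  structure(p, class = "multidm_params")
}

validate_params <- function(p) {
  stopifnot(length(p) == 12L)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all model parameters must be numeric")
  if (p$a_vis < 0 || p$k_vest < 0) stop("sensitivities must be >= 0")
  if (p$theta_vis <= 0 || p$theta_comb <= 0 || p$theta_vest <= 0)
    stop("bounds must be > 0")
  if (p$gamma_vis <= 0 || p$gamma_comb <= 0) stop("gamma must be > 0")
  if (p$b_vis < 0 || p$b_comb < 0) stop("b must be >= 0")
  if (p$tnd_vis < 0 || p$tnd_vest < 0 || p$tnd_comb < 0)
    stop("non-decision times must be >= 0")
  invisible(p)
}

#' @export
print.multidm_params <- function(x, ...) {
  cat("Extended diffusion model parameters (12 core):\n")
  print(unlist(x))
  invisible(x)
}

#' Nuisance parameters: per-condition biases and a shared lapse rate
#'
#' One heading bias (degrees, a horizontal shift of the psychometric
#' function: drift uses sin(h - bias)) per modality/coherence combination,
#' plus a single lapse rate: the probability that a trial's choice is
#' replaced by a fair coin flip, shared across all conditions.
#'
#' @param biases named numeric vector, one entry per modality/coherence
#'   combination, named as `"<modality>"` for vestibular and
#'   `"<modality>:<coherence%>"` otherwise (see [condition_labels()]).
#' @param lapse lapse probability in \[0, 1\].
#' @return An object of class `multidm_nuisance`.
#' @export
multidm_nuisance <- function(biases = numeric(0), lapse = 0) {
  stopifnot(is.numeric(biases), is.numeric(lapse), length(lapse) == 1L)
  if (lapse < 0 || lapse > 1) stop("lapse must be in [0, 1]")
  structure(list(biases = biases, lapse = lapse), class = "multidm_nuisance")
}

#' Modality/coherence condition labels of a design
#'
#' Vestibular trials have no coherence, so the vestibular label is plain
#' `"vestibular"`; visual and combined conditions are labelled per
#' coherence, e.g. `"visual:70"`. A 3-coherence design therefore has 7
#' combinations and a 6-coherence design has 13.
#'
#' @param coherences coherence levels in percent.
#' @return Character vector of condition labels.
#' @export
condition_labels <- function(coherences) {
  c(paste0("visual:", coherences), "vestibular",
    paste0("combined:", coherences))
}

condition_label <- function(modality, coherence) {
  ifelse(modality == "vestibular", "vestibular",
         paste0(modality, ":", format(coherence, trim = TRUE)))
}

get_bias <- function(nuisance, modality, coherence) {
  lab <- condition_label(modality, coherence)
  b <- nuisance$biases[lab]
  ifelse(is.na(b), 0, b)
}

#' Visual sensitivity as a function of motion coherence
#'
#' k_vis(c) = a_vis * c^gamma_vis, with coherence `c` a fraction in
#' \[0, 1\]. Zero coherence carries no heading information, so the
#' sensitivity vanishes there.
#'
#' @param c coherence as a fraction in \[0, 1\] (70% -> 0.7).
#' @param a_vis,gamma_vis scale and exponent.
#' @return Sensitivity (drift-rate coefficient per unit sin-heading).
#' @export
k_visual <- function(c, a_vis, gamma_vis) {
  if (any(c < 0)) stop("coherence must be >= 0")
  a_vis * c^gamma_vis
}

#' Optimal combined sensitivity
#'
#' Sensitivities add in squares (Fisher information is additive across
#' independent cues): k_comb = sqrt(k_vis^2 + k_vest^2), always at least
#' the larger unimodal sensitivity.
#'
#' @param k_vis,k_vest unimodal sensitivities (>= 0).
#' @return Combined sensitivity.
#' @export
k_combined <- function(k_vis, k_vest) {
  stopifnot(all(k_vis >= 0), all(k_vest >= 0))
  sqrt(k_vis^2 + k_vest^2)
}

#' Fisher information rate of an accumulator
#'
#' The information about sin(h) delivered per unit (effective) time is the
#' squared sensitivity, so information is additive across cues under the
#' optimal combination rule.
#'
#' @param k sensitivity (>= 0).
#' @return Information rate k^2.
#' @export
fisher_information <- function(k) {
  stopifnot(all(k >= 0))
  k^2
}

#' Coherence-dependent diffusion standard deviation
#'
#' The momentary-evidence variance is assumed proportional to
#' 1 + b * c^gamma (motivated by a neural population code in which response
#' variance scales with mean rate and total population activity grows
#' roughly linearly with coherence). Returns the SD multiplier
#' sqrt(1 + b * c^gamma), equal to 1 at c = 0.
#'
#' @param c coherence fraction in \[0, 1\].
#' @param b,gamma scaling coefficient (>= 0) and exponent.
#' @return SD multiplier (>= 1).
#' @export
diffusion_sd <- function(c, b, gamma) {
  stopifnot(all(b >= 0), all(c >= 0))
  sqrt(1 + b * c^gamma)
}

#' Combined temporal sensitivity profile
#'
#' The combined accumulator's sensitivity profile d(t) satisfies
#' d(t)^2 = (k_vis^2 v(t)^2 + k_vest^2 a(t)^2) / (k_vis^2 + k_vest^2),
#' the sensitivity-weighted mean of the squared unimodal profiles. This is
#' the unique profile for which the combined accumulator's posterior over
#' sin(h) carries exactly the information of the two unimodal accumulators
#' at every time: k_comb^2 * D(t) = k_vis^2 * V(t) + k_vest^2 * A(t), where
#' D, V, A are the respective effective times.
#'
#' @param v,a unit-peak velocity and acceleration-magnitude profiles on the
#'   same grid.
#' @param k_vis,k_vest unimodal sensitivities, not both zero.
#' @return A `temporal_profile` for the combined condition. Note d(t) is
#'   not re-normalized: its shape and scale are fixed by the consistency
#'   requirement (max d <= 1 when v and a are unit-peak).
#' @export
combined_profile <- function(v, a, k_vis, k_vest) {
  stopifnot(inherits(v, "temporal_profile"), inherits(a, "temporal_profile"))
  if (length(v$time) != length(a$time) ||
      max(abs(v$time - a$time)) > 1e-9)
    stop("v and a must share the same grid")
  if (k_vis == 0 && k_vest == 0) stop("k_vis and k_vest cannot both be zero")
  w <- k_vis^2 + k_vest^2
  d <- sqrt((k_vis^2 * v$values^2 + k_vest^2 * a$values^2) / w)
  temporal_profile(v$time, d, normalized = v$normalized && a$normalized)
}

#' Optimal combination of momentary evidence increments
#'
#' Increments from the two cues are averaged with weights proportional to
#' the squared sensitivities (i.e. each cue's Fisher information), which
#' sum to one. With equal sensitivities this is the plain arithmetic mean;
#' a cue with zero sensitivity is ignored entirely.
#'
#' @param dx_vis,dx_vest momentary evidence increments.
#' @param k_vis,k_vest sensitivities (>= 0, not both 0).
#' @return The optimally combined increment.
#' @export
combine_momentary_evidence <- function(dx_vis, dx_vest, k_vis, k_vest) {
  stopifnot(all(k_vis >= 0), all(k_vest >= 0))
  if (all(k_vis == 0 & k_vest == 0))
    stop("k_vis and k_vest cannot both be zero")
  (k_vis^2 * dx_vis + k_vest^2 * dx_vest) / (k_vis^2 + k_vest^2)
}

#' Posterior over sin(heading) from a weighted accumulator
#'
#' Under a flat prior, after accumulating sensitivity-weighted evidence X
#' for an effective time E with sensitivity k, the posterior of sin(h) is
#' Normal with mean X / (k E) and variance 1 / (k^2 E). With a constant
#' unit profile E = t and this reduces to the classical diffusion-model
#' posterior N(x/(kt), 1/(k^2 t)).
#'
#' @param X weighted accumulated evidence.
#' @param E effective time (> 0).
#' @param k sensitivity (> 0).
#' @return List with `mean` and `variance` of the posterior over sin(h).
#' @export
heading_posterior <- function(X, E, k) {
  if (any(E <= 0) || any(k <= 0))
    stop("posterior undefined for E <= 0 or k <= 0")
  list(mean = X / (k * E), variance = 1 / (k^2 * E))
}

#' Belief that heading is rightward
#'
#' The posterior probability that sin(h) > 0 given accumulated evidence x
#' at effective time t is the standard normal CDF of x / sqrt(t): the
#' decision variable and elapsed (effective) time are sufficient for the
#' choice.
#'
#' @param x accumulated evidence.
#' @param t effective time (> 0).
#' @return Probability in (0, 1).
#' @export
prob_rightward <- function(x, t) {
  if (any(t <= 0)) stop("effective time must be > 0")
  stats::pnorm(x / sqrt(t))
}
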