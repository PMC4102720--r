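## Per-condition model predictions: assemble drift, bound and weighting
## profile for a stimulus condition under a given model variant, and solve
## the first-passage problem.

#' Stimulus profile bundle for a trial window
#'
#' Builds the unit-peak velocity, acceleration-magnitude and constant
#' profiles used by the evidence model, from the physical Gaussian velocity
#' profile of the motion stimulus.
#'
#' @inheritParams gaussian_velocity_profile
#' @return List with elements `v`, `a`, `one` (unit-peak
#'   `temporal_profile`s), `time`, `step`, `duration`.
#' @export
stimulus_profiles <- function(duration = 2, step = 0.001,
                              peak_velocity = 0.403, displacement = 0.3) {
  vp <- gaussian_velocity_profile(peak_velocity, displacement, duration, step)
  v <- normalize_profile(vp)
  a <- normalize_profile(acceleration_profile(vp))
  one <- temporal_profile(v$time, rep(1, length(v$time)), normalized = TRUE)
  list(v = v, a = a, one = one, time = v$time, step = step,
       duration = duration)
}

#' Model variants
#'
#' Defines the prediction rule of the optimal model and its six
#' alternatives. `separate_k` frees the combined sensitivity at each
#' coherence (one extra parameter per coherence); `no_cue_weighting`
#' replaces the sensitivity-weighted cue combination by a plain average of
#' the weighted unimodal accumulators; `weight_by_acceleration` /
#' `weight_by_velocity` force both modalities to use the acceleration
#' (resp. velocity) profile; `no_temporal_weighting` drops the temporal
#' weighting (constant unit profile); `no_cue_temporal_weighting` drops
#' both.
#'
#' @param name one of `"optimal"`, `"separate_k"`, `"no_cue_weighting"`,
#'   `"weight_by_acceleration"`, `"weight_by_velocity"`,
#'   `"no_temporal_weighting"`, `"no_cue_temporal_weighting"`.
#' @return An object of class `multidm_variant`.
#' @export
make_variant <- function(name) {
  known <- c("optimal", "separate_k", "no_cue_weighting",
             "weight_by_acceleration", "weight_by_velocity",
             "no_temporal_weighting", "no_cue_temporal_weighting")
  if (!name %in% known)
    stop("unknown model variant: ", name,
         " (must be one of ", paste(known, collapse = ", "), ")")
  structure(list(name = name,
                 extra_per_coherence = identical(name, "separate_k")),
            class = "multidm_variant")
}

as_variant <- function(variant) {
  if (inherits(variant, "multidm_variant")) variant else make_variant(variant)
}

## Assemble the first-passage problem of one modality/coherence combination.
## Returns either a time-change setup (weighting profile + scalar drift
## coefficient) or a Volterra setup (drift and SD profiles), all normalized
## to a unit-variance baseline (drift and bound divided by sigma(c)).
cond_setup <- function(params, modality, coherence, profiles,
                       variant = "optimal", extra = NULL) {
  variant <- as_variant(variant)$name
  cf <- coherence / 100
  k_vis <- k_visual(cf, params$a_vis, params$gamma_vis)
  k_vest <- params$k_vest
  base <- switch(modality,
    visual = list(k = k_vis,
                  sigma = diffusion_sd(cf, params$b_vis, params$gamma_vis),
                  theta = params$theta_vis, tnd = params$tnd_vis,
                  profile = profiles$v),
    vestibular = list(k = k_vest, sigma = 1,
                      theta = params$theta_vest, tnd = params$tnd_vest,
                      profile = profiles$a),
    combined = list(k = k_combined(k_vis, k_vest),
                    sigma = diffusion_sd(cf, params$b_comb, params$gamma_comb),
                    theta = params$theta_comb, tnd = params$tnd_comb,
                    profile = combined_profile(profiles$v, profiles$a,
                                               k_vis, k_vest)),
    stop("unknown modality: ", modality))
  if (variant == "separate_k" && modality == "combined") {
    kc <- extra[paste0("k_comb:", format(coherence, trim = TRUE))]
    if (is.null(kc) || is.na(kc))
      stop("separate_k variant needs an extra k_comb parameter for coherence ",
           coherence)
    base$k <- as.numeric(kc)
  } else if (variant %in% c("weight_by_acceleration", "weight_by_velocity")) {
    base$profile <- if (variant == "weight_by_acceleration") profiles$a
                    else profiles$v
  } else if (variant == "no_temporal_weighting") {
    base$profile <- profiles$one
  } else if (variant == "no_cue_temporal_weighting") {
    base$profile <- profiles$one
    if (modality == "combined") {
      # equal-weight sum of unweighted streams, scaled by 1/sqrt(2) so the
      # noise stays unit variance: drift (k_vis + k_vest)/sqrt(2)
      base$k <- (k_vis + k_vest) / sqrt(2)
    }
  } else if (variant == "no_cue_weighting" && modality == "combined") {
    # equal-weight average of the temporally weighted unimodal streams:
    # drift and diffusion profiles are no longer proportional, so the
    # effective-time change does not apply and the Volterra engine is used
    # equal-weight combination (k_vis^2, k_vest^2 weights replaced by 1/2),
    # scaled by 1/sqrt(2) so that equal sensitivities reproduce the optimal
    # model exactly: drift (v^2 k_vis + a^2 k_vest)/sqrt(2), SD
    # sqrt((v^2 + a^2)/2)
    v <- profiles$v$values; a <- profiles$a$values
    q <- (v^2 * k_vis + a^2 * k_vest) / (sqrt(2) * base$sigma)
    sdprof <- sqrt((v^2 + a^2) / 2)
    time <- profiles$time
    # the O(n^2) Volterra solve only needs a modest grid inside fitting
    # loops; decimate to ~120 points (keeping the endpoints)
    n <- length(time)
    if (n > 121) {
      idx <- unique(c(seq(1L, n, by = ceiling((n - 1) / 120)), n))
      q <- q[idx]; sdprof <- sdprof[idx]; time <- time[idx]
    }
    return(list(type = "volterra", q = q, sdprof = sdprof,
                theta = base$theta / base$sigma,
                tnd = base$tnd, time = time))
  }
  list(type = "tc", k = base$k, sigma = base$sigma,
       theta = base$theta / base$sigma, tnd = base$tnd,
       profile = base$profile)
}

## time-change internals split so the drift-independent part (effective
## time grid and zero-drift density) can be shared across headings
tc_setup <- function(profile, bound, deadline = NULL) {
  time <- profile$time
  w2 <- profile$values^2
  if (!is.null(deadline)) {
    keep <- time <= deadline + 1e-12
    time <- time[keep]; w2 <- w2[keep]
  }
  n <- length(time)
  s <- c(0, cumsum((w2[-1] + w2[-n]) / 2 * diff(time)))
  list(time = time, w2 = w2, s = s, S = s[n], theta = bound,
       h0 = fp_h0(s, 2 * bound))
}

tc_eval <- function(setup, mu) {
  lh <- ifelse(setup$h0 > 0, log(setup$h0), -Inf)
  ex <- -mu^2 * setup$s / 2 + lh
  g_up <- exp(mu * setup$theta + ex)
  g_lo <- exp(-mu * setup$theta + ex)
  pr <- fp_probs(mu, setup$theta, setup$S)
  sv <- fp_survived(mu, setup$theta, setup$S)
  surv <- max(0, min(1, 1 - pr$p_up - pr$p_lo))
  surv_pos <- if (sv$tot > 1e-300) surv * sv$pos / sv$tot else surv / 2
  fpt_result(setup$time, g_up * setup$w2, g_lo * setup$w2,
             pr$p_up, pr$p_lo, surv, surv_pos, method = "time-change series")
}

#' Predict choice and reaction-time statistics for one stimulus condition
#'
#' Assembles the condition's normalized drift `k_m(c) sin(h - bias) /
#' sigma_m(c)`, bound `theta_m / sigma_m(c)` and weighting profile, solves
#' the first-passage problem, and reports the probability of a rightward
#' choice (including lapses and deadline-forced choices) and the mean
#' reaction times of correct and error responses (decision time plus the
#' modality's non-decision time; deadline-forced trials are excluded from
#' the RT means).
#'
#' Correctness is defined by sign agreement of the choice with the nominal
#' heading; for h = 0 the nominal rightward direction is used.
#'
#' @param params a [multidm_params] object.
#' @param nuisance a [multidm_nuisance] object.
#' @param modality `"visual"`, `"vestibular"` or `"combined"`.
#' @param coherence motion coherence in percent (ignored for vestibular).
#' @param heading heading angle in degrees (sign = direction).
#' @param profiles a [stimulus_profiles()] bundle.
#' @param variant model variant name or [make_variant()] object.
#' @param extra named vector of extra variant parameters (e.g.
#'   `k_comb:<coherence>` for `separate_k`).
#' @param deadline response deadline (s).
#' @return List with `p_right`, `mean_rt_correct`, `mean_rt_error`,
#'   `p_undecided` and the underlying `fpt` result.
#' @export
predict_condition <- function(params, nuisance, modality, coherence, heading,
                              profiles, variant = "optimal", extra = NULL,
                              deadline = profiles$duration) {
  setup <- cond_setup(params, modality, coherence, profiles, variant, extra)
  bias <- get_bias(nuisance, modality, coherence)
  sh <- sin((heading - bias) * pi / 180)
  res <- if (setup$type == "tc") {
    fpt_time_change(setup$k * sh / setup$sigma, setup$theta, setup$profile,
                    deadline)
  } else {
    fpt_volterra(setup$q * sh, setup$sdprof, setup$theta, setup$time)
  }
  finish_prediction(res, heading, nuisance$lapse, setup$tnd)
}

finish_prediction <- function(res, heading, lapse, tnd) {
  p_dm_right <- res$p_upper + res$p_forced_upper
  p_right <- lapse / 2 + (1 - lapse) * p_dm_right
  up_is_correct <- heading >= 0
  mean_correct <- if (up_is_correct) res$mean_rt_upper else res$mean_rt_lower
  mean_error <- if (up_is_correct) res$mean_rt_lower else res$mean_rt_upper
  list(p_right = p_right,
       mean_rt_correct = mean_correct + tnd,
       mean_rt_error = mean_error + tnd,
       p_undecided = res$p_undecided_at_T,
       fpt = res)
}

#' Predictions for a grid of conditions
#'
#' Vectorized version of [predict_condition()]: shares the
#' drift-independent part of the first-passage computation across headings
#' within each modality/coherence combination.
#'
#' @param conditions data frame with columns `modality`, `coherence`,
#'   `heading`.
#' @inheritParams predict_condition
#' @return The `conditions` data frame with columns `p_right`,
#'   `mean_rt_correct`, `mean_rt_error`, `p_undecided` appended.
#' @export
predict_conditions <- function(params, nuisance, conditions, profiles,
                               variant = "optimal", extra = NULL,
                               deadline = profiles$duration) {
  conditions$p_right <- NA_real_
  conditions$mean_rt_correct <- NA_real_
  conditions$mean_rt_error <- NA_real_
  conditions$p_undecided <- NA_real_
  key <- paste(conditions$modality, conditions$coherence)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    modality <- conditions$modality[idx[1]]
    coherence <- conditions$coherence[idx[1]]
    setup <- cond_setup(params, modality, coherence, profiles, variant, extra)
    bias <- get_bias(nuisance, modality, coherence)
    tcs <- if (setup$type == "tc")
      tc_setup(setup$profile, setup$theta, deadline) else NULL
    for (i in idx) {
      h <- conditions$heading[i]
      sh <- sin((h - bias) * pi / 180)
      res <- if (setup$type == "tc") {
        tc_eval(tcs, setup$k * sh / setup$sigma)
      } else {
        fpt_volterra(setup$q * sh, setup$sdprof, setup$theta, setup$time)
      }
      pred <- finish_prediction(res, h, nuisance$lapse, setup$tnd)
      conditions$p_right[i] <- pred$p_right
      conditions$mean_rt_correct[i] <- pred$mean_rt_correct
      conditions$mean_rt_error[i] <- pred$mean_rt_error
      conditions$p_undecided[i] <- pred$p_undecided
    }
  }
  conditions
}
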