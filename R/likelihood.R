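## Likelihood of a trial table under the extended diffusion model, and the
## parameter-vector packing used by the optimizer and sampler.

## derive the design implicit in a trial table
infer_design <- function(data, max_duration = 2) {
  modalities <- intersect(c("visual", "vestibular", "combined"),
                          unique(data$modality))
  coh <- sort(unique(data$coherence[data$modality != "vestibular"]))
  if (length(coh) == 0) coh <- 0
  experiment_design(headings = unique(abs(data$heading_deg)),
                    coherences = coh, modalities = modalities,
                    trials_per_condition = 1,
                    max_duration = max_duration)
}

## parameter vector layout for a variant: 12 core, optional extras,
## one bias per observed modality/coherence combination, one lapse
par_layout <- function(variant, combo_labels, coherences) {
  variant <- as_variant(variant)
  core <- c("a_vis", "gamma_vis", "b_vis", "theta_vis",
            "b_comb", "gamma_comb", "theta_comb",
            "k_vest", "theta_vest", "tnd_vis", "tnd_vest", "tnd_comb")
  extra <- if (variant$extra_per_coherence)
    paste0("k_comb:", format(coherences, trim = TRUE)) else character(0)
  bias <- paste0("bias:", combo_labels)
  c(core, extra, bias, "lapse")
}

unpack_par <- function(theta, layout) {
  names(theta) <- layout
  core <- as.list(theta[1:12])
  params <- structure(core, class = "multidm_params")
  is_extra <- grepl("^k_comb:", layout)
  extra <- theta[is_extra]
  names(extra) <- layout[is_extra]
  is_bias <- grepl("^bias:", layout)
  biases <- theta[is_bias]
  names(biases) <- sub("^bias:", "", layout[is_bias])
  list(params = params,
       nuisance = multidm_nuisance(biases, theta[["lapse"]]),
       extra = extra)
}

pack_par <- function(params, nuisance, extra, layout) {
  v <- c(unlist(params[1:12]), extra,
         stats::setNames(nuisance$biases,
                         paste0("bias:", names(nuisance$biases))),
         lapse = nuisance$lapse)
  v <- v[match(layout, c(names(params), names(extra),
                         paste0("bias:", names(nuisance$biases)), "lapse"))]
  stats::setNames(v, layout)
}

## default box constraints (uniform bounded prior of the sampler)
default_box <- function(layout) {
  lower <- upper <- stats::setNames(numeric(length(layout)), layout)
  for (i in seq_along(layout)) {
    nm <- layout[i]
    b <- if (nm %in% c("a_vis", "k_vest") || grepl("^k_comb:", nm))
      c(0, 50)
    else if (grepl("^theta", nm)) c(1e-3, 10)
    else if (grepl("^gamma", nm)) c(1e-2, 3)
    else if (grepl("^b_", nm)) c(0, 100)
    else if (grepl("^tnd", nm)) c(0, 1)
    else if (nm == "lapse") c(0, 0.2)
    else if (grepl("^bias:", nm)) c(-5, 5)
    else stop("no box for parameter ", nm)
    lower[i] <- b[1]; upper[i] <- b[2]
  }
  list(lower = lower, upper = upper)
}

## core likelihood from per-condition aggregates and model predictions.
## Returns the log-likelihood with attributes counting clipped choice
## probabilities and floored SEMs.
loglik_from_agg <- function(agg, pred, deadline, tnd_by_row) {
  eps <- 1e-12
  p <- pmin(pmax(pred$p_right, eps), 1 - eps)
  n_clip <- sum(pred$p_right < eps | pred$p_right > 1 - eps)
  # Bernoulli product per condition (no binomial coefficient), so a chance
  # model on balanced data contributes exactly n * log(1/2)
  ll <- sum(agg$n_right * log(p) + (agg$n - agg$n_right) * log1p(-p))
  sems <- c(agg$sem_rt_correct, agg$sem_rt_error)
  floor_sem <- stats::median(sems[is.finite(sems) & sems > 0])
  n_floor <- 0L
  rt_term <- function(n_obs, m_obs, s_obs, m_pred, tnd) {
    ok <- n_obs > 0 & is.finite(m_obs)
    if (!any(ok)) return(0)
    s <- s_obs
    bad <- ok & (!is.finite(s) | s <= 0)
    if (any(bad)) {
      if (!is.finite(floor_sem)) return(0)
      s[bad] <- floor_sem
      n_floor <<- n_floor + sum(bad)
    }
    mp <- m_pred
    # a predicted class with vanishing probability still has to answer for
    # observed trials of that class: use the latest attainable RT
    na_pred <- ok & !is.finite(mp)
    mp[na_pred] <- deadline + tnd[na_pred]
    sum(stats::dnorm(mp[ok], m_obs[ok], s[ok], log = TRUE))
  }
  ll <- ll +
    rt_term(agg$n_correct, agg$mean_rt_correct, agg$sem_rt_correct,
            pred$mean_rt_correct, tnd_by_row) +
    rt_term(agg$n_error, agg$mean_rt_error, agg$sem_rt_error,
            pred$mean_rt_error, tnd_by_row)
  attr(ll, "n_clipped") <- n_clip
  attr(ll, "n_sem_floored") <- n_floor
  ll
}

tnd_of <- function(params, modality) {
  unlist(params[c(visual = "tnd_vis", vestibular = "tnd_vest",
                  combined = "tnd_comb")[modality]], use.names = FALSE)
}

#' Log-likelihood of a trial table under the model
#'
#' Sum over conditions of the binomial log-likelihood of the rightward
#' counts at the model's predicted choice probability (as a Bernoulli
#' product, without the combinatorial constant), plus Gaussian
#' log-densities of the predicted mean reaction times (correct and error
#' separately) under Normal(empirical mean, empirical SEM). Conditions
#' with no trials of a correctness class contribute no RT term; degenerate
#' SEMs are floored at the dataset's median SEM (reported via a warning),
#' and predicted choice probabilities are clipped to \[1e-12, 1 - 1e-12\].
#'
#' @inheritParams predict_condition
#' @param data a trial table.
#' @param step time-grid step (s) for the first-passage computation.
#' @return Log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(params, nuisance, data, variant = "optimal",
                           extra = NULL, step = 0.005, deadline = 2) {
  agg <- aggregate_trials(data)
  profiles <- stimulus_profiles(duration = deadline, step = step)
  conds <- agg[, c("modality", "coherence", "heading")]
  pred <- predict_conditions(params, nuisance, conds, profiles, variant,
                             extra)
  ll <- loglik_from_agg(agg, pred, deadline, tnd_of(params, agg$modality))
  if (attr(ll, "n_clipped") > 0)
    warning(attr(ll, "n_clipped"),
            " predicted choice probabilities clipped at 1e-12",
            call. = FALSE)
  if (attr(ll, "n_sem_floored") > 0)
    warning(attr(ll, "n_sem_floored"),
            " degenerate RT SEMs floored at the dataset median",
            call. = FALSE)
  as.numeric(ll)
}

#' Adjusted goodness of fit of model predictions
#'
#' Observation-count-weighted adjusted coefficients of determination for
#' the psychometric function (choice fractions) and the chronometric
#' function (mean RTs of correct and error responses), each adjusted for
#' the number of model parameters via `1 - (1 - R2)(n - 1)/(n - p - 1)`,
#' and their average.
#'
#' @param agg per-condition aggregates ([aggregate_trials()]).
#' @param pred matching predictions ([predict_conditions()]).
#' @param n_params number of model parameters for the adjustment.
#' @return List with `r2_psych`, `r2_chron`, `r2_mean`.
#' @export
adjusted_r2 <- function(agg, pred, n_params = 0) {
  wr2 <- function(obs, prd, w) {
    ok <- is.finite(obs) & is.finite(prd) & is.finite(w) & w > 0
    obs <- obs[ok]; prd <- prd[ok]; w <- w[ok]
    n <- length(obs)
    if (n < 2) return(NA_real_)
    mu <- sum(w * obs) / sum(w)
    r2 <- 1 - sum(w * (obs - prd)^2) / sum(w * (obs - mu)^2)
    if (n - n_params - 1 > 0)
      r2 <- 1 - (1 - r2) * (n - 1) / (n - n_params - 1)
    r2
  }
  r2_psych <- wr2(agg$p_right, pred$p_right, agg$n)
  r2_chron <- wr2(c(agg$mean_rt_correct, agg$mean_rt_error),
                  c(pred$mean_rt_correct, pred$mean_rt_error),
                  c(agg$n_correct, agg$n_error))
  list(r2_psych = r2_psych, r2_chron = r2_chron,
       r2_mean = (r2_psych + r2_chron) / 2)
}
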