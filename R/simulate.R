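#' Experiment design
#'
#' The heading-discrimination design: headings symmetric about straight
#' ahead (defaults to the laboratory values +/-0.686, +/-1.96, +/-5.6,
#' +/-16 degrees), motion coherences in percent (three- or six-level
#' versions), stimulus modalities, trials per condition and the trial
#' deadline.
#'
#' @param headings heading angles in degrees, symmetric about 0.
#' @param coherences coherence levels in percent, unique.
#' @param modalities subset of `"visual"`, `"vestibular"`, `"combined"`.
#' @param trials_per_condition trials per (modality/coherence/heading) cell.
#' @param max_duration trial deadline in seconds.
#' @return An object of class `multidm_design`.
#' @export
experiment_design <- function(headings = c(0.686, 1.96, 5.6, 16),
                              coherences = c(25, 37, 70),
                              modalities = c("visual", "vestibular",
                                             "combined"),
                              trials_per_condition = 100,
                              max_duration = 2) {
  headings <- sort(unique(c(-abs(headings), abs(headings))))
  if (max(abs(headings + rev(headings))) > 1e-9)
    stop("headings must be symmetric about zero")
  coherences <- sort(coherences)
  if (anyDuplicated(coherences)) stop("coherences must be unique")
  if (any(coherences < 0 | coherences > 100))
    stop("coherences must be in [0, 100] percent")
  modalities <- match.arg(modalities,
                          c("visual", "vestibular", "combined"),
                          several.ok = TRUE)
  if (trials_per_condition <= 0) stop("trials_per_condition must be > 0")
  structure(list(headings = headings, coherences = coherences,
                 modalities = modalities,
                 trials_per_condition = trials_per_condition,
                 max_duration = max_duration),
            class = "multidm_design")
}

#' @export
print.multidm_design <- function(x, ...) {
  cat(sprintf(
    "Design: %d headings x %d coherences, modalities {%s}, %d trials/cond, %.3g s deadline\n",
    length(x$headings), length(x$coherences),
    paste(x$modalities, collapse = ", "), x$trials_per_condition,
    x$max_duration))
  invisible(x)
}

#' Condition grid of a design
#'
#' One row per modality/coherence/heading cell (vestibular carries a
#' single nominal coherence of 0); the grid format consumed by
#' [predict_conditions()].
#'
#' @param design a [experiment_design()] object.
#' @return Data frame with columns `modality`, `coherence`, `heading`.
#' @export
design_conditions <- function(design) {
  out <- list()
  for (m in design$modalities) {
    coh <- if (m == "vestibular") 0 else design$coherences
    out[[m]] <- expand.grid(modality = m, coherence = coh,
                            heading = design$headings,
                            stringsAsFactors = FALSE)
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' Number of fitted data points of a design
#'
#' Each modality/coherence combination contributes, per heading, a choice
#' fraction plus mean reaction times for correct and for error trials:
#' `combos * headings * 3`. The six-coherence design has 13 combinations
#' and 8 headings, giving 312 data points; the three-coherence version
#' gives 168.
#'
#' @param design a [experiment_design()] object.
#' @return Integer count.
#' @export
count_data_points <- function(design) {
  n_comb <- sum(vapply(design$modalities, function(m)
    if (m == "vestibular") 1L else length(design$coherences), integer(1)))
  n_comb * length(design$headings) * 3L
}

#' Parameter counts of a model variant under a design
#'
#' The optimal model has 12 core parameters; `separate_k` adds one combined
#' sensitivity per coherence. Nuisance parameters are one heading bias per
#' modality/coherence combination plus a single shared lapse rate (14 for
#' the six-coherence design, 8 for the three-coherence version).
#'
#' @param variant variant name or [make_variant()] object.
#' @param design a [experiment_design()] object.
#' @return Named integer vector `c(core = ..., nuisance = ...)`.
#' @export
count_parameters <- function(variant, design) {
  variant <- as_variant(variant)
  core <- 12L
  if (variant$extra_per_coherence)
    core <- core + length(design$coherences)
  n_comb <- sum(vapply(design$modalities, function(m)
    if (m == "vestibular") 1L else length(design$coherences), integer(1)))
  c(core = core, nuisance = n_comb + 1L)
}

#' Probability that a star follows one trajectory
#'
#' In the random-dot optic-flow display a fraction c/100 of stars is
#' redrawn coherently on each video update, so the probability that a
#' single star follows the heading-consistent trajectory for N updates is
#' `(c/100)^N`. At 70% coherence and 10 updates (0.17 s) this is about 3%,
#' making individual star tracking practically impossible.
#'
#' @param c coherence in percent (0-100).
#' @param n_updates number of consecutive video updates.
#' @return Probability.
#' @export
star_trajectory_probability <- function(c, n_updates) {
  stopifnot(all(c >= 0), all(c <= 100), all(n_updates >= 0))
  (c / 100)^n_updates
}

#' Field of view of a flat screen
#'
#' Horizontal and vertical visual angle subtended by a flat screen of the
#' given physical size at the given viewing distance:
#' `2 * atan(dim / (2 * distance))` per axis. The laboratory geometry
#' (149 x 127 cm at ~70 cm) gives roughly 94 x 84 degrees.
#'
#' @param screen_w,screen_h screen width and height (cm).
#' @param distance viewing distance (cm).
#' @return Named numeric vector `c(horizontal = ..., vertical = ...)` in
#'   degrees.
#' @export
field_of_view <- function(screen_w, screen_h, distance) {
  stopifnot(screen_w > 0, screen_h > 0, distance > 0)
  c(horizontal = 2 * atan(screen_w / (2 * distance)) * 180 / pi,
    vertical = 2 * atan(screen_h / (2 * distance)) * 180 / pi)
}

#' Simulate trial-level behavior from the generative model
#'
#' Euler-Maruyama simulation of the sensitivity-weighted accumulator for
#' every condition cell of a design: the unit-variance-normalized particle
#' `dX = w(t)^2 mu dt + w(t) dW` is absorbed at `+/- theta/sigma(c)`;
#' reaction time is decision time plus the modality's non-decision time.
#' Trials still undecided at the deadline are forced to the choice given by
#' the sign of the accumulated evidence (ties broken at random) and flagged
#' in the `forced` column. Lapse trials keep the accumulator's reaction
#' time but replace the choice with a fair coin flip.
#'
#' @param params a [multidm_params] object.
#' @param nuisance a [multidm_nuisance] object.
#' @param design a [experiment_design()] object.
#' @param seed integer seed (mandatory: no silent nondeterminism).
#' @param step Euler step in seconds (default 1 ms; 0.1 ms for
#'   oracle-grade runs).
#' @param variant generative variant (default `"optimal"`).
#' @param extra extra variant parameters (see [predict_condition()]).
#' @param subject subject label stored in the table.
#' @param tnd_jitter optional SD (s) of Gaussian non-decision-time jitter,
#'   default 0 (constant non-decision time, as in the fitted model).
#' @return A `trial_table` data frame with columns `subject`, `modality`,
#'   `coherence`, `heading_deg`, `choice`, `rt_s`, `correct`, `forced`.
#' @export
simulate_trials <- function(params, nuisance, design, seed, step = 0.001,
                            variant = "optimal", extra = NULL,
                            subject = "sim", tnd_jitter = 0) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  profiles <- stimulus_profiles(duration = design$max_duration, step = step)
  conds <- design_conditions(design)
  nt <- design$trials_per_condition
  time <- profiles$time
  ngrid <- length(time)
  sqdt <- sqrt(step)
  rows <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    modality <- conds$modality[ci]
    coherence <- conds$coherence[ci]
    heading <- conds$heading[ci]
    setup <- cond_setup(params, modality, coherence, profiles, variant, extra)
    bias <- get_bias(nuisance, modality, coherence)
    sh <- sin((heading - bias) * pi / 180)
    if (setup$type == "tc") {
      w <- setup$profile$values
      driftvec <- w^2 * setup$k * sh / setup$sigma
      sdvec <- w
    } else {
      driftvec <- setup$q * sh
      sdvec <- setup$sdprof
    }
    theta <- setup$theta
    X <- numeric(nt)
    dtime <- rep(NA_real_, nt)
    bound <- integer(nt)                       # +1 upper, -1 lower, 0 none
    active <- rep(TRUE, nt)
    for (i in 2:ngrid) {
      idx <- which(active)
      na <- length(idx)
      if (na == 0) break
      Xold <- X[idx]
      Xnew <- Xold + driftvec[i] * step + sdvec[i] * sqdt * stats::rnorm(na)
      X[idx] <- Xnew
      hit_up <- Xnew >= theta
      hit_lo <- Xnew <= -theta
      # Brownian-bridge correction: the path may have grazed a bound
      # between grid points even when both endpoints lie inside; without
      # it, simulated bounds are effectively widened by O(sqrt(step))
      inside <- !hit_up & !hit_lo
      if (any(inside) && sdvec[i] > 0) {
        v2 <- sdvec[i]^2 * step
        pu <- exp(-2 * (theta - Xold[inside]) * (theta - Xnew[inside]) / v2)
        pl <- exp(-2 * (theta + Xold[inside]) * (theta + Xnew[inside]) / v2)
        u <- stats::runif(sum(inside))
        graze_up <- u < pu
        graze_lo <- !graze_up & (u < pu + pl)
        hit_up[inside] <- graze_up
        hit_lo[inside] <- graze_lo
      }
      bound[idx[hit_up]] <- 1L
      bound[idx[hit_lo]] <- -1L
      dtime[idx[hit_up | hit_lo]] <- time[i]
      active[idx[hit_up | hit_lo]] <- FALSE
    }
    forced <- is.na(dtime)
    if (any(forced)) {
      sgn <- sign(X[forced])
      ties <- sgn == 0
      if (any(ties)) sgn[ties] <- sample(c(-1, 1), sum(ties), replace = TRUE)
      bound[forced] <- as.integer(sgn)
      dtime[forced] <- design$max_duration
    }
    rt <- dtime + setup$tnd
    if (tnd_jitter > 0)
      rt <- pmax(dtime, rt + stats::rnorm(nt, 0, tnd_jitter))
    choice <- ifelse(bound > 0, "right", "left")
    lapsed <- stats::runif(nt) < nuisance$lapse
    if (any(lapsed))
      choice[lapsed] <- sample(c("left", "right"), sum(lapsed),
                               replace = TRUE)
    correct <- (choice == "right") == (heading >= 0)
    rows[[ci]] <- data.frame(
      subject = subject, modality = modality, coherence = coherence,
      heading_deg = heading, choice = choice, rt_s = rt,
      correct = correct, forced = forced, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  attr(out, "design") <- design
  out
}

#' Per-condition aggregates of a trial table
#'
#' For each (modality, coherence, heading) cell: trial count, rightward
#' count and fraction, and mean/SEM of reaction time split by correctness.
#' Deadline-forced trials contribute to choice fractions but are excluded
#' from the reaction-time means.
#'
#' @param trials a trial table (see [simulate_trials()], [read_trials()]).
#' @return Data frame of per-condition aggregates.
#' @export
aggregate_trials <- function(trials) {
  key <- interaction(trials$modality, trials$coherence, trials$heading_deg,
                     drop = TRUE)
  forced <- if ("forced" %in% names(trials)) trials$forced
            else rep(FALSE, nrow(trials))
  agg <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    tr <- trials[idx, ]
    fr <- forced[idx]
    rt_stats <- function(sel) {
      r <- tr$rt_s[sel & !fr]
      if (length(r) == 0) return(c(NA_real_, NA_real_, 0))
      c(mean(r), stats::sd(r) / sqrt(length(r)), length(r))
    }
    sc <- rt_stats(tr$correct)
    se <- rt_stats(!tr$correct)
    data.frame(modality = tr$modality[1], coherence = tr$coherence[1],
               heading = tr$heading_deg[1],
               n = nrow(tr), n_right = sum(tr$choice == "right"),
               p_right = mean(tr$choice == "right"),
               n_correct = sc[3], mean_rt_correct = sc[1],
               sem_rt_correct = sc[2],
               n_error = se[3], mean_rt_error = se[1],
               sem_rt_error = se[2],
               n_forced = sum(fr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$modality, out$coherence, out$heading), ]
  rownames(out) <- NULL
  out
}
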