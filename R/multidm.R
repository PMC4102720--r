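#' Fit the extended multisensory diffusion model to behavioral data
#'
#' Maximum-likelihood fit of the extended drift-diffusion model (optimal
#' sensitivity-weighted accumulation across time and cues, or one of its
#' suboptimal variants) to a trial table of choices and reaction times,
#' using the three-stage procedure: (1) local likelihood ascent from a
#' default start, (2) random-walk Metropolis sampling of the parameter
#' posterior under a uniform bounded prior (44,000 samples by default),
#' (3) local ascent from the best posterior sample.
#'
#' The likelihood treats per-condition rightward counts as binomial at the
#' model's predicted choice probability, and the empirical mean reaction
#' times of correct and error responses as Gaussian around the model's
#' predicted means with the empirical standard errors.
#'
#' @param data trial table: data frame with columns `modality`,
#'   `coherence` (percent), `heading_deg`, `choice` (`"left"`/`"right"`),
#'   `rt_s` (see [simulate_trials()], [read_trials()]).
#' @param variant model variant name or [make_variant()] object.
#' @param seed integer seed controlling the sampler (mandatory).
#' @param budget list of computational budgets: `mcmc` (posterior samples,
#'   default 44000), `stage1_maxit`, `stage3_maxit` (optimizer iteration
#'   caps), `keep` (stored thinned samples).
#' @param step time-grid step (s) of the first-passage computations during
#'   fitting; 5 ms keeps the likelihood smooth at a fraction of the 1 ms
#'   grid's cost.
#' @param box list with named vectors `lower`, `upper` overriding the
#'   default uniform prior box.
#' @param start optional named start vector (defaults to a fixed heuristic
#'   start with the non-decision times anchored just below the fastest
#'   observed responses).
#' @param deadline trial deadline in seconds.
#' @param verbose print per-stage progress.
#' @return An object of class `multidm`: the maximum-likelihood parameters
#'   (`$params`, `$nuisance`, `$extra`, flat vector via [coef()]), the
#'   maximized log-likelihood ([logLik()]), per-condition aggregates and
#'   fitted predictions, adjusted R-squared components, thinned posterior
#'   samples (`$samples`), and fitting metadata.
#' @seealso [predict.multidm()], [simulate.multidm()], [multidm_compare()]
#' @export
multidm <- function(data, variant = "optimal", seed,
                    budget = list(), step = 0.005, box = NULL,
                    start = NULL, deadline = 2, verbose = FALSE) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (nrow(data) == 0) stop("empty trial table")
  variant <- as_variant(variant)
  set.seed(seed)
  bdg <- utils::modifyList(list(mcmc = 44000, stage1_maxit = 1000,
                                stage3_maxit = 1000, keep = 2000), budget)
  agg <- aggregate_trials(data)
  design <- infer_design(data, max_duration = deadline)
  combos <- unique(condition_label(agg$modality, agg$coherence))
  layout <- par_layout(variant, combos, design$coherences)
  bx <- default_box(layout)
  if (!is.null(box)) {
    if (!is.null(box$lower)) bx$lower[names(box$lower)] <- box$lower
    if (!is.null(box$upper)) bx$upper[names(box$upper)] <- box$upper
  }
  if (any(!is.finite(bx$lower)) || any(!is.finite(bx$upper)))
    stop("box constraints must be finite")
  profiles <- stimulus_profiles(duration = deadline, step = step)
  conds <- agg[, c("modality", "coherence", "heading")]

  obj <- function(theta) {
    up <- unpack_par(theta, layout)
    pred <- try(predict_conditions(up$params, up$nuisance, conds, profiles,
                                   variant, up$extra), silent = TRUE)
    if (inherits(pred, "try-error")) return(-Inf)
    ll <- loglik_from_agg(agg, pred, deadline,
                          tnd_of(up$params, agg$modality))
    if (!is.finite(ll)) return(-Inf)
    as.numeric(ll)
  }

  if (is.null(start)) {
    start <- multidm_start(data, agg, layout, profiles, deadline)
  } else {
    start <- start[layout]
    if (any(is.na(start))) stop("start vector misses parameters")
  }
  start <- pmin(pmax(start, bx$lower), bx$upper)
  ll0 <- obj(start)
  tries <- 0
  while (!is.finite(ll0) && tries < 20) {
    start <- bx$lower + stats::runif(length(layout)) * (bx$upper - bx$lower)
    ll0 <- obj(start)
    tries <- tries + 1
  }
  if (!is.finite(ll0))
    stop("could not find a finite-likelihood starting point")

  pscale <- pmax((bx$upper - bx$lower) / 10, 1e-3)
  # Nelder-Mead ascent (no numerical gradients: each likelihood evaluation
  # solves ~100 first-passage problems); the box is enforced by clamping
  # with a smooth quadratic penalty on the excursion
  ascend <- function(from, maxit) {
    fn <- function(th) {
      cl <- pmin(pmax(th, bx$lower), bx$upper)
      v <- obj(cl)
      if (!is.finite(v)) return(1e10)
      -v + 1e4 * sum(((th - cl) / pscale)^2)
    }
    o <- stats::optim(from, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, parscale = pscale,
                                     reltol = 1e-10))
    par <- pmin(pmax(o$par, bx$lower), bx$upper)
    list(par = stats::setNames(par, layout), value = obj(par))
  }
  if (verbose) message("stage 1: local ascent (loglik at start ",
                       formatC(ll0, format = "f", digits = 1), ")")
  s1 <- ascend(start, bdg$stage1_maxit)
  # restarting the simplex at the optimum is cheap and often recovers
  # progress a collapsed simplex left on the table
  s1b <- ascend(s1$par, bdg$stage1_maxit)
  if (s1b$value > s1$value) s1 <- s1b
  if (verbose) message("stage 1 done: loglik ",
                       formatC(s1$value, format = "f", digits = 1))

  # stage 2: Gaussian random-walk Metropolis under the uniform boxed prior,
  # per-parameter steps tuned to 20-40% acceptance during burn-in
  nmc <- bdg$mcmc
  nkeep <- min(bdg$keep, max(1, nmc))
  samples <- NULL; best <- s1; acc_rate <- NA_real_
  if (nmc > 0) {
    stepsd <- (bx$upper - bx$lower) / 200
    cur <- s1$par; cur_ll <- s1$value
    burn <- max(1, floor(nmc * 0.2))
    thin <- max(1, floor((nmc - burn) / nkeep))
    samples <- matrix(NA_real_, nrow = 0, ncol = length(layout),
                      dimnames = list(NULL, layout))
    kept <- vector("list", ceiling((nmc - burn) / thin))
    ki <- 0L; acc <- 0L; acc_win <- 0L
    for (it in seq_len(nmc)) {
      prop <- cur + stats::rnorm(length(cur), 0, stepsd)
      ok <- all(prop >= bx$lower & prop <= bx$upper)
      if (ok) {
        prop_ll <- obj(prop)
        if (is.finite(prop_ll) &&
            log(stats::runif(1)) < prop_ll - cur_ll) {
          cur <- prop; cur_ll <- prop_ll
          acc <- acc + 1L; acc_win <- acc_win + 1L
          if (cur_ll > best$value)
            best <- list(par = stats::setNames(cur, layout), value = cur_ll)
        }
      }
      if (it <= burn && it %% 50 == 0) {
        r <- acc_win / 50
        if (r < 0.2) stepsd <- stepsd * 0.7
        if (r > 0.4) stepsd <- stepsd * 1.3
        acc_win <- 0L
      }
      if (it > burn && (it - burn) %% thin == 0) {
        ki <- ki + 1L
        kept[[ki]] <- cur
      }
    }
    if (ki > 0)
      samples <- do.call(rbind, kept[seq_len(ki)])
    colnames(samples) <- layout
    acc_rate <- acc / nmc
    if (verbose) message("stage 2 done: ", nmc, " samples, acceptance ",
                         formatC(acc_rate, digits = 2), ", best loglik ",
                         formatC(best$value, format = "f", digits = 1))
  }
  s3 <- ascend(best$par, bdg$stage3_maxit)
  s3b <- ascend(s3$par, bdg$stage3_maxit)
  if (s3b$value > s3$value) s3 <- s3b
  if (s3$value < best$value) s3 <- best
  if (verbose) message("stage 3 done: loglik ",
                       formatC(s3$value, format = "f", digits = 1))

  up <- unpack_par(s3$par, layout)
  pred <- predict_conditions(up$params, up$nuisance, conds, profiles,
                             variant, up$extra)
  n_par <- length(layout)
  r2 <- adjusted_r2(agg, pred, n_par)
  structure(list(
    coefficients = s3$par, params = up$params, nuisance = up$nuisance,
    extra = up$extra, variant = variant$name, layout = layout,
    loglik = s3$value, n_params = n_par, n_trials = nrow(data),
    n_data = 3L * nrow(agg), aggregates = agg, predictions = pred,
    r2 = r2, samples = samples, acceptance = acc_rate,
    box = bx, step = step, deadline = deadline, seed = seed,
    budget = bdg, call = match.call()), class = "multidm")
}

## Data-driven default start: model-free psychometric fits give, per
## modality/coherence combination, the product drift_coefficient * bound
## (from the psychometric slope), while the chronometric intercept at the
## smallest heading gives the bound through the effective-time clock
## (mean decision time at zero drift equals bound^2 in effective time).
## Variance scaling starts at b = 1, gamma = 1.
multidm_start <- function(data, agg, layout, profiles, deadline) {
  start <- stats::setNames(rep(0, length(layout)), layout)
  start[grepl("^gamma", layout)] <- 1
  start[grepl("^b_", layout)] <- 1
  start["lapse"] <- 0.02
  eff <- list(visual = effective_time(profiles$v),
              vestibular = effective_time(profiles$a),
              combined = effective_time(profiles$v))
  # non-decision time: fastest responses minus the profile's gate time
  # (evidence cannot be absorbed before the sensitivity profile has
  # delivered an appreciable share of its effective time)
  for (m in intersect(c("visual", "vestibular", "combined"),
                      unique(data$modality))) {
    nm <- paste0("tnd_", c(visual = "vis", vestibular = "vest",
                           combined = "comb")[m])
    e <- eff[[m]]
    t_gate <- e$time[which(e$effective >= 0.02 * max(e$effective))[1]]
    start[nm] <- min(1, max(0.05, stats::quantile(
      data$rt_s[data$modality == m], 0.005, names = FALSE) - t_gate))
  }
  psy <- try(fit_psychometric(data), silent = TRUE)
  if (inherits(psy, "try-error")) {
    start[c("a_vis", "k_vest")] <- c(20, 15)
    start[grepl("^k_comb:", layout)] <- 20
    start[grepl("^theta", layout)] <- 0.6
    return(start)
  }
  start["lapse"] <- min(0.2, psy$lapse)
  bl <- paste0("bias:", psy$conditions$condition)
  ok <- bl %in% layout
  start[bl[ok]] <- pmin(pmax(psy$conditions$bias[ok], -5), 5)
  est <- psy$conditions
  est$P <- pmin(360 / (est$threshold * sqrt(2 * pi) * pi), 100)
  est$theta <- NA_real_
  est$k <- NA_real_
  for (i in seq_len(nrow(est))) {
    m <- est$modality[i]
    sel <- agg$modality == m &
      (m == "vestibular" | agg$coherence == est$coherence[i])
    h0 <- min(abs(agg$heading[sel]))
    dt0 <- mean(agg$mean_rt_correct[sel & abs(agg$heading) == h0],
                na.rm = TRUE) -
      start[paste0("tnd_", c(visual = "vis", vestibular = "vest",
                             combined = "comb")[m])]
    dt0 <- min(max(dt0, 0.05, na.rm = TRUE), deadline * 0.95)
    e <- eff[[m]]
    s_dt0 <- stats::approx(e$time, e$effective, xout = dt0)$y
    sig2 <- 1 + (m != "vestibular") * est$coherence[i] / 100  # b=1, gamma=1
    est$theta[i] <- min(max(sqrt(s_dt0) * sqrt(sig2), 0.05), 5)
    est$k[i] <- min(est$P[i] * sig2 / est$theta[i], 50)
  }
  vest <- est$modality == "vestibular"
  if (any(vest)) {
    start["k_vest"] <- est$k[vest][1]
    start["theta_vest"] <- est$theta[vest][1]
  } else start[c("k_vest", "theta_vest")] <- c(15, 0.6)
  for (m in c("visual", "combined")) {
    sel <- est$modality == m
    thname <- if (m == "visual") "theta_vis" else "theta_comb"
    start[thname] <- if (any(sel)) mean(est$theta[sel]) else 0.6
  }
  vis <- est$modality == "visual" & est$coherence > 0 & est$k < 49
  if (sum(vis) >= 2) {
    co <- stats::coef(stats::lm(log(est$k[vis]) ~
                                  log(est$coherence[vis] / 100)))
    start["a_vis"] <- min(max(exp(co[1]), 1), 50)
    start["gamma_vis"] <- min(max(co[2], 0.2), 3)
  } else if (any(vis)) {
    start["a_vis"] <- min(est$k[vis][1] / (est$coherence[vis][1] / 100), 50)
  } else start["a_vis"] <- 20
  ex <- grepl("^k_comb:", layout)
  if (any(ex)) {
    for (nm in layout[ex]) {
      cc <- sub("^k_comb:", "", nm)
      sel <- est$modality == "combined" & format(est$coherence,
                                                 trim = TRUE) == cc
      start[nm] <- if (any(sel)) est$k[sel][1] else 20
    }
  }
  start
}

#' @export
print.multidm <- function(x, ...) {
  cat(sprintf("Extended diffusion model fit (variant: %s)\n", x$variant))
  cat(sprintf("  %d parameters, %d trials, %d data points\n",
              x$n_params, x$n_trials, x$n_data))
  cat(sprintf("  log-likelihood %.2f, adjusted R2 %.3f (psych %.3f, chron %.3f)\n",
              x$loglik, x$r2$r2_mean, x$r2$r2_psych, x$r2$r2_chron))
  invisible(x)
}

#' @export
summary.multidm <- function(object, ...) {
  ci <- NULL
  if (!is.null(object$samples) && nrow(object$samples) > 10) {
    qs <- apply(object$samples, 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE)
    ci <- t(qs)
    colnames(ci) <- c("q2.5", "q97.5")
  }
  out <- list(fit = object,
              table = data.frame(estimate = object$coefficients,
                                 row.names = object$layout),
              ci = ci)
  if (!is.null(ci)) out$table <- cbind(out$table, ci)
  class(out) <- "summary.multidm"
  out
}

#' @export
print.summary.multidm <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates",
      if (!is.null(x$ci)) " (with 95% posterior-sample intervals)", ":\n",
      sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.multidm <- function(object, ...) object$coefficients

## rebuild the fitting objective of a fitted model (for curvature-based
## inference)
multidm_objective <- function(object) {
  agg <- object$aggregates
  profiles <- stimulus_profiles(duration = object$deadline,
                                step = object$step)
  conds <- agg[, c("modality", "coherence", "heading")]
  layout <- object$layout
  variant <- object$variant
  deadline <- object$deadline
  function(theta) {
    up <- unpack_par(theta, layout)
    pred <- try(predict_conditions(up$params, up$nuisance, conds, profiles,
                                   variant, up$extra), silent = TRUE)
    if (inherits(pred, "try-error")) return(-Inf)
    ll <- loglik_from_agg(agg, pred, deadline,
                          tnd_of(up$params, agg$modality))
    if (!is.finite(ll)) return(-Inf)
    as.numeric(ll)
  }
}

#' Observed-information covariance of a fitted model
#'
#' Numerical negative inverse Hessian of the log-likelihood at the
#' maximum-likelihood estimate (central differences). For the short
#' random-walk chains typically used with reduced budgets this is the
#' better-calibrated uncertainty estimate: finite chains in 20+ dimensions
#' systematically understate posterior spread.
#'
#' @param object a fitted `multidm` model.
#' @param step_frac finite-difference step as a fraction of each
#'   parameter's prior-box width.
#' @param ... unused.
#' @return Covariance matrix over the fitted parameters (a small ridge is
#'   added if the observed information is not invertible).
#' @export
vcov.multidm <- function(object, step_frac = 2e-3, ...) {
  obj <- multidm_objective(object)
  th <- object$coefficients
  n <- length(th)
  h <- pmax((object$box$upper - object$box$lower) * step_frac, 1e-6)
  # keep evaluation points inside the box (curvature at an active bound
  # is ill-defined; the ridge fallback below covers that case)
  h <- pmin(h,
            pmax((object$box$upper - th) / 2, 1e-8),
            pmax((th - object$box$lower) / 2, 1e-8))
  f0 <- obj(th)
  fp <- fm <- numeric(n)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    fp[i] <- obj(th + ei); fm[i] <- obj(th - ei)
  }
  H <- matrix(NA_real_, n, n, dimnames = list(names(th), names(th)))
  for (i in seq_len(n)) {
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
    if (i < n) for (j in (i + 1):n) {
      ei <- replace(numeric(n), i, h[i])
      ej <- replace(numeric(n), j, h[j])
      fpp <- obj(th + ei + ej); fmm <- obj(th - ei - ej)
      H[i, j] <- H[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) /
        (2 * h[i] * h[j])
    }
  }
  info <- -H
  V <- try(solve(info), silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V)) ||
      any(diag(V) < 0)) {
    ridge <- max(abs(diag(info))) * 1e-8 + 1e-12
    V <- solve(info + diag(ridge * (1 + abs(diag(info))), n))
  }
  dimnames(V) <- list(names(th), names(th))
  V
}

#' @export
logLik.multidm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_trials,
            class = "logLik")
}

#' Model predictions for a fitted model
#'
#' @param object a fitted `multidm` model.
#' @param newdata optional data frame of conditions (`modality`,
#'   `coherence`, `heading`); defaults to the fitted conditions.
#' @param step time-grid step for the prediction (defaults to the fitting
#'   step).
#' @param ... unused.
#' @return Data frame of per-condition predictions (`p_right`,
#'   `mean_rt_correct`, `mean_rt_error`, `p_undecided`).
#' @export
predict.multidm <- function(object, newdata = NULL, step = object$step,
                            ...) {
  conds <- if (is.null(newdata))
    object$aggregates[, c("modality", "coherence", "heading")]
  else newdata
  profiles <- stimulus_profiles(duration = object$deadline, step = step)
  predict_conditions(object$params, object$nuisance, conds, profiles,
                     object$variant, object$extra)
}

#' Simulate trials from a fitted model
#'
#' @param object a fitted `multidm` model.
#' @param nsim trials per condition cell.
#' @param seed integer seed (mandatory).
#' @param design optional [experiment_design()]; defaults to the fitted
#'   conditions' design.
#' @param ... passed to [simulate_trials()].
#' @return A trial table.
#' @export
simulate.multidm <- function(object, nsim = 100, seed, design = NULL, ...) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (is.null(design)) {
    agg <- object$aggregates
    design <- experiment_design(
      headings = unique(abs(agg$heading)),
      coherences = sort(unique(agg$coherence[agg$modality != "vestibular"])),
      modalities = intersect(c("visual", "vestibular", "combined"),
                             unique(agg$modality)),
      trials_per_condition = nsim,
      max_duration = object$deadline)
  } else {
    design$trials_per_condition <- nsim
  }
  simulate_trials(object$params, object$nuisance, design, seed = seed,
                  variant = object$variant, extra = object$extra, ...)
}

#' Residuals of a fitted model
#'
#' Observed minus predicted choice fractions (`type = "psych"`) or mean
#' reaction times of correct and error responses (`type = "chron"`).
#'
#' @param object a fitted `multidm` model.
#' @param type `"psych"` or `"chron"`.
#' @param ... unused.
#' @return Numeric vector of residuals (named by condition).
#' @export
residuals.multidm <- function(object, type = c("psych", "chron"), ...) {
  type <- match.arg(type)
  agg <- object$aggregates
  prd <- object$predictions
  lab <- paste(condition_label(agg$modality, agg$coherence), agg$heading,
               sep = "@")
  if (type == "psych")
    stats::setNames(agg$p_right - prd$p_right, lab)
  else
    stats::setNames(
      c(agg$mean_rt_correct - prd$mean_rt_correct,
        agg$mean_rt_error - prd$mean_rt_error),
      c(paste0(lab, ":correct"), paste0(lab, ":error")))
}

#' Plot psychometric and chronometric fits
#'
#' One panel per modality/coherence combination: observed proportion of
#' rightward choices (points) with the model's psychometric prediction
#' (line), or mean reaction times of correct responses with the
#' chronometric prediction.
#'
#' @param x a fitted `multidm` model.
#' @param type `"psych"` or `"chron"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.multidm <- function(x, type = c("psych", "chron"), ...) {
  type <- match.arg(type)
  agg <- x$aggregates
  prd <- x$predictions
  combos <- unique(condition_label(agg$modality, agg$coherence))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(combos)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cb in combos) {
    sel <- condition_label(agg$modality, agg$coherence) == cb
    h <- agg$heading[sel]
    if (type == "psych") {
      graphics::plot(h, agg$p_right[sel], ylim = c(0, 1), main = cb,
                     xlab = "heading (deg)", ylab = "P(rightward)", ...)
      graphics::lines(h[order(h)], prd$p_right[sel][order(h)])
    } else {
      yl <- range(c(agg$mean_rt_correct[sel], prd$mean_rt_correct[sel]),
                  na.rm = TRUE)
      graphics::plot(h, agg$mean_rt_correct[sel], ylim = yl, main = cb,
                     xlab = "heading (deg)", ylab = "mean RT correct (s)",
                     ...)
      graphics::lines(h[order(h)], prd$mean_rt_correct[sel][order(h)])
    }
  }
  invisible(x)
}
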