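## First-passage-time engine for the (time-inhomogeneous) bounded diffusion.
##
## Two independent routes:
##  * fpt_time_change(): exploits that the sensitivity-weighted accumulator
##    is a constant-drift unit-variance diffusion in effective time
##    s(t) = int w(u)^2 du, where the two-boundary first-passage problem has
##    a classical series solution; densities are mapped back to real time
##    with Jacobian w(t)^2.
##  * fpt_volterra(): direct second-kind Volterra integral-equation solution
##    for arbitrary time-varying drift and diffusion SD (compiled kernel),
##    used both as an independent validator and as the likelihood kernel of
##    model variants that break the time-change structure.

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

## zero-drift first-passage density through one boundary for a unit-variance
## diffusion started midway between boundaries a apart, evaluated at s.
## Small-time representation (method of images) below r = s/a^2 = 0.09,
## spectral (large-time) representation above; both truncated far below
## 1e-8 relative accuracy in their regime.
fp_h0 <- function(s, a) {
  h <- numeric(length(s))
  pos <- s > 0
  if (!any(pos)) return(h)
  sp <- s[pos]
  r <- sp / a^2
  small <- r < 0.09
  z <- a / 2
  if (any(small)) {
    ss <- sp[small]
    k <- -5:5
    coef <- z + 2 * k * a                       # image offsets
    ex <- exp(-outer(1 / (2 * ss), coef^2))     # n_small x n_k
    h[pos][small] <- pmax(0, (ex %*% coef) / sqrt(2 * pi * ss^3))
  }
  if (any(!small)) {
    sl <- sp[!small]
    k <- seq(1, 21, by = 2)
    sgn <- (-1)^((k - 1) / 2)
    lam <- k^2 * pi^2 / (2 * a^2)
    ex <- exp(-outer(sl, lam))
    h[pos][!small] <- pmax(0, (pi / a^2) * (ex %*% (sgn * k)))
  }
  h
}

## survived (not-yet-absorbed) mass beyond the deadline S and the part of it
## lying above zero evidence, for constant drift mu, bounds +/- theta.
fp_survived <- function(mu, theta, S, nx = 201) {
  a <- 2 * theta
  if (S <= 0) return(list(tot = 1, pos = 0.5))
  x <- seq(-theta, theta, length.out = nx)
  y <- x + theta                                # in (0, a) coordinates
  r <- S / a^2
  if (r < 0.09) {
    k <- -5:5
    z <- theta
    d1 <- outer(y, z + 2 * k * a, "-")
    d2 <- outer(y, -z + 2 * k * a, "-")         # image of reflected source
    p0 <- (exp(-d1^2 / (2 * S)) - exp(-d2^2 / (2 * S))) %*% rep(1, length(k))
    p0 <- p0 / sqrt(2 * pi * S)
  } else {
    k <- seq(1, 21, by = 2)
    sgn <- (-1)^((k - 1) / 2)
    lam <- k^2 * pi^2 / (2 * a^2)
    p0 <- sin(outer(y, k * pi / a)) %*% (sgn * exp(-lam * S)) * (2 / a)
  }
  p <- pmax(0, as.vector(p0)) * exp(mu * x - mu^2 * S / 2)
  dx <- x[2] - x[1]
  tot <- trapz(x, p)
  pos <- trapz(x[x >= 0], p[x >= 0])
  list(tot = tot, pos = pos)
}

## absorption probabilities at the two bounds by deadline S (analytic
## term-wise integration of the spectral series; exact closed form as S->Inf)
fp_probs <- function(mu, theta, S) {
  a <- 2 * theta
  p_up_inf <- 1 / (1 + exp(-2 * mu * theta))
  p_lo_inf <- 1 / (1 + exp(2 * mu * theta))
  if (!is.finite(S)) return(list(p_up = p_up_inf, p_lo = p_lo_inf))
  k <- seq(1, 41, by = 2)
  sgn <- (-1)^((k - 1) / 2)
  lam <- k^2 * pi^2 / (2 * a^2)
  q <- mu^2 / 2 + lam
  ck <- (pi / a^2) * sgn * k
  tail_up <- sum(ck * exp(mu * theta - q * S) / q)
  tail_lo <- sum(ck * exp(-mu * theta - q * S) / q)
  if (S / a^2 < 0.05) {
    # deadline far shorter than the diffusion scale: almost nothing is
    # absorbed and the term-wise tail converges too slowly; integrate the
    # (tiny) small-time density directly instead.
    sq <- seq(0, S, length.out = 512)
    h <- fp_h0(sq, a)
    tail_up <- NA
    p_up <- trapz(sq, exp(mu * theta - mu^2 * sq / 2) * h)
    p_lo <- trapz(sq, exp(-mu * theta - mu^2 * sq / 2) * h)
  } else {
    p_up <- p_up_inf - tail_up
    p_lo <- p_lo_inf - tail_lo
  }
  list(p_up = min(max(p_up, 0), 1), p_lo = min(max(p_lo, 0), 1))
}

fpt_result <- function(time, dens_up, dens_lo, p_up, p_lo, surv, surv_pos,
                       method) {
  mean_of <- function(f, p) {
    if (p < 1e-12) return(NA_real_)
    trapz(time, time * f) / max(trapz(time, f), 1e-300)
  }
  structure(list(
    p_upper = p_up, p_lower = p_lo,
    p_undecided_at_T = surv,
    p_forced_upper = surv_pos,
    p_forced_lower = surv - surv_pos,
    mean_rt_upper = mean_of(dens_up, p_up),
    mean_rt_lower = mean_of(dens_lo, p_lo),
    time = time,
    rt_density_upper = dens_up, rt_density_lower = dens_lo,
    method = method), class = "fpt_result")
}

#' @export
print.fpt_result <- function(x, ...) {
  cat(sprintf(
    "First-passage result (%s): P(up) = %.4f, P(lo) = %.4f, P(undecided) = %.2g\n",
    x$method, x$p_upper, x$p_lower, x$p_undecided_at_T))
  cat(sprintf("  mean decision time up/lo: %.3f / %.3f s\n",
              x$mean_rt_upper, x$mean_rt_lower))
  invisible(x)
}

#' First-passage solution by effective-time change
#'
#' Solves the two-boundary first-passage problem of the weighted
#' accumulator `dX = w(t)^2 * drift dt + w(t) dW` with constant bounds
#' `+/- bound` and a response deadline, by transforming to effective time
#' `s(t) = int w(u)^2 du`, where the process is a constant-drift,
#' unit-variance diffusion with a classical series solution, and mapping
#' the first-passage densities back to real time with Jacobian `w(t)^2`.
#'
#' Mass not absorbed by the deadline is reported as `p_undecided_at_T`,
#' split into `p_forced_upper` / `p_forced_lower` by the sign of the
#' accumulated evidence at the deadline (the forced-choice closure).
#'
#' @param drift constant drift per unit effective time (the unit-variance
#'   normalized drift, i.e. already divided by the diffusion SD).
#' @param bound bound in units of the unit-variance process (> 0).
#' @param profile a unit-peak `temporal_profile` w(t).
#' @param deadline response deadline in seconds (defaults to the end of the
#'   profile grid).
#' @return An object of class `fpt_result` with absorption probabilities,
#'   real-time first-passage densities and conditional mean decision times.
#' @export
fpt_time_change <- function(drift, bound, profile, deadline = NULL) {
  stopifnot(inherits(profile, "temporal_profile"))
  if (bound <= 0) stop("bound must be > 0")
  time <- profile$time
  w2 <- profile$values^2
  if (!is.null(deadline)) {
    keep <- time <= deadline + 1e-12
    if (sum(keep) < 2) stop("deadline too short for the profile grid")
    time <- time[keep]; w2 <- w2[keep]
  }
  s <- c(0, cumsum((w2[-1] + w2[-length(w2)]) / 2 * diff(time)))
  S <- s[length(s)]
  if (S <= 0) stop("effective time is identically zero")
  a <- 2 * bound
  h0 <- fp_h0(s, a)
  lh <- ifelse(h0 > 0, log(h0), -Inf)
  g_up <- exp(drift * bound - drift^2 * s / 2 + lh)
  g_lo <- exp(-drift * bound - drift^2 * s / 2 + lh)
  pr <- fp_probs(drift, bound, S)
  sv <- fp_survived(drift, bound, S)
  surv <- max(0, min(1, 1 - pr$p_up - pr$p_lo))
  surv_pos <- if (sv$tot > 1e-300) surv * sv$pos / sv$tot else surv / 2
  fpt_result(time, g_up * w2, g_lo * w2, pr$p_up, pr$p_lo, surv, surv_pos,
             method = "time-change series")
}

#' First-passage solution by Volterra integral equations
#'
#' Direct solution of the two-boundary first-passage problem for a
#' diffusion `dX = mu(t) dt + sd(t) dW` with constant bounds, by a
#' second-kind Volterra integral-equation discretization on the grid
#' (compiled kernel). Serves as an independent cross-check of
#' [fpt_time_change()] and as the likelihood kernel of model variants whose
#' drift and diffusion profiles are not proportional.
#'
#' @param drift numeric vector (or scalar) of drift per unit real time on
#'   the grid.
#' @param sd numeric vector (or scalar) of diffusion SD on the grid.
#' @param bounds bound magnitude; scalar for symmetric bounds or
#'   `c(upper, lower)` (both positive).
#' @param time uniform time grid in seconds starting at 0.
#' @return An object of class `fpt_result`.
#' @export
fpt_volterra <- function(drift, sd, bounds, time) {
  n <- length(time)
  if (n < 3) stop("grid too coarse for the Volterra discretization")
  drift <- rep_len(drift, n)
  sd <- rep_len(sd, n)
  if (any(!is.finite(drift)) || any(!is.finite(sd)))
    stop("drift and sd must be finite on the grid")
  if (length(bounds) == 1) bounds <- c(bounds, bounds)
  if (any(bounds <= 0)) stop("bounds must be > 0")
  dt <- diff(time)
  s2 <- sd^2
  s <- c(0, cumsum((s2[-1] + s2[-n]) / 2 * dt))
  M <- c(0, cumsum((drift[-1] + drift[-n]) / 2 * dt))
  if (s[n] <= 0) stop("diffusion variance is identically zero")
  out <- volterra_fpt_cpp(s, M, bounds[1], bounds[2])
  dens_up <- out$g_up * s2
  dens_lo <- out$g_lo * s2
  p_up <- trapz(time, dens_up)
  p_lo <- trapz(time, dens_lo)
  surv <- max(0, min(1, 1 - p_up - p_lo))
  surv_pos <- if (out$surv_tot > 1e-300) surv * out$surv_pos / out$surv_tot
              else surv / 2
  fpt_result(time, dens_up, dens_lo, p_up, p_lo, surv, surv_pos,
             method = "Volterra")
}
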