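#' Temporal sensitivity profiles
#'
#' A `temporal_profile` is a nonnegative weighting function of time on a
#' uniform grid, used to describe how the momentary sensitivity of a sensory
#' cue waxes and wanes within a trial. The stimulus moves along a Gaussian
#' velocity profile, so the visual (optic-flow) cue is most informative
#' around peak velocity while the vestibular (inertial) cue, encoded by
#' otolith afferents in terms of acceleration, is most informative around
#' the acceleration extrema.
#'
#' @param time numeric vector of times in seconds, uniformly spaced from 0.
#' @param values numeric vector of profile values (same length as `time`).
#' @param normalized logical; `TRUE` once the profile has unit peak.
#'
#' @return An object of class `temporal_profile`: a list with elements
#'   `time`, `values`, `step` (grid spacing in seconds) and `normalized`.
#' @export
temporal_profile <- function(time, values, normalized = FALSE) {
  stopifnot(is.numeric(time), is.numeric(values), length(time) == length(values))
  if (length(time) < 2L)
    stop("a temporal profile needs at least two grid points")
  d <- diff(time)
  if (any(d <= 0))
    stop("profile times must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(d))
    stop("profile grid must be uniform")
  if (!all(is.finite(values)))
    stop("profile values must be finite")
  structure(list(time = time, values = values, step = mean(d),
                 normalized = isTRUE(normalized)),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf("Temporal profile: %d points, 0-%.3g s (step %.4g s), peak %.4g%s\n",
              length(x$time), max(x$time), x$step, max(abs(x$values)),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.temporal_profile <- function(x, ..., xlab = "time (s)", ylab = "weight") {
  graphics::plot(x$time, x$values, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Gaussian stimulus velocity profile
#'
#' Constructs the translational velocity profile of the motion stimulus: a
#' Gaussian bump centred at `duration / 2`, with its standard deviation
#' solved numerically so that the integral of velocity over the trial equals
#' the total displacement. The defaults reproduce the laboratory stimulus
#' (peak velocity 0.403 m/s, displacement 0.3 m over a 2 s window), whose
#' implied peak acceleration is close to 0.822 m/s^2.
#'
#' @param peak_velocity peak velocity in m/s.
#' @param displacement total displacement in m.
#' @param duration trial duration in seconds.
#' @param step grid step in seconds.
#'
#' @return A `temporal_profile` in physical units (m/s), not normalized.
#' @export
#' @examples
#' v <- gaussian_velocity_profile()
#' max(abs(diff(v$values)) / v$step)  # ~0.822 m/s^2 peak acceleration
gaussian_velocity_profile <- function(peak_velocity = 0.403,
                                      displacement = 0.3,
                                      duration = 2,
                                      step = 0.001) {
  stopifnot(peak_velocity > 0, displacement > 0, duration > 0, step > 0)
  t0 <- duration / 2
  # sigma such that peak_velocity * integral of exp(-(t-t0)^2 / (2 sigma^2))
  # over [0, duration] equals displacement.  Untruncated solution:
  # sigma = displacement / (peak_velocity * sqrt(2*pi)); refine on the
  # truncated integral by root finding.
  sigma0 <- displacement / (peak_velocity * sqrt(2 * pi))
  trunc_disp <- function(sigma) {
    peak_velocity * sigma * sqrt(2 * pi) *
      (stats::pnorm(duration, t0, sigma) - stats::pnorm(0, t0, sigma)) -
      displacement
  }
  # displacement is increasing in sigma while tails stay small
  upper <- sigma0 * 2
  if (trunc_disp(upper) < 0)
    stop("no Gaussian profile matches these inputs within the trial window")
  sigma <- stats::uniroot(trunc_disp, c(sigma0 * 0.5, upper), tol = 1e-12)$root
  # reject inputs whose solution leaves appreciable tail mass outside [0, T]
  tail_mass <- 2 * stats::pnorm(0, t0, sigma)
  if (tail_mass > 0.01)
    stop(sprintf(
      "Gaussian velocity profile leaves %.1f%% of its mass outside the trial window; inputs inconsistent",
      100 * tail_mass))
  time <- seq(0, duration, by = step)
  values <- peak_velocity * exp(-(time - t0)^2 / (2 * sigma^2))
  p <- temporal_profile(time, values)
  p$sigma <- sigma
  p
}

#' Acceleration profile from a velocity profile
#'
#' Central-difference time derivative of a velocity profile. By default the
#' magnitude `|a(t)|` is returned, since a sensitivity profile is
#' nonnegative by definition: a signed profile would flip the sign of the
#' evidence mid-trial, which the model's effective-time construction (which
#' squares the profile) does not do.
#'
#' @param v a `temporal_profile` (velocity).
#' @param magnitude return `|a(t)|` (default) rather than signed a(t).
#' @return A `temporal_profile` on the same grid.
#' @export
acceleration_profile <- function(v, magnitude = TRUE) {
  stopifnot(inherits(v, "temporal_profile"))
  n <- length(v$time)
  if (n < 3L) stop("need at least 3 grid points to differentiate")
  a <- numeric(n)
  a[2:(n - 1)] <- (v$values[3:n] - v$values[1:(n - 2)]) / (2 * v$step)
  a[1] <- (v$values[2] - v$values[1]) / v$step
  a[n] <- (v$values[n] - v$values[n - 1]) / v$step
  if (magnitude) a <- abs(a)
  temporal_profile(v$time, a)
}

#' Normalize a profile to unit peak
#'
#' All stimulus magnitude is absorbed into the sensitivity parameters k, so
#' profiles enter the evidence model normalized to `max(values) == 1`.
#' Idempotent.
#'
#' @param p a `temporal_profile`.
#' @return A `temporal_profile` with unit peak and `normalized = TRUE`.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "temporal_profile"))
  m <- max(abs(p$values))
  if (m == 0) stop("cannot normalize an all-zero profile")
  temporal_profile(p$time, p$values / m, normalized = TRUE)
}

#' Effective time of a weighting profile
#'
#' The accumulated squared profile, `E(t) = sum(w_n^2 * step)` up to `t`.
#' When momentary evidence is weighted by its sensitivity profile w(t), the
#' weighted accumulator is a constant-drift unit-variance diffusion in this
#' effective-time clock, which is what makes the first-passage problem
#' tractable.
#'
#' @param p a `temporal_profile` (normally unit-peak).
#' @return An object of class `effective_time`: list with `time` (s),
#'   `effective` (nondecreasing, `effective[1] == 0`) and `step`.
#' @export
effective_time <- function(p) {
  stopifnot(inherits(p, "temporal_profile"))
  w2 <- p$values^2
  # trapezoidal accumulation so that a constant profile gives E(t) = t exactly
  eff <- c(0, cumsum((w2[-1] + w2[-length(w2)]) / 2 * p$step))
  structure(list(time = p$time, effective = eff, step = p$step),
            class = "effective_time")
}

#' @export
print.effective_time <- function(x, ...) {
  cat(sprintf("Effective time: %d points, E(%.3g s) = %.4g\n",
              length(x$time), max(x$time), max(x$effective)))
  invisible(x)
}

#' Write / read a profile as two-column delimited text
#'
#' Columns `time_s` and `value`, tab-separated with header.
#'
#' @param p a `temporal_profile`.
#' @param path file path.
#' @return `read_profile` returns a `temporal_profile`; `write_profile`
#'   returns `path` invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "temporal_profile"))
  utils::write.table(data.frame(time_s = p$time, value = p$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "value") %in% names(d)))
    stop("profile file must have columns time_s and value")
  temporal_profile(d$time_s, d$value)
}
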