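test_that("constant-drift absorption matches the closed form", {
  cp <- const_profile()
  for (mu in c(0.5, 1, 2)) for (th in c(0.5, 1, 1.5)) {
    r <- fpt_time_change(mu, th, cp)
    expect_equal(r$p_upper, 1 / (1 + exp(-2 * mu * th)), tolerance = 1e-6)
    expect_equal(r$p_upper + r$p_lower + r$p_undecided_at_T, 1,
                 tolerance = 1e-6)
  }
  # classic check: mu = 1, theta = 1
  r <- fpt_time_change(1, 1, cp)
  expect_equal(r$p_upper, 0.8807971, tolerance = 1e-5)
  # conditional mean decision time: theta * tanh(mu * theta) / mu
  expect_equal(r$mean_rt_upper, tanh(1), tolerance = 1e-3)
})

test_that("zero drift splits absorption evenly", {
  r <- fpt_time_change(0, 0.8, profiles_5ms$v)
  expect_equal(r$p_upper, r$p_lower, tolerance = 1e-10)
  rv <- fpt_volterra(0, 1, 0.8, seq(0, 10, by = 0.01))
  expect_equal(rv$p_upper, rv$p_lower, tolerance = 1e-6)
  expect_equal(rv$p_upper, 0.5, tolerance = 1e-4)
})

test_that("reflection symmetry swaps the absorption densities", {
  v <- profiles_5ms$v
  for (mu in c(0.7, 3)) {
    r1 <- fpt_time_change(mu, 0.6, v)
    r2 <- fpt_time_change(-mu, 0.6, v)
    expect_equal(r1$p_upper, r2$p_lower, tolerance = 1e-10)
    expect_equal(r1$rt_density_upper, r2$rt_density_lower, tolerance = 1e-10)
    expect_equal(r1$mean_rt_upper, r2$mean_rt_lower, tolerance = 1e-10)
  }
})

test_that("densities integrate to their absorption probabilities", {
  v <- profiles_1ms$v
  for (mu in c(0, 1.5, 5)) {
    r <- fpt_time_change(mu, 0.7, v)
    expect_equal(trapz_num(r$time, r$rt_density_upper), r$p_upper,
                 tolerance = 1e-4)
    expect_equal(trapz_num(r$time, r$rt_density_lower), r$p_lower,
                 tolerance = 1e-4)
    expect_true(all(r$rt_density_upper >= 0))
    expect_true(all(r$rt_density_lower >= 0))
  }
})

test_that("the Volterra solver is a faithful independent route", {
  # constant drift/SD reduces to the closed form
  tt <- seq(0, 15, by = 0.01)
  rv <- fpt_volterra(1.2, 1, 0.8, tt)
  expect_equal(rv$p_upper, 1 / (1 + exp(-2 * 1.2 * 0.8)), tolerance = 1e-4)
  # no absorption limit: zero drift, huge bound, short deadline
  rn <- fpt_volterra(0, 1, 20, seq(0, 0.5, by = 0.005))
  expect_gt(rn$p_undecided_at_T, 0.999)
  # grid too coarse is refused
  expect_error(fpt_volterra(1, 1, 1, c(0, 1)))
})

test_that("time-change and Volterra agree on the Gaussian-profile model", {
  v <- profiles_1ms$v
  for (mu in c(0, 2, 6)) {
    r1 <- fpt_time_change(mu, 0.6, v)
    r2 <- fpt_volterra(v$values^2 * mu, v$values, 0.6, v$time)
    tv <- 0.5 * trapz_num(v$time,
                          abs(r1$rt_density_upper - r2$rt_density_upper) +
                          abs(r1$rt_density_lower - r2$rt_density_lower))
    expect_lt(tv, 0.01)
    expect_equal(r1$p_upper, r2$p_upper, tolerance = 1e-4)
    expect_equal(r1$p_undecided_at_T, r2$p_undecided_at_T, tolerance = 1e-4)
  }
})

test_that("choice probability increases monotonically with heading", {
  pr <- profiles_5ms
  hs <- c(-16, -5.6, -1.96, -0.686, 0.686, 1.96, 5.6, 16)
  p <- vapply(hs, function(h)
    predict_condition(true_params, true_nuisance, "combined", 70, h,
                      pr)$p_right, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("per-condition predictions respect lapse and bias conventions", {
  pr <- profiles_5ms
  # full lapsing makes every choice a coin flip
  n1 <- multidm_nuisance(lapse = 1)
  expect_equal(predict_condition(true_params, n1, "visual", 70, 5.6,
                                 pr)$p_right, 0.5)
  # heading equal to the bias nulls the drift
  n2 <- multidm_nuisance(setNames(2, "vestibular"), lapse = 0)
  expect_equal(predict_condition(true_params, n2, "vestibular", 0, 2,
                                 pr)$p_right, 0.5, tolerance = 1e-10)
  # strong vestibular evidence: almost sure correct, decision time far
  # below the deadline so mean RT approaches the non-decision time plus
  # the profile's gate time
  p3 <- multidm_params(k_vest = 50, theta_vest = 0.5)
  pred <- predict_condition(p3, multidm_nuisance(), "vestibular", 0, 16, pr)
  expect_gt(pred$p_right, 0.999)
  expect_lt(pred$mean_rt_correct, p3$tnd_vest + 0.6)
  expect_gt(pred$mean_rt_correct, p3$tnd_vest)
})

test_that("combined prediction equals explicit two-stream accumulation", {
  # simulating two weighted unimodal streams and combining them with the
  # information weights must reproduce the single combined accumulator
  pr <- profiles_1ms
  kv <- k_visual(0.7, true_params$a_vis, true_params$gamma_vis)
  ks <- true_params$k_vest
  kc <- k_combined(kv, ks)
  d <- combined_profile(pr$v, pr$a, kv, ks)
  sh <- sin(5.6 * pi / 180)
  sig <- diffusion_sd(0.7, true_params$b_comb, true_params$gamma_comb)
  ana <- fpt_time_change(kc * sh / sig, true_params$theta_comb / sig, d)
  set.seed(19)
  n <- 6000; dt <- 5e-4
  prf <- stimulus_profiles(step = dt)
  v <- prf$v$values; a <- prf$a$values
  ng <- length(v)
  X <- numeric(n); act <- rep(TRUE, n); b <- integer(n); tt <- rep(2, n)
  th <- true_params$theta_comb / sig
  for (i in 2:ng) {
    na <- sum(act); if (na == 0) break
    # momentary unimodal evidence with the condition's noise scale, each
    # weighted by its sensitivity profile; natural-parameter combination
    # (k_vis Xvis + k_vest Xvest)/k_comb recovers the combined accumulator
    dx_v <- v[i] * kv * sh * dt + sig * sqrt(dt) * rnorm(na)
    dx_s <- a[i] * ks * sh * dt + sig * sqrt(dt) * rnorm(na)
    X[act] <- X[act] + (kv * v[i] * dx_v + ks * a[i] * dx_s) / (kc * sig)
    up <- act & X >= th; lo <- act & X <= -th
    b[up] <- 1L; b[lo] <- -1L
    tt[up | lo] <- (i - 1) * dt
    act <- act & !(up | lo)
  }
  dec <- b != 0
  p_mc <- mean(b == 1)
  se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(p_mc - (ana$p_upper + ana$p_forced_upper)), 3 * se + 0.01)
  sem <- sd(tt[b == 1]) / sqrt(sum(b == 1))
  expect_lt(abs(mean(tt[b == 1]) - ana$mean_rt_upper), 3 * sem + 0.01)
})
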