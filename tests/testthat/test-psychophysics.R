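test_that("psychometric fits recover a known cumulative Gaussian", {
  hs <- c(-8, -4, -2, -1, 1, 2, 4, 8)
  tr <- psy_table(hs, 1000, threshold = 2, bias = 0, lapse = 0, seed = 41)
  fit <- fit_psychometric(tr)
  expect_equal(fit$conditions$threshold, 2, tolerance = 0.10)
  expect_lt(abs(fit$conditions$bias), 0.3)
  expect_lt(fit$lapse, 0.05)
})

test_that("sign-flipped data negate the bias and keep the threshold", {
  hs <- c(-8, -4, -1, 1, 4, 8)
  tr <- psy_table(hs, 800, threshold = 2.5, bias = 1, seed = 42)
  flip <- tr
  flip$heading_deg <- -flip$heading_deg
  flip$choice <- ifelse(flip$choice == "right", "left", "right")
  f1 <- fit_psychometric(tr, lapse = 0)
  f2 <- fit_psychometric(flip, lapse = 0)
  expect_equal(f1$conditions$threshold, f2$conditions$threshold,
               tolerance = 1e-4)
  expect_equal(f1$conditions$bias, -f2$conditions$bias, tolerance = 1e-3)
})

test_that("heavy lapsing is absorbed by the shared lapse parameter", {
  hs <- c(-8, -4, -1, 1, 4, 8)
  tr <- psy_table(hs, 1200, threshold = 2, lapse = 0.5, seed = 43)
  fit <- fit_psychometric(tr)
  # asymptotes at lapse/2 and 1 - lapse/2
  expect_equal(fit$lapse, 0.5, tolerance = 0.12)
})

test_that("optimal threshold prediction is the harmonic combination", {
  expect_equal(predict_combined_threshold(3, 4), 2.4)
  expect_equal(predict_combined_threshold(4, 3),
               predict_combined_threshold(3, 4))
  s <- 2.7
  expect_equal(predict_combined_threshold(s, s), s / sqrt(2))
  expect_equal(predict_combined_threshold(3, 4e6), 3, tolerance = 1e-6)
  set.seed(44)
  a <- runif(20, 0.5, 8); b <- runif(20, 0.5, 8)
  expect_true(all(predict_combined_threshold(a, b) <= pmin(a, b)))
})

test_that("bootstrap CIs behave like sampling distributions", {
  hs <- c(-8, -4, -1, 1, 4, 8)
  tr1 <- psy_table(hs, 250, threshold = 2, seed = 45)
  tr4 <- psy_table(hs, 1000, threshold = 2, seed = 46)
  f1 <- fit_psychometric(tr1, lapse = 0)
  f4 <- fit_psychometric(tr4, lapse = 0)
  b1 <- bootstrap_thresholds(f1, n_boot = 200, seed = 47)
  b4 <- bootstrap_thresholds(f4, n_boot = 200, seed = 48)
  w1 <- diff(b1$ci[1, ]); w4 <- diff(b4$ci[1, ])
  # width shrinks roughly like 1/sqrt(trials): ratio ~ 0.5
  expect_lt(w4 / w1, 0.75)
  expect_gt(w4 / w1, 0.3)
  # truth inside the 95% interval
  expect_lt(b4$ci[1, 1], 2); expect_gt(b4$ci[1, 2], 2)
  expect_warning(bootstrap_thresholds(f1, n_boot = 50, seed = 49))
})

test_that("null threshold comparisons give unremarkable p-values", {
  hs <- c(-8, -4, -1, 1, 4, 8)
  # two conditions with identical generating parameters
  tr <- rbind(psy_table(hs, 500, 2, modality = "visual", coherence = 25,
                        seed = 50),
              psy_table(hs, 500, 2, modality = "visual", coherence = 70,
                        seed = 51))
  fit <- fit_psychometric(tr, lapse = 0)
  bt <- bootstrap_thresholds(fit, n_boot = 300, seed = 52,
                             comparisons = list(c("visual:25", "visual:70")))
  expect_gt(bt$comparisons$p_raw, 0.02)
  expect_lt(bt$comparisons$p_raw, 0.98)
  # per-sample propagation of the optimal prediction matches direct
  # recomputation from the stored draws
  tr2 <- rbind(psy_table(hs, 400, 3, modality = "visual", coherence = 70,
                         seed = 53),
               psy_table(hs, 400, 4, modality = "vestibular", coherence = 0,
                         seed = 54))
  f2 <- fit_psychometric(tr2, lapse = 0)
  b2 <- bootstrap_thresholds(f2, n_boot = 200, seed = 55)
  direct <- predict_combined_threshold(b2$samples[, "visual:70"],
                                       b2$samples[, "vestibular"])
  expect_equal(unname(b2$predicted$lo), quantile(direct, 0.025,
                                                 names = FALSE))
  expect_equal(unname(b2$predicted$hi), quantile(direct, 0.975,
                                                 names = FALSE))
  expect_equal(b2$predicted$predicted,
               predict_combined_threshold(
                 f2$conditions$threshold[f2$conditions$condition ==
                                           "visual:70"],
                 f2$conditions$threshold[f2$conditions$condition ==
                                           "vestibular"]))
})

test_that("race bound diagnostics detect constructed violations", {
  set.seed(56)
  # combined identical in distribution to vestibular; visual at the
  # deadline: Grice's bound holds with equality, Miller's holds
  rt_v <- rep(1.99, 60)
  rt_s <- runif(60, 0.5, 1.5)
  rt_c <- runif(60, 0.5, 1.5)
  d_eq <- rbind(rt_table("visual", 70, 16, rt_v),
                rt_table("vestibular", 0, 16, rt_s),
                rt_table("combined", 70, 16, rt_c))
  res <- race_bound_tests(d_eq, n_perm = 300, seed = 57)
  # Grice's bound satisfied up to sampling noise: no "slower" verdict
  expect_lt(res$grice_violation, 0.25)
  expect_gt(res$grice_p, 0.05)
  # combined faster than both unimodal minima: Miller violation
  d_fast <- rbind(rt_table("visual", 70, 16, runif(60, 1.0, 1.6)),
                  rt_table("vestibular", 0, 16, runif(60, 1.0, 1.6)),
                  rt_table("combined", 70, 16, runif(60, 0.3, 0.5)))
  res_f <- race_bound_tests(d_fast, n_perm = 300, seed = 58)
  expect_gt(res_f$miller_violation, 0)
  expect_lt(res_f$miller_p, 0.05)
  expect_equal(res_f$direction, "faster than parallel race")
  # combined much slower than the faster channel: Grice violation
  d_slow <- rbind(rt_table("visual", 70, 16, runif(60, 0.6, 1.0)),
                  rt_table("vestibular", 0, 16, runif(60, 0.6, 1.0)),
                  rt_table("combined", 70, 16, runif(60, 1.5, 1.9)))
  res_s <- race_bound_tests(d_slow, n_perm = 300, seed = 59)
  expect_gt(res_s$grice_violation, 0)
  expect_lt(res_s$grice_p, 0.05)
  expect_equal(res_s$direction, "slower than parallel race")
  # undersized cells are skipped with a message
  d_small <- rbind(rt_table("visual", 70, 16, runif(5, 1, 2)),
                   rt_table("vestibular", 0, 16, runif(60, 1, 2)),
                   rt_table("combined", 70, 16, runif(60, 1, 2)))
  expect_message(race_bound_tests(d_small, n_perm = 50, seed = 60),
                 "skipped")
})

test_that("an elevated combined bound makes responses slower than a race", {
  # simulated from the optimal generative model with theta_comb raised:
  # the combined condition violates Grice's bound against the unimodal
  # conditions, mirroring decisions slower than any parallel race
  p <- multidm_params(theta_comb = 1.3)
  des <- experiment_design(headings = c(5.6, 16), coherences = 70,
                           trials_per_condition = 250)
  tr <- simulate_trials(p, multidm_nuisance(), des, seed = 61)
  res <- race_bound_tests(tr, n_perm = 400, seed = 62)
  expect_true(any(res$grice_p < 0.05 & res$grice_violation > 0))
  expect_false(any(res$direction == "faster than parallel race"))
})
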