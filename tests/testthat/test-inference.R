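test_that("the likelihood matches a brute-force recomputation", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           trials_per_condition = 60)
  tr <- simulate_trials(true_params, true_nuisance, des, seed = 21)
  expect_warning(
    ll <- log_likelihood(true_params, true_nuisance, tr, step = 0.005),
    "SEMs floored")
  # independent reconstruction from raw rows, including the SEM floor used
  # for degenerate correctness classes (the dataset-wide median SEM)
  cells <- unique(tr[, c("modality", "coherence", "heading_deg")])
  cell_rts <- function(i, corr) {
    rows <- tr[tr$modality == cells$modality[i] &
                 tr$coherence == cells$coherence[i] &
                 tr$heading_deg == cells$heading_deg[i], ]
    rows$rt_s[rows$correct == corr & !rows$forced]
  }
  all_sems <- unlist(lapply(seq_len(nrow(cells)), function(i)
    lapply(c(TRUE, FALSE), function(corr) {
      rts <- cell_rts(i, corr)
      if (length(rts) >= 2) sd(rts) / sqrt(length(rts)) else NA_real_
    })))
  sem_floor <- median(all_sems[is.finite(all_sems) & all_sems > 0])
  brute <- 0
  for (i in seq_len(nrow(cells))) {
    rows <- tr[tr$modality == cells$modality[i] &
                 tr$coherence == cells$coherence[i] &
                 tr$heading_deg == cells$heading_deg[i], ]
    pred <- predict_condition(true_params, true_nuisance,
                              cells$modality[i], cells$coherence[i],
                              cells$heading_deg[i], profiles_5ms)
    p <- min(max(pred$p_right, 1e-12), 1 - 1e-12)
    k <- sum(rows$choice == "right")
    brute <- brute + k * log(p) + (nrow(rows) - k) * log(1 - p)
    for (corr in c(TRUE, FALSE)) {
      rts <- cell_rts(i, corr)
      if (length(rts) == 0) next
      s <- if (length(rts) >= 2) sd(rts) / sqrt(length(rts)) else NA_real_
      if (!is.finite(s) || s <= 0) s <- sem_floor
      mpred <- if (corr) pred$mean_rt_correct else pred$mean_rt_error
      brute <- brute + dnorm(mpred, mean(rts), s, log = TRUE)
    }
  }
  expect_equal(ll, brute, tolerance = 1e-8)
})

test_that("a chance model on balanced data scores n log(1/2) per choice", {
  des <- experiment_design(headings = 16, coherences = 70,
                           modalities = "vestibular",
                           trials_per_condition = 400)
  tr <- simulate_trials(true_params, multidm_nuisance(lapse = 1), des,
                        seed = 22)
  tr <- tr[, setdiff(names(tr), "forced")]
  agg <- aggregate_trials(tr)
  ll <- log_likelihood(true_params, multidm_nuisance(lapse = 1), tr,
                       step = 0.005)
  choice_part <- sum(agg$n) * log(0.5)
  # remove the (data-independent) RT part to isolate the choice term
  pred <- predict_conditions(true_params, multidm_nuisance(lapse = 1),
                             agg[, c("modality", "coherence", "heading")],
                             profiles_5ms)
  rt_part <- sum(dnorm(pred$mean_rt_correct, agg$mean_rt_correct,
                       agg$sem_rt_correct, log = TRUE), na.rm = TRUE) +
    sum(dnorm(pred$mean_rt_error, agg$mean_rt_error, agg$sem_rt_error,
              log = TRUE), na.rm = TRUE)
  expect_equal(ll - rt_part, choice_part, tolerance = 1e-8)
})

test_that("the likelihood is mirror symmetric", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           trials_per_condition = 80)
  nuis <- multidm_nuisance(
    setNames(c(0.5, -1, 0.25), condition_labels(70)), lapse = 0.05)
  tr <- simulate_trials(true_params, nuis, des, seed = 23)
  ll <- suppressWarnings(
    log_likelihood(true_params, nuis, tr, step = 0.005))
  mirror <- tr
  mirror$heading_deg <- -mirror$heading_deg
  mirror$choice <- ifelse(mirror$choice == "right", "left", "right")
  nuis_m <- multidm_nuisance(-nuis$biases, nuis$lapse)
  ll_m <- suppressWarnings(
    log_likelihood(true_params, nuis_m, mirror, step = 0.005))
  expect_equal(ll, ll_m, tolerance = 1e-8)
})

test_that("adjusted R2 matches a hand-computed toy table", {
  agg <- data.frame(
    modality = "visual", coherence = 70,
    heading = c(-16, -5.6, 0.686, 5.6, 16),
    n = c(10, 20, 30, 20, 10),
    p_right = c(0.1, 0.3, 0.55, 0.8, 0.9),
    n_correct = c(9, 15, 16, 17, 9),
    mean_rt_correct = c(0.9, 1.1, 1.3, 1.05, 0.95),
    sem_rt_correct = 0.02,
    n_error = c(1, 5, 14, 3, 1),
    mean_rt_error = c(1.0, 1.2, 1.35, 1.15, 1.0),
    sem_rt_error = 0.05)
  pred <- data.frame(
    p_right = c(0.12, 0.28, 0.5, 0.78, 0.93),
    mean_rt_correct = c(0.92, 1.08, 1.25, 1.08, 0.93),
    mean_rt_error = c(1.05, 1.18, 1.3, 1.18, 1.05))
  # spreadsheet-style recomputation
  wr2_hand <- function(o, p, w) {
    mu <- sum(w * o) / sum(w)
    1 - sum(w * (o - p)^2) / sum(w * (o - mu)^2)
  }
  adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)
  r2p <- adj(wr2_hand(agg$p_right, pred$p_right, agg$n), 5, 2)
  r2c <- adj(wr2_hand(c(agg$mean_rt_correct, agg$mean_rt_error),
                      c(pred$mean_rt_correct, pred$mean_rt_error),
                      c(agg$n_correct, agg$n_error)), 10, 2)
  got <- adjusted_r2(agg, pred, n_params = 2)
  expect_equal(got$r2_psych, r2p, tolerance = 1e-12)
  expect_equal(got$r2_chron, r2c, tolerance = 1e-12)
  expect_equal(got$r2_mean, (r2p + r2c) / 2, tolerance = 1e-12)
  # perfect predictions give 1; constant predictions give <= 0
  perfect <- data.frame(p_right = agg$p_right,
                        mean_rt_correct = agg$mean_rt_correct,
                        mean_rt_error = agg$mean_rt_error)
  expect_equal(adjusted_r2(agg, perfect, 0)$r2_mean, 1)
  const <- data.frame(
    p_right = rep(weighted.mean(agg$p_right, agg$n), 5),
    mean_rt_correct = rep(weighted.mean(agg$mean_rt_correct,
                                        agg$n_correct), 5),
    mean_rt_error = rep(weighted.mean(agg$mean_rt_error, agg$n_error), 5))
  expect_lte(adjusted_r2(agg, const, 0)$r2_psych, 1e-10)
})

test_that("variant prediction rules nest the optimal model correctly", {
  pr <- profiles_5ms
  nuis <- multidm_nuisance()
  # separate_k evaluated at the optimal combination equals optimal
  kv <- k_visual(0.7, true_params$a_vis, true_params$gamma_vis)
  extra <- setNames(k_combined(kv, true_params$k_vest), "k_comb:70")
  for (h in c(-5.6, 1.96)) {
    po <- predict_condition(true_params, nuis, "combined", 70, h, pr)
    ps <- predict_condition(true_params, nuis, "combined", 70, h, pr,
                            variant = "separate_k", extra = extra)
    expect_equal(ps$p_right, po$p_right, tolerance = 1e-10)
    expect_equal(ps$mean_rt_correct, po$mean_rt_correct, tolerance = 1e-10)
  }
  # equal sensitivities make the equal-weight average optimal
  peq <- multidm_params(a_vis = 20, gamma_vis = 1, k_vest = 20)
  pn <- predict_condition(peq, nuis, "combined", 100, 5.6, pr,
                          variant = "no_cue_weighting")
  po <- predict_condition(peq, nuis, "combined", 100, 5.6, pr)
  expect_equal(pn$p_right, po$p_right, tolerance = 0.005)
  expect_equal(pn$mean_rt_correct, po$mean_rt_correct, tolerance = 0.01)
  # constant stimulus profiles make temporal weighting irrelevant
  flat <- list(v = pr$one, a = pr$one, one = pr$one, time = pr$time,
               step = pr$step, duration = pr$duration)
  pnt <- predict_condition(true_params, nuis, "visual", 70, 5.6, flat,
                           variant = "no_temporal_weighting")
  pot <- predict_condition(true_params, nuis, "visual", 70, 5.6, flat)
  expect_equal(pnt$p_right, pot$p_right, tolerance = 1e-10)
  # misweighted profiles genuinely change predictions
  pwa <- predict_condition(true_params, nuis, "visual", 70, 1.96, pr,
                           variant = "weight_by_acceleration")
  pov <- predict_condition(true_params, nuis, "visual", 70, 1.96, pr)
  expect_gt(abs(pwa$mean_rt_correct - pov$mean_rt_correct), 0.01)
})

test_that("refitting from the truth cannot decrease the likelihood", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           modalities = "vestibular",
                           trials_per_condition = 150)
  tr <- simulate_trials(true_params, multidm_nuisance(lapse = 0.02), des,
                        seed = 24)
  truth_start <- c(unlist(true_params), "bias:vestibular" = 0,
                   lapse = 0.02)
  ll_truth <- suppressWarnings(
    log_likelihood(true_params,
                   multidm_nuisance(setNames(0, "vestibular"), 0.02),
                   tr, step = 0.005))
  f <- multidm(tr, seed = 25, start = truth_start,
               budget = list(mcmc = 0, stage1_maxit = 150,
                             stage3_maxit = 100))
  expect_gte(f$loglik, ll_truth - 1e-6)
  expect_s3_class(f, "multidm")
  expect_true(is.finite(f$loglik))
})

test_that("a reduced sampling budget reaches a similar optimum", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           modalities = "vestibular",
                           trials_per_condition = 200)
  tr <- simulate_trials(true_params, multidm_nuisance(lapse = 0.02), des,
                        seed = 26)
  f_small <- multidm(tr, seed = 27,
                     budget = list(mcmc = 440, stage1_maxit = 400,
                                   stage3_maxit = 400))
  f_full <- multidm(tr, seed = 27,
                    budget = list(mcmc = 4400, stage1_maxit = 400,
                                  stage3_maxit = 400))
  expect_lt(abs(f_full$loglik - f_small$loglik), 2)
})

test_that("model fits expose the standard S3 surface", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           modalities = "vestibular",
                           trials_per_condition = 120)
  tr <- simulate_trials(true_params, multidm_nuisance(lapse = 0.02), des,
                        seed = 28)
  f <- multidm(tr, seed = 29, budget = list(mcmc = 100, stage1_maxit = 200,
                                            stage3_maxit = 100))
  expect_named(coef(f), f$layout)
  expect_s3_class(logLik(f), "logLik")
  expect_identical(attr(logLik(f), "nobs"), nrow(tr))
  pr <- predict(f)
  expect_true(all(pr$p_right >= 0 & pr$p_right <= 1))
  rs <- residuals(f, "psych")
  expect_length(rs, nrow(f$aggregates))
  sm <- summary(f)
  expect_s3_class(sm, "summary.multidm")
  st <- simulate(f, nsim = 5, seed = 30)
  expect_s3_class(st, "trial_table")
  expect_identical(nrow(st), 5L * 2L * 2L)  # 2 signed headings, 1 modality
  # r2_mean is exactly the average of its parts
  expect_identical(f$r2$r2_mean, (f$r2$r2_psych + f$r2$r2_chron) / 2)
  out <- capture.output(print(f))
  expect_match(out[1], "variant: optimal")
})

test_that("BIC bookkeeping drives the comparison report", {
  des <- experiment_design(headings = c(1.96, 16), coherences = 70,
                           modalities = "vestibular",
                           trials_per_condition = 100)
  tr <- simulate_trials(true_params, multidm_nuisance(lapse = 0.02), des,
                        seed = 31)
  f <- multidm(tr, seed = 32, budget = list(mcmc = 50, stage1_maxit = 150,
                                            stage3_maxit = 50))
  # identical model listed twice: pooled log10 BF exactly zero
  cmp <- multidm_compare(list(d1 = tr),
                         variants = c("optimal", "optimal2"),
                         fits = list(d1 = list(optimal = f, optimal2 = f)))
  expect_identical(unname(cmp$log10_bf[["optimal2"]]), 0)
  expect_false(cmp$decisive[["optimal2"]])
  # one extra parameter at equal likelihood costs exactly log(N) in BIC
  f2 <- f
  f2$n_params <- f$n_params + 1L
  cmp2 <- multidm_compare(list(d1 = tr),
                          variants = c("optimal", "padded"),
                          fits = list(d1 = list(optimal = f, padded = f2)))
  bic_diff <- with(cmp2$table,
                   bic[variant == "padded"] - bic[variant == "optimal"])
  expect_equal(bic_diff, log(nrow(tr)), tolerance = 1e-12)
})
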