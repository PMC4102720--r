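# Shared fixtures: coarse profile bundles and small simulated datasets are
# built once per test run.  All stochastic fixtures carry fixed seeds.

trapz_num <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# coarse grid keeps unit tests fast; acceptance tests use finer grids
profiles_5ms <- stimulus_profiles(step = 0.005)
profiles_1ms <- stimulus_profiles(step = 0.001)

true_params <- multidm_params()
true_nuisance <- multidm_nuisance(lapse = 0.03)

# long constant profile: effectively no deadline for moderate bounds
const_profile <- function(duration = 40, step = 0.002) {
  tt <- seq(0, duration, by = step)
  temporal_profile(tt, rep(1, length(tt)), normalized = TRUE)
}

# trial table built directly from given RT samples (for race-bound tests)
rt_table <- function(modality, coherence, heading, rts) {
  data.frame(subject = "fix", modality = modality, coherence = coherence,
             heading_deg = heading, choice = "right", rt_s = rts,
             correct = TRUE, forced = FALSE, stringsAsFactors = FALSE)
}

# binomial psychometric data as a trial table
psy_table <- function(headings, n_per, threshold, bias = 0, lapse = 0,
                      modality = "visual", coherence = 70, seed = 1) {
  set.seed(seed)
  rows <- lapply(headings, function(h) {
    p <- lapse / 2 + (1 - lapse) * pnorm((h - bias) / threshold)
    k <- rbinom(1, n_per, p)
    data.frame(subject = "fix", modality = modality, coherence = coherence,
               heading_deg = h,
               choice = rep(c("right", "left"), c(k, n_per - k)),
               rt_s = 1, correct = TRUE, forced = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
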