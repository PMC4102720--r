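## Model-free psychophysics: cumulative-Gaussian psychometric fits with a
## shared lapse rate, parametric-bootstrap threshold CIs and comparisons,
## the classical optimal-integration threshold prediction, and race-model
## (Miller / Grice) bound diagnostics.

## rightward-choice counts per heading for each modality/coherence combo
choice_counts <- function(data) {
  key <- interaction(data$modality, data$coherence, data$heading_deg,
                     drop = TRUE)
  out <- lapply(split(seq_len(nrow(data)), key), function(idx) {
    d <- data[idx, ]
    data.frame(modality = d$modality[1], coherence = d$coherence[1],
               heading = d$heading_deg[1], n = nrow(d),
               n_right = sum(d$choice == "right"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## per-condition (threshold, bias) MLE at a fixed lapse; counts is the
## output of choice_counts restricted to one modality/coherence combo
fit_one_psy <- function(counts, lapse) {
  nll <- function(p) {
    sig <- exp(p[1]); mu <- p[2]
    pr <- lapse / 2 + (1 - lapse) * stats::pnorm((counts$heading - mu) / sig)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(counts$n_right, counts$n, pr, log = TRUE))
  }
  o <- stats::optim(c(log(2), 0), nll, method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-10))
  list(threshold = exp(o$par[1]), bias = o$par[2], nll = o$value)
}

fit_psychometric_counts <- function(counts, lapse = NULL) {
  key <- condition_label(counts$modality, counts$coherence)
  groups <- split(seq_len(nrow(counts)), key)
  if (any(vapply(groups, function(i) length(unique(counts$heading[i])),
                 integer(1)) < 2))
    stop("each condition needs at least 2 distinct headings")
  joint_nll <- function(lp) {
    sum(vapply(groups, function(idx) fit_one_psy(counts[idx, ], lp)$nll,
               numeric(1)))
  }
  if (is.null(lapse)) {
    lapse <- stats::optimize(joint_nll, c(0, 0.5), tol = 1e-5)$minimum
    if (joint_nll(0) <= joint_nll(lapse)) lapse <- 0
  }
  fits <- lapply(groups, function(idx) fit_one_psy(counts[idx, ], lapse))
  conditions <- data.frame(
    condition = names(groups),
    modality = counts$modality[vapply(groups, `[`, integer(1), 1)],
    coherence = counts$coherence[vapply(groups, `[`, integer(1), 1)],
    threshold = vapply(fits, `[[`, numeric(1), "threshold"),
    bias = vapply(fits, `[[`, numeric(1), "bias"),
    row.names = NULL, stringsAsFactors = FALSE)
  pinned <- conditions$condition[conditions$threshold < 0.01]
  conditions$threshold <- pmax(conditions$threshold, 0.01)
  structure(list(conditions = conditions, lapse = lapse,
                 loglik = -joint_nll(lapse), counts = counts,
                 pinned = pinned), class = "psychfit")
}

#' Psychometric fits with a shared lapse rate
#'
#' Joint maximum-likelihood fit of cumulative-Gaussian psychometric
#' functions to the proportion of rightward choices against signed heading:
#' one threshold (the Gaussian SD) and one bias (the mean, a horizontal
#' shift) per modality/coherence combination, and a single lapse rate
#' shared across all conditions,
#' `P(right | h) = lapse/2 + (1 - lapse) * pnorm((h - bias)/threshold)`.
#'
#' @param data a trial table.
#' @param lapse optional fixed lapse rate; by default the shared lapse is
#'   profiled over \[0, 0.5\].
#' @return An object of class `psychfit`: data frame of per-condition
#'   thresholds and biases (`$conditions`), the shared `$lapse` and the
#'   joint log-likelihood. Conditions driven to the lower threshold
#'   box bound (0.01 deg; perfect separation) are flagged in `$pinned`.
#' @export
fit_psychometric <- function(data, lapse = NULL) {
  fit_psychometric_counts(choice_counts(data), lapse)
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Psychometric fits (shared lapse %.3f):\n", x$lapse))
  print(x$conditions[, c("condition", "threshold", "bias")], row.names = FALSE)
  if (length(x$pinned))
    cat("NOTE: thresholds pinned at the lower bound for:",
        paste(x$pinned, collapse = ", "), "\n")
  invisible(x)
}

#' Optimal combined-condition threshold prediction
#'
#' The classical fixed-duration cue-integration prediction: combined
#' squared threshold `sigma_pred^2 = sigma_vis^2 sigma_vest^2 /
#' (sigma_vis^2 + sigma_vest^2)`, always at most the smaller unimodal
#' threshold.
#'
#' @param sigma_vis,sigma_vest unimodal thresholds in degrees (> 0).
#' @return Predicted combined threshold in degrees.
#' @export
predict_combined_threshold <- function(sigma_vis, sigma_vest) {
  stopifnot(all(sigma_vis > 0), all(sigma_vest > 0))
  sqrt(sigma_vis^2 * sigma_vest^2 / (sigma_vis^2 + sigma_vest^2))
}

#' Parametric bootstrap of psychometric thresholds
#'
#' Simulates rightward counts from the fitted psychometric curves,
#' refits the joint model per sample, and returns percentile confidence
#' intervals for every threshold, optionally one-tailed comparisons
#' between conditions (the p-value is the fraction of bootstrap threshold
#' differences crossing zero, Bonferroni-corrected across the declared
#' comparison family), and the per-sample optimal combined-threshold
#' prediction obtained by propagating the unimodal samples through
#' [predict_combined_threshold()].
#'
#' @param fit a [fit_psychometric()] object.
#' @param n_boot bootstrap samples (5000 in the full analysis; at least a
#'   few hundred for stable CIs — below 100 a warning is raised).
#' @param seed integer seed (mandatory).
#' @param comparisons optional list of `c(condition_a, condition_b)` label
#'   pairs; the one-tailed p-value is for threshold(a) > threshold(b).
#' @return An object of class `psychboot` with `$ci` (95% percentile CIs),
#'   `$samples` (bootstrap threshold draws), `$comparisons` (raw and
#'   Bonferroni-corrected p-values) and `$predicted` (per-coherence
#'   combined-threshold predictions with CIs, when both unimodal
#'   conditions are present).
#' @export
bootstrap_thresholds <- function(fit, n_boot = 1000, seed,
                                 comparisons = NULL) {
  stopifnot(inherits(fit, "psychfit"))
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (n_boot < 100)
    warning("fewer than 100 bootstrap samples give unstable CIs")
  set.seed(seed)
  counts <- fit$counts
  lab <- condition_label(counts$modality, counts$coherence)
  cond <- fit$conditions
  p_fit <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    row <- cond[cond$condition == lab[i], ]
    p_fit[i] <- fit$lapse / 2 + (1 - fit$lapse) *
      stats::pnorm((counts$heading[i] - row$bias) / row$threshold)
  }
  draws <- matrix(NA_real_, n_boot, nrow(cond),
                  dimnames = list(NULL, cond$condition))
  for (b in seq_len(n_boot)) {
    bc <- counts
    bc$n_right <- stats::rbinom(nrow(bc), bc$n, p_fit)
    # the shared lapse is held at its point estimate during resampling;
    # thresholds are refit per condition
    bf <- fit_psychometric_counts(bc, lapse = fit$lapse)
    draws[b, ] <- bf$conditions$threshold[
      match(cond$condition, bf$conditions$condition)]
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  comp <- NULL
  if (!is.null(comparisons)) {
    m <- length(comparisons)
    comp <- do.call(rbind, lapply(comparisons, function(pr) {
      d <- draws[, pr[1]] - draws[, pr[2]]
      p_raw <- mean(d <= 0)
      data.frame(a = pr[1], b = pr[2], p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * m),
                 stringsAsFactors = FALSE)
    }))
  }
  predicted <- NULL
  coh <- unique(cond$coherence[cond$modality == "visual"])
  if ("vestibular" %in% cond$modality && length(coh)) {
    predicted <- do.call(rbind, lapply(coh, function(cc) {
      vlab <- paste0("visual:", format(cc, trim = TRUE))
      if (!vlab %in% colnames(draws)) return(NULL)
      pred <- predict_combined_threshold(draws[, vlab],
                                         draws[, "vestibular"])
      data.frame(coherence = cc,
                 predicted = predict_combined_threshold(
                   cond$threshold[cond$condition == vlab],
                   cond$threshold[cond$condition == "vestibular"]),
                 lo = stats::quantile(pred, 0.025, names = FALSE),
                 hi = stats::quantile(pred, 0.975, names = FALSE))
    }))
  }
  structure(list(ci = ci, samples = draws, comparisons = comp,
                 predicted = predicted, n_boot = n_boot),
            class = "psychboot")
}

#' Race-model bound tests (Miller and Grice)
#'
#' For every coherence/heading cell present in all three modalities,
#' compares the empirical reaction-time CDF of the combined condition with
#' the bounds implied by a parallel race of the two unimodal channels:
#' Miller's upper bound `F_comb(t) <= F_vis(t) + F_vest(t)` (violated by
#' co-activation faster than any race) and Grice's lower bound
#' `F_comb(t) >= max(F_vis(t), F_vest(t))` (violated when the combined
#' response is slower than the faster channel). Significance is assessed
#' by permuting modality labels within the cell; the reported direction is
#' `"faster than parallel race"` for a significant Miller violation and
#' `"slower than parallel race"` for a significant Grice violation.
#'
#' @param data a trial table containing all three modalities.
#' @param n_perm label permutations per cell.
#' @param seed integer seed (mandatory).
#' @param min_trials cells with fewer trials than this in any modality are
#'   skipped (with a message).
#' @return Data frame with one row per cell: maximal bound violations,
#'   permutation p-values and direction.
#' @export
race_bound_tests <- function(data, n_perm = 1000, seed, min_trials = 10) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  combos <- unique(data[data$modality == "combined",
                        c("coherence", "heading_deg")])
  stat_fun <- function(rt_v, rt_s, rt_c) {
    tg <- sort(unique(c(rt_v, rt_s, rt_c)))
    Fv <- stats::ecdf(rt_v)(tg); Fs <- stats::ecdf(rt_s)(tg)
    Fc <- stats::ecdf(rt_c)(tg)
    c(miller = max(Fc - pmin(Fv + Fs, 1)),
      grice = max(pmax(Fv, Fs) - Fc))
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cc <- combos$coherence[i]; hh <- combos$heading_deg[i]
    rt <- lapply(c("visual", "vestibular", "combined"), function(m) {
      sel <- data$modality == m & data$heading_deg == hh &
        (m == "vestibular" | data$coherence == cc)
      data$rt_s[sel]
    })
    if (any(vapply(rt, length, integer(1)) < min_trials)) {
      message(sprintf("race test: cell coherence %s / heading %s skipped (< %d trials)",
                      cc, hh, min_trials))
      next
    }
    obs <- stat_fun(rt[[1]], rt[[2]], rt[[3]])
    pool <- c(rt[[1]], rt[[2]], rt[[3]])
    sizes <- vapply(rt, length, integer(1))
    perm <- matrix(NA_real_, n_perm, 2)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(pool))
      r1 <- pool[idx[seq_len(sizes[1])]]
      r2 <- pool[idx[sizes[1] + seq_len(sizes[2])]]
      r3 <- pool[idx[sizes[1] + sizes[2] + seq_len(sizes[3])]]
      perm[b, ] <- stat_fun(r1, r2, r3)
    }
    p_miller <- mean(perm[, 1] >= obs["miller"])
    p_grice <- mean(perm[, 2] >= obs["grice"])
    direction <- if (p_miller < 0.05 && obs["miller"] > 0)
      "faster than parallel race"
    else if (p_grice < 0.05 && obs["grice"] > 0)
      "slower than parallel race"
    else "consistent with parallel race"
    rows[[i]] <- data.frame(
      coherence = cc, heading = hh,
      miller_violation = obs["miller"], miller_p = p_miller,
      grice_violation = obs["grice"], grice_p = p_grice,
      direction = direction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
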