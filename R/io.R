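## Delimited-text interfaces: trial tables, parameter configs, and the
## end-to-end simulate -> fit -> compare -> psychophysics pipeline.

#' Read and write trial tables
#'
#' Trial tables are tab-separated text with a header and columns
#' `subject`, `modality`, `coherence` (percent), `heading_deg`, `choice`
#' (`left`/`right`), `rt_s` (seconds), plus optional `correct` and
#' `forced` flags. Round trips are lossless at full double precision.
#' Schema violations (negative or non-finite RT, unknown modality or
#' choice, coherence outside \[0, 100\]) are reported with their row
#' numbers.
#'
#' @param path file path.
#' @param table a trial table data frame.
#' @return `read_trials` returns a `trial_table` data frame;
#'   `write_trials` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("modality", "coherence", "heading_deg", "choice", "rt_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial file misses columns: ", paste(miss, collapse = ", "))
  if (nrow(d)) {
    bad <- which(!(d$modality %in% c("visual", "vestibular", "combined")) |
                 !(d$choice %in% c("left", "right")) |
                 !is.finite(d$rt_s) | d$rt_s < 0 |
                 !is.finite(d$coherence) |
                 d$coherence < 0 | d$coherence > 100)
    if (length(bad))
      stop("malformed trial rows: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  if (is.null(d$subject)) d$subject <- rep("unknown", nrow(d))
  if (is.null(d$correct))
    d$correct <- (d$choice == "right") == (d$heading_deg >= 0)
  if (is.null(d$forced)) d$forced <- logical(nrow(d))
  class(d) <- c("trial_table", "data.frame")
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(table, path) {
  cols <- intersect(c("subject", "modality", "coherence", "heading_deg",
                      "choice", "rt_s", "correct", "forced"), names(table))
  df <- as.data.frame(table)[, cols]
  if (is.numeric(df$rt_s))
    df$rt_s <- formatC(df$rt_s, format = "g", digits = 17)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write parameter sets as flat key = value text
#'
#' One `name = value` pair per line; names are the core parameter names
#' plus `bias:<condition>` entries and `lapse`. Lines starting with `#`
#' are comments.
#'
#' @param path file path.
#' @param params a [multidm_params] object or named numeric vector.
#' @param nuisance optional [multidm_nuisance] object written alongside.
#' @return `read_params` returns a list with `params`, `nuisance`;
#'   `write_params` returns `path` invisibly.
#' @export
write_params <- function(params, path, nuisance = NULL) {
  v <- unlist(params)
  if (!is.null(nuisance))
    v <- c(v, stats::setNames(nuisance$biases,
                              paste0("bias:", names(nuisance$biases))),
           lapse = nuisance$lapse)
  writeLines(sprintf("%s = %.17g", names(v), v), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad))
    stop("malformed config lines: ", paste(bad, collapse = ", "))
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                          vapply(kv, `[`, character(1), 1))
  core <- c("a_vis", "gamma_vis", "b_vis", "theta_vis", "b_comb",
            "gamma_comb", "theta_comb", "k_vest", "theta_vest",
            "tnd_vis", "tnd_vest", "tnd_comb")
  miss <- setdiff(core, names(vals))
  if (length(miss))
    stop("config misses core parameters: ", paste(miss, collapse = ", "))
  params <- do.call(multidm_params, as.list(vals[core]))
  b <- vals[grepl("^bias:", names(vals))]
  names(b) <- sub("^bias:", "", names(b))
  lapse <- if ("lapse" %in% names(vals)) vals[["lapse"]] else 0
  list(params = params, nuisance = multidm_nuisance(b, lapse))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> fit -> compare -> psychophysics on a single
#' configuration: simulates a trial table from ground-truth parameters (or
#' loads one from file), fits the requested variants, compares them, fits
#' psychometric functions and, when all three modalities are present, runs
#' the race-bound tests. All outputs are written under `out_dir` as
#' delimited text / JSON, stamped with the seed and a hash of the
#' configuration.
#'
#' @param config list with entries: `seed` (mandatory), and optionally
#'   `trials_file` (input data) or `design`/`params`/`nuisance` (synthetic
#'   generation), `variants` (default `"optimal"`), `budget`, `step`
#'   (fitting grid), `sim_step`, `n_boot`, `stages` (subset of
#'   `c("simulate", "fit", "compare", "psych", "race")`).
#' @param out_dir output directory, created if needed.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the produced objects.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.null(config$seed)) stop("config must contain an explicit seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "fit", "psych")
  say <- function(...) if (verbose) message(...)
  stamp <- list(seed = config$seed,
                config_hash = sum(utf8ToInt(paste(
                  deparse(config[order(names(config))]), collapse = ""))))
  out <- list(stamp = stamp)

  if (!is.null(config$trials_file)) {
    trials <- read_trials(config$trials_file)
    say("loaded ", nrow(trials), " trials from ", config$trials_file)
  } else if ("simulate" %in% stages) {
    design <- config$design %||% experiment_design()
    params <- config$params %||% multidm_params()
    nuisance <- config$nuisance %||%
      multidm_nuisance(lapse = 0.03)
    say("simulating ", count_data_points(design) / 3 *
          design$trials_per_condition, " trials")
    trials <- simulate_trials(params, nuisance, design, seed = config$seed,
                              step = config$sim_step %||% 0.001)
    write_trials(trials, file.path(out_dir, "trials.tsv"))
  } else stop("pipeline needs either a trials_file or a simulate stage")
  out$trials <- trials

  variants <- config$variants %||% "optimal"
  if ("fit" %in% stages) {
    fits <- lapply(seq_along(variants), function(i) {
      say("fitting variant ", variants[i])
      multidm(trials, variant = variants[i], seed = config$seed + i,
              budget = config$budget %||% list(),
              step = config$step %||% 0.005)
    })
    names(fits) <- variants
    out$fits <- fits
    ftab <- do.call(rbind, lapply(names(fits), function(v) {
      f <- fits[[v]]
      data.frame(variant = v, loglik = f$loglik, n_params = f$n_params,
                 r2_mean = f$r2$r2_mean)
    }))
    utils::write.table(ftab, file.path(out_dir, "fits.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (v in names(fits))
      write_params(fits[[v]]$params,
                   file.path(out_dir, paste0("params_", v, ".txt")),
                   fits[[v]]$nuisance)
    if ("compare" %in% stages && length(fits) > 1) {
      cmp <- multidm_compare(list(dataset1 = trials), variants,
                             fits = list(dataset1 = fits))
      out$comparison <- cmp
      jsonlite::write_json(
        c(stamp, list(log10_bf = as.list(cmp$log10_bf))),
        file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  if ("psych" %in% stages) {
    say("fitting psychometric functions")
    psy <- fit_psychometric(trials)
    out$psychometric <- psy
    utils::write.table(psy$conditions, file.path(out_dir, "thresholds.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(config$n_boot) && config$n_boot > 0) {
      out$bootstrap <- bootstrap_thresholds(psy, n_boot = config$n_boot,
                                            seed = config$seed + 99)
    }
  }
  if ("race" %in% stages &&
      all(c("visual", "vestibular", "combined") %in% trials$modality)) {
    say("running race-model bound tests")
    out$race <- race_bound_tests(trials, n_perm = config$n_perm %||% 1000,
                                 seed = config$seed + 7)
    if (!is.null(out$race))
      utils::write.table(out$race, file.path(out_dir, "race_tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    else message("race tests: no cell had enough trials in all modalities")
  }
  jsonlite::write_json(stamp, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
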