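#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. `config` files in
#' YAML or JSON with these field names can be loaded via
#' [load_pipeline_config()].
#'
#' @param n_bins Bins per subject grid (default 10).
#' @param min_rt,sd_multiplier Cleaning rules, see [clean_trials()].
#' @param control A [race_control()].
#' @param chance_reps Monte-Carlo evaluations per double condition for
#'   [chance_level()] (default 1000; 0 skips the stage).
#' @param chance_refit Refit scope for the chance procedure (default
#'   `"race_only"`).
#' @param bootstrap_reps Bootstrap replicates (default 0 = skip).
#' @param percentiles Bootstrap percentile pair.
#' @param ties Tie-crediting rule for contributions.
#' @param seed Master seed; every stage's randomness descends from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_bins = 10, min_rt = 0.2, sd_multiplier = 3,
                            control = race_control(), chance_reps = 1000,
                            chance_refit = c("race_only", "full"),
                            bootstrap_reps = 0,
                            percentiles = c(0.025, 0.975),
                            ties = c("full", "split"), seed = 1) {
  structure(list(n_bins = as.integer(n_bins), min_rt = min_rt,
                 sd_multiplier = sd_multiplier, control = control,
                 chance_reps = as.integer(chance_reps),
                 chance_refit = match.arg(chance_refit),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 percentiles = percentiles, ties = match.arg(ties),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` (requires the yaml package) or `.json` file
#'   whose keys match the arguments of [pipeline_config()]; `control` may be
#'   a nested block with [race_control()] fields.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$control)) vals$control <- do.call(race_control, vals$control)
  do.call(pipeline_config, vals)
}

#' Run the full race-model pipeline over a multi-subject trial file
#'
#' Orchestrates, per subject: cleaning, bin-grid construction, joint racer
#' fit, contributions, consistency indices, the Monte-Carlo chance level of
#' every observed double condition, and (optionally) percentile-bootstrap
#' intervals — followed by the cross-subject summary of
#' [summarize_across_subjects()]. Subjects missing a required condition are
#' skipped with a warning; other subjects are still processed.
#'
#' The run is a deterministic function of the input data and
#' `config$seed`: per-subject sub-seeds are derived from the master seed,
#' so [report_json()] output is byte-identical across reruns.
#'
#' @param trials A trial data frame or a path readable by [read_trials()].
#' @param config A [pipeline_config()].
#' @return Object of class `race_report`: list with `subjects` (per-subject
#'   fits, chance levels, bootstraps), `summary`, `skipped` and `config`.
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(trials)) trials <- read_trials(trials)
  validate_trials(trials)
  subjects <- unique(trials$subject)
  results <- list()
  skipped <- character(0)
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    sub_trials <- trials[trials$subject == sub, , drop = FALSE]
    sub_seed <- (config$seed + 7919L * si) %% .Machine$integer.max
    res <- tryCatch(
      pipeline_one_subject(sub_trials, config, sub_seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("subject '", sub, "' skipped: ", conditionMessage(res),
              call. = FALSE)
      skipped <- c(skipped, sub)
    } else {
      results[[sub]] <- res
    }
  }
  if (length(results) == 0) stop("no subject could be processed")
  summary <- if (length(results) >= 2) {
    summarize_across_subjects(results)
  } else NULL
  structure(list(subjects = results, summary = summary, skipped = skipped,
                 config = config),
            class = "race_report")
}

pipeline_one_subject <- function(sub_trials, config, sub_seed) {
  missing <- setdiff(CONDITIONS, unique(sub_trials$condition))
  if (length(missing) > 0) {
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  }
  control <- config$control
  control$seed <- sub_seed
  fit <- race_fit(sub_trials, n_bins = config$n_bins, clean = TRUE,
                  min_rt = config$min_rt,
                  sd_multiplier = config$sd_multiplier,
                  control = control, ties = config$ties)
  chance <- list()
  if (config$chance_reps > 0) {
    for (cond in names(fit$contributions)) {
      chance[[cond]] <- chance_level(
        fit, cond, n_reps = config$chance_reps,
        seed = (sub_seed + condition_index(cond)) %% .Machine$integer.max,
        refit = config$chance_refit)
    }
  }
  boot <- NULL
  if (config$bootstrap_reps > 0) {
    boot <- bootstrap_intervals(fit, n_reps = config$bootstrap_reps,
                                seed = (sub_seed + 101L) %% .Machine$integer.max,
                                probs = config$percentiles)
  }
  list(fit = fit, chance = chance, bootstrap = boot)
}

#' Cross-subject summary with group t-tests
#'
#' Averages the per-racer contributions across subjects and runs the group
#' statistics: per double condition, a one-sided paired t-test of the
#' conjunctive contribution against each subject's mean Monte-Carlo chance
#' level, and two-sided matched-sample t-tests between the conjunctive
#' contribution and each single-feature contribution of the same race.
#' No multiple-testing correction is applied.
#'
#' @param results List of per-subject results from [run_pipeline()] (each
#'   holding `fit` and optionally `chance`), or a bare list of [race_fit()]
#'   objects; at least 2 subjects.
#' @return Object of class `race_group_summary` with `contributions`
#'   (subject-averaged means and standard errors), `conj_vs_chance` and
#'   `conj_vs_single` test tables. Degenerate tests (zero variance across
#'   subjects) are flagged with `NA` statistics.
#' @export
summarize_across_subjects <- function(results) {
  if (length(results) < 2) stop("group summary needs at least 2 subjects")
  fits <- lapply(results, function(r) if (inherits(r, "race_fit")) r else r$fit)
  per_sub <- lapply(fits, function(f) {
    vals <- list()
    for (cond in names(f$contributions)) {
      cc <- f$contributions[[cond]]$contributions
      for (nm in names(cc)) vals[[paste0(cond, ":", nm)]] <- unname(cc[nm])
    }
    vals
  })
  keys <- Reduce(intersect, lapply(per_sub, names))
  mat <- vapply(per_sub, function(v) unlist(v[keys]),
                numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys), dimnames = list(keys, names(fits)))
  contributions <- data.frame(
    quantity = keys,
    mean = rowMeans(mat),
    se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
    stringsAsFactors = FALSE)
  rownames(contributions) <- NULL

  chance_means <- vapply(results, function(r) {
    if (inherits(r, "race_fit") || length(r$chance) == 0) return(NA_real_)
    mean(vapply(r$chance, function(ch) ch$mean_chance, numeric(1)))
  }, numeric(1))

  conj_vs_chance <- NULL
  conj_vs_single <- NULL
  for (cond in DOUBLE_CONDITIONS) {
    conj_key <- paste0(cond, ":", cond)
    if (!conj_key %in% keys) next
    conj <- mat[conj_key, ]
    sub_chance <- vapply(results, function(r) {
      if (inherits(r, "race_fit") || is.null(r$chance[[cond]])) NA_real_
      else r$chance[[cond]]$mean_chance
    }, numeric(1))
    if (!anyNA(sub_chance)) {
      tt <- safe_t_test(conj, sub_chance, alternative = "greater")
      conj_vs_chance <- rbind(conj_vs_chance, data.frame(
        condition = cond, mean_contribution = mean(conj),
        mean_chance = mean(sub_chance), t = tt$t, p = tt$p,
        degenerate = tt$degenerate, stringsAsFactors = FALSE))
    }
    for (single in RACE_MEMBERS[[cond]][1:2]) {
      key <- paste0(cond, ":", single)
      tt <- safe_t_test(conj, mat[key, ], alternative = "two.sided")
      conj_vs_single <- rbind(conj_vs_single, data.frame(
        condition = cond, single = single,
        mean_conj = mean(conj), mean_single = mean(mat[key, ]),
        t = tt$t, p = tt$p, degenerate = tt$degenerate,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(n_subjects = ncol(mat), contributions = contributions,
                 conj_vs_chance = conj_vs_chance,
                 conj_vs_single = conj_vs_single,
                 subject_mean_chance = chance_means,
                 note = "paired t-tests, no multiple-testing correction"),
            class = "race_group_summary")
}

safe_t_test <- function(x, y, alternative) {
  d <- x - y
  if (stats::sd(d) == 0 || anyNA(d)) {
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' @export
print.race_group_summary <- function(x, ...) {
  cat("Group summary over", x$n_subjects, "subjects\n")
  cat("\nSubject-averaged contributions:\n")
  print(x$contributions, row.names = FALSE, digits = 4)
  if (!is.null(x$conj_vs_chance)) {
    cat("\nConjunctive contribution vs Monte-Carlo chance (paired, one-sided):\n")
    print(x$conj_vs_chance, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$conj_vs_single)) {
    cat("\nConjunctive vs single-feature contributions (paired, two-sided):\n")
    print(x$conj_vs_single, row.names = FALSE, digits = 4)
  }
  cat("\n", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
print.race_report <- function(x, ...) {
  cat("Race-model pipeline report:", length(x$subjects), "subject(s)")
  if (length(x$skipped)) cat(",", length(x$skipped), "skipped")
  cat("\n")
  for (sub in names(x$subjects)) {
    print(x$subjects[[sub]]$fit)
    for (ch in x$subjects[[sub]]$chance) print(ch)
  }
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic (byte-identical for identical reports) JSON rendering of
#' everything the pipeline computed: per subject the cleaning report, bin
#' grid, fitted distributions, NLL, contributions, consistency indices,
#' chance levels and bootstrap intervals, plus the group summary.
#'
#' @param report A `race_report` from [run_pipeline()].
#' @param path Optional output file.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "race_report"))
  subjects <- lapply(report$subjects, function(r) {
    f <- r$fit
    out <- list(
      subject = f$subject,
      n_bins = f$n_bins,
      boundaries = f$grid$boundaries[-(f$n_bins + 1)],
      cleaning = f$cleaning,
      counts = as.data.frame(t(f$counts)),
      params = as.data.frame(t(f$params)),
      nll = f$nll,
      converged = f$converged,
      contributions = lapply(f$contributions, function(cc)
        list(contributions = as.list(cc$contributions),
             joint_win_prob = cc$joint_win_prob)),
      consistency_k = lapply(f$consistency, function(z)
        list(kl = z$kl, entropy = z$entropy, k = z$k)))
    if (length(r$chance)) {
      out$chance <- lapply(r$chance, function(ch)
        list(observed = ch$observed, mean_chance = ch$mean_chance,
             threshold = ch$threshold, significant = ch$significant,
             n_reps = ch$n_reps, refit = ch$refit))
    }
    if (!is.null(r$bootstrap)) {
      out$bootstrap <- list(
        n_reps = r$bootstrap$n_reps,
        contrib_lower = as.list(r$bootstrap$contrib_lower),
        contrib_upper = as.list(r$bootstrap$contrib_upper))
    }
    out
  })
  payload <- list(subjects = subjects, skipped = report$skipped)
  if (!is.null(report$summary)) {
    s <- report$summary
    payload$summary <- list(
      n_subjects = s$n_subjects, contributions = s$contributions,
      conj_vs_chance = s$conj_vs_chance, conj_vs_single = s$conj_vs_single,
      note = s$note)
  }
  payload$config <- list(
    n_bins = report$config$n_bins, min_rt = report$config$min_rt,
    sd_multiplier = report$config$sd_multiplier,
    chance_reps = report$config$chance_reps,
    chance_refit = report$config$chance_refit,
    bootstrap_reps = report$config$bootstrap_reps,
    ties = report$config$ties, seed = report$config$seed)
  js <- jsonlite::toJSON(payload, digits = I(12), auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
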