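#' Simulate winner counts of a two-racer race
#'
#' Draws `n_trials` independent bin indices from each of the two racer
#' distributions and tabulates the per-trial minimum (the winning bin).
#'
#' @param d1,d2 Probability vectors on one grid.
#' @param n_trials Number of simulated trials (0 gives a zero vector).
#' @param seed Optional seed.
#' @return Integer count vector of winning bins.
#' @export
simulate_race_winner_counts <- function(d1, d2, n_trials, seed = NULL) {
  check_distribution(d1)
  check_distribution(d2)
  if (length(d1) != length(d2)) stop("racers must share a grid")
  stopifnot(n_trials >= 0)
  if (!is.null(seed)) set.seed(seed)
  N <- length(d1)
  if (n_trials == 0) return(integer(N))
  i1 <- sample.int(N, n_trials, replace = TRUE, prob = d1)
  i2 <- sample.int(N, n_trials, replace = TRUE, prob = d2)
  tabulate(pmin(i1, i2), nbins = N)
}

#' Monte-Carlo chance level of a conjunctive contribution
#'
#' Calibrates how large a conjunctive contribution arises spuriously when
#' the double-feature RTs really come from a race between the two
#' single-feature racers alone. Per evaluation, the double condition's
#' counts are replaced by simulated two-racer winner counts (same trial
#' total, racers = the *fitted* single distributions), the model is
#' refitted, and the conjunctive contribution recomputed. The observed
#' contribution is called significant when it exceeds the 95th percentile
#' of these chance values (strictly; ties at the threshold are not
#' significant).
#'
#' @param fit A [race_fit()] object.
#' @param condition Double-feature condition: `"CO"`, `"MO"` or `"CM"`.
#' @param n_reps Number of Monte-Carlo evaluations (default 1000; at least
#'   20 for the percentile to mean anything).
#' @param seed Optional seed.
#' @param refit `"race_only"` (default) refits only the three racer
#'   distributions of the affected race, holding the other three fixed at
#'   their fitted values (the full likelihood is still used); `"full"`
#'   refits all six.
#' @param control Fit control for the refits; defaults to the original
#'   control with one restart.
#' @return Object of class `chance_level`: `observed` (the fit's
#'   conjunctive contribution), `chance_values`, `mean_chance`, `threshold`
#'   (95th percentile), `significant`, `n_reps`, `condition`, `refit`.
#' @export
chance_level <- function(fit, condition, n_reps = 1000, seed = NULL,
                         refit = c("race_only", "full"), control = NULL) {
  stopifnot(inherits(fit, "race_fit"))
  refit <- match.arg(refit)
  if (!condition %in% DOUBLE_CONDITIONS) {
    stop("condition must be one of ", paste(DOUBLE_CONDITIONS, collapse = ", "))
  }
  if (!condition %in% names(fit$contributions)) {
    stop("condition ", condition, " was not observed in this fit")
  }
  if (n_reps < 20) stop("n_reps below 20 makes the 95th percentile meaningless")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control)) {
    control <- fit$control
    control$n_restarts <- 1L
    control$seed <- NULL
  }
  members <- RACE_MEMBERS[[condition]]
  singles <- members[1:2]
  conj <- members[3]
  n_trials <- sum(fit$counts[condition, ])
  free <- fit$free
  if (refit == "race_only") {
    free[] <- FALSE
    free[members] <- TRUE
  }
  observed <- unname(fit$contributions[[condition]]$contributions[conj])
  chance_values <- numeric(n_reps)
  counts <- fit$counts
  for (r in seq_len(n_reps)) {
    counts[condition, ] <- simulate_race_winner_counts(
      fit$params[singles[1], ], fit$params[singles[2], ], n_trials)
    ref <- fit_model(counts, control = control, free = free)
    wp <- win_probabilities(ref$params[members, , drop = FALSE],
                            ties = fit$ties)
    chance_values[r] <- unname(wp$contributions[conj])
  }
  threshold <- unname(stats::quantile(chance_values, 0.95))
  structure(list(observed = observed, chance_values = chance_values,
                 mean_chance = mean(chance_values), threshold = threshold,
                 significant = observed > threshold,
                 n_reps = as.integer(n_reps), condition = condition,
                 refit = refit),
            class = "chance_level")
}

#' @export
print.chance_level <- function(x, ...) {
  cat(sprintf(
    "Chance level for %s conjunctive contribution (%d Monte-Carlo reps, %s refit)\n",
    x$condition, x$n_reps, x$refit))
  cat(sprintf("  observed %.4f | chance mean %.4f, 95th percentile %.4f -> %s\n",
              x$observed, x$mean_chance, x$threshold,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}
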