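#' Control parameters for the race-model fit
#'
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param tol Convergence tolerance on the change in negative log-likelihood
#'   between iterations (default 1e-9).
#' @param n_restarts Number of EM restarts; the first starts from the
#'   smoothed-empirical/uniform initializer, later ones add Dirichlet jitter
#'   (default 5).
#' @param seed Optional RNG seed for the jittered restarts.
#' @param prob_floor Floor applied to model probabilities inside logarithms,
#'   keeping the objective finite when counts fall in zero-probability bins
#'   (default 1e-12).
#' @param init_eps Smoothing constant for the empirical initializer
#'   (default 1e-6).
#' @return A list of class `race_control`.
#' @export
race_control <- function(max_iter = 2000, tol = 1e-9, n_restarts = 5,
                         seed = NULL, prob_floor = 1e-12, init_eps = 1e-6) {
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 1,
            prob_floor > 0, prob_floor <= 1e-6, init_eps > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 prob_floor = prob_floor, init_eps = init_eps),
            class = "race_control")
}

check_counts_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != length(CONDITIONS)) {
    stop("counts must be a 6 x N matrix with rows C, M, O, CO, MO, CM")
  }
  if (is.null(rownames(counts))) rownames(counts) <- CONDITIONS
  if (!identical(rownames(counts), CONDITIONS)) {
    counts <- counts[CONDITIONS, , drop = FALSE]
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  counts
}

#' Negative log-likelihood of the race model
#'
#' The joint multinomial negative log-likelihood of all six conditions'
#' binned counts: single-feature conditions use their racer's distribution
#' directly, and each double-feature condition uses the race-winner
#' distribution of its three racers (see [race_min_distribution()]). Model
#' probabilities are floored at `prob_floor` inside the (natural) logarithm.
#'
#' @param params 6 x N matrix of racer distributions with rows
#'   `C, M, O, CO, MO, CM` (or a list of six such probability vectors).
#' @param counts 6 x N matrix of binned counts in the same row order.
#' @param prob_floor Probability floor inside the log (default 1e-12).
#' @return The scalar negative log-likelihood (nats).
#' @export
negative_log_likelihood <- function(params, counts, prob_floor = 1e-12) {
  P <- as_params_matrix(params)
  counts <- check_counts_matrix(counts)
  if (ncol(P) != ncol(counts)) stop("params and counts must share one grid")
  nll <- 0
  for (cond in SINGLE_CONDITIONS) {
    n <- counts[cond, ]
    nll <- nll - sum(n[n > 0] * log(pmax(P[cond, ], prob_floor)[n > 0]))
  }
  for (cond in DOUBLE_CONDITIONS) {
    n <- counts[cond, ]
    if (all(n == 0)) next
    q <- race_min_distribution(P[RACE_MEMBERS[[cond]], , drop = FALSE])
    nll <- nll - sum(n[n > 0] * log(pmax(q, prob_floor)[n > 0]))
  }
  nll
}

as_params_matrix <- function(params) {
  if (is.list(params) && !is.matrix(params)) params <- do.call(rbind, params)
  if (!is.matrix(params) || nrow(params) != length(CONDITIONS)) {
    stop("params must be a 6 x N matrix with rows C, M, O, CO, MO, CM")
  }
  if (is.null(rownames(params))) rownames(params) <- CONDITIONS
  params <- params[CONDITIONS, , drop = FALSE]
  apply(params, 1, check_distribution)
  params
}

#' Initialize racer distributions from binned counts
#'
#' Single-feature racers start at their smoothed empirical frequencies
#' `(n + eps) / sum(n + eps)`; conjunctive racers (and single racers with no
#' counts) start uniform over the bins. With `jitter > 0` each row is mixed
#' with a Dirichlet(1, ..., 1) draw from the current RNG stream, which is how
#' later restarts of [fit_model()] decorrelate.
#'
#' @param counts 6 x N count matrix (rows `C, M, O, CO, MO, CM`).
#' @param eps Smoothing constant (default 1e-6).
#' @param jitter Mixing weight in `[0, 1)` of the Dirichlet component
#'   (default 0, deterministic).
#' @return A 6 x N matrix of valid probability vectors.
#' @export
initialize_params <- function(counts, eps = 1e-6, jitter = 0) {
  counts <- check_counts_matrix(counts)
  N <- ncol(counts)
  P <- matrix(1 / N, nrow = length(CONDITIONS), ncol = N,
              dimnames = list(CONDITIONS, NULL))
  for (cond in SINGLE_CONDITIONS) {
    n <- counts[cond, ]
    if (sum(n) > 0) P[cond, ] <- (n + eps) / sum(n + eps)
  }
  if (jitter > 0) {
    for (k in seq_len(nrow(P))) {
      g <- stats::rgamma(N, shape = 1)
      P[k, ] <- (1 - jitter) * P[k, ] + jitter * g / sum(g)
    }
  }
  P
}

#' Fit the six racer distributions by constrained maximum likelihood
#'
#' Jointly minimizes [negative_log_likelihood()] over the six racer
#' distributions, each constrained to the probability simplex, using an EM
#' algorithm whose latent variables are the racers' individual bins given
#' each race's observed winning bin. The EM update preserves the simplex
#' exactly (boundary values included) and decreases the objective
#' monotonically; the best of `control$n_restarts` runs is returned.
#'
#' Conditions with all-zero count rows contribute nothing and their
#' conjunctive racer can be held fixed via `free`.
#'
#' @param counts 6 x N matrix of binned counts (rows `C, M, O, CO, MO, CM`);
#'   absent conditions as zero rows.
#' @param control A [race_control()] list.
#' @param free Logical vector of length 6 naming which racers are updated;
#'   default: every racer appearing in a condition with data.
#' @param init Optional 6 x N start matrix; default [initialize_params()].
#' @return List of class `race_fit_result` with elements `params` (6 x N
#'   fitted matrix), `nll`, `converged`, `n_iter`, `restart_nlls` and `free`.
#' @export
fit_model <- function(counts, control = race_control(), free = NULL,
                      init = NULL) {
  counts <- check_counts_matrix(counts)
  if (is.null(free)) free <- default_free_racers(counts)
  stopifnot(is.logical(free), length(free) == length(CONDITIONS))
  if (!is.null(control$seed)) set.seed(control$seed)
  base_init <- if (is.null(init)) {
    initialize_params(counts, eps = control$init_eps)
  } else {
    as_params_matrix(init)
  }
  best <- NULL
  restart_nlls <- numeric(0)
  for (r in seq_len(control$n_restarts)) {
    start <- if (r == 1) base_init else {
      jittered <- initialize_params(counts, eps = control$init_eps,
                                    jitter = 0.3)
      if (!is.null(init)) 0.7 * base_init + 0.3 * jittered else jittered
    }
    res <- cpp_em_fit(counts, start, free, control$max_iter, control$tol,
                      control$prob_floor)
    if (!is.finite(res$nll)) next
    restart_nlls <- c(restart_nlls, res$nll)
    if (is.null(best) || res$nll < best$nll) best <- res
  }
  if (is.null(best)) stop("optimizer failed on every restart (non-finite NLL)")
  params <- best$probs
  dimnames(params) <- list(CONDITIONS, NULL)
  structure(list(params = params, nll = best$nll,
                 converged = isTRUE(best$converged), n_iter = best$n_iter,
                 restart_nlls = restart_nlls, free = free),
            class = "race_fit_result")
}

default_free_racers <- function(counts) {
  present <- rowSums(counts) > 0
  free <- stats::setNames(logical(length(CONDITIONS)), CONDITIONS)
  free[SINGLE_CONDITIONS] <- present[SINGLE_CONDITIONS]
  for (cond in DOUBLE_CONDITIONS) {
    if (present[cond]) {
      free[RACE_MEMBERS[[cond]]] <- TRUE
    }
  }
  free
}

#' Fit the race model to one subject's trials
#'
#' The front door of the package: takes per-trial RT records of a single
#' subject, optionally cleans them ([clean_trials()]), builds the pooled
#' per-subject bin grid ([make_bin_grid()]), bins each condition, and fits
#' the six racer distributions jointly by constrained maximum likelihood
#' ([fit_model()]). Contributions (win probabilities) for each observed
#' double-feature condition and consistency indices for every condition are
#' attached.
#'
#' A subset of the six conditions is allowed as long as every observed
#' double-feature condition is accompanied by its two single-feature
#' conditions (e.g. `C`, `O`, `CO`).
#'
#' @param trials Trial data frame (`subject`, `condition`, `rt`, `correct`)
#'   of one subject.
#' @param n_bins Number of RT bins including the reservoir (default 10).
#' @param clean Apply the exclusion rules first? (default TRUE).
#' @param min_rt,sd_multiplier Cleaning parameters, see [clean_trials()].
#' @param control A [race_control()] list.
#' @param ties Tie-crediting rule for contributions, see
#'   [win_probabilities()].
#' @return An object of class `race_fit`; see [summary.race_fit()],
#'   [coef.race_fit()], [predict.race_fit()], [plot.race_fit()],
#'   [simulate.race_fit()], [residuals.race_fit()], [chance_level()] and
#'   [bootstrap_intervals()].
#' @examples
#' cfg <- synthetic_config(n_subjects = 1, n_trials = 120)
#' trials <- generate_dataset(cfg, seed = 1)$trials
#' fit <- race_fit(trials, n_bins = 8,
#'                 control = race_control(n_restarts = 2, max_iter = 500))
#' summary(fit)
#' @export
race_fit <- function(trials, n_bins = 10, clean = TRUE, min_rt = 0.2,
                     sd_multiplier = 3, control = race_control(),
                     ties = c("full", "split")) {
  ties <- match.arg(ties)
  validate_trials(trials)
  subjects <- unique(trials$subject)
  if (length(subjects) != 1) {
    stop("race_fit() handles one subject at a time (got ",
         length(subjects), "); use run_pipeline() for multi-subject data")
  }
  cleaning <- NULL
  if (clean) {
    cleaned <- clean_trials(trials, min_rt = min_rt,
                            sd_multiplier = sd_multiplier)
    trials <- cleaned$trials
    cleaning <- cleaned$report
  }
  present <- intersect(CONDITIONS, unique(trials$condition))
  for (cond in intersect(DOUBLE_CONDITIONS, present)) {
    singles <- RACE_MEMBERS[[cond]][1:2]
    if (!all(singles %in% present)) {
      stop("double condition ", cond, " requires its single conditions ",
           paste(singles, collapse = " and "))
    }
  }
  grid <- make_bin_grid(trials$rt, n_bins = n_bins)
  counts <- bin_counts(trials, grid)
  fit <- fit_model(counts, control = control)
  contributions <- list()
  for (cond in intersect(DOUBLE_CONDITIONS, present)) {
    contributions[[cond]] <-
      win_probabilities(fit$params[RACE_MEMBERS[[cond]], , drop = FALSE],
                        ties = ties)
  }
  consistency <- fit_consistency(fit$params, counts, present,
                                 control$prob_floor)
  structure(list(subject = subjects, trials = trials, cleaning = cleaning,
                 grid = grid, counts = counts, conditions = present,
                 params = fit$params, free = fit$free, nll = fit$nll,
                 converged = fit$converged, n_iter = fit$n_iter,
                 restart_nlls = fit$restart_nlls,
                 contributions = contributions, consistency = consistency,
                 ties = ties, control = control, n_bins = grid$n_bins),
            class = "race_fit")
}

fit_consistency <- function(params, counts, present, prob_floor) {
  out <- list()
  for (cond in present) {
    n <- counts[cond, ]
    if (sum(n) == 0) next
    model <- implied_distribution(params, cond)
    out[[cond]] <- consistency_index(empirical_distribution(n), model,
                                     prob_floor = prob_floor)
  }
  out
}

## model-implied distribution of the *observed* RT bin for a condition
implied_distribution <- function(params, condition) {
  if (condition %in% SINGLE_CONDITIONS) {
    params[condition, ]
  } else {
    race_min_distribution(params[RACE_MEMBERS[[condition]], , drop = FALSE])
  }
}
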