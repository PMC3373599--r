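#' Empirical (relative-frequency) distribution from counts
#'
#' @param counts Non-negative count vector with positive total.
#' @return Probability vector `counts / sum(counts)`.
#' @export
empirical_distribution <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("cannot normalize all-zero counts")
  counts / tot
}

#' Normalized Kullback-Leibler consistency index
#'
#' Quantifies how well a model-implied binned distribution reproduces the
#' measured one: `k = KL(empirical || model) / H(empirical)` with
#' `KL = sum q_i log(q_i / p_i)` (terms with `q_i = 0` contribute zero, `p`
#' floored at `prob_floor`) and `H` the empirical entropy. `k = 0` exactly
#' when the two distributions agree on the empirical support; small `k`
#' means a good fit. The ratio is invariant to the logarithm base.
#'
#' Applied by [race_fit()] both to double-feature conditions (measured RTs
#' vs the fitted race-winner distribution) and to single-feature conditions
#' (measured RTs vs the fitted racer).
#'
#' @param empirical Measured probability vector.
#' @param model Model probability vector on the same bins.
#' @param base Logarithm base (default `exp(1)`; the index itself does not
#'   depend on it).
#' @param prob_floor Floor for model probabilities (default 1e-12).
#' @return List of class `consistency_index`: `kl`, `entropy`, `k`, and
#'   `support_mismatch` (TRUE when empirical mass sits where the model is
#'   below the floor, so `kl` is floor-dependent).
#' @examples
#' consistency_index(c(0.5, 0.5), c(0.9, 0.1))  # k ~ 0.737
#' @export
consistency_index <- function(empirical, model, base = exp(1),
                              prob_floor = 1e-12) {
  check_distribution(empirical)
  check_distribution(model)
  if (length(empirical) != length(model)) stop("distributions must share a grid")
  q <- empirical
  p <- pmax(model, prob_floor)
  pos <- q > 0
  kl <- sum(q[pos] * log(q[pos] / p[pos], base = base))
  kl <- max(kl, 0)
  entropy <- -sum(q[pos] * log(q[pos], base = base))
  if (entropy == 0) {
    stop("empirical distribution is a point mass; consistency ratio undefined")
  }
  structure(list(kl = kl, entropy = entropy, k = kl / entropy,
                 support_mismatch = any(q > 0 & model < prob_floor)),
            class = "consistency_index")
}

#' @export
print.consistency_index <- function(x, ...) {
  cat(sprintf("consistency k = %.4f (KL %.4f / H %.4f)%s\n", x$k, x$kl,
              x$entropy,
              if (x$support_mismatch) "  [support mismatch: KL floor-limited]"
              else ""))
  invisible(x)
}

## piecewise-linear empirical CDF of one condition's RT sample:
## F = 0 at min - 1e-4, knots (k - 0.5)/n at the sorted values, F = 1 at
## max + 1e-4; inverse-CDF sampling draws smooth resamples from it
pwl_cdf_sampler <- function(rts) {
  n <- length(rts)
  s <- sort(rts)
  x <- c(s[1] - 1e-4, s, s[n] + 1e-4)
  F <- c(0, (seq_len(n) - 0.5) / n, 1)
  keep <- !duplicated(x)           # tied RTs: keep first knot at each x
  x <- x[keep]; F <- F[keep]
  function(m) stats::approx(F, x, xout = stats::runif(m), rule = 2)$y
}

#' Percentile-bootstrap intervals for a race-model fit
#'
#' For each condition a piecewise-linear empirical CDF is interpolated
#' through the sorted cleaned RT sample (anchored at 0 and 1 just outside
#' the sample range, interior knots at `(k - 0.5)/n`), and each bootstrap
#' replicate draws the original per-condition trial counts afresh by
#' inverse-CDF sampling. The full pipeline — pooled bin grid, binning, joint
#' fit, contributions — is rerun on every replicate, and percentile
#' intervals are returned for every fitted racer-bin probability and every
#' contribution.
#'
#' @param fit A [race_fit()] object (keeps its cleaned trials).
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param seed Optional seed; fixing it makes the result reproducible.
#' @param probs Lower/upper percentile pair (default `c(0.025, 0.975)`).
#' @param control Fit control for the replicates; defaults to the original
#'   fit's control with a single restart (replicates start from the same
#'   deterministic initializer).
#' @return Object of class `race_boot`: `racer_lower`/`racer_upper` (6 x N
#'   matrices), `contrib_lower`/`contrib_upper`, `contrib_reps` (replicate
#'   draws of each contribution), `n_reps`, `probs`.
#' @export
bootstrap_intervals <- function(fit, n_reps = 500, seed = NULL,
                                probs = c(0.025, 0.975), control = NULL) {
  stopifnot(inherits(fit, "race_fit"))
  if (n_reps < 2) stop("n_reps must be at least 2")
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control)) {
    control <- fit$control
    control$n_restarts <- 1L
    control$seed <- NULL
  }
  samplers <- list()
  n_per_cond <- integer(0)
  for (cond in fit$conditions) {
    rts <- fit$trials$rt[fit$trials$condition == cond]
    if (length(unique(rts)) < 2) {
      samplers[[cond]] <- local({ v <- rts[1]; function(m) rep(v, m) })
    } else {
      samplers[[cond]] <- pwl_cdf_sampler(rts)
    }
    n_per_cond[cond] <- length(rts)
  }
  N <- fit$n_bins
  racer_reps <- array(NA_real_, c(n_reps, length(CONDITIONS), N))
  contrib_names <- unlist(lapply(names(fit$contributions), function(cond)
    paste0(cond, ":", names(fit$contributions[[cond]]$contributions))))
  contrib_reps <- matrix(NA_real_, n_reps, length(contrib_names),
                         dimnames = list(NULL, contrib_names))
  for (r in seq_len(n_reps)) {
    res <- lapply(fit$conditions, function(cond)
      samplers[[cond]](n_per_cond[cond]))
    names(res) <- fit$conditions
    pool <- unlist(res, use.names = FALSE)
    grid <- make_bin_grid(pool, n_bins = N)
    counts <- matrix(0L, length(CONDITIONS), N,
                     dimnames = list(CONDITIONS, NULL))
    for (cond in fit$conditions) counts[cond, ] <- bin_rts(res[[cond]], grid)
    rep_fit <- fit_model(counts, control = control)
    racer_reps[r, , ] <- rep_fit$params
    for (cond in names(fit$contributions)) {
      wp <- win_probabilities(rep_fit$params[RACE_MEMBERS[[cond]], ,
                                             drop = FALSE], ties = fit$ties)
      contrib_reps[r, paste0(cond, ":", names(wp$contributions))] <-
        wp$contributions
    }
  }
  q_lo <- apply(racer_reps, c(2, 3), stats::quantile, probs = probs[1])
  q_hi <- apply(racer_reps, c(2, 3), stats::quantile, probs = probs[2])
  dimnames(q_lo) <- dimnames(q_hi) <- list(CONDITIONS, NULL)
  structure(list(racer_lower = q_lo, racer_upper = q_hi,
                 contrib_lower = apply(contrib_reps, 2, stats::quantile,
                                       probs = probs[1]),
                 contrib_upper = apply(contrib_reps, 2, stats::quantile,
                                       probs = probs[2]),
                 contrib_reps = contrib_reps,
                 n_reps = as.integer(n_reps), probs = probs),
            class = "race_boot")
}

#' @export
print.race_boot <- function(x, ...) {
  cat("Percentile bootstrap:", x$n_reps, "replicates, interval",
      paste(x$probs, collapse = "-"), "\n")
  tab <- data.frame(lower = x$contrib_lower, upper = x$contrib_upper)
  print(round(tab, 4))
  invisible(x)
}
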