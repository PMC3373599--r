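#' @export
print.race_fit <- function(x, ...) {
  cat("Race-model fit: subject", x$subject, "|", x$n_bins, "bins |",
      sum(x$counts), "trials\n")
  cat("NLL:", format(x$nll, digits = 10),
      if (x$converged) "(converged)" else "(iteration limit)", "\n")
  for (cond in names(x$contributions)) {
    cc <- x$contributions[[cond]]$contributions
    cat(sprintf("  %s: %s  joint-win %.3f\n", cond,
                paste(sprintf("C_%s=%.3f", names(cc), cc), collapse = " "),
                x$contributions[[cond]]$joint_win_prob))
  }
  invisible(x)
}

#' Summarize a race-model fit
#'
#' @param object A [race_fit()] object.
#' @param ... Unused.
#' @return A list of class `summary.race_fit` with the contribution table,
#'   consistency indices and fit diagnostics.
#' @export
summary.race_fit <- function(object, ...) {
  contrib <- NULL
  for (cond in names(object$contributions)) {
    cc <- object$contributions[[cond]]
    contrib <- rbind(contrib, data.frame(
      condition = cond, racer = names(cc$contributions),
      contribution = unname(cc$contributions),
      joint_win_prob = cc$joint_win_prob, stringsAsFactors = FALSE))
  }
  k <- vapply(object$consistency, function(z) z$k, numeric(1))
  structure(list(subject = object$subject, n_bins = object$n_bins,
                 n_trials = sum(object$counts), nll = object$nll,
                 converged = object$converged, n_iter = object$n_iter,
                 restart_nlls = object$restart_nlls,
                 contributions = contrib, consistency_k = k),
            class = "summary.race_fit")
}

#' @export
print.summary.race_fit <- function(x, ...) {
  cat("Race-model fit for subject", x$subject, "\n")
  cat(sprintf("  %d bins, %d trials, NLL %.4f (%s, %d EM iterations)\n",
              x$n_bins, x$n_trials, x$nll,
              if (x$converged) "converged" else "iteration limit", x$n_iter))
  cat("\nContributions (probability each racer dictates saliency):\n")
  print(x$contributions, row.names = FALSE, digits = 4)
  cat("\nConsistency index k = KL/H per condition (small is good):\n")
  print(round(x$consistency_k, 4))
  invisible(x)
}

#' Fitted racer distributions
#'
#' @param object A [race_fit()] object.
#' @param ... Unused.
#' @return The 6 x N matrix of fitted racer probability vectors (rows
#'   `C, M, O, CO, MO, CM`); racers that were not free in the fit keep their
#'   initialization and are marked by the `free` attribute.
#' @export
coef.race_fit <- function(object, ...) {
  structure(object$params, free = object$free)
}

#' @export
logLik.race_fit <- function(object, ...) {
  structure(-object$nll, df = sum(object$free) * (object$n_bins - 1),
            nobs = sum(object$counts), class = "logLik")
}

#' Model-implied distributions from a race-model fit
#'
#' @param object A [race_fit()] object.
#' @param condition Condition label(s); default: all observed conditions.
#' @param type `"observed"` returns the model-implied distribution of the
#'   measured RT bin (the racer's own distribution for single-feature
#'   targets, the race-winner distribution for double-feature targets);
#'   `"racer"` returns the fitted racer distribution of that label itself.
#' @param ... Unused.
#' @return A matrix with one row per requested condition.
#' @export
predict.race_fit <- function(object, condition = object$conditions,
                             type = c("observed", "racer"), ...) {
  type <- match.arg(type)
  stopifnot(all(condition %in% CONDITIONS))
  out <- t(vapply(condition, function(cond) {
    if (type == "racer") object$params[cond, ]
    else implied_distribution(object$params, cond)
  }, numeric(object$n_bins)))
  rownames(out) <- condition
  out
}

#' Probability-scale residuals per condition
#'
#' Empirical bin frequencies minus the model-implied probabilities, for every
#' observed condition.
#'
#' @param object A [race_fit()] object.
#' @param ... Unused.
#' @return Matrix (conditions x bins) of residuals.
#' @export
residuals.race_fit <- function(object, ...) {
  conds <- object$conditions
  out <- t(vapply(conds, function(cond) {
    empirical_distribution(object$counts[cond, ]) -
      implied_distribution(object$params, cond)
  }, numeric(object$n_bins)))
  rownames(out) <- conds
  out
}

#' Simulate binned datasets from a fitted race model
#'
#' Draws new binned counts per condition with the observed per-condition
#' trial totals: single-feature counts multinomially from the fitted racer,
#' double-feature counts as the winning bin of independent draws of the
#' race's three fitted racers.
#'
#' @param object A [race_fit()] object.
#' @param nsim Number of replicate datasets (default 1).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` count matrices shaped like `object$counts`.
#' @export
simulate.race_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$n_bins
  replicate(nsim, simplify = FALSE, {
    counts <- matrix(0L, nrow = length(CONDITIONS), ncol = N,
                     dimnames = list(CONDITIONS, NULL))
    for (cond in object$conditions) {
      n <- sum(object$counts[cond, ])
      if (n == 0) next
      if (cond %in% SINGLE_CONDITIONS) {
        counts[cond, ] <- as.integer(stats::rmultinom(1, n,
                                                      object$params[cond, ]))
      } else {
        members <- RACE_MEMBERS[[cond]]
        draws <- vapply(members, function(m)
          sample.int(N, n, replace = TRUE, prob = object$params[m, ]),
          integer(n))
        winner <- apply(matrix(draws, nrow = n), 1, min)
        counts[cond, ] <- tabulate(winner, nbins = N)
      }
    }
    counts
  })
}

#' Plot measured and inferred RT distributions
#'
#' Renders, for one double-feature condition, the piecewise-linear density
#' curves of the measured RT distributions of the two single-feature targets
#' and the double-feature target, together with the inferred conjunctive
#' racer distribution. Each bin's probability is drawn at the bin midpoint
#' as probability / bin width; every curve starts at zero at the grid origin
#' and the infinite reservoir bin is omitted.
#'
#' @param x A [race_fit()] object.
#' @param condition Double-feature condition to display (default first one
#'   observed).
#' @param boot Optional [bootstrap_intervals()] result; adds percentile
#'   error bars.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.race_fit <- function(x, condition = names(x$contributions)[1],
                          boot = NULL, ...) {
  stopifnot(condition %in% DOUBLE_CONDITIONS)
  members <- RACE_MEMBERS[[condition]]
  b <- x$grid$boundaries
  N <- x$n_bins
  mid <- (b[1:(N - 1)] + b[2:N]) / 2          # finite bins only
  width <- diff(b)[1:(N - 1)]
  curves <- list()
  for (m in members[1:2]) {
    curves[[m]] <- empirical_distribution(x$counts[m, ])[1:(N - 1)] / width
  }
  curves[[condition]] <-
    empirical_distribution(x$counts[condition, ])[1:(N - 1)] / width
  conj <- members[3]
  curves[[paste0(conj, " (inferred racer)")]] <-
    x$params[conj, 1:(N - 1)] / width
  xx <- c(b[1], mid)
  ys <- vapply(curves, function(v) c(0, v), numeric(N))
  graphics::matplot(xx, ys, type = "l", lty = 1, lwd = 2,
                    col = seq_along(curves), xlab = "RT (s)",
                    ylab = "probability density (1/s)",
                    main = paste("Condition", condition), ...)
  if (!is.null(boot) && conj %in% rownames(boot$racer_lower)) {
    lo <- boot$racer_lower[conj, 1:(N - 1)] / width
    hi <- boot$racer_upper[conj, 1:(N - 1)] / width
    graphics::arrows(mid, lo, mid, hi, angle = 90, code = 3, length = 0.03,
                     col = length(curves))
  }
  graphics::legend("topright", legend = names(curves), lty = 1, lwd = 2,
                   col = seq_along(curves), bty = "n")
  invisible(x)
}
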