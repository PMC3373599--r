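#' Survivor (tail-sum) function of a binned distribution
#'
#' `survivor(p)[i]` is the probability that the racer's RT falls in bin `i`
#' or later, `S_i = sum(p[i:N])`; `S_1 = 1` and the vector is non-increasing.
#'
#' @param p Probability vector over the bins of one grid.
#' @return Numeric vector of tail sums, same length as `p`.
#' @export
survivor <- function(p) {
  check_distribution(p)
  rev(cumsum(rev(p)))
}

check_distribution <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1) stop("distribution must be a numeric vector")
  if (any(p < -1e-12)) stop("distribution has negative components")
  if (abs(sum(p) - 1) > tol) stop("distribution must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

as_dist_matrix <- function(dists) {
  if (is.matrix(dists)) {
    P <- dists
  } else if (is.list(dists)) {
    len <- unique(lengths(dists))
    if (length(len) != 1) stop("racer distributions have mismatched lengths")
    P <- do.call(rbind, dists)
  } else {
    stop("dists must be a list of probability vectors or a matrix (racers in rows)")
  }
  if (nrow(P) < 2) stop("a race needs at least two racers")
  apply(P, 1, check_distribution)
  P
}

## row-wise survivor functions, dimension-safe for single-bin grids
surv_matrix <- function(P) {
  S <- P
  for (k in seq_len(nrow(P))) S[k, ] <- rev(cumsum(rev(P[k, ])))
  S
}

#' Distribution of the race winner (minimum bin index)
#'
#' For independent racers with binned distributions on a shared grid, returns
#' the distribution of the bin holding the minimum RT:
#' `q_i = prod_k S_k(i) - prod_k S_k(i+1)` with `S_k(N+1) = 0`, where `S_k`
#' is each racer's survivor function.
#'
#' @param dists Two or more racer distributions (a list of probability
#'   vectors, or a matrix with racers in rows) on one grid.
#' @return Probability vector of the winning bin, same length as the inputs.
#' @examples
#' race_min_distribution(list(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5)))
#' # (0.875, 0.125): the race ends in bin 2 only if all three land there
#' @export
race_min_distribution <- function(dists) {
  P <- as_dist_matrix(dists)
  S <- surv_matrix(P)
  S_next <- cbind(S[, -1, drop = FALSE], 0)
  q <- apply(S, 2, prod) - apply(S_next, 2, prod)
  q[q < 0] <- 0  # guard tiny negative round-off
  q / sum(q)
}

#' Per-racer win probabilities ("contributions")
#'
#' Computes, for each racer, the probability that it attains the minimum bin
#' of the race — the probability that the corresponding neuron dictates the
#' target's saliency. With finitely wide bins, two or more racers can tie in
#' the winning bin; under the default `ties = "full"` crediting every joint
#' winner receives full credit, so the contributions can sum to more than
#' one, with the excess governed by `joint_win_prob`. `ties = "split"`
#' divides the credit equally among joint winners instead (contributions then
#' sum to exactly one).
#'
#' @param dists Labeled racer distributions (list or matrix with rownames) on
#'   one grid; two or three racers.
#' @param ties `"full"` (default) or `"split"` tie crediting.
#' @return An object of class `contributions`: list with `contributions`
#'   (named probabilities), `joint_win_prob` (probability that at least two
#'   racers share the winning bin) and `ties`.
#' @examples
#' win_probabilities(list(C = c(0.5, 0.5), O = c(0.5, 0.5), CO = c(0.5, 0.5)))
#' # each racer wins with probability 0.625; the sum 1.875 exceeds 1 by the
#' # tie mass
#' @export
win_probabilities <- function(dists, ties = c("full", "split")) {
  ties <- match.arg(ties)
  P <- as_dist_matrix(dists)
  K <- nrow(P)
  if (K > 3) stop("win_probabilities supports two or three racers")
  labels <- rownames(P)
  if (is.null(labels)) labels <- paste0("racer", seq_len(K))
  S <- surv_matrix(P)
  S_next <- cbind(S[, -1, drop = FALSE], 0)
  if (ties == "full") {
    cvec <- vapply(seq_len(K), function(k) {
      sum(P[k, ] * apply(S[-k, , drop = FALSE], 2, prod))
    }, numeric(1))
  } else {
    cvec <- split_tie_contributions(P, S_next)
  }
  unique_win <- sum(vapply(seq_len(K), function(k) {
    sum(P[k, ] * apply(S_next[-k, , drop = FALSE], 2, prod))
  }, numeric(1)))
  joint <- max(0, 1 - unique_win)
  structure(list(contributions = stats::setNames(cvec, labels),
                 joint_win_prob = joint, ties = ties),
            class = "contributions")
}

## fractional credit: sum over winning subsets B (racers tied in the minimum
## bin, all others strictly later), each member of B getting 1/|B|
split_tie_contributions <- function(P, S_next) {
  K <- nrow(P)
  N <- ncol(P)
  cvec <- numeric(K)
  subsets <- lapply(seq_len(2^K - 1), function(m) which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0))
  for (B in subsets) {
    out <- setdiff(seq_len(K), B)
    for (i in seq_len(N)) {
      pr <- prod(P[B, i]) * (if (length(out)) prod(S_next[out, i]) else 1)
      cvec[B] <- cvec[B] + pr / length(B)
    }
  }
  cvec
}

#' @export
print.contributions <- function(x, ...) {
  cat("Race contributions (tie crediting:", x$ties, ")\n")
  print(round(x$contributions, 4))
  cat("joint-winner probability:", round(x$joint_win_prob, 4), "\n")
  invisible(x)
}
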