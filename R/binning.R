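#' Build the per-subject RT bin grid
#'
#' Discretizes a subject's pooled RTs (all six target conditions together)
#' into `n_bins` half-open bins `(t[i-1], t[i]]`. The first boundary is
#' `min(rts) - 0.0001` s and the boundary before last is `max(rts) + 0.0001`
#' s, so every observed RT falls in one of the first `n_bins - 1` bins and
#' those bins hold near-equal pooled counts. The final bin
#' `(max + 0.0001, Inf)` is a reservoir: it contains no observed RT and
#' absorbs the probability mass of hidden long conjunctive-racer RTs that
#' never win a race.
#'
#' Interior boundaries are placed midway between the `round(k * n / (N - 1))`-th
#' order statistic of the pooled sample and its successor, for
#' `k = 1, ..., N - 2`.
#'
#' @param rts Numeric vector of pooled RTs (seconds) from all conditions of
#'   one subject.
#' @param n_bins Number of bins `N >= 2` including the reservoir (default 10).
#' @return An object of class `bin_grid`: list with `boundaries`
#'   (length `N + 1`, last entry `Inf`) and `n_bins`.
#' @examples
#' g <- make_bin_grid(seq(0.4, 0.95, by = 0.05), n_bins = 4)
#' g$boundaries
#' @export
make_bin_grid <- function(rts, n_bins = 10) {
  if (length(rts) == 0) stop("rts must be non-empty")
  if (!all(is.finite(rts))) stop("rts must be finite")
  if (n_bins < 2) stop("n_bins must be at least 2")
  n_distinct <- length(unique(rts))
  if (n_distinct < 2) stop("all RTs identical: no strictly increasing boundaries exist")
  if (n_bins - 1 > n_distinct) {
    stop("n_bins (", n_bins, ") exceeds what ", n_distinct,
         " distinct RTs can support; choose a smaller n_bins")
  }
  s <- sort(rts)
  n <- length(s)
  t0 <- s[1] - 1e-4
  t_last_finite <- s[n] + 1e-4
  interior <- numeric(0)
  if (n_bins > 2) {
    ks <- seq_len(n_bins - 2)
    m <- round(ks * n / (n_bins - 1))
    m <- pmin(pmax(m, 1), n - 1)
    interior <- (s[m] + s[m + 1]) / 2
  }
  boundaries <- c(t0, interior, t_last_finite, Inf)
  if (any(diff(boundaries[-length(boundaries)]) <= 0)) {
    stop("tied RT values collapse bin boundaries; choose a smaller n_bins")
  }
  structure(list(boundaries = boundaries, n_bins = as.integer(n_bins)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("RT bin grid:", x$n_bins, "bins (last is the infinite reservoir)\n")
  cat("boundaries (s):",
      paste(formatC(x$boundaries, digits = 4, format = "f"), collapse = " "),
      "\n")
  invisible(x)
}

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  b <- grid$boundaries
  if (length(b) != grid$n_bins + 1) stop("boundary/bin count mismatch")
  if (!is.infinite(b[length(b)])) stop("last boundary must be Inf")
  if (any(diff(b[-length(b)]) <= 0)) stop("boundaries must be strictly increasing")
  invisible(grid)
}

#' Count RTs per bin
#'
#' Assigns each RT to its half-open bin `(t[i-1], t[i]]` on a [make_bin_grid()]
#' grid and returns the count vector.
#'
#' @param rts Numeric vector of RTs in seconds (may be empty).
#' @param grid A `bin_grid`.
#' @return Integer vector of length `grid$n_bins`; its sum equals
#'   `length(rts)`.
#' @export
bin_rts <- function(rts, grid) {
  validate_grid(grid)
  if (length(rts) == 0) return(integer(grid$n_bins))
  idx <- findInterval(rts, grid$boundaries, left.open = TRUE)
  if (any(idx == 0)) {
    stop("RT value ", min(rts), " lies at or below the grid's first boundary")
  }
  tabulate(idx, nbins = grid$n_bins)
}

#' Binned counts for every condition of one subject
#'
#' @param trials Trial data frame of a single subject (cleaned).
#' @param grid A `bin_grid` built from the subject's pooled RTs.
#' @return Integer matrix with one row per condition in
#'   `c("C","M","O","CO","MO","CM")` (zero rows for absent conditions) and
#'   `grid$n_bins` columns.
#' @export
bin_counts <- function(trials, grid) {
  validate_trials(trials)
  counts <- matrix(0L, nrow = length(CONDITIONS), ncol = grid$n_bins,
                   dimnames = list(CONDITIONS, NULL))
  for (cond in intersect(CONDITIONS, unique(trials$condition))) {
    counts[cond, ] <- bin_rts(trials$rt[trials$condition == cond], grid)
  }
  counts
}

#' Serialize a bin grid to JSON
#'
#' @param grid A `bin_grid`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written). The infinite reservoir
#'   boundary is encoded as the string `"Inf"`.
#' @export
bin_grid_json <- function(grid, path = NULL) {
  validate_grid(grid)
  b <- grid$boundaries
  payload <- list(n_bins = grid$n_bins,
                  boundaries = c(as.list(b[-length(b)]), list("Inf")))
  js <- jsonlite::toJSON(payload, digits = I(10), auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
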