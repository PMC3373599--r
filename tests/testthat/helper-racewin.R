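# shared fixtures and independent brute-force oracles

conds6 <- c("C", "M", "O", "CO", "MO", "CM")

# random probability vectors on a shared grid
rand_dists <- function(k, n) {
  lapply(seq_len(k), function(i) {
    p <- stats::rexp(n)
    p / sum(p)
  })
}

# enumeration oracle for the winner-bin distribution of independent racers
brute_race_min <- function(dists) {
  n <- length(dists[[1]])
  grids <- expand.grid(rep(list(seq_len(n)), length(dists)))
  q <- numeric(n)
  for (r in seq_len(nrow(grids))) {
    idx <- as.integer(grids[r, ])
    pr <- prod(vapply(seq_along(dists), function(k) dists[[k]][idx[k]],
                      numeric(1)))
    q[min(idx)] <- q[min(idx)] + pr
  }
  q
}

# enumeration oracle for win probabilities, full or split tie credit
brute_win_probs <- function(dists, ties = "full") {
  n <- length(dists[[1]])
  K <- length(dists)
  grids <- expand.grid(rep(list(seq_len(n)), K))
  cvec <- numeric(K)
  joint <- 0
  for (r in seq_len(nrow(grids))) {
    idx <- as.integer(grids[r, ])
    pr <- prod(vapply(seq_len(K), function(k) dists[[k]][idx[k]], numeric(1)))
    winners <- which(idx == min(idx))
    if (length(winners) > 1) joint <- joint + pr
    if (ties == "full") {
      cvec[winners] <- cvec[winners] + pr
    } else {
      cvec[winners] <- cvec[winners] + pr / length(winners)
    }
  }
  list(c = cvec, joint = joint)
}

# one synthetic subject holding only the C, O and CO conditions, with the CO
# RTs produced by a pure two-racer race (the conjunctive-null situation)
make_two_racer_subject <- function(n = 320, seed = 1,
                                   spec = racer_spec("truncated_normal",
                                                     0.6, 0.118)) {
  set.seed(seed)
  data.frame(
    subject = "null1",
    condition = rep(c("C", "O", "CO"), each = n),
    rt = c(sample_racer_rts(spec, n), sample_racer_rts(spec, n),
           pmin(sample_racer_rts(spec, n), sample_racer_rts(spec, n))),
    correct = TRUE, stringsAsFactors = FALSE)
}

# default-generator subject (CO/MO conjunctive racers present, no CM racer)
make_default_subject <- function(seed = 1, n_trials = 320) {
  cfg <- synthetic_config(n_subjects = 1, n_trials = n_trials)
  generate_dataset(cfg, seed = seed)$trials
}

fast_control <- function(seed = NULL) {
  race_control(n_restarts = 2, seed = seed)
}
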