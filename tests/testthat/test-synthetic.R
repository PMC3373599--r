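test_that("racer sampling is seeded, floored and moment-faithful", {
  spec <- racer_spec("truncated_normal", 0.6, 0.118)
  a <- sample_racer_rts(spec, 50, seed = 3)
  expect_identical(a, sample_racer_rts(spec, 50, seed = 3))
  expect_true(all(a >= 0.2))

  big <- sample_racer_rts(spec, 1e5, seed = 4)
  expect_lt(abs(mean(big) - 0.600), 3 * 0.118 / sqrt(1e5) + 1e-3)

  tight <- sample_racer_rts(racer_spec("truncated_normal", 0.7, 1e-6), 100,
                            seed = 5)
  expect_lt(max(abs(tight - 0.7)), 1e-4)

  expect_error(sample_racer_rts(racer_spec("truncated_normal", 0.01, 1e-4),
                                10, seed = 6), "unsatisfiable")
})

test_that("all racer families produce valid RT samples", {
  ex <- sample_racer_rts(racer_spec("exgaussian", 0.5, 0.08, tail = 0.1),
                         5000, seed = 7)
  expect_true(all(ex >= 0.2))
  expect_gt(mean(ex), 0.5)               # the exponential tail adds its mean

  emp <- sample_racer_rts(racer_spec("empirical_table",
                                     values = c(0.4, 0.6, 0.9),
                                     probs = c(0.2, 0.5, 0.3)),
                          1000, seed = 8)
  expect_true(all(emp %in% c(0.4, 0.6, 0.9)))

  lat <- sample_racer_rts(racer_spec("latent_normal", location = 1, scale = 0.2,
                                     map_scale = 0.6), 5000, seed = 9)
  expect_true(all(lat >= 0.2))
})

test_that("the generator reproduces the target single and double RT means", {
  d <- generate_dataset(synthetic_config(n_subjects = 2, n_trials = 1000,
                                         error_rate = 0, outlier_rate = 0),
                        seed = 10)
  tr <- d$trials
  singles <- with(tr, mean(rt[condition %in% c("C", "M", "O")]))
  doubles <- with(tr, mean(rt[condition %in% c("CO", "MO")]))
  expect_lt(abs(singles * 1000 - 600), 5)
  expect_lt(abs(doubles * 1000 - 500), 10)
  # CM has no conjunctive racer: a two-racer race is slower than the
  # three-racer CO/MO ones
  cm <- with(tr, mean(rt[condition == "CM"]))
  expect_gt(cm, doubles)
})

test_that("a conjunctive-free double condition is exactly a two-racer race", {
  cfg <- synthetic_config(n_subjects = 1, n_trials = 600,
                          error_rate = 0, outlier_rate = 0)
  d <- generate_dataset(cfg, seed = 11)
  cm <- d$trials$rt[d$trials$condition == "CM"]
  spec <- racer_spec("truncated_normal", 0.6, 0.118)
  set.seed(12)
  direct <- pmin(sample_racer_rts(spec, 600), sample_racer_rts(spec, 600))
  expect_gt(suppressWarnings(ks.test(cm, direct)$p.value), 0.001)
})

test_that("generated datasets are deterministic in (config, seed)", {
  cfg <- synthetic_config(n_subjects = 1, n_trials = 40)
  expect_identical(generate_dataset(cfg, seed = 13)$trials,
                   generate_dataset(cfg, seed = 13)$trials)
})

test_that("ground-truth contributions obey symmetry and absence", {
  cfg <- synthetic_config(n_subjects = 1)
  gt <- true_contributions(cfg, n_mc = 5e4, seed = 14)
  co <- gt$contributions[gt$contributions$condition == "CO", ]
  # three i.i.d. racers: each wins a third of the time
  expect_lt(max(abs(c(co$c_first, co$c_second, co$c_conj) - 1 / 3)), 0.02)
  expect_equal(co$c_first + co$c_second + co$c_conj, 1)
  cm <- gt$contributions[gt$contributions$condition == "CM", ]
  expect_equal(cm$c_conj, 0)
  expect_lt(max(abs(c(cm$c_first, cm$c_second) - 0.5)), 0.02)
})

test_that("the Monte-Carlo oracle matches a larger brute-force estimate", {
  # a three-racer race between normals (600, 118), (600, 118), (650, 118) ms
  cfg <- synthetic_config(racers = list(
    C = racer_spec("truncated_normal", 0.600, 0.118),
    M = racer_spec("truncated_normal", 0.600, 0.118),
    CM = racer_spec("truncated_normal", 0.650, 0.118),
    CO = NULL, MO = NULL))
  gt <- true_contributions(cfg, n_mc = 5e4, seed = 15)
  cm <- gt$contributions[gt$contributions$condition == "CM", ]
  # independent brute-force estimate at larger n (truncation at 0.2 s is
  # negligible for these parameters)
  set.seed(16)
  n <- 1e6
  mat <- cbind(rnorm(n, 0.600, 0.118), rnorm(n, 0.600, 0.118),
               rnorm(n, 0.650, 0.118))
  winner <- max.col(-mat, ties.method = "first")
  ref <- c(mean(winner == 1), mean(winner == 2), mean(winner == 3))
  se <- sqrt(ref * (1 - ref) / 5e4)
  got <- c(cm$c_first, cm$c_second, cm$c_conj)
  expect_true(all(abs(got - ref) < 3 * se + 3 * sqrt(ref * (1 - ref) / n)))
})

test_that("atomic racer families are refused by the continuous oracle", {
  cfg <- synthetic_config(racers = list(
    C = racer_spec("empirical_table", values = c(0.5, 0.7))))
  expect_error(true_contributions(cfg, n_mc = 1e4), "atoms")
})

test_that("synthetic trials flow through the whole cleaning interface", {
  d <- generate_dataset(synthetic_config(n_subjects = 1, n_trials = 200),
                        seed = 17)
  f <- tempfile(fileext = ".csv")
  write_trials(d$trials, f)
  cleaned <- clean_trials(read_trials(f))
  expect_true(all(cleaned$report$fraction_excluded <= 0.092))
  js <- jsonlite::fromJSON(cleaning_report_json(cleaned))
  expect_equal(nrow(js), 6)
})
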