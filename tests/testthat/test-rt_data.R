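test_that("trial files round-trip through the reader and writer", {
  trials <- data.frame(subject = c("s1", "s1", "s2"),
                       condition = c("C", "CO", "M"),
                       rt = c(0.612345, 0.48, 0.5551),
                       correct = c(TRUE, TRUE, FALSE),
                       stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_trials(trials, f)
  back <- read_trials(f)
  expect_equal(back$subject, trials$subject)
  expect_equal(back$condition, trials$condition)
  expect_equal(back$rt, trials$rt, tolerance = 1e-9)
  expect_equal(back$correct, trials$correct)

  ftsv <- tempfile(fileext = ".tsv")
  write_trials(trials, ftsv)
  expect_equal(read_trials(ftsv)$rt, trials$rt, tolerance = 1e-9)
})

test_that("millisecond input is converted to seconds", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject,condition,rt,correct", "s1,C,612,1", "s1,O,480,true"), f)
  tr <- read_trials(f, rt_unit = "ms")
  expect_equal(tr$rt, c(0.612, 0.480))
  expect_equal(tr$correct, c(TRUE, TRUE))
})

test_that("malformed input is rejected with located errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject,condition,rt,correct", "s1,C,0.5,1", "s1,CX,0.6,1"), f)
  expect_error(read_trials(f), "CX.*row 2")

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("subject,condition,rt,correct", "s1,C,fast,1"), f2)
  expect_error(read_trials(f2), "non-numeric rt.*row 1")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("subject,condition,correct", "s1,C,1"), f3)
  expect_error(read_trials(f3), "missing required column.*rt")
})

test_that("cleaning applies the RT floor and the one-pass 3 SD rule", {
  # below-floor trial dropped; floor is strict so rt == 0.2 survives
  tr <- data.frame(subject = "s1", condition = "C",
                   rt = c(0.1, 0.2, 0.5, 0.6), correct = TRUE)
  out <- clean_trials(tr)
  expect_equal(sort(out$trials$rt), c(0.2, 0.5, 0.6))
  expect_equal(out$report$n_outlier, 1)

  # 20 trials at 0.6 s plus one at 10 s: mean/SD computed once over all 21
  rts <- c(rep(0.6, 20), 10)
  m <- mean(rts); s <- sd(rts)            # independent evaluation of the rule
  expect_true(m + 3 * s < 10)             # 10 s lies beyond the threshold
  tr2 <- data.frame(subject = "s1", condition = "O", rt = rts, correct = TRUE)
  out2 <- clean_trials(tr2)
  expect_equal(nrow(out2$trials), 20)
  expect_false(any(out2$trials$rt > m + 3 * s))
  expect_equal(out2$report$fraction_excluded, 1 / 21)
})

test_that("incorrect trials are dropped but still anchor nothing", {
  tr <- data.frame(subject = "s1", condition = "C",
                   rt = c(0.5, 0.55, 0.6, 3.0),
                   correct = c(TRUE, TRUE, TRUE, FALSE))
  out <- clean_trials(tr)
  # the 3 s trial is excluded as incorrect, not as an outlier; thresholds use
  # correct trials only
  expect_equal(out$report$n_incorrect, 1)
  expect_equal(out$report$n_outlier, 0)
  expect_equal(nrow(out$trials), 3)
})

test_that("cleaning a clean dataset is a no-op with zero exclusions", {
  tr <- data.frame(subject = "s1", condition = rep(c("C", "O"), each = 5),
                   rt = runif(10, 0.4, 0.8), correct = TRUE)
  out <- clean_trials(tr)
  expect_equal(out$trials$rt, tr$rt)
  expect_true(all(out$report$fraction_excluded == 0))
})

test_that("exclusion thresholds are local to each (subject, condition) cell", {
  set.seed(42)
  base <- data.frame(subject = "s1", condition = "C",
                     rt = rnorm(50, 0.6, 0.05), correct = TRUE)
  wild <- data.frame(subject = "s1", condition = "O",
                     rt = c(rnorm(49, 0.6, 0.05), 5), correct = TRUE)
  alone <- clean_trials(base)
  together <- clean_trials(rbind(base, wild))
  kept_C <- together$trials$rt[together$trials$condition == "C"]
  expect_equal(sort(kept_C), sort(alone$trials$rt))
})

test_that("degenerate cells raise cleaning errors", {
  tr <- data.frame(subject = "s1", condition = "C",
                   rt = c(0.5, 0.6), correct = c(TRUE, FALSE))
  expect_error(clean_trials(tr), "fewer than 2 correct")
  tr2 <- data.frame(subject = "s1", condition = "M",
                    rt = c(0.15, 0.18), correct = TRUE)
  expect_error(clean_trials(tr2), "all trials excluded")
})

test_that("default synthetic data stays under the exclusion ceiling", {
  d <- generate_dataset(synthetic_config(n_subjects = 2), seed = 5)
  out <- clean_trials(d$trials)
  expect_true(all(out$report$fraction_excluded <= 0.092))
  # injected errors and outliers are actually present
  expect_true(sum(out$report$n_incorrect) > 0)
  expect_true(sum(out$report$n_outlier) > 0)
})
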