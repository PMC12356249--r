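test_that("neuropil correction follows the subtraction formula and is linear", {
  expect_equal(neuropil_correct(c(1, 1), c(0, 0)), c(1, 1))
  expect_equal(neuropil_correct(2.0, 1.0, r = 0.7), 1.3)
  x <- c(3, 4, 5)
  expect_equal(neuropil_correct(x, c(9, 9, 9), r = 0), x)
  expect_error(neuropil_correct(1:3, 1:2), "equal length")
  set.seed(1)
  roi <- runif(50); np <- runif(50)
  for (a in c(0.5, 2, 10)) {
    expect_equal(neuropil_correct(a * roi, a * np),
                 a * neuropil_correct(roi, np))
  }
})

test_that("shifted frames are flagged by strict >20 px displacement", {
  sh <- rbind(c(21L, 0L), c(20L, 20L), c(0L, 0L), c(0L, -25L), c(-21L, 3L))
  expect_equal(flag_shifted_frames(sh), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_false(any(flag_shifted_frames(matrix(0L, 10, 2))))
})

test_that("short shifted runs interpolate from nearest unshifted neighbours", {
  tr <- c(1, 99, 3)
  res <- interpolate_or_reject(tr, c(FALSE, TRUE, FALSE))
  expect_equal(res$values, c(1, 2, 3))
  expect_equal(res$interpolated, c(FALSE, TRUE, FALSE))

  # run of two uses the frames flanking the whole run
  tr2 <- c(1, 50, 60, 5)
  res2 <- interpolate_or_reject(tr2, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res2$values, c(1, 3, 3, 5))

  # boundary run uses the single available neighbour
  res3 <- interpolate_or_reject(c(9, 2, 2), c(TRUE, FALSE, FALSE))
  expect_equal(res3$values, c(2, 2, 2))
})

test_that("long shifted runs invalidate overlapping trials, not short ones", {
  n <- 400L
  fr <- 5.11
  mask <- logical(n)
  on <- 120L
  mask[(on + 3L):(on + 7L)] <- TRUE  # 5-frame run inside the trial window
  res <- interpolate_or_reject(rep(1, n), mask,
                               data.frame(onset_frame = on,
                                          trial_type = "stimulus"),
                               frame_rate_hz = fr)
  expect_false(res$trial_valid[1])
  expect_equal(res$trial_reason[1], "shifted_run")
  expect_true(all(res$masked[(on + 3L):(on + 7L)]))

  # a 2-frame run is interpolated, trial stays valid
  mask2 <- logical(n); mask2[(on + 3L):(on + 4L)] <- TRUE
  res2 <- interpolate_or_reject(rep(1, n), mask2,
                                data.frame(onset_frame = on,
                                           trial_type = "stimulus"),
                                frame_rate_hz = fr)
  expect_true(res2$trial_valid[1])

  # a run of exactly 3 is grouped with removal, not interpolation
  mask3 <- logical(n); mask3[(on + 3L):(on + 5L)] <- TRUE
  res3 <- interpolate_or_reject(rep(1, n), mask3,
                                data.frame(onset_frame = on,
                                           trial_type = "stimulus"),
                                frame_rate_hz = fr)
  expect_false(res3$trial_valid[1])
})

test_that("interpolation leaves clean traces untouched and is idempotent", {
  set.seed(2)
  tr <- runif(200)
  mask <- logical(200)
  mask[c(20, 50, 51, 130)] <- TRUE
  clean <- interpolate_or_reject(tr, logical(200))
  expect_equal(clean$values, tr)
  once <- interpolate_or_reject(tr, mask)
  twice <- interpolate_or_reject(once$values, mask)
  expect_equal(twice$values, once$values)
})

test_that("trial dF/F uses the 1-s pre-onset baseline only", {
  fr <- 5.11
  n <- 300L
  tr <- rep(2, n)
  tw <- dff_trial(tr, 100L, fr)
  expect_true(tw$valid)
  expect_true(all(tw$dff == 0))
  expect_equal(tw$baseline_f0, 2)

  # a frame at 1.5x baseline gives dff 0.5 at that frame
  tr2 <- rep(2, n); tr2[106] <- 3
  tw2 <- dff_trial(tr2, 100L, fr)
  expect_equal(max(tw2$dff), 0.5)

  # post-onset values do not touch F0
  tr3 <- tr; tr3[120:140] <- 50
  expect_equal(dff_trial(tr3, 100L, fr)$baseline_f0, tw$baseline_f0)

  # degenerate baselines and edge windows invalidate the trial
  expect_false(dff_trial(rep(-1, n), 100L, fr)$valid)
  expect_match(dff_trial(rep(-1, n), 100L, fr)$reason, "baseline")
  expect_false(dff_trial(tr, 5L, fr)$valid)
  expect_false(dff_trial(tr, n - 3L, fr)$valid)
})

test_that("sliding-percentile baseline matches a brute-force filter", {
  fr <- 5.11
  set.seed(3)
  x <- c(rep(10, 100), rep(20, 100)) + runif(200)
  got <- dff_spontaneous(x, fr, stride = 1L)
  half <- sec_to_frames(30, fr)
  f0 <- vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    unname(quantile(w, 0.2, type = 7))
  }, 0)
  expect_equal(got$f0, f0)
  expect_equal(got$dff, (x - f0) / f0)
  # constant positive trace has identically zero dff
  expect_true(all(dff_spontaneous(rep(5, 100), fr)$dff == 0))
  # percentile 0 on a monotone trace tracks the window minimum
  mono <- seq(1, 50, length.out = 120)
  g0 <- dff_spontaneous(mono, fr, percentile = 0, stride = 1L)
  mins <- vapply(seq_along(mono), function(i)
    min(mono[max(1, i - half):min(length(mono), i + half)]), 0)
  expect_equal(g0$f0, mins)
  # nonpositive baseline frames become NA, not fabricated signal
  neg <- rep(-3, 120)
  expect_true(all(is.na(dff_spontaneous(neg, fr, stride = 1L)$dff)))
})

test_that("strided percentile baseline stays close to the exact filter", {
  set.seed(4)
  x <- 50 + cumsum(rnorm(600, sd = 0.5)) + rlnorm(600, -2, 1)
  exact <- dff_spontaneous(x, 5.11, stride = 1L)
  fast <- dff_spontaneous(x, 5.11, stride = 10L)
  expect_lt(max(abs(exact$f0 - fast$f0)) / stats::median(exact$f0), 0.02)
})

test_that("session segmentation tiles trials and spontaneous blocks", {
  fr <- 5.11
  # trials every 20 s -> intertrial blocks of about 12 s
  onsets <- sec_to_frames(103, fr) + sec_to_frames(20, fr) * 0:4
  blocks <- segment_session(3000L,
                            data.frame(onset_frame = onsets,
                                       trial_type = rep("stimulus", 5)), fr)
  inter <- blocks[blocks$kind == "intertrial", ]
  expect_equal(nrow(inter), 4L)
  spans <- (inter$end_frame - inter$start_frame + 1) / fr
  expect_true(all(abs(spans - 12) < 0.5))
  # initial block is 100 s ending at the first trial window
  ini <- blocks[blocks$kind == "initial", ]
  expect_equal(ini$end_frame + 1L, onsets[1] - sec_to_frames(3, fr))
  expect_equal(ini$end_frame - ini$start_frame + 1L, sec_to_frames(100, fr))

  # onsets closer than 8 s leave no intertrial block
  b2 <- segment_session(1000L,
                        data.frame(onset_frame = c(600L, 630L),
                                   trial_type = c("stimulus", "blank")), fr)
  expect_equal(sum(b2$kind == "intertrial"), 0L)

  # no trials: the whole trace is one initial block
  b3 <- segment_session(500L, data.frame(), fr)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$kind, "initial")
  expect_equal(c(b3$start_frame, b3$end_frame), c(0L, 499L))

  # every frame belongs to at most one trial window
  win <- unlist(lapply(onsets, function(o)
    (o - sec_to_frames(3, fr)):(o + sec_to_frames(5, fr))))
  expect_false(anyDuplicated(win) > 0)
  for (i in seq_len(nrow(blocks)))
    expect_length(intersect(blocks$start_frame[i]:blocks$end_frame[i], win), 0L)
})

test_that("invalid-trial fraction grows with injected shift artifacts", {
  frac_invalid <- function(runs) {
    cls <- default_classes()[2]
    cls[[1]]$n <- 4L
    cfg <- generator_config(classes = cls, days = "ACC4", n_trials = 15L,
                            shift_runs_per_session = runs, seed = 42L)
    exp1 <- generate_experiment(cfg)
    pp <- preprocess_session(exp1$sessions[[1]])
    mean(!pp$qc$valid)
  }
  fr <- vapply(c(0, 3, 12), frac_invalid, 0)
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[1], 0)
  expect_gt(fr[3], 0)
})
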