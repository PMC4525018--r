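test_that("peak extraction averages the peak frame and its neighbours", {
  # epoch frames [0, 0, 10, 10, 10, 0] starting at t = 0, 2 Hz
  tr <- c(0, 0, 10, 10, 10, 0)
  expect_equal(extract_peak_response(tr, 0, 3, 2), 10)
  tr2 <- c(0, 5, 10, 10, 9, 0)
  expect_equal(extract_peak_response(tr2, 0, 3, 2), (10 + 10 + 9) / 3)
  # flat trace with baseline equal to the epoch value gives zero
  flat <- rep(7, 20)
  expect_equal(extract_peak_response(flat, 5, 9, 2), 0)
})

test_that("boundary peaks match the in-epoch 3-frame oracle", {
  # oracle: best value is the mean of 3 consecutive in-epoch frames
  # containing the epoch argmax
  set.seed(42)
  fr <- 2
  for (rep in 1:50) {
    trace <- stats::rnorm(30)
    on <- 4; off <- 11  # frames 9..22 -> epoch frames
    got <- extract_peak_response(trace, on, off, fr, prestim_window_s = 0)
    ep <- trace[(on * fr + 1):(off * fr)]
    pk <- which.max(ep)
    windows <- vapply(max(1, pk - 2):min(pk, length(ep) - 2), function(lo) {
      mean(ep[lo:(lo + 2)])
    }, numeric(1))
    expect_true(got %in% windows)
    # and the chosen window is peak +- 1 clamped inside the epoch
    lo <- min(max(pk - 1, 1), length(ep) - 2)
    expect_equal(got, mean(ep[lo:(lo + 2)]))
  }
})

test_that("extraction is invariant to adding a constant to the trace", {
  set.seed(7)
  trace <- stats::rnorm(40)
  v1 <- extract_peak_response(trace, 5, 10, 2)
  v2 <- extract_peak_response(trace + 123.4, 5, 10, 2)
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("epochs shorter than three frames are rejected", {
  expect_error(extract_peak_response(rep(0, 20), 5, 5.5, 2), "3 frames")
})

test_that("the 2-SD responsiveness rule counts trials strictly", {
  # 3/5 trials above threshold on some stimulus -> responsive
  expect_true(screen_responsive(list(a = c(3, 3, 3, 0, 0)), baseline_sd = 1))
  # 2/5 is not more than half
  expect_false(screen_responsive(list(a = c(3, 3, 0, 0, 0)), baseline_sd = 1))
  expect_false(screen_responsive(list(a = rep(0, 5)), baseline_sd = 1))
  expect_error(screen_responsive(list(a = 1:5), baseline_sd = 0), "positive")
})

test_that("the ANOVA selectivity screen detects shifted stimuli", {
  set.seed(3)
  v <- stats::rnorm(40)
  s <- rep(paste0("s", 1:8), each = 5)
  v[s == "s3"] <- v[s == "s3"] + 10  # 10-SD shift
  expect_true(screen_selective(v, s)$selective)
  # identical constant responses everywhere: no variance between groups
  res <- screen_selective(rep(5, 40), s)
  expect_false(res$selective)
  expect_equal(res$p, 1)
})

test_that("reliability hits its closed-form extremes", {
  tab <- data.frame(cell_id = "c", stim_id = rep(paste0("s", 1:8), 3),
                    trial_idx = rep(1:3, each = 8),
                    response_dff_pct = rep(c(1, 5, 2, 8, 1, 0, 3, 4), 3))
  expect_equal(as.numeric(reliability(tab)), 1)
  v <- c(-2, 3, -1, 0, 1, 2, -3, 0)  # zero-mean vector
  tab2 <- data.frame(cell_id = "c", stim_id = rep(paste0("s", 1:8), 2),
                     trial_idx = rep(1:2, each = 8),
                     response_dff_pct = c(v, -v))
  expect_equal(as.numeric(reliability(tab2)), -1)
})

test_that("reliability of independent noise is near zero", {
  set.seed(5)
  m <- replicate(1000, {
    tab <- data.frame(cell_id = "c", stim_id = rep(paste0("s", 1:8), 2),
                      trial_idx = rep(1:2, each = 8),
                      response_dff_pct = stats::rnorm(16))
    as.numeric(reliability(tab))
  })
  expect_lt(abs(mean(m)), 0.1)
})

test_that("reliability is invariant to positive affine transforms", {
  set.seed(8)
  tab <- data.frame(cell_id = "c", stim_id = rep(paste0("s", 1:8), 4),
                    trial_idx = rep(1:4, each = 8),
                    response_dff_pct = stats::rnorm(32, 5, 3))
  r1 <- as.numeric(reliability(tab))
  tab$response_dff_pct <- 2.5 * tab$response_dff_pct + 11
  expect_equal(as.numeric(reliability(tab)), r1, tolerance = 1e-12)
})
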