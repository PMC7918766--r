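# Recording data model, CSV I/O, resampling and smoothing.

test_that("constructors enforce the channel and rating invariants", {
  expect_error(channel_signal("EDA", c(1, NA), 8), "finite")
  expect_error(channel_signal("EDA", 1:4, -1), "positive")
  expect_error(pain_reports(c(1, 1), c(2, 3)), "increasing")
  expect_error(pain_reports(5, 11), "0-10")
  expect_error(pain_reports(5, 2.5), "0-10")
  sub <- simulate_subject(sim_config(n_subjects = 1, seed = 3), 1)
  rec <- sub$recording
  expect_s3_class(rec, "multimodal_recording")
  expect_setequal(names(rec$channels), c("EDA", "EMG", "RSP", "BVP", "GRIP"))
  expect_error(
    multimodal_recording("x", rec$channels[c("EDA", "EMG")], rec$reports),
    "missing channel"
  )
  expect_error(
    multimodal_recording("x", rec$channels, rec$reports, baseline_end = 1e5),
    "session span"
  )
})

test_that("a recording round-trips through the CSV directory layout", {
  dir <- withr::local_tempdir()
  rec <- default_subject()$raw
  write_recording(rec, dir)
  back <- load_recording(dir)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$baseline_end, rec$baseline_end)
  for (nm in names(rec$channels)) {
    expect_equal(back$channels[[nm]]$samples, rec$channels[[nm]]$samples,
                 tolerance = 1e-6)
    expect_equal(back$channels[[nm]]$fs, rec$channels[[nm]]$fs,
                 tolerance = 1e-6)
  }
  expect_equal(back$reports$ratings, rec$reports$ratings)
})

test_that("the loader rejects malformed directories", {
  dir <- withr::local_tempdir()
  write_recording(default_subject()$raw, dir)

  # out-of-range rating
  bad <- read.csv(file.path(dir, "reports.csv"))
  bad$rating[1] <- 11
  write.csv(bad, file.path(dir, "reports.csv"), row.names = FALSE)
  expect_error(load_recording(dir), "0-10")
  bad$rating[1] <- 0
  write.csv(bad, file.path(dir, "reports.csv"), row.names = FALSE)

  # non-uniform timestamps
  ch <- read.csv(file.path(dir, "rsp.csv"))
  ch$time_s[10] <- ch$time_s[10] + 0.4 / 8
  write.csv(ch, file.path(dir, "rsp.csv"), row.names = FALSE)
  expect_error(load_recording(dir), "non-uniform")

  # missing channel file
  file.remove(file.path(dir, "rsp.csv"))
  expect_error(load_recording(dir), "RSP")
})

test_that("resampling preserves DC exactly and spectral peaks", {
  r <- resample_channel(channel_signal("EDA", rep(1, 40), 4), 8)
  expect_equal(r$fs, 8)
  expect_length(r$samples, 80)
  expect_lt(max(abs(r$samples - 1)), 1e-6)

  # 2 Hz sinusoid survives 64 -> 8 Hz decimation with its DFT peak intact
  t <- seq(0, 4 - 1 / 64, by = 1 / 64)
  x <- sin(2 * pi * 2 * t)
  before <- Mod(fft(x))[2:32]
  r2 <- resample_channel(channel_signal("EMG", x, 64), 8)
  after <- Mod(fft(r2$samples))[2:16]
  expect_equal(which.max(after), which.max(before))
  expect_length(r2$samples, 32)

  # identity target rate
  r3 <- resample_channel(channel_signal("EMG", x, 64), 64)
  expect_equal(r3$samples, x)
})

test_that("round-trip resampling reproduces a bandlimited signal", {
  t <- seq(0, 10 - 1 / 32, by = 1 / 32)
  x <- sin(2 * pi * 0.7 * t) + 0.5 * cos(2 * pi * 2.3 * t)
  rt <- resample_channel(resample_channel(channel_signal("RSP", x, 32), 64), 32)
  expect_lt(sqrt(sum((rt$samples - x)^2) / sum(x^2)), 1e-3)
  expect_error(resample_channel(channel_signal("RSP", x, 32), 0), "positive")
})

test_that("gaussian smoothing is normalized, variance-reducing and linear", {
  const <- gaussian_smooth(channel_signal("EDA", rep(3.5, 50), 8), 8)
  expect_equal(const$samples, rep(3.5, 50), tolerance = 1e-9)

  imp <- gaussian_smooth(channel_signal("EDA", c(rep(0, 25), 1, rep(0, 25)), 8), 9)
  expect_equal(sum(imp$samples), 1, tolerance = 1e-9)
  expect_equal(which.max(imp$samples), 26)
  # symmetric, unimodal response
  expect_true(all(diff(imp$samples[20:26]) > -1e-12))

  noise <- withr::with_seed(1, rnorm(400))
  sm <- gaussian_smooth(channel_signal("EDA", noise, 8), 8)
  expect_lt(var(sm$samples), var(noise))

  x <- withr::with_seed(2, rnorm(100))
  y <- withr::with_seed(3, rnorm(100))
  lhs <- gaussian_smooth(channel_signal("EDA", 2 * x - 3 * y, 8), 8)$samples
  rhs <- 2 * gaussian_smooth(channel_signal("EDA", x, 8), 8)$samples -
    3 * gaussian_smooth(channel_signal("EDA", y, 8), 8)$samples
  expect_equal(lhs, rhs, tolerance = 1e-9)

  expect_error(gaussian_smooth(channel_signal("EDA", 1:5, 8), 10), "longer")
})
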