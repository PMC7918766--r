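# Framewise features and the feature-matrix contracts.

test_that("frame counts follow floor((D - window)/hop) + 1", {
  expect_equal(n_frames(180), 89)
  expect_equal(n_frames(4), 1)
  expect_equal(n_frames(5.9), 1)
  expect_equal(n_frames(6), 2)
  expect_error(n_frames(3.5), "shorter")
})

test_that("frame energy sums squared coefficients per path", {
  cfg <- scattering_config(32, q = c(8, 1))
  x <- withr::with_seed(8, rnorm(32 * 10))
  sc <- align_frames(scattering_transform(x, cfg), 4)
  en <- frame_energy(sc)
  expect_equal(colnames(en), c("S1", "U1", "S2", "U2"))
  expect_equal(unname(en[2, "S1"]), sum(sc$S[[1]][, 2]^2))

  # three-layer output yields 6 columns
  cfg3 <- scattering_config(64, q = c(8, 4, 1))
  sc3 <- align_frames(scattering_transform(rnorm(64 * 6), cfg3), 2)
  expect_equal(ncol(frame_energy(sc3)), 6)

  # zero coefficients give zero energy; scaling is quadratic
  sc0 <- align_frames(scattering_transform(rep(0, 32 * 10), cfg), 4)
  expect_true(all(frame_energy(sc0) == 0))
  sc2 <- align_frames(scattering_transform(2 * x, cfg), 4)
  expect_equal(frame_energy(sc2), 4 * en, tolerance = 1e-10)
})

test_that("spectral entropy matches closed forms on degenerate spectra", {
  fs <- 8
  # impulse mid-frame: flat power spectrum -> log2(number of bins)
  x <- numeric(32); x[16] <- 1
  h <- spectral_entropy(x, fs, window = "rect")
  expect_equal(h, log2(17), tolerance = 1e-9)   # 17 one-sided bins for L=32
  # constant frame: single nonzero (DC) bin -> 0
  expect_equal(spectral_entropy(rep(2, 32), fs, window = "rect"), 0)
  # all-zero frame -> 0 by convention
  expect_equal(spectral_entropy(rep(0, 32), fs), 0)
  # two equiprobable bins -> 1 bit (cosine with symmetric +/- lines removed
  # by the one-sided fold leaves one line; construct directly instead)
  expect_equal(painreact:::power_entropy_bits(c(0.5, 0.5, 0, 0)), 1)
  expect_equal(painreact:::power_entropy_bits(rep(1, 8)), 3)
})

test_that("time-domain statistics match hand arithmetic", {
  st <- time_domain_stats(c(1, 2, 3, 4), fs = 1)
  expect_equal(unname(st[1, ]), c(4, 2.5, sd(1:4), 3))
  expect_equal(unname(st[1, "sd"]), 1.2909944, tolerance = 1e-6)

  const <- time_domain_stats(rep(7, 8), fs = 2)
  expect_equal(unname(const[1, ]), c(7, 7, 0, 0))

  flip <- time_domain_stats(-c(1, 2, 3, 4), fs = 1)
  expect_equal(flip[1, "amplitude"], c(amplitude = 3))
  expect_equal(flip[1, "max"], c(max = -1))
})

test_that("derivative statistics match hand arithmetic", {
  expect_equal(unname(derivative_stats(rep(2, 4), fs = 1)[1, ]), c(0, 0, 0))
  ramp <- derivative_stats(0.5 * (0:7), fs = 2)   # slope 1 unit/s
  expect_equal(unname(ramp[1, ]), c(1, 1, 0), tolerance = 1e-12)
  d <- derivative_stats(c(0, 1, 0, 1), fs = 1)
  expect_equal(unname(d[1, ]), c(1, 1 / 3, sd(c(1, -1, 1))), tolerance = 1e-6)
  expect_equal(unname(d[1, "sd"]), 1.1547005, tolerance = 1e-6)
})

test_that("STFT frame energy obeys Parseval and quadratic scaling", {
  x <- withr::with_seed(9, rnorm(64))
  e <- stft_frame_energy(x, fs = 16)
  w <- painreact:::hann_window(64)
  expect_equal(e[1], sum((x * w)^2), tolerance = 0.01 * e[1])
  expect_equal(stft_frame_energy(2 * x, 16), 4 * e, tolerance = 1e-9)
  expect_equal(stft_frame_energy(rep(0, 64), 16), 0)
})

test_that("the feature matrix honors the 33/17 column contracts", {
  pre <- default_subject()$pre
  fm <- extract_features(pre)
  expect_equal(ncol(fm$values), 33)
  expect_false(anyDuplicated(fm$feature_names) > 0)
  expect_true(all(is.finite(fm$values)))

  fm_stft <- extract_features(pre, mode = "stft")
  expect_equal(ncol(fm_stft$values), 17)
  expect_equal(nrow(fm_stft$values), nrow(fm$values))

  # 6 scattering-energy columns for the three-layer modalities, 4 for the
  # two-layer ones
  expect_length(grep("^EMG_.*_energy$", fm$feature_names), 6)
  expect_length(grep("^BVP_.*_energy$", fm$feature_names), 6)
  expect_length(grep("^EDA_.*_energy$", fm$feature_names), 4)
  expect_length(grep("^RSP_.*_energy$", fm$feature_names), 4)
  expect_length(grep("GRIP", fm$feature_names), 0)

  # shared frame grid across modalities
  expect_equal(nrow(fm$values),
               n_frames(recording_duration(pre)))
})

test_that("extraction is deterministic", {
  pre <- default_subject()$pre
  a <- extract_features(pre, mode = "stft")
  b <- extract_features(pre, mode = "stft")
  expect_identical(a$values, b$values)
})

test_that("z-scoring normalizes per subject and handles degeneracy", {
  pre <- default_subject()$pre
  fm <- extract_features(pre, mode = "stft")
  z <- zscore_by_subject(fm)
  expect_equal(unname(colMeans(z$values)), rep(0, 17), tolerance = 1e-9)
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, 17), tolerance = 1e-9)

  # zero-variance column becomes zeros
  fm2 <- fm
  fm2$values[, 3] <- 5
  z2 <- zscore_by_subject(fm2)
  expect_true(all(z2$values[, 3] == 0))

  # a constant offset between two copies vanishes after normalization
  fm3 <- fm
  fm3$values <- fm$values + 100
  expect_equal(zscore_by_subject(fm3)$values, z$values, tolerance = 1e-9)

  # single-frame subject is rejected
  fm4 <- fm
  fm4$values <- fm$values[1, , drop = FALSE]
  expect_error(zscore_by_subject(fm4), "fewer than 2")
})
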