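# Morlet filter banks and the deep scattering transform.

test_that("filter banks have the configured voices per octave", {
  fb <- build_filterbank(scattering_config(256, q = c(8, 4, 1)))
  expect_length(fb$layers, 3)
  xi1 <- fb$layers[[1]]$xi
  expect_equal(unique(round(xi1[-length(xi1)] / xi1[-1], 10)), 2^(1 / 8))
  # eight filters per octave in layer 1
  octave <- xi1[xi1 <= xi1[1] & xi1 > xi1[1] / 2]
  expect_length(octave, 8)
  fb2 <- build_filterbank(scattering_config(8, q = c(8, 1)))
  expect_length(fb2$layers, 2)
})

test_that("each layer satisfies the Littlewood-Paley bound", {
  fb <- build_filterbank(scattering_config(256, q = c(8, 4, 1)))
  for (l in 1:3) {
    grid <- sort(c(seq(0, 128, length.out = 20001), fb$layers[[l]]$xi))
    lp <- lp_sum(fb, l, grid)
    expect_lte(max(lp), 1 + 1e-6)
    expect_gt(min(lp), 0)
    expect_gt(max(lp), 0.99)   # the bound is attained
  }
})

test_that("zero input produces exactly zero coefficients", {
  cfg <- scattering_config(64, q = c(8, 1))
  sc <- scattering_transform(rep(0, 64 * 6), cfg)
  expect_true(all(vapply(sc$S, function(m) all(m == 0), logical(1))))
  expect_true(all(vapply(sc$U, function(m) all(m == 0), logical(1))))
  expect_equal(sc$n_frames, 2)
})

test_that("a pure tone excites the nearest first-layer path", {
  cfg <- scattering_config(256, q = c(8, 4, 1))
  fb <- build_filterbank(cfg)
  x <- sin(2 * pi * 10 * seq(0, 8 - 1 / 256, by = 1 / 256))
  sc <- scattering_transform(x, cfg, filterbank = fb)
  best <- which.max(rowMeans(sc$U[[1]]))
  expect_equal(best, which.min(abs(fb$layers[[1]]$xi - 10)))
  expect_true(all(vapply(sc$S, min, numeric(1)) >= 0))
  expect_true(all(vapply(sc$U, min, numeric(1)) >= 0))
})

test_that("the representation is stable to sub-window time shifts", {
  fs <- 256
  cfg <- scattering_config(fs, q = c(8, 4, 1))
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 7 * t) * exp(-((t - 6) / 2)^2)
  shift <- round(0.05 * fs)
  xs <- c(rep(0, shift), x)[seq_along(x)]
  s1 <- scattering_transform(x, cfg)
  s2 <- scattering_transform(xs, cfg)
  num <- sqrt(sum(unlist(Map(function(a, b) (a - b)^2, s1$S, s2$S))))
  den <- sqrt(sum(unlist(lapply(s1$S, function(m) m^2))))
  expect_lt(num / den, 0.05)
})

test_that("the transform is nonexpansive and its layer energy decays", {
  cfg <- scattering_config(128, q = c(8, 1))
  fb <- build_filterbank(cfg)
  for (seed in 1:4) {
    pair <- withr::with_seed(seed, list(x = rnorm(768), y = rnorm(768)))
    sx <- scattering_transform(pair$x, cfg, filterbank = fb)
    sy <- scattering_transform(pair$y, cfg, filterbank = fb)
    ds <- sqrt(sum(unlist(Map(function(a, b) (a - b)^2, sx$S, sy$S))))
    expect_lte(ds, sqrt(sum((pair$x - pair$y)^2)))
    eU <- vapply(sx$U, function(m) sum(m^2), numeric(1))
    expect_lte(eU[2], eU[1])
  }
})

test_that("coefficients scale exactly with the input amplitude", {
  cfg <- scattering_config(64, q = c(8, 4, 1))
  x <- withr::with_seed(5, rnorm(64 * 6))
  s1 <- scattering_transform(x, cfg)
  s2 <- scattering_transform(-2 * x, cfg)
  for (l in 1:3) {
    expect_equal(s2$S[[l]], 2 * s1$S[[l]], tolerance = 1e-10)
    expect_equal(s2$U[[l]], 2 * s1$U[[l]], tolerance = 1e-10)
  }
})

test_that("frequency-decreasing path truncation holds", {
  cfg <- scattering_config(64, q = c(8, 4, 1))
  sc <- scattering_transform(withr::with_seed(6, rnorm(64 * 5)), cfg)
  chains <- strsplit(sc$path_metadata$xi_chain, ">")
  for (ch in chains) {
    xi <- as.numeric(ch)
    if (length(xi) > 1) expect_true(all(diff(xi) < 0))
  }
})

test_that("frame alignment interpolates with the FFT", {
  cfg <- scattering_config(32, q = c(8, 1))
  x <- withr::with_seed(7, rnorm(32 * 8))
  sc <- scattering_transform(x, cfg)

  same <- align_frames(sc, ncol(sc$U[[1]]))
  expect_equal(same$U[[1]], sc$U[[1]], tolerance = 1e-9)

  al <- align_frames(sc, sc$n_frames)
  expect_true(all(vapply(al$U, ncol, integer(1)) == sc$n_frames))
  expect_true(all(vapply(al$S, ncol, integer(1)) == sc$n_frames))

  # DC preservation and harmonic preservation on constructed rows
  const_row <- matrix(3.2, 1, 64)
  sc$U[[1]] <- const_row
  expect_equal(align_frames(sc, 48)$U[[1]][1, ], rep(3.2, 48),
               tolerance = 1e-9)
  one_cycle <- matrix(2 + sin(2 * pi * (0:63) / 64), 1, 64)
  out <- align_frames(`[[<-`(sc, "U", list(one_cycle)), 48)$U[[1]][1, ]
  expect_equal(which.max(Mod(fft(out))[2:24]), 1)
  # mean-square energy preserved for a smooth band-limited row
  expect_equal(mean(out^2), mean(one_cycle^2), tolerance = 0.01)
})

test_that("signals shorter than the invariance window are rejected", {
  cfg <- scattering_config(8, q = c(8, 1))
  expect_error(scattering_transform(rnorm(16), cfg), "shorter")
})
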