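test_that("bandpass design places -3 dB exactly at the band edges", {
  fl <- design_filter_chain(filter_spec(), fs = 300)
  edges <- filter_response(fl, c(1, 20), "bandpass")
  expect_equal(edges, rep(1 / sqrt(2), 2), tolerance = 1e-6)
  # near-unity gain at the geometric band centre
  expect_equal(filter_response(fl, sqrt(20), "bandpass"), 1,
               tolerance = 0.01)
})

test_that("zero-phase notch suppresses 60 Hz below 1e-3 in magnitude", {
  fl <- design_filter_chain(filter_spec(), fs = 300)
  expect_lt(filter_response(fl, 60, "notch_zero_phase"), 1e-3)
  # quality factor 30: -3 dB single-pass points ~1 Hz either side of 60
  bw <- 60 / 30
  side <- filter_response(fl, c(60 - bw / 2, 60 + bw / 2), "notch")
  expect_equal(side, rep(1 / sqrt(2), 2), tolerance = 5e-3)
  # and the passband is untouched away from the notch
  expect_equal(filter_response(fl, c(10, 45), "notch"), c(1, 1),
               tolerance = 5e-3)
})

test_that("design rejects bands incompatible with the sampling rate", {
  expect_error(design_filter_chain(filter_spec(band_high = 80), fs = 300),
               "Nyquist")
  expect_error(filter_spec(band_low = 0), "band_low")
  expect_error(filter_spec(band_low = 20, band_high = 10), "band_low")
})

test_that("filter chain attenuates 60 Hz and passes 10 Hz at designed gain", {
  fs <- 300
  fl <- design_filter_chain(filter_spec(), fs)
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x60 <- matrix(sin(2 * pi * 60 * t), 1)
  y60 <- apply_filter_chain(x60, fl)
  expect_lt(sqrt(mean(y60^2)) / sqrt(mean(x60^2)), 1e-3)

  x10 <- matrix(sin(2 * pi * 10 * t), 1)
  y10 <- apply_filter_chain(x10, fl)
  steady <- y10[1, (ncol(y10) / 2):ncol(y10)]
  amp <- sqrt(2 * mean(steady^2))
  expect_equal(amp, filter_response(fl, 10, "chain"), tolerance = 0.02)
})

test_that("zero and too-short segments are handled per contract", {
  fl <- design_filter_chain(filter_spec(), fs = 300)
  z <- matrix(0, 2, 600)
  out <- apply_filter_chain(z, fl)
  expect_equal(dim(out), c(2, 300))
  expect_true(all(out == 0))
  expect_error(apply_filter_chain(matrix(0, 1, 20), fl), "need more than")
})

test_that("zero-phase notch introduces no net delay at 10 Hz", {
  fs <- 300
  fl <- design_filter_chain(filter_spec(), fs)
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- bciparity:::.zero_phase(fl$notch$b, fl$notch$a, x)
  # every interior upward zero crossing of the output sits within one
  # sample of an input crossing (no net delay); crossing times are
  # linearly interpolated to sub-sample precision
  zc <- function(v) {
    i <- which(v[-length(v)] < 0 & v[-1] >= 0)
    i <- i[i >= 300 & i <= 2700]
    i + v[i] / (v[i] - v[i + 1])
  }
  zx <- zc(x); zy <- zc(y)
  shift <- vapply(zy, function(ti) min(abs(zx - ti)), 1)
  expect_lt(max(shift), 1)
})

test_that("downsampling after the bandpass leaves <1% energy above 75 Hz", {
  fs <- 300
  spec <- filter_spec(downsample_factor = 1)  # inspect pre-decimation signal
  fl <- design_filter_chain(spec, fs)
  set.seed(8)
  x <- matrix(rnorm(fs * 20), 1)
  y <- apply_filter_chain(x, fl)[1, ]
  spec_y <- Mod(stats::fft(y))^2
  freqs <- (seq_along(y) - 1) * fs / length(y)
  half <- freqs <= fs / 2
  frac <- sum(spec_y[half & freqs > 75]) / sum(spec_y[half])
  expect_lt(frac, 0.01)
})

test_that("all four standard bands design and epoch at 300 Hz", {
  raw <- cached_session(n_inquiries = 4)
  for (b in list(c(1, 10), c(0.2, 20), c(1, 20), c(0.1, 50))) {
    spec <- filter_spec(band_low = b[1], band_high = b[2])
    expect_silent(design_filter_chain(spec, 300))
    ds <- conventional_pipeline(raw, spec)
    expect_equal(dim(ds$trials)[1], n_stimuli(raw$schedule))
  }
})
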