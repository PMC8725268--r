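fs <- 100

test_that("beat detection recovers sinusoid amplitude and rate", {
  tt <- seq(0, 60, by = 1 / fs)
  b <- detect_beats(2 * sin(2 * pi * 1.74 * tt) + 10, fs)
  expect_equal(mean(b$amplitude), 4, tolerance = 0.02)
  expect_equal(attr(b, "rate"), 1.74, tolerance = 0.03)
  # beat count x mean interval covers the segment within 2%
  span <- nrow(b) * mean(diff(b$time))
  expect_equal(span, 60, tolerance = 0.02)
  expect_true(all(b$amplitude >= 0))
  expect_false(is.unsorted(b$time, strictly = TRUE))
})

test_that("beat detection fails cleanly without beats", {
  expect_error(detect_beats(rep(7, 30 * fs), fs), "no beats")
  expect_error(detect_beats(rnorm(50), fs), "10 s")
})

test_that("simulated pulse amplitudes match the generating configuration", {
  # quiet sheep-F-like baseline: large intrathecal pulse
  comp <- quick_comp(Pr = 27)
  wave <- waveform_params(amp0 = c(ICP = 6.9, ITP = 5.7, ABP = 26.5,
                                   CVP = 4.7),
                          amp_threshold = 30, noise_sd = 0.1)
  sim <- simulate_animal(comp, wave, coupling_params(), infusion_protocol(),
                         duration = 300, seed = 3)
  b <- detect_beats(sim$recording$samples$ITP, fs, f_cardiac_hint = 1.74)
  expect_equal(amplitude_stat(b, c(10, 290)), 5.7, tolerance = 0.1)
})

test_that("amplitude_stat is a windowed arithmetic mean", {
  b <- structure(data.frame(time = 1:10, systolic = 5, diastolic = 1.8,
                            amplitude = 3.2),
                 class = c("beat_series", "data.frame"))
  expect_equal(amplitude_stat(b, c(0, 11)), 3.2)
  b$amplitude <- c(1, 2, 3, rep(10, 7))
  expect_equal(amplitude_stat(b, c(0.5, 3.5)), 2)
  expect_error(amplitude_stat(b, c(100, 110)), "fewer than 3")
})

test_that("amplitudes are invariant to a constant pressure offset", {
  tt <- seq(0, 60, by = 1 / fs)
  x <- 2 * sin(2 * pi * 1.74 * tt) + 0.3 * sin(2 * pi * 0.3 * tt)
  a0 <- mean(detect_beats(x, fs)$amplitude)
  a1 <- mean(detect_beats(x + 100, fs)$amplitude)
  expect_equal(a0, a1, tolerance = 1e-10)
})

test_that("spectrum identifies cardiac and respiratory fundamentals", {
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  x <- 10 +
    1.0 * sin(2 * pi * 0.30 * tt) + 0.5 * sin(2 * pi * 0.60 * tt) +
    0.33 * sin(2 * pi * 0.90 * tt) +       # respiratory + harmonics
    1.6 * sin(2 * pi * 1.74 * tt) + 0.8 * sin(2 * pi * 3.48 * tt)
  sp <- pressure_spectrum(x, fs)
  expect_equal(unname(sp$fundamentals["respiratory"]), 0.30,
               tolerance = sp$df)
  expect_equal(unname(sp$fundamentals["cardiac"]), 1.74, tolerance = sp$df)
  # harmonics of the respiratory fundamental must not be picked
  expect_false(isTRUE(all.equal(unname(sp$fundamentals["cardiac"]), 0.60,
                                tolerance = sp$df)))
  # scale invariance
  sp2 <- pressure_spectrum(100 * x, fs)
  expect_equal(sp2$fundamentals, sp$fundamentals)
})

test_that("spectrum rejects featureless input", {
  set.seed(9)
  expect_error(pressure_spectrum(rnorm(300 * fs), fs), "no dominant peaks")
  expect_error(pressure_spectrum(rnorm(30 * fs), fs), "60 s")
})

test_that("cross-correlation recovers constructed lags to sub-sample accuracy", {
  sim <- sim_baseline(duration = 240, seed = 4)
  x <- sim$recording$samples$ITP
  for (lag_s in c(0.31, 0.34)) {
    k <- round(lag_s * fs)
    y <- c(rep(x[1], k), x)[seq_along(x)]
    expect_equal(xcorr_lag(x, y, fs, max_lag = 2), lag_s, tolerance = 0.005)
  }
  expect_equal(xcorr_lag(x, x, fs, max_lag = 2), 0, tolerance = 1e-6)
  expect_error(xcorr_lag(x, rep(1, length(x)), fs), "zero-variance")
  expect_error(xcorr_lag(x, x[-1], fs), "equal length")
})

test_that("lag recovery holds over random shifts in both directions", {
  set.seed(21)
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.21 * tt) + 0.5 * sin(2 * pi * 0.047 * tt) +
    rnorm(length(tt), sd = 0.05)
  for (k in sample(-80:80, 8)) {
    y <- if (k >= 0) c(rep(x[1], k), x)[seq_along(x)]
         else c(x[(-k + 1):length(x)], rep(x[length(x)], -k))
    expect_equal(xcorr_lag(x, y, fs, max_lag = 2), k / fs,
                 tolerance = 1 / fs)
  }
})
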