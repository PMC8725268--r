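test_that("noiseless bolus analysis recovers the generating quantities", {
  comp <- quick_comp()
  proto <- standard_protocol(comp, "bolus", n_boluses = 1)
  sim <- simulate_animal(comp, waveform_params(noise_sd = 0),
                         coupling_params(), proto, duration = 800, seed = 2)
  pp <- preprocess_recording(sim$recording, proto)
  res <- analyze_bolus(pp, proto$boluses[[1]], amplitudes = FALSE)
  pc <- res$per_channel
  itp <- pc[pc$channel == "ITP", ]
  expect_equal(itp$Pr, 10, tolerance = 0.03)
  expect_equal(itp$Pp_raw, 10 * 10^(2 / 6.644), tolerance = 0.01)
  expect_equal(itp$Pp, 10 * 10^(2 / 6.644), tolerance = 0.07)
  expect_equal(itp$d_mean, 10, tolerance = 0.10)
  # relaxation series against the generating dynamics, within 2%
  dyn <- simulate_mean_dynamics(comp, proto, fs = 100, duration = 800)
  i0 <- which.max(dyn$p)
  for (q in 1:4)
    expect_equal(unname(res$Pt["ITP", q]), dyn$p[i0 + q * 6000],
                 tolerance = 0.02)
  # monotone non-increasing relaxation between Pr and Pp
  expect_true(all(diff(res$Pt["ITP", ]) < 0.5))
  expect_true(all(res$Pt["ITP", ] > itp$Pr & res$Pt["ITP", ] < itp$Pp))
})

test_that("a null event on baseline measures no reaction", {
  sim <- sim_baseline(duration = 700, seed = 13)
  pp <- preprocess_recording(sim$recording)
  res <- analyze_bolus(pp, bolus_event(350, 2), amplitudes = FALSE)
  expect_true(all(abs(res$per_channel$d_mean) < 0.3))
})

test_that("d_mean is invariant to a common pressure offset", {
  ss <- sim_sessions(seed = 14, n_boluses = 1, cpi = FALSE)
  rec <- ss$bolus$rec
  rec2 <- recording(lapply(rec$samples, `+`, 50), fs = rec$fs)
  ev <- ss$bolus$proto$boluses[[1]]
  r1 <- analyze_bolus(preprocess_recording(rec), ev, amplitudes = FALSE)
  r2 <- analyze_bolus(preprocess_recording(rec2), ev, amplitudes = FALSE)
  expect_equal(r1$per_channel$d_mean, r2$per_channel$d_mean,
               tolerance = 1e-6)
})

test_that("bolus windows outside the recording are rejected; truncated tails flagged", {
  sim <- sim_baseline(duration = 400, seed = 15)
  pp <- preprocess_recording(sim$recording)
  expect_error(analyze_bolus(pp, bolus_event(30, 2), amplitudes = FALSE),
               "beyond")
  expect_warning(
    res <- analyze_bolus(pp, bolus_event(200, 2), amplitudes = FALSE),
    "truncated")
  expect_true(res$truncated)
  expect_true(any(is.na(res$Pt["ITP", ])))
})

test_that("CPI staircase yields settled 3.75 mmHg steps", {
  ss <- sim_sessions(seed = 16, n_boluses = 0, cpi = TRUE)
  pp <- preprocess_recording(ss$cpi$rec, ss$cpi$proto)
  cr <- analyze_cpi(pp, ss$cpi$proto$cpi_steps, amplitudes = FALSE)
  means <- vapply(cr, function(s)
    s$per_channel$step_mean[s$per_channel$channel == "ITP"], numeric(1))
  expect_equal(diff(means), rep(3.75, 5), tolerance = 0.055)
  expect_true(all(diff(means) > 0))
  expect_true(all(vapply(cr, `[[`, logical(1), "settled")))
  # the shared pre-infusion baseline is the resting pressure
  expect_equal(attr(cr, "Pb"), 10, tolerance = 0.05)
})

test_that("a never-settling ramp is flagged", {
  fs <- 100
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)
  ramp <- 10 + 0.05 * tt + 1.5 * sin(2 * pi * 1.74 * tt)
  rec <- recording(list(ICP = ramp, ITP = ramp), fs = fs)
  steps <- list(cpi_step(1, 20, 200, 500))
  cr <- analyze_cpi(rec, steps, amplitudes = FALSE)
  expect_false(cr[[1]]$settled)
  expect_error(rout_cpi(cr), "no settled step")
})

test_that("communication classification splits by transmission ratio", {
  tab <- reference_cohort()$bolus
  calls <- lapply(seq_len(nrow(tab)), function(i)
    classify_communication(data.frame(d_itp = tab$d_itp[i],
                                      d_icp = tab$d_icp[i]),
                           min_events = 1))
  names(calls) <- tab$sheep
  expect_equal(calls$B$ratio, 24.2 / 24.4, tolerance = 1e-6)
  expect_true(calls$B$communicating)
  expect_equal(calls$E$ratio, 2.3 / 42.2, tolerance = 1e-6)
  expect_false(calls$E$communicating)
  # exact equality of the two reactions gives ratio 1
  expect_equal(classify_communication(
    data.frame(d_itp = 5, d_icp = 5), min_events = 1)$ratio, 1)
  # scale invariance
  c1 <- classify_communication(
    data.frame(d_itp = c(10, 12, 9), d_icp = c(7, 8, 6)))
  c2 <- classify_communication(
    data.frame(d_itp = 3 * c(10, 12, 9), d_icp = 3 * c(7, 8, 6)))
  expect_equal(c1$ratio, c2$ratio)
  # boluses without an intrathecal rise are excluded
  c3 <- classify_communication(
    data.frame(d_itp = c(10, -1, 9), d_icp = c(7, 5, 6)))
  expect_equal(c3$n_used, 2L)
  expect_error(classify_communication(
    data.frame(d_itp = c(-1, -2, -3), d_icp = c(1, 1, 1))), "positive")
  expect_error(classify_communication(
    data.frame(d_itp = 1, d_icp = 1)), "at least 3")
})

test_that("trend regression reflects the craniospinal coupling", {
  ss <- sim_sessions(seed = 17, n_boluses = 2, noise_sd = 0, cpi = FALSE)
  pp <- preprocess_recording(ss$bolus$rec, ss$bolus$proto)
  expect_gt(regression_coupling(pp, c(240, 1100)), 0.999)
  # anti-phase construction
  fs <- 100
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 0.02 * tt)
  rec <- recording(list(ICP = 10 - 3 * s, ITP = 10 + 3 * s), fs = fs)
  expect_lt(regression_coupling(rec, c(20, 280)), -0.98)
  expect_error(regression_coupling(rec, c(0, 60)), "120 s")
})
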