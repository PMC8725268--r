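test_that("bolus peak follows the closed-form pressure-volume relation", {
  comp <- quick_comp()
  proto <- infusion_protocol(boluses = list(bolus_event(60, 2)))
  dyn <- simulate_mean_dynamics(comp, proto, fs = 100, duration = 300)
  expect_equal(max(dyn$p), 10 * 10^(2 / 6.644), tolerance = 1e-4)
  # constant at the resting pressure before the first event
  expect_true(all(abs(dyn$p[1:5999] - 10) < 1e-12))
})

test_that("sustained constant infusion plateaus at Pr + Q * Rout", {
  comp <- quick_comp(Rout = 75)
  # 0.05 mL/min held for 150 min (the linearized settling time constant is
  # ~950 s, so the plateau needs several of those), as a slow 7.5 mL infusion
  proto <- infusion_protocol(boluses = list(bolus_event(60, 7.5)),
                             relaxation_limit = 9100)
  dyn <- simulate_mean_dynamics(comp, proto, fs = 10, duration = 9100,
                                bolus_duration = 9000)
  expect_equal(dyn$p[90500], 10 + 0.05 * 75, tolerance = 0.01)
})

test_that("no events means a flat trace at the resting pressure", {
  dyn <- simulate_mean_dynamics(quick_comp(), infusion_protocol(), fs = 10,
                                duration = 120)
  expect_true(all(dyn$p == 10))
  expect_true(all(dyn$q == 0))
})

test_that("noiseless traces invert exactly through the estimation formulas", {
  for (Rout in c(50, 75)) {
    comp <- quick_comp(Rout = Rout)
    proto <- infusion_protocol(boluses = list(bolus_event(60, 2)))
    dyn <- simulate_mean_dynamics(comp, proto, fs = 100, duration = 400)
    ipk <- which.max(dyn$p)
    Pp <- dyn$p[ipk]
    pv <- pvi(2, Pp, 10)
    expect_equal(pv, 6.644, tolerance = 0.01)                      # 1%
    for (tmin in 1:4) {
      Pt <- dyn$p[ipk + tmin * 6000]
      expect_equal(rout_bolus(tmin, 10, Pp, Pt, pv), Rout,
                   tolerance = 0.02)                               # 2%
    }
  }
})

test_that("the step controller reaches its targets at the predicted rates", {
  comp <- quick_comp(Rout = 75)
  cpi <- make_cpi_controller(comp, targets = 10 + 3.75 * (1:6))
  q <- vapply(cpi$cpi_steps, `[[`, numeric(1), "q_inf")
  expect_equal(q, 3.75 * (1:6) / 75, tolerance = 0.05)
  # six distinct monotone plateaus in the underlying trace
  dyn <- attr(cpi, "trace")
  plateaus <- vapply(cpi$cpi_steps, function(s)
    mean(dyn$p[dyn$time >= s$t_start + 60 & dyn$time < s$t_end]), numeric(1))
  expect_true(all(diff(plateaus) > 3))
  expect_equal(plateaus, 10 + 3.75 * (1:6), tolerance = 0.01)
  # a target at the resting pressure needs (almost) no infusion
  cpi0 <- make_cpi_controller(comp, targets = 10 + 1e-9)
  expect_lt(cpi0$cpi_steps[[1]]$q_inf, 1e-6)
  expect_error(make_cpi_controller(comp, targets = c(12, 10)), "increasing")
  expect_error(make_cpi_controller(comp, targets = 10 + 400), "unreachable")
})

test_that("identical seeds give bit-identical recordings", {
  comp <- quick_comp()
  proto <- standard_protocol(comp, "bolus", n_boluses = 1)
  args <- list(comp, waveform_params(), coupling_params(), proto,
               duration = 500)
  s1 <- do.call(simulate_animal, c(args, seed = 7))
  s2 <- do.call(simulate_animal, c(args, seed = 7))
  expect_identical(s1$recording$samples, s2$recording$samples)
  s3 <- do.call(simulate_animal, c(args, seed = 8))
  expect_false(identical(s1$recording$samples, s3$recording$samples))
  expect_error(do.call(simulate_animal, args), "seed")
})

test_that("unit craniospinal gain transmits the mean response one-to-one", {
  comp <- quick_comp()
  proto <- standard_protocol(comp, "bolus", n_boluses = 1)
  sim <- simulate_animal(comp, waveform_params(noise_sd = 0),
                         coupling_params(g_craniospinal = 1, lag_s = 0),
                         proto, duration = 500, seed = 2)
  tr <- compute_trends(sim$recording)
  icp <- tr$ICP - tr$ICP[1]
  itp <- tr$ITP - tr$ITP[1]
  mid <- 2000:48000
  expect_lt(max(abs(icp[mid] - itp[mid])) / max(itp[mid]), 0.02)
})

test_that("a low gain produces a non-communicating animal", {
  ss <- sim_sessions(seed = 8, g = 0.05, n_boluses = 3, cpi = FALSE)
  pp <- preprocess_recording(ss$bolus$rec, ss$bolus$proto)
  tr <- compute_trends(pp)
  br <- lapply(ss$bolus$proto$boluses, function(ev)
    analyze_bolus(pp, ev, trends = tr, amplitudes = FALSE))
  d <- vapply(br, function(r) {
    pc <- r$per_channel
    pc$d_mean[pc$channel == "ICP"] / pc$d_mean[pc$channel == "ITP"]
  }, numeric(1))
  expect_true(all(d < 0.2))
})

test_that("baseline spectra carry the configured fundamentals", {
  sim <- sim_baseline(duration = 300, seed = 6)
  sp <- pressure_spectrum(sim$recording$samples$ITP, 100, c(0, 295))
  expect_equal(unname(sp$fundamentals["respiratory"]), 0.30,
               tolerance = sp$df)
  expect_equal(unname(sp$fundamentals["cardiac"]), 1.74, tolerance = sp$df)
})

test_that("generated pulse amplitude grows with mean pressure", {
  comp <- quick_comp()
  proto <- standard_protocol(comp, "cpi")
  sim <- simulate_animal(comp, waveform_params(amp_slope = 0.15),
                         coupling_params(), proto, seed = 9)
  pp <- preprocess_recording(sim$recording, proto)
  b <- detect_beats(pp$samples$ITP, 100, f_cardiac_hint = 1.74)
  amps <- vapply(proto$cpi_steps, function(s)
    amplitude_stat(b, c(s$t_start + 60, s$t_end)), numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("simulation domain violations are reported", {
  # a protocol event outside the simulated span
  comp <- quick_comp()
  expect_error(simulate_mean_dynamics(
    comp, infusion_protocol(boluses = list(bolus_event(500, 2))),
    fs = 10, duration = 100), "outside")
  expect_error(simulate_mean_dynamics(comp, infusion_protocol(), fs = 5),
               "fs")
})
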