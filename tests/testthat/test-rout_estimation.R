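test_that("pressure-volume index follows the log-ratio closed form", {
  expect_equal(pvi(2, 20, 2), 2)
  expect_equal(pvi(2, 20, 10), 2 / log10(2), tolerance = 1e-10)
  expect_equal(pvi(2, 20, 10), 6.6439, tolerance = 1e-4)
  # doubling the volume at a fixed pressure ratio doubles the index
  expect_equal(pvi(4, 20, 10), 2 * pvi(2, 20, 10))
  expect_error(pvi(2, 10, 10), "non-positive pressure rise")
  expect_error(pvi(2, 20, 0, P0 = 0), "reference")
  expect_error(pvi(0, 20, 10), "dV")
})

test_that("relaxation formula inverts the generating dynamics", {
  for (Rout in c(50, 75)) {
    comp <- quick_comp(Rout = Rout)
    proto <- infusion_protocol(boluses = list(bolus_event(60, 2)))
    dyn <- simulate_mean_dynamics(comp, proto, fs = 100, duration = 400)
    ipk <- which.max(dyn$p)
    Pp <- dyn$p[ipk]
    pv <- pvi(2, Pp, 10)
    est <- rout_bolus(1:4, 10, Pp, dyn$p[ipk + (1:4) * 6000], pv)
    expect_true(all(abs(est - Rout) / Rout < 0.02))
  }
})

test_that("relaxation formula units and degenerate inputs", {
  # seconds and minutes agree after unit normalization
  expect_equal(rout_bolus(2, 10, 20, 18, 6.6),
               rout_bolus(120, 10, 20, 18, 6.6, t_unit = "s"))
  expect_error(rout_bolus(1, 10, 20, 9, 6.6), "no valid relaxation")
  expect_error(rout_bolus(1, 10, 20, 20, 6.6), "no valid relaxation")
  expect_error(rout_bolus(0, 10, 20, 18, 6.6), "time")
  expect_error(rout_bolus(1, 10, 20, 18, -1), "PVI")
  # one invalid timepoint among valid ones is dropped with a warning
  expect_warning(est <- rout_bolus(c(1, 2), 10, 20, c(18, 9.5), 6.6),
                 "dropped")
  expect_true(is.na(est[2]) && is.finite(est[1]))
})

fake_bolus_result <- function(Pr, Pp, Pt, dV = 2, channel = "ICP") {
  structure(list(
    per_channel = data.frame(channel = channel, d_mean = Pp - Pr,
                             d_amp = NA_real_, Pr = Pr, Pp = Pp,
                             Pp_raw = Pp, t_peak = 0),
    Pt = matrix(Pt, nrow = 1, dimnames = list(channel, NULL)),
    pt_offsets = c(60, 120, 180, 240), dV = dV, t_start = 0,
    truncated = FALSE), class = "bolus_result")
}

test_that("bolus averaging spans timepoints then boluses", {
  # symmetric per-timepoint values average to their centre
  comp <- quick_comp(Rout = 75)
  dyn <- simulate_mean_dynamics(
    comp, infusion_protocol(boluses = list(bolus_event(60, 2))),
    fs = 100, duration = 400)
  ipk <- which.max(dyn$p)
  r <- fake_bolus_result(10, dyn$p[ipk], dyn$p[ipk + (1:4) * 6000])
  est <- rout_bolus_mean(list(r, r))
  expect_equal(est$Rout, 75, tolerance = 0.02)
  expect_equal(est$n_used, 2L)
  expect_equal(est$Rout, mean(est$per_timepoint))
  # an invalid timepoint (relaxation through baseline) is dropped, flagged
  r2 <- fake_bolus_result(10, dyn$p[ipk],
                          c(dyn$p[ipk + (1:3) * 6000], 9.9))
  est2 <- rout_bolus_mean(list(r2))
  expect_equal(est2$Rout, 75, tolerance = 0.02)
  expect_match(paste(est2$flags, collapse = " "), "dropped")
  expect_error(rout_bolus_mean(list(fake_bolus_result(10, 20, c(9, 9, 9, 9)))),
               "no bolus")
})

fake_cpi_results <- function(Pa, Pb, q, settled = TRUE) {
  n <- length(Pa)
  structure(lapply(seq_len(n), function(k) {
    structure(list(index = k, target = Pa[k], q_inf = q[k],
                   per_channel = data.frame(channel = "ICP",
                                            step_mean = Pa[k],
                                            step_amp = NA_real_),
                   Pa = Pa[k], Pb = Pb,
                   settled = settled[min(k, length(settled))]),
              class = "cpi_step_result")
  }), class = "cpi_results", Pb = Pb, rout_channel = "ICP")
}

test_that("constant-pressure estimator is the settled pressure rise per rate", {
  est <- rout_cpi(fake_cpi_results(Pa = 13.75, Pb = 10, q = 0.05))
  expect_equal(est$Rout, 75)
  # steps without information are excluded and flagged
  est2 <- rout_cpi(fake_cpi_results(Pa = c(13.75, 10, 17.5), Pb = 10,
                                    q = c(0.05, 0.02, 0)))
  expect_equal(est2$Rout, 75)
  expect_equal(est2$n_used, 1L)
  expect_match(paste(est2$flags, collapse = " "), "uninformative")
  expect_match(paste(est2$flags, collapse = " "), "q_inf = 0")
  expect_error(rout_cpi(fake_cpi_results(13.75, 10, 0.05, settled = FALSE)),
               "no settled")
})

test_that("bolus and constant-pressure estimators agree on exact dynamics", {
  ss <- sim_sessions(seed = 18, noise_sd = 0)
  res <- analyze_infusion_test(ss$bolus$rec, ss$bolus$proto,
                               ss$cpi$rec, ss$cpi$proto, amplitudes = FALSE)
  expect_equal(res$rout_bolus$Rout, 75, tolerance = 0.03)
  expect_equal(res$rout_cpi$Rout, 75, tolerance = 0.03)
  expect_equal(res$rout_bolus$Rout, res$rout_cpi$Rout, tolerance = 0.03)
  expect_equal(res$rout_bolus$PVI, 6.644, tolerance = 0.03)
})

test_that("viscoelastic relaxation biases the bolus method downwards", {
  for (seed in 1:3) {
    r <- recover_animal(Rout = 55 + 10 * seed, PVI = 5 + seed, seed = seed,
                        visco_eps = 0.3)
    expect_lt(r["rout_bolus"], r["rout_cpi"])
  }
})
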