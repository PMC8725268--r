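# Shared builders for simulated animals and sessions.

quick_comp <- function(Rout = 75, PVI = 6.644, Pr = 10, visco_eps = 0) {
  compartment_params(Pr = Pr, PVI = PVI, Rout_true = Rout,
                     visco_eps = visco_eps, visco_tau = 30)
}

# A short baseline-only recording (no infusion events).
sim_baseline <- function(duration = 600, seed = 1, noise_sd = 0.2, ...) {
  comp <- quick_comp()
  simulate_animal(comp, waveform_params(noise_sd = noise_sd, ...),
                  coupling_params(), infusion_protocol(),
                  duration = duration, seed = seed)
}

# Bolus and CPI sessions for one animal under the standard protocol.
sim_sessions <- function(Rout = 75, PVI = 6.644, Pr = 10, seed = 1,
                         visco_eps = 0, g = 1, noise_sd = 0.2,
                         n_boluses = 6, cpi = TRUE) {
  comp <- quick_comp(Rout, PVI, Pr, visco_eps)
  wave <- waveform_params(noise_sd = noise_sd)
  coup <- coupling_params(g_craniospinal = g)
  pb <- standard_protocol(comp, "bolus", n_boluses = n_boluses)
  sb <- simulate_animal(comp, wave, coup, pb, seed = seed)
  out <- list(comp = comp,
              bolus = list(rec = sb$recording, proto = pb,
                           gt = sb$ground_truth))
  if (cpi) {
    pc <- standard_protocol(comp, "cpi")
    sc <- simulate_animal(comp, wave, coup, pc, seed = seed + 500000L)
    out$cpi <- list(rec = sc$recording, proto = sc$ground_truth$protocol,
                    gt = sc$ground_truth)
  }
  out
}

# Full two-session recovery for one animal; amplitudes off for speed.
recover_animal <- function(Rout, PVI, seed, visco_eps = 0) {
  ss <- sim_sessions(Rout = Rout, PVI = PVI, seed = seed,
                     visco_eps = visco_eps)
  res <- analyze_infusion_test(ss$bolus$rec, ss$bolus$proto,
                               ss$cpi$rec, ss$cpi$proto,
                               amplitudes = FALSE)
  c(rout_bolus = res$rout_bolus$Rout, rout_cpi = res$rout_cpi$Rout,
    pvi = res$rout_bolus$PVI)
}
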