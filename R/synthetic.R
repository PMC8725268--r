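#' CSF compartment parameters
#'
#' Ground-truth parameters of the nonlinear single-compartment
#' pressure-volume model that drives the simulator:
#' `dP/dt = (ln10 * P / PVI) * (I(t) - (P - Pr)/Rout)` with pressures in
#' mmHg, volumes in mL and infusion/absorption rates in mL/min. `PVI` is the
#' pressure-volume index (the volume that raises pressure tenfold), `Rout`
#' the outflow resistance, `Pr` the resting pressure and `P0` the reference
#' pressure of the exponential pressure-volume relation (zero by
#' convention). `visco_eps`/`visco_tau` optionally superimpose a
#' viscoelastic relaxation-shape perturbation on post-bolus decays: the
#' deviation from the pre-bolus pressure is multiplied by
#' `1 + visco_eps * exp(-(t - t_bolus)/visco_tau)`; the default
#' `visco_eps = 0` leaves the dynamics exactly compartmental.
#'
#' @param Pr resting pressure (mmHg), > P0.
#' @param PVI pressure-volume index (mL), > 0.
#' @param Rout_true outflow resistance (mmHg/mL/min), > 0.
#' @param P0 reference pressure (mmHg).
#' @param visco_eps viscoelastic perturbation magnitude (dimensionless, >= 0).
#' @param visco_tau viscoelastic time constant (s).
#' @return object of class `compartment_params`.
#' @export
compartment_params <- function(Pr = 10, PVI = 6.6, Rout_true = 75, P0 = 0,
                               visco_eps = 0, visco_tau = 30) {
  if (PVI <= 0) stop("PVI must be > 0")
  if (Rout_true <= 0) stop("Rout_true must be > 0")
  if (Pr <= P0) stop("resting pressure Pr must exceed reference pressure P0")
  structure(list(Pr = Pr, PVI = PVI, Rout_true = Rout_true, P0 = P0,
                 visco_eps = visco_eps, visco_tau = visco_tau),
            class = "compartment_params")
}

#' Waveform parameters of the synthetic pressure channels
#'
#' Controls the pulsatile structure superimposed on the compartmental mean
#' dynamics: cardiac and respiratory harmonic series (sinusoids with `1/k`
#' harmonic decay), pressure-dependent cardiac pulse amplitude, the
#' roller-pump oscillation artifact present while pressure is being
#' regulated, and white sensor noise. Per-channel amplitudes are
#' peak-to-peak in mmHg. The cardiac amplitude of a channel grows linearly
#' with its mean pressure above `amp_threshold` at `amp_slope` mmHg of
#' amplitude per mmHg of mean pressure, emulating the pulsatility curve of
#' pressure-dependent compliance.
#'
#' @param f_cardiac cardiac fundamental (Hz).
#' @param f_resp respiratory fundamental (Hz), `0 < f_resp < f_cardiac`
#'   (fixed-rate positive-pressure ventilation).
#' @param n_harmonics harmonics per source.
#' @param amp0 named per-channel baseline cardiac peak-to-peak amplitude
#'   (mmHg).
#' @param amp_resp named per-channel respiratory peak-to-peak amplitude
#'   (mmHg).
#' @param amp_slope cardiac-amplitude increase per mmHg of mean pressure
#'   above `amp_threshold` (dimensionless, >= 0).
#' @param amp_threshold mean-pressure threshold (mmHg) of the pulsatility
#'   relation.
#' @param noise_sd Gaussian sensor-noise SD (mmHg), >= 0.
#' @param pump_freq roller-pump oscillation frequency (Hz), inside the
#'   0.2--0.5 Hz stopband of the conditioning chain.
#' @param pump_amp pump oscillation peak-to-peak amplitude (mmHg) on the
#'   intrathecal channel; active only while a pressure step is regulated.
#' @return object of class `waveform_params`.
#' @export
waveform_params <- function(f_cardiac = 1.74, f_resp = 0.30, n_harmonics = 4,
                            amp0 = c(ICP = 3.2, ITP = 3.2, ABP = 18, CVP = 3.4),
                            amp_resp = c(ICP = 0.6, ITP = 0.8, ABP = 1.5,
                                         CVP = 0.8),
                            amp_slope = 0.15, amp_threshold = 10,
                            noise_sd = 0.2, pump_freq = 0.4, pump_amp = 0.8) {
  if (!(f_resp > 0 && f_resp < f_cardiac))
    stop("need 0 < f_resp < f_cardiac")
  if (amp_slope < 0) stop("amp_slope must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pump_freq < 0.2 || pump_freq > 0.5)
    stop("pump_freq must lie in [0.2, 0.5] Hz")
  structure(list(f_cardiac = f_cardiac, f_resp = f_resp,
                 n_harmonics = as.integer(n_harmonics), amp0 = amp0,
                 amp_resp = amp_resp, amp_slope = amp_slope,
                 amp_threshold = amp_threshold, noise_sd = noise_sd,
                 pump_freq = pump_freq, pump_amp = pump_amp),
            class = "waveform_params")
}

#' Inter-compartment coupling parameters
#'
#' How the intrathecal mean-pressure response is transmitted to the other
#' channels: the cranio-spinal gain `g_craniospinal` (1 = free
#' communication, near 0 = obstructed) with transmission delay `lag_s`; a
#' lagged first-order compensatory arterial response (`g_abp` mmHg of ABP
#' per mmHg of ICP elevation, time constant `tau_abp`); an analogous muted
#' venous response; and an optional extrasystole process.
#'
#' @param g_craniospinal ITP-to-ICP mean transmission gain in `[0, 1]`.
#' @param lag_s transmission delay (s), >= 0.
#' @param g_abp arterial compensatory gain (mmHg per mmHg ICP rise).
#' @param tau_abp arterial response time constant (s).
#' @param g_cvp venous gain (mmHg per mmHg ICP rise).
#' @param tau_cvp venous response time constant (s).
#' @param extrasystole_rate extrasystole events per minute (default 0).
#' @param baseline_icp ICP baseline (mmHg); default `NULL` uses the
#'   compartment resting pressure (hydrostatic equivalence of the zeroed
#'   transducers).
#' @param baseline_abp,baseline_cvp arterial/venous baselines (mmHg).
#' @return object of class `coupling_params`.
#' @export
coupling_params <- function(g_craniospinal = 1, lag_s = 0.31, g_abp = 0.25,
                            tau_abp = 15, g_cvp = 0.1, tau_cvp = 180,
                            extrasystole_rate = 0, baseline_icp = NULL,
                            baseline_abp = 85, baseline_cvp = 4) {
  if (g_craniospinal < 0 || g_craniospinal > 1)
    stop("g_craniospinal must lie in [0, 1]")
  if (lag_s < 0) stop("lag_s must be >= 0")
  structure(list(g_craniospinal = g_craniospinal, lag_s = lag_s,
                 g_abp = g_abp, tau_abp = tau_abp, g_cvp = g_cvp,
                 tau_cvp = tau_cvp, extrasystole_rate = extrasystole_rate,
                 baseline_icp = baseline_icp, baseline_abp = baseline_abp,
                 baseline_cvp = baseline_cvp),
            class = "coupling_params")
}

#' Simulate the compartmental mean-pressure dynamics
#'
#' Integrates `dP/dt = (ln10 * P / PVI) * (I(t) - (P - Pr)/Rout)` (fixed-step
#' RK4 at the output rate with 10x substepping) under the events of
#' `protocol`: bolus infusions are instantaneous volume additions
#' (`P -> P * 10^(dV/PVI)`, the closed-form peak of the pressure-volume
#' relation) unless `bolus_duration > 0` spreads the volume linearly over
#' that many seconds; constant-pressure steps are tracked by a
#' proportional-plus-feedforward controller whose applied infusion rate is
#' recorded per sample. Before the first event the trace equals `Pr`;
#' under a sustained constant infusion `Q` the steady state is
#' `Pr + Q * Rout`.
#'
#' @param comp [compartment_params()].
#' @param protocol [infusion_protocol()]; all events must fall inside the
#'   simulated span.
#' @param fs output sampling rate (Hz), >= 10.
#' @param duration simulated duration (s); default extends 60 s past the
#'   last event (plus the relaxation limit after a final bolus).
#' @param bolus_duration 0 for instantaneous boluses (default), otherwise
#'   the infusion is spread linearly over this many seconds.
#' @param kp controller proportional gain (mL/min per mmHg).
#' @param imax controller maximum infusion rate (mL/min).
#' @param substeps internal RK4 substeps per output sample.
#' @return object of class `mean_dynamics`: list with `time` (s), `p`
#'   (mmHg), `q` (applied infusion rate, mL/min) and `fs`.
#' @export
simulate_mean_dynamics <- function(comp, protocol, fs = 100, duration = NULL,
                                   bolus_duration = 0, kp = 2, imax = 3,
                                   substeps = 10) {
  stopifnot(inherits(comp, "compartment_params"),
            inherits(protocol, "infusion_protocol"))
  if (fs < 10) stop("fs must be >= 10 Hz")
  t_last <- 0
  if (length(protocol$boluses))
    t_last <- max(t_last, max(vapply(protocol$boluses, `[[`, numeric(1),
                                     "t_start")) + protocol$relaxation_limit)
  if (length(protocol$cpi_steps))
    t_last <- max(t_last, max(vapply(protocol$cpi_steps, `[[`, numeric(1),
                                     "t_end")))
  if (is.null(duration)) duration <- t_last + 60
  n <- as.integer(round(duration * fs))
  tm <- (seq_len(n) - 1L) / fs
  for (b in protocol$boluses)
    if (b$t_start < 0 || b$t_start >= duration)
      stop("bolus event outside the simulated span")
  for (s in protocol$cpi_steps)
    if (s$t_start < 0 || s$t_end > duration)
      stop("cpi step outside the simulated span")

  inf_rate <- numeric(n)
  target <- rep(NA_real_, n)
  bolus_idx <- integer(0)
  bolus_dv <- numeric(0)
  for (b in protocol$boluses) {
    i0 <- as.integer(round(b$t_start * fs))
    if (bolus_duration > 0) {
      ii <- i0:min(n - 1L, i0 + as.integer(round(bolus_duration * fs)) - 1L)
      inf_rate[ii + 1L] <- inf_rate[ii + 1L] + 60 * b$dV / bolus_duration
    } else {
      bolus_idx <- c(bolus_idx, i0)
      bolus_dv <- c(bolus_dv, b$dV)
    }
  }
  for (s in protocol$cpi_steps) {
    i0 <- as.integer(round(s$t_start * fs)) + 1L
    i1 <- as.integer(round(s$t_end * fs))
    target[i0:i1] <- s$target
  }

  res <- marmarou_integrate_cpp(comp$Pr, comp$PVI, comp$Pr, comp$Rout_true,
                                comp$P0, fs, as.integer(substeps), inf_rate,
                                target, kp, imax, bolus_idx, bolus_dv)
  if (!res$ok)
    stop(sprintf("pressure-volume model domain violated (P <= P0) at t = %.2f s",
                 (res$bad_index - 1) / fs))
  p <- res$p
  if (comp$visco_eps > 0 && length(bolus_idx)) {
    ends <- c(bolus_idx[-1L], n)
    for (k in seq_along(bolus_idx)) {
      i0 <- bolus_idx[k] + 1L
      ii <- i0:ends[k]
      pr_ev <- if (i0 > 1L) p[i0 - 1L] else comp$Pr
      fac <- 1 + comp$visco_eps * exp(-(tm[ii] - tm[i0]) / comp$visco_tau)
      p[ii] <- pr_ev + (p[ii] - pr_ev) * fac
    }
  }
  structure(list(time = tm, p = p, q = res$q, fs = fs),
            class = "mean_dynamics")
}

#' Build a constant-pressure-infusion protocol with measured infusion rates
#'
#' Simulates the pressure-step controller on the noise-free compartment
#' dynamics for six (or fewer) strictly increasing pressure targets held
#' `step_duration` seconds each, and records each step's mean infusion rate
#' over the settled portion `[t_start + settle, t_end)` -- the `q_inf` an
#' infusion apparatus would report. Errors when a target needs more than
#' `imax` mL/min at steady state or when the controller misses a target by
#' more than `tol` mmHg.
#'
#' @param comp [compartment_params()].
#' @param targets strictly increasing commanded pressures (mmHg).
#' @param settle settling allowance per step (s).
#' @param step_duration step length (s); 7 min in the standard protocol.
#' @param t_start start time of the first step (s).
#' @param fs controller simulation rate (Hz).
#' @param kp,imax controller gain and maximum rate (see
#'   [simulate_mean_dynamics()]).
#' @param tol target tracking tolerance (mmHg).
#' @return an [infusion_protocol()] whose steps carry measured `q_inf`; the
#'   simulated pressure/rate traces are attached as attribute `"trace"`.
#' @export
make_cpi_controller <- function(comp, targets, settle = 60,
                                step_duration = 420, t_start = 300, fs = 20,
                                kp = 2, imax = 3, tol = 0.2) {
  stopifnot(inherits(comp, "compartment_params"))
  if (length(targets) < 1L || is.unsorted(targets, strictly = TRUE))
    stop("targets must be strictly increasing")
  need <- (max(targets) - comp$Pr) / comp$Rout_true
  if (need > imax)
    stop(sprintf("unreachable target: steady-state rate %.2f mL/min exceeds imax %.2f",
                 need, imax))
  steps <- lapply(seq_along(targets), function(k)
    cpi_step(index = k, target = targets[k],
             t_start = t_start + (k - 1L) * step_duration,
             t_end = t_start + k * step_duration))
  proto <- infusion_protocol(cpi_steps = steps)
  dyn <- simulate_mean_dynamics(comp, proto, fs = fs, kp = kp, imax = imax)
  for (k in seq_along(steps)) {
    s <- steps[[k]]
    ii <- which(dyn$time >= s$t_start + settle & dyn$time < s$t_end)
    q_k <- mean(dyn$q[ii])
    p_k <- mean(dyn$p[ii])
    if (abs(p_k - s$target) > tol)
      stop(sprintf("controller missed target %g mmHg at step %d (settled mean %.2f)",
                   s$target, k, p_k))
    steps[[k]]$q_inf <- q_k
  }
  out <- infusion_protocol(cpi_steps = steps,
                           relaxation_limit = proto$relaxation_limit)
  attr(out, "trace") <- dyn
  out
}

#' Standard infusion-test session protocols
#'
#' The standard study runs the two infusion tests as separate sessions,
#' each starting from rest with a 5-min baseline: a bolus session of six
#' 2-mL infusions 7 min apart, and a constant-pressure session of six
#' 3.75-mmHg steps above the resting pressure, 7 min each, with apparatus
#' infusion rates filled in by [make_cpi_controller()]. (Running both in
#' one session is possible but, with the slow compartmental relaxation,
#' leaves the CPI phase starting from an elevated baseline.)
#'
#' @param comp [compartment_params()].
#' @param session `"bolus"`, `"cpi"` or `"both"` (boluses first, then the
#'   pressure staircase after a second baseline period).
#' @param n_boluses number of bolus events.
#' @param dV bolus volume (mL).
#' @param spacing bolus spacing / relaxation limit (s).
#' @param baseline pre-infusion baseline length (s).
#' @param n_steps number of CPI steps.
#' @param step_mmHg pressure increment per step (mmHg).
#' @param ... further arguments to [make_cpi_controller()].
#' @return an [infusion_protocol()].
#' @export
standard_protocol <- function(comp, session = c("bolus", "cpi", "both"),
                              n_boluses = 6, dV = 2, spacing = 420,
                              baseline = 300, n_steps = 6, step_mmHg = 3.75,
                              ...) {
  session <- match.arg(session)
  boluses <- list()
  if (session %in% c("bolus", "both")) {
    boluses <- lapply(seq_len(n_boluses), function(k)
      bolus_event(t_start = baseline + (k - 1L) * spacing, dV = dV))
  }
  steps <- list()
  if (session %in% c("cpi", "both") && n_steps > 0L) {
    cpi_start <- if (session == "cpi") baseline
                 else baseline + n_boluses * spacing + baseline
    cpi <- make_cpi_controller(comp,
                               targets = comp$Pr + step_mmHg * seq_len(n_steps),
                               t_start = cpi_start, ...)
    steps <- cpi$cpi_steps
  }
  infusion_protocol(boluses = boluses, cpi_steps = steps,
                    relaxation_limit = spacing)
}

# Harmonic series with 1/k decay, normalised to unit peak-to-peak amplitude.
harmonic_series <- function(t, f, K, phase = 0) {
  s <- 0
  for (k in seq_len(K)) s <- s + sin(2 * pi * k * f * t + k * phase) / k
  tt <- seq(0, 1 / f, length.out = 1024L)
  s0 <- 0
  for (k in seq_len(K)) s0 <- s0 + sin(2 * pi * k * f * tt + k * phase) / k
  s / (max(s0) - min(s0))
}

# First-order lag y' = (x - y)/tau, unit DC gain, implemented recursively.
first_order_lag <- function(x, fs, tau) {
  alpha <- 1 / (fs * tau)
  alpha <- alpha / (1 + alpha)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1L]))
}

#' Simulate a full four-channel infusion-test recording
#'
#' Composes a synthetic animal: the intrathecal channel carries the
#' compartmental mean dynamics under the protocol plus cardiac and
#' respiratory harmonic series (cardiac amplitude following the pulsatility
#' relation of [waveform_params()]), the roller-pump artifact during
#' regulated pressure steps, and Gaussian sensor noise. The intracranial
#' channel carries the `g_craniospinal`-scaled, `lag_s`-delayed mean
#' response about its own baseline plus its own pulsatile series; arterial
#' and venous channels carry their baselines plus lagged first-order
#' compensatory responses to the intracranial elevation plus pulsatile
#' series. All generating parameters (and the mean traces and measured CPI
#' infusion rates) are returned as ground truth. Identical inputs and seed
#' give bit-identical output.
#'
#' @param comp [compartment_params()].
#' @param wave [waveform_params()].
#' @param coupling [coupling_params()].
#' @param protocol [infusion_protocol()].
#' @param duration recording length (s); default covers the protocol.
#' @param fs sampling rate (Hz).
#' @param seed integer random seed (mandatory: simulated recordings must be
#'   reproducible).
#' @param ... further arguments to [simulate_mean_dynamics()].
#' @return list with elements `recording` (a [recording()]) and
#'   `ground_truth` (generating parameters, per-channel mean traces,
#'   measured per-step infusion rates).
#' @export
simulate_animal <- function(comp, wave, coupling, protocol, duration = NULL,
                            fs = 100, seed, ...) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory: simulated recordings must be reproducible")
  stopifnot(inherits(wave, "waveform_params"),
            inherits(coupling, "coupling_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  dyn <- simulate_mean_dynamics(comp, protocol, fs = fs, duration = duration,
                                ...)
  n <- length(dyn$p)
  tm <- dyn$time
  itp_mean <- dyn$p

  lag_n <- as.integer(round(coupling$lag_s * fs))
  itp_shift <- if (lag_n > 0)
    c(rep(itp_mean[1L], lag_n), itp_mean[seq_len(n - lag_n)]) else itp_mean
  b_icp <- if (is.null(coupling$baseline_icp)) comp$Pr else coupling$baseline_icp
  icp_mean <- b_icp + coupling$g_craniospinal * (itp_shift - comp$Pr)
  icp_dev <- icp_mean - b_icp
  abp_mean <- coupling$baseline_abp +
    first_order_lag(coupling$g_abp * icp_dev, fs, coupling$tau_abp)
  cvp_mean <- coupling$baseline_cvp +
    first_order_lag(coupling$g_cvp * icp_dev, fs, coupling$tau_cvp)
  means <- list(ICP = icp_mean, ITP = itp_mean, ABP = abp_mean,
                CVP = cvp_mean)

  # deterministic per-channel pulse phase offsets (cardiac transit)
  phases <- c(ICP = 0.6, ITP = 0.6 + 2 * pi * wave$f_cardiac * coupling$lag_s,
              ABP = 0, CVP = 2.4)
  card_base <- lapply(phases, function(ph)
    harmonic_series(tm, wave$f_cardiac, wave$n_harmonics, phase = ph))
  resp_base <- harmonic_series(tm, wave$f_resp, wave$n_harmonics, phase = 1)

  in_cpi <- rep(FALSE, n)
  for (s in protocol$cpi_steps) {
    ii <- which(tm >= s$t_start & tm < s$t_end)
    in_cpi[ii] <- TRUE
  }
  pump <- 0.5 * wave$pump_amp * sin(2 * pi * wave$pump_freq * tm) * in_cpi

  samples <- list()
  for (ch in REC_CHANNELS) {
    # pulsatility relation: CSF channels gain amplitude above the global
    # threshold; blood channels above their own resting baseline
    thr_ch <- if (ch %in% c("ICP", "ITP")) wave$amp_threshold
              else means[[ch]][1L]
    amp <- wave$amp0[[ch]] +
      wave$amp_slope * pmax(0, means[[ch]] - thr_ch)
    x <- means[[ch]] + amp * card_base[[ch]] +
      wave$amp_resp[[ch]] * resp_base
    if (ch == "ITP") x <- x + pump
    if (coupling$extrasystole_rate > 0 && ch %in% c("ABP", "ITP", "ICP")) {
      n_ev <- stats::rpois(1L, coupling$extrasystole_rate * tm[n] / 60)
      if (n_ev > 0) {
        te <- sort(stats::runif(n_ev, 0, tm[n]))
        for (t_e in te) {
          ii <- which(abs(tm - t_e) < 0.4)
          x[ii] <- x[ii] + 0.6 * wave$amp0[[ch]] *
            exp(-((tm[ii] - t_e) / 0.08)^2)
        }
      }
    }
    if (wave$noise_sd > 0) x <- x + stats::rnorm(n, sd = wave$noise_sd)
    samples[[ch]] <- x
  }

  # measured infusion rate per settled step, as the apparatus would log it
  proto_out <- protocol
  for (k in seq_along(proto_out$cpi_steps)) {
    s <- proto_out$cpi_steps[[k]]
    ii <- which(tm >= s$t_start + 60 & tm < s$t_end)
    if (length(ii)) proto_out$cpi_steps[[k]]$q_inf <- mean(dyn$q[ii])
  }

  list(recording = recording(samples, fs = fs, t0 = 0),
       ground_truth = list(comp = comp, wave = wave, coupling = coupling,
                           protocol = proto_out, seed = as.integer(seed),
                           mean_traces = means, q = dyn$q))
}
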