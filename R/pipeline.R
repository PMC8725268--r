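#' Analyse a complete infusion test (bolus and CPI sessions)
#'
#' The full analysis chain for one animal: condition each session
#' ([preprocess_recording()]), extract mean trends and beats, quantify
#' every bolus ([analyze_bolus()]) and pressure step ([analyze_cpi()]),
#' classify cranio-spinal communication, and estimate outflow resistance
#' by both methods. The resistance channel is intracranial when the animal
#' communicates; otherwise the intrathecal channel is used and flagged
#' (the intracranial response is then too muted to carry the relaxation).
#' The resting pressure used in the relaxation formula is the 5-min
#' arithmetic-mean baseline before the first infusion.
#'
#' @param bolus_rec [recording()] of the bolus session.
#' @param bolus_protocol its [infusion_protocol()].
#' @param cpi_rec,cpi_protocol optional CPI session (omit when the CPI test
#'   could not be completed).
#' @param id animal label.
#' @param amplitudes compute pulse-amplitude statistics (beat detection is
#'   the most expensive stage; disable when only mean reactions and
#'   resistances are needed).
#' @param f_cardiac_hint expected cardiac frequency (Hz) for beat
#'   detection, or `NULL`.
#' @param threshold communication classification threshold.
#' @param baseline_window `c(start, end)` of the resting baseline (s).
#' @return list with `bolus_results`, `cpi_results`, `communication`,
#'   `rout_bolus`, `rout_cpi`, `rout_channel`, `Pr_rest` and `summary`
#'   (an `animal_summary`).
#' @export
analyze_infusion_test <- function(bolus_rec, bolus_protocol, cpi_rec = NULL,
                                  cpi_protocol = NULL, id = "animal",
                                  amplitudes = TRUE, f_cardiac_hint = NULL,
                                  threshold = 0.5,
                                  baseline_window = c(0, 300)) {
  ppb <- preprocess_recording(bolus_rec, bolus_protocol)
  trb <- compute_trends(ppb)
  btb <- if (amplitudes) detect_beats_all(ppb, f_cardiac_hint) else NULL
  bolus_results <- lapply(bolus_protocol$boluses, function(ev)
    analyze_bolus(ppb, ev, trends = trb, beats = btb,
                  amplitudes = amplitudes))
  comm <- classify_communication(bolus_results, threshold = threshold,
                                 min_events = min(3L, length(bolus_results)))
  rout_channel <- if (comm$communicating) "ICP" else "ITP"
  base_i <- rec_window_idx(ppb, baseline_window[1L], baseline_window[2L])
  Pr_rest <- mean(trb[[rout_channel]][base_i])
  rout_b <- tryCatch(
    rout_bolus_mean(bolus_results, channel = rout_channel, Pr_rest = Pr_rest),
    error = function(e) NULL)
  if (!comm$communicating && !is.null(rout_b))
    rout_b$flags <- c(rout_b$flags,
                      "non-communicating: intrathecal fallback channel")

  cpi_results <- NULL
  rout_c <- NULL
  if (!is.null(cpi_rec) && !is.null(cpi_protocol) &&
      length(cpi_protocol$cpi_steps)) {
    ppc <- preprocess_recording(cpi_rec, cpi_protocol)
    trc <- compute_trends(ppc)
    btc <- if (amplitudes) detect_beats_all(ppc, f_cardiac_hint) else NULL
    cpi_results <- analyze_cpi(ppc, cpi_protocol$cpi_steps, trends = trc,
                               beats = btc, amplitudes = amplitudes,
                               rout_channel = rout_channel)
    rout_c <- tryCatch(rout_cpi(cpi_results), error = function(e) NULL)
  }

  summary <- summarize_animal(id, bolus_results, cpi_results,
                              rout_bolus = rout_b, rout_cpi = rout_c,
                              rec = ppb, beats = btb,
                              baseline_window = baseline_window,
                              threshold = threshold)
  list(bolus_results = bolus_results, cpi_results = cpi_results,
       communication = comm, rout_bolus = rout_b, rout_cpi = rout_c,
       rout_channel = rout_channel, Pr_rest = Pr_rest, summary = summary)
}
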