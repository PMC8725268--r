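Package: csfinfusion
Title: Analysis of Intrathecal Infusion Tests and CSF Outflow Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multichannel pressure recordings (intracranial,
    intrathecal, arterial and central venous) acquired during standardized
    intrathecal infusion tests. Implements the full processing chain: zero-phase
    Butterworth conditioning (outlier rejection, pump-artifact band-stop,
    mean-trend lowpass), beat detection and pulse-amplitude statistics, FFT
    spectra with cardiac/respiratory fundamental identification,
    cross-correlation lag estimation, per-event quantification of bolus and
    constant-pressure infusions, and cerebrospinal-fluid outflow resistance
    estimation by the Marmarou pressure-volume (bolus relaxation) and
    constant-pressure methods. A coupled-compartment synthetic recording
    generator with known ground truth supports end-to-end verification, and a
    bundled six-animal ovine reference cohort supports summary reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
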