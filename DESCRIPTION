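Package: prrtdose
Title: Per-Cycle Internal Dosimetry for 177Lu-DOTA-TATE Peptide Receptor
    Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-cycle internal dosimetry during peptide receptor
    radionuclide therapy (PRRT) with 177Lu-DOTA-TATE. Fits mono-exponential
    time-activity curves to SPECT and blood activity-concentration
    measurements, propagates cycle-1 effective half-lives to later cycles,
    integrates residence times, and computes absorbed doses to organs at
    risk, bone marrow, and tumors with the MIRD formalism (self- and
    cross-doses, phantom mass scaling, concentration dose factors).
    Tracks cumulative doses across treatment cycles and applies the
    expected-dose treatment-withholding rule (23 Gy kidneys, 2 Gy bone
    marrow, plus a 10% margin). Includes agreement statistics for
    comparing a classical per-cycle SPECT/CT protocol against a single-CT
    protocol (Bland-Altman limits of agreement, Pearson correlation,
    management concordance, exact one-sided binomial power), a synthetic
    cohort generator with an analytic true-dose oracle, and a voxel
    phantom for studying the effect of SPECT/CT misregistration on
    activity recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
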