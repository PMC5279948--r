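Package: cavcmi
Title: Modeling C-Terminus-Mediated Inhibition of CaV1.3 Calcium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of C-terminus-mediated
    inhibition (CMI) of CaV1.3 L-type calcium channels. Simulates
    whole-cell calcium and barium currents under voltage-step protocols
    with calcium-dependent inactivation (CDI), voltage-dependent
    inactivation, and CMI modeled as a two-state mixture whose
    non-inactivating component is pinned at the end-stage CDI amplitude
    (the constant-I300 rule). Computes the standard gating indices
    (I_peak, I_50, I_300, r_50, S_Ca, J_peak), voltage profiles,
    induction time-course summaries, and an inhibition-modality
    classifier that separates CMI from conventional blockage and
    run-down. Includes the FRET two-hybrid binding isotherm with
    least-squares estimation of Kd and FRmax, a synthetic patch-clamp
    and FRET cohort generator for parameter-recovery testing, and a
    minimal conductance-based pacemaker model of a substantia nigra
    dopaminergic neuron carrying the CaV1.3 mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
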