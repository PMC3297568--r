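Package: sepsisflow
Title: Ensemble Modeling of Neutrophil Trafficking in Experimental Sepsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental ordinary-differential-equation model of the acute
    inflammatory response to cecal ligation and puncture (CLP) induced sepsis,
    with distinct resting, primed, activated, tissue, sequestered and lung
    neutrophil pools, coarse-grained pro-/anti-inflammation and damage states,
    and sigmoidal observation mappings onto eight plasma markers. Parameter
    ensembles consistent with cohort time-course data are generated by
    Metropolis Markov chain Monte Carlo sampling under a log-uniform prior,
    diagnosed with the Gelman-Rubin potential scale reduction factor, and
    contrasted between survivor and non-survivor cohorts through the inverse
    correlation matrix (stiffness spectrum, multiple and partial correlations,
    classification of pairwise correlation changes). A synthetic two-cohort
    data generator emulates normalized rat time-course measurements, and a
    time-windowed hemoadsorption intervention module simulates extracorporeal
    blood purification on virtual cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
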