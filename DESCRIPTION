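Package: lysoca
Title: Lysosomal Calcium Handling in Ventricular Cardiomyocyte Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation model of a mouse ventricular
    cardiomyocyte action potential and calcium cycling extended with a
    lysosomal calcium compartment: an NAADP-gated two-pore channel (TPC2)
    release flux into the cytosol, a calcium loading channel (CLC) uptake
    flux from the junctional space, and passive leaks. Includes static
    beta-adrenergic (isoprenaline) parameter scalings, declarative pacing
    and calcium-overload protocols, Latin-hypercube populations of models
    with calibration filtering, spontaneous calcium release and delayed
    afterdepolarization detection, paired wild-type versus TPC2-knockout
    classification, and calcium-transient biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
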