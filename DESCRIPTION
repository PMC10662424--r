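Package: salivabench
Title: In Vitro Benchmarking of Saliva Substitutes by Rheology, Tribology and
    QCM-D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for benchmarking saliva-substitute lubricants
    from instrument trace data. Classifies products into liquids, viscous
    liquids and gels from rotational flow curves at an orally relevant shear
    rate; fits capillary-breakup (CaBER) filament-thinning traces with
    elastocapillary and power-law models and derives strain, strain rate,
    apparent extensional viscosity and a strain-rate-matched Trouton ratio;
    analyses soft-tribology Stribeck curves (Hertzian contact pressure,
    torque-to-friction conversion, boundary/mixed/hydrodynamic regime
    segmentation); and quantifies QCM-D adsorption kinetics, saturation time
    and rinse-induced desorption extent (an in vitro coating index). A
    synthetic-data module generates instrument-like flow curves, thinning
    traces, Stribeck sweeps and QCM-D traces with known ground truth so the
    whole pipeline is testable without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
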