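Package: eadmap
Title: Poincare-Map Bifurcation Analysis of Paced Cardiac Action Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying multistable and hysteretic action-potential
    dynamics in periodically paced ventricular myocyte models. A paced ionic
    model is treated as a periodic non-autonomous system whose steady
    responses are fixed points of the stroboscopic (Poincare) map; the package
    provides beat-by-beat stiff integration with a strict steady-state
    criterion, Newton shooting for stable and unstable periodic responses,
    monodromy matrices and characteristic multipliers, pseudo-arclength
    continuation with saddle-node, period-doubling and Neimark-Sacker
    bifurcation detection and localization, and protocol drivers for
    hysteresis sweeps, multistability censuses and sodium-clamped analyses.
    Per-beat features (APD90, early-afterdepolarisation counts, diastolic ion
    levels) and a bundled analytically tractable testbed of maps and paced
    surrogate models are included.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
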