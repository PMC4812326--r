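Package: fiberSLS
Title: Viscoelastic Characterization of Stress Fibers by Cantilever Force Probing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and staged parameter inference for transverse
    cantilever probing of single stress fibers. A fiber of half-length d,
    modeled as an active standard linear solid (pre-tension T0, parallel
    spring k1, Maxwell branch k2 in series with a dashpot eta), is pulled at
    its midpoint by a calibrated soft cantilever while the stage ramps and
    then holds. The package integrates the quasi-static force-balance ODE for
    the transverse displacement e(t), recovers (T0, k1, k2, eta) from
    measured stage/cantilever displacement traces via y-intercept extraction,
    exponential relaxation fitting and a two-stage grid search, and generates
    synthetic experiment cohorts (protocol, parameter population, measurement
    noise) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
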