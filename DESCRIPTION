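Package: airprint
Title: Simulation and Analysis of Embedded Air Printing in Yield-Stress Support Baths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying embedded 3D printing of air (bubbles and
    channels) inside yield-stress support materials. Implements a
    Cahn-Hilliard diffuse-interface model of the air/gel order parameter
    coupled to incompressible variable-viscosity flow with a regularized
    Herschel-Bulkley constitutive law, continuum surface-tension forcing
    and a Brinkman-penalized moving nozzle; virtual printing scenarios
    (bubble-to-channel transition, printability-number sweeps,
    neighbor-channel disturbance); shape metrics for extracted air bodies
    (diameter profiles, aspect ratio, circularity, uniformity,
    deformation ratio); flow-curve fitting, gel-tearing recovery and
    regime classification; and a printability classifier bank trained on
    yield stress, reference viscosity and nozzle diameter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    xgboost,
    nnet,
    class,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
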