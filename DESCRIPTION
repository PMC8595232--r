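Package: stentring
Title: Reduced-Order Ring Simulation of Stent-Graft Deployment in Aortic
    Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Station-wise (thin-ring) mechanical simulator of thoracic
    endovascular stent-graft deployment in type B aortic dissection. Provides
    closed-form constitutive laws (incompressible Yeoh hyperelasticity for the
    dissected aortic wall, a linear-elastic intimal flap, a history-dependent
    one-dimensional superelastic Nitinol model for the stent wire), a fitting
    pipeline for uniaxial strip-test data, a fixed-point algorithm that
    recovers the diastolic pre-stress field of the imaged geometry, crimp and
    release deployment with three loading variants, and the geometric
    validation metrics (local open area and strut-centre deviation) used to
    compare simulated against follow-up device configurations. A synthetic
    patient generator stands in for CT-derived anatomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
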