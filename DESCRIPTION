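Package: icmreduce
Title: Iodinated Contrast Dose Reduction via CNR Calibration for Single- and Dual-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for reducing iodinated contrast media (ICM)
    dose in CT while preserving the iodine contrast-to-noise ratio (CNR).
    Measures CNR of iodine inserts in phantom CT volumes, fits CNR as a
    zero-intercept linear function of iodine concentration per acquisition
    stratum (scanner, energy, phantom size, reconstruction), and converts
    slope ratios into achievable contrast-dose reductions when lowering the
    tube potential in single-energy CT or switching to lower-energy virtual
    monochromatic images from dual-energy CT. Includes a synthetic phantom
    image generator with an energy-dependent iodine contrast model and a
    size- and dose-dependent Gaussian noise model, automatic and
    geometry-driven ROI placement, reduction planning across energies and
    phantom sizes, and the worked-example arithmetic for patient ROI
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
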