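Package: pparstab
Title: Stability Analysis of Nuclear-Receptor Ligand-Binding-Domain Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for characterizing the stability of point
    variants of the PPARgamma ligand-binding domain (and similar all-helical
    proteins) from solution spectroscopy and molecular-dynamics trajectories.
    Provides spectral summary statistics (intensity-averaged emission
    wavelength, mean residue ellipticity, 222/208 nm ellipticity ratio, SVD
    denoising of spectral titration series), thermal-melt processing with
    first-derivative melting-temperature extraction and photomultiplier-voltage
    aggregation flagging, two-state and three-state equilibrium-unfolding fits
    under the linear extrapolation model with sloping baselines, trajectory
    metrics (superposition RMSD, radius of gyration, per-residue RMSF,
    inter-helix distances, salt-bridge occupancy), seeded synthetic-data
    generators with embedded ground truth, and batch reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
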