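Package: nirct
Title: Calibration Transfer for Near-Infrared Spectra with Stability-Based Wavelength Selection
Version: 0.1.0
Authors@R: person("NIRCT", "Developers", email = "nirct@example.org", role = c("aut", "cre"))
Description: Tools for transferring multivariate near-infrared (NIR) calibration
    models between instruments or measurement conditions. Implements a
    stability-analysis feature selection (SAFS) procedure that scores each
    wavelength by the joint Monte-Carlo stability of master and slave partial
    least squares regression coefficients and tunes the selection threshold
    with a genetic algorithm; the classical transfer algorithms slope/bias
    correction (SBC), piecewise direct standardization (PDS), spectral space
    transformation (SST) and orthogonal signal correction (OSC); baseline
    wavelength selectors CARS and SiPLS; SNV and Savitzky-Golay preprocessing;
    SPXY sample-set partitioning and leverage/residual outlier screening; a
    synthetic paired-spectra generator with known ground truth; and a
    benchmark driver producing selector-by-transfer evaluation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
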