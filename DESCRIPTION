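Package: rsomqc
Title: Quality Control for Raster-Scan Optoacoustic Mesoscopy Raw Data
Version: 0.1.0
Authors@R:
    person("RSOM", "QC Maintainers", email = "rsomqc@example.org", role = c("aut", "cre"))
Description: Quality-control scheme for raster-scan optoacoustic mesoscopy
    (RSOM) raw data: suture-reference SNR gating, quantification of vertical
    skin motion from the raw sinogram via melanin-surface segmentation, the
    QASIN motion-quality index (Q_motion = M_std + beta * M_max) with
    simulation-calibrated thresholds, surface-based motion correction,
    simplified dual-band delay-and-sum reconstruction with CNR scoring, and a
    synthetic RSOM forward simulator (skin phantom, suture and point
    measurements, physiological motion models) that makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
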