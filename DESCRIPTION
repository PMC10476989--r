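Package: epidCWP
Title: Automated Chest Wall Position Tracking in EPID Cine Images for
    DIBH Breast Radiotherapy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the chest wall position (CWP) in tangential-field
    electronic portal imaging device (EPID) cine images and in
    megavoltage-windowed digitally reconstructed radiographs (MV DRRs)
    acquired during deep inspiration breath hold (DIBH) breast
    radiotherapy. Three per-row detectors are provided (Canny edge
    outline, in-breast peak intensity, and the first-derivative
    inflection point at the lung-rib junction), aggregated as the median
    and standard deviation over a fixed region of interest. From
    per-beam cine series and a reference DRR the package derives
    intrafraction motion and setup error with clinical tolerance
    flagging, reads and writes DICOM RT Image files, and ships a
    synthetic dynamic thorax-phantom generator (2-D frames, programmed
    cine trajectories and a voxel CT phantom with parallel-ray DRR
    projection) that provides exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
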