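Package: magnetoquant
Title: Quantification of Magnetogenetic Behavior and Neurophysiology Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the readouts of magnetogenetic neuromodulation
    experiments in freely moving mice. Scores open-field keypoint trajectories
    for freezing of gait, ambulation, distance, activity and rotations; maps
    tracked positions onto gaussmeter magnetic-field grids and summarises
    behavior by field-strength bin; computes isosbestic-corrected fiber
    photometry dF/F with epoch means and event-aligned averages; quantifies
    per-ROI fluorescence traces (dF/F0, peak, windowed AUC) for calcium and
    chloride indicators; derives PET %ID/g with cerebellum reference
    normalisation and condition ratios; and counts immunolabelled cells with a
    fixed blur/threshold/size-filter scheme plus DAPI colocalization. A
    synthetic-data module generates every input modality from seeded processes
    with known ground truth so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pracma,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
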