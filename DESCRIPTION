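Package: fourcv
Title: Automated Four-Chamber-View Biometry and Screening from Fetal
    Cardiac Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fetal cardiac screening biometry from per-structure
    segmentation masks of the four-chamber view (4CV): the cardiothoracic
    area ratio (CTAR) by pixel counting, the cardiac axis from the
    ventricular-septal principal axis and the thorax-bisecting line through
    the spine centroid, apex-side and fetal-presentation inference,
    heart/descending-aorta laterality (solitus vs inversus), and the
    cardiac-position landmark (point P) in a thorax-centred, tilt-corrected,
    chord-normalised coordinate frame.  Parameters are classified against
    guideline normal ranges (CTAR < 35%, axis 45 +/- 20 degrees, point P in
    a reference box) and aggregated from image to video to patient-level
    screening calls.  Includes a synthetic phantom generator with analytic
    ground truth standing in for a segmentation front end, segmentation and
    screening metrics (Dice, MAE, ROC/AUC, Youden operating point), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    pracma,
    igraph,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
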