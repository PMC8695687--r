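Package: electrolocate
Title: Localization, Geometry Correction and Anatomical Labeling of
    Intracranial Electrodes from Postimplant CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for localizing intracranial electrode contacts
    (ECoG grids/strips and SEEG depth leads) in postimplant CT volumes.
    Detects contacts as bright connected components with a stability-based
    adaptive threshold search and intensity-weighted centroids; builds brain
    and smoothed projection surfaces from gray/white tissue-probability maps;
    corrects contact geometry (brain-shift projection onto the smoothed
    surface for grids and strips, iterative intercontact-spacing correction
    for depth leads); classifies contacts as gray or white matter with a
    rank-sum test on tissue probabilities; and assigns anatomical atlas
    labels through non-linear deformation fields between patient and MNI
    space. Includes a synthetic head-phantom generator (CT, tissue maps,
    deformation fields, toy atlas, ground truth) so the full pipeline is
    testable without patient data, and channel-sorted tabular export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr
Config/testthat/edition: 3
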