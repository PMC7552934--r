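Package: choroquant
Title: Choroidal Thickness and Vascularity Index from Widefield OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated quantification of the choroid from widefield
    swept-source optical coherence tomography (OCT) volume scans. Given a
    volume and choroidal segmentation surfaces, the package computes
    magnification-corrected extended ETDRS grid maps and regional values of
    choroidal thickness (ChT) and the choroidal vascularity index (CVI),
    using liquid-norm intensity normalization and Niblack local adaptive
    thresholding with a circular window to separate vessel lumina from
    stroma. Also included are the repeatability statistics used in
    choroidal biometry (quartile-based coefficient of variation, Spearman
    rank correlation, and a nonparametric coefficient of repeatability for
    intersession designs), and a seeded synthetic phantom generator with
    ground-truth lumen masks for end-to-end validation without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
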