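Package: digibiopsy
Title: Segmentation-Robustness Analysis of Radiomic Features with Digital
    Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how robust intensity and texture radiomic features
    are to imprecise "digital biopsy" segmentations of lung nodules in CT
    volumes. Provides grid-aware NIfTI/NRRD volume and mask handling,
    physically-sized spherical morphological erosion and dilation to
    simulate conservative and aggressive readers, a 94-feature first-order
    and texture bank (GLCM, GLRLM, GLSZM, GLDM, NGTDM), intersection-over-
    union overlap and two-way absolute-agreement intraclass correlation
    (ICC A-1) statistics, synthetic CT nodule phantoms with calibrated
    painted-biopsy simulation, and end-to-end robustness reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
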