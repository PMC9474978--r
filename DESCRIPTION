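Package: radiomaps
Title: Parametric Radiomic Feature Maps for VOI-Size-Robust CT Texture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the size of a volume of interest (VOI)
    confounds CT radiomic features, and how computing features as parametric
    maps on a fixed block grid removes that confounding. Simulates seeded
    series of homogeneous CT-like phantom scans, computes 93 first-order and
    grey-level texture-matrix features (GLCM, GLRLM, GLSZM, GLDM, NGTDM) from
    arbitrary voxel masks, converts volumes into per-feature parametric maps
    with a fixed block edge, reads features back through spherical VOIs in
    both conventional and map mode, and quantifies cross-size stability with
    exact Mann-Whitney U tests (Bonferroni-adjusted) and overall concordance
    correlation coefficients (OCCC).
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
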