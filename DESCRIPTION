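Package: dlthick
Title: Registration-Based Cortical Thickness from Tissue Probability Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cortical thickness from soft white-matter and
    gray-matter probability volumes, downstream of any tissue segmenter.
    Probability maps are hardened into a DiReCT-ready hard segmentation and
    boundary-sharpened maps, the white/gray interface is propagated
    diffeomorphically toward the pial surface to obtain a voxel-wise
    thickness map, and thickness is reduced to parcellation-wise averages.
    Includes an independent Laplacian thickness solver for cross-validation,
    scan-rescan reproducibility and atrophy-rate statistics, and synthetic
    phantoms with analytically known thickness for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
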