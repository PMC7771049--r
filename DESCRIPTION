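Package: veinfuse
Title: Multimodal MR Fusion and Validation of Superficial Cortical Vein
    Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combining a structural MR volume with a venous
    MR-angiography volume into a threshold-labelled data set, quantifying the
    geometric error of interactive rigid co-registration by masked Monte-Carlo
    sampling, validating reconstructed superficial cortical veins against
    annotated surgical photographs with a five-category scheme, and measuring
    bridging-vein anatomy at the superior sagittal sinus (counts per sinus
    third, confluence angles, hemispheric drainage types). A synthetic phantom
    generator produces every input the pipeline consumes, with ground truth
    for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    pracma,
    igraph,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
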