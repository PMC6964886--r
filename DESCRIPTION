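Package: PeelStack
Title: Surface-Guided Layer Extraction and Quantification for Confocal
    Z-Stacks of Plant Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments the contoured outer surface of a plant tissue in a
    multi-channel confocal Z-stack, extracts the voxel layer lying a
    user-defined offset and depth below that surface (e.g. epidermis
    versus mesophyll), renders Z-sum or maximum projections of the peeled
    layer, and quantifies per-layer channel signal.  Also implements the
    standard phenotype quantification formulas used alongside such
    imaging: stomatal index and density from epidermal cell counts,
    relative gene expression by the delta-delta-Ct method, and
    dual-luciferase reporter normalization.  Includes a ground-truthed
    synthetic phantom generator for validating every pipeline stage and a
    command-line interface for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
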