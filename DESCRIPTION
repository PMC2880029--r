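Package: hexbead
Title: Bead-Level Quality Assessment and Simulation for BeadArray Section Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for working with raw Illumina-style BeadArray section
    images at the bead level: hexagonal-lattice chip geometry and bead
    neighbour graphs, Illumina-dialect feature-intensity extraction
    (image sharpening, fractionally weighted 4x4 foreground, local 17x17
    five-lowest-pixel background with robust alternatives), grid
    registration diagnostics and automatic re-mapping of scrambled
    bead-type annotation, spatial artefact detection (non-decoded bead
    clusters, encroaching bright features, abnormally low background
    pixels, neighbouring same-type "twin" probes with analytic and
    permutation nulls), an idealized-bead digitization study linking
    sub-pixel bead location to measured intensity, robust two-pass
    bead-type summarization with detection calls against negative
    controls, and a ground-truthed synthetic section generator that
    renders hexagonal grids of fluorescent beads to 16-bit TIFF with
    injectable artefacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
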