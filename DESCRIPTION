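Package: bactrack
Title: Semi-Automated Segmentation, Tracking and Lineage Analysis of
    Bacterial Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable platform for quantitative analysis of time-lapse
    microscopy movies of difficult-to-segment bacteria such as mycobacteria,
    which grow in closely packed microcolonies without visible edges between
    neighbouring cells.  Provides translational frame registration, a
    skeleton-guided propagation algorithm that tracks each cell's region of
    interest from frame to frame (Sobel edge detection, IsoData
    auto-thresholding, Zhang-Suen thinning, constrained pole elongation and
    disk reconstruction), binomial lineage bookkeeping with user-annotated
    division events, configurable per-cell fluorescence measurements with
    background correction, a single-file SQLite datastore with SQL querying
    and CSV export, lineage-tree visualization mapping two measured variables
    to branch width and colour, and a ground-truthed synthetic movie
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    EBImage,
    png,
    tiff,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
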