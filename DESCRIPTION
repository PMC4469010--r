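Package: ctbrush
Title: Selective-Ray MART Tomography with a Brush-Driven Acquisition Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless engine for brush-driven sparse-view computed tomography.
    A "CT brush" is a star of equally spaced rays through a movable central
    point; as the brush is stroked over a hidden image, each previously unused
    ray is measured once (pseudoprojection) and applied as a multiplicative
    algebraic reconstruction technique (MART) update, with deduplicated
    unique-ray dose accounting. Includes closed-form dose formulas for
    all-pixel star coverage, a procedural phantom ("level") generator with
    difficulty rules, scripted gameplay sessions with mouse-path
    interpolation, a bit-exact writer and parser for the line-oriented
    tracking-log grammar, full-view MART emulation, and a command-line
    interface for reconstruction, dose tables, phantom export and scripted
    play.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    graphics,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
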