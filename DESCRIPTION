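Package: woundtrack
Title: Quantification of Leukocyte Migration Toward Tail Wounds from Cell Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify leukocyte (neutrophil and macrophage)
    migration in wound-recruitment assays from per-frame 2D cell tracks.
    Implements per-track statistics (net and total displacement, meandering
    index, mean speed), wound-relative measures (shortest distance to a
    wound-edge polyline, distant versus local-resident classification,
    arrival and retention within a capture radius, recruited-cell counts),
    cohort mean squared displacement anchored at track start with a
    persistent-random-walk (Fuerth) fit yielding intrinsic speed, persistence
    time and cell diffusivity, anteroposterior velocity projection and its
    smoothed time course, unpaired two-sample group comparison, a synthetic
    correlated-random-walk cohort generator with chemotactic bias and wound
    arrest, and a minimal Viterbi-style global track linker with a swap
    repair pass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
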