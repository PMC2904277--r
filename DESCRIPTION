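Package: osmotrap
Title: Osmotic Fluid Trapping in the Small Bowel and Sodium Homeostasis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models intermittent osmotic trapping of water in the small bowel
    after ingestion of hyperosmolar drinks, notably high-fructose corn syrup
    (HFCS) soft drinks, and the downstream regulatory loop: a transient
    circulatory volume deficit drives aldosterone and ADH secretion, colonic
    sodium-absorption capacity adapts over days to the trailing hormone
    exposure, and sustained sodium retention expands the extracellular fluid
    compartment, raising a mean-arterial-pressure surrogate.  Provides an
    ideal-solution osmolarity calculator for beverage compositions, the static
    trapping model (trapped volume, absorbable volume, fast/slow partition and
    absorption timecourse), a deterministic event-driven compartmental
    simulator for multi-day ingestion schedules, a grid-search fit of the
    colon-adaptation parameters, and a seeded virtual-cohort generator for
    dose-response experiments with heterogeneous fructose absorption.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
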