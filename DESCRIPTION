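Package: classfx
Title: Drug-Class Adverse Event Signal Detection from Literature Co-Mentions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pharmacovigilance signals at the pharmacologic-class
    level from MeSH-indexed citation records. Extracts drug and adverse-event
    mentions via indexing qualifiers, normalizes drug terms to ingredients and
    ATC-style classes, rolls adverse-event terms up to second-level hierarchy
    classes, computes proportional reporting ratios (PRR) over article-level
    2x2 contingency tables at drug and class resolution, and classifies each
    (drug class, adverse event) pair as a class effect or not by optimal
    one-dimensional two-cluster partitioning of member log-PRRs followed by
    Welch's t-test. Includes hierarchically clustered heat-map matrix export
    at three resolutions and a seeded synthetic-corpus generator with planted
    class and subset effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
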