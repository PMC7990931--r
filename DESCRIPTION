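Package: orcascape
Title: Isoscape-Based Geographic Assignment of Killer Whales from Tooth and Bone Oxygen Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers killer whale geographic distributions from oxygen isotope
    ratios in dentine phosphate and bone. Inverts a published linear calibration
    between tissue delta-18O and source seawater delta-18O with first-order
    Taylor (delta-method) error propagation, adjusts structural-carbonate
    delta-13C for the oceanic Suess effect to a common reference year, assigns
    individuals to sea-surface delta-18O isoscape cells encompassed by their
    confidence intervals, and provides the accompanying cohort statistics:
    tie-corrected Kruskal-Wallis, Dunn's post-hoc comparisons with
    Benjamini-Hochberg adjustment, UPGMA clustering, and within-tooth
    growth-layer-group variation indices. Includes synthetic isoscape and
    specimen generators for end-to-end validation of the assignment procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
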