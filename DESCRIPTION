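Package: CrambeDerep
Title: Rule-Based Dereplication of Crambe crambe Guanidine Alkaloids from
    LC-MS/MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation pipeline for the guanidine alkaloids of the
    Mediterranean sponge Crambe crambe from centroided LC-MS/MS data.
    Provides elemental-formula arithmetic under the exact mass conventions
    used for reporting these compounds (multiply charged ion deconvolution,
    ppm errors referenced to the full cation mass), parametric homologue
    libraries for the crambescin A/B/C sub-families with sub-family-specific
    diagnostic fragmentation rules, a closed crambescidin entry list with
    marker-ion logic, feature assembly and charge inference from isotope
    envelopes, intensity-based discrimination of isobaric crambescin B/C
    pairs, report generation in the conventional table layout, a minimal
    feature-based molecular-networking stage (modified cosine), and a
    seeded synthetic-run generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
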