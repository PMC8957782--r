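Package: cavscreen
Title: Family-Based Rare-Variant Screening and T-Type Calcium Channel
    Biophysics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens annotated family whole-genome variant calls for rare,
    damaging variants in voltage-gated calcium-channel genes under dominant
    and recessive inheritance models, including compound heterozygotes in
    trios and quads, and characterizes T-type (Cav3.2) channel biophysics
    from whole-cell voltage-clamp recordings: modified-Boltzmann fits of
    current-density-voltage relations, steady-state inactivation fits,
    activation kinetics (time to peak, exponential decay) and charge
    transfer, with per-genotype summaries and one-way ANOVA group
    comparisons. A Hodgkin-Huxley-style gating simulator generates synthetic
    whole-cell recordings under the standard activation and inactivation
    voltage protocols, and a toy-cohort generator emits annotated VCF/PED
    fixtures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
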