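Package: ribolim
Title: Growth Rate-Dependent Translation Efficiency and Free-Ribosome
    Limitation in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of growth rate-dependent translation in
    Bacillus subtilis. Implements spike-in anchored mRNA quantification,
    reporter translation-efficiency pipelines, joint inference of a latent
    free-ribosome trajectory together with per-transcript Michaelis-Menten
    constants, a mechanistic three-step translation-initiation model with its
    quasi-steady-state reduction, and a whole-proteome ribosome-conservation
    solver. Ships a synthetic-data generator that emulates the study design
    (eight-condition growth-rate grid, reporter TIR library, spike-in arrays,
    paired transcriptome/proteome panels) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
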