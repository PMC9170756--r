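Package: silacpatterns
Title: Pattern Analysis for Triple-SILAC Fatty-Acid Proteomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for triple-label SILAC quantitative proteomics
    experiments that compare a palmitic-acid (PA) treatment and a combined
    fatty-acid treatment (PA+OA or PA+EPA) against a common vehicle control.
    Harmonizes heavy/medium and light/medium channel ratios across forward and
    reverse labeling replicates, applies the quantified-at-least-twice filter,
    calls differentially expressed proteins at a two-fold threshold with
    one-sample t statistics for volcano output, classifies every protein into
    one of nine fatty-acid response patterns (P1-P9), performs hypergeometric
    gene-set over-representation analysis with count/factor/p filters, and
    intersects transcription-factor target predictions with pattern groups.
    Includes a seeded synthetic-data generator that emulates triple-SILAC
    ratio tables with planted response patterns, multiplicative ratio noise,
    and per-replicate missingness, so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
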