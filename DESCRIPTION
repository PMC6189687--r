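Package: rgstab
Title: Reference-Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects stable reference (housekeeping) genes for RT-qPCR
    normalization from a matrix of quantification cycles (Cp/Ct). Implements
    the BestKeeper index and correlation ranking, the geNorm expression
    stability measure M with stepwise exclusion and pairwise variation
    V(n/n+1), a NormFinder-style model-based decomposition of intra- and
    inter-group variation, the comparative delta-delta-Ct descriptive
    statistic, and a consensus ranking by the geometric mean of method ranks.
    Also provides dilution-series standard-curve fitting with amplification
    efficiency estimation, reference-normalized target-gene fold-change time
    courses, a seedable synthetic Cp-data generator with ground-truth
    stability labels, and a reproducible end-to-end pipeline writing tabular
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
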