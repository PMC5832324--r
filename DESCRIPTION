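Package: patternDE
Title: Directional Pattern Clustering of Treatment Responses with Exact
    Nonparametric Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifies gene responses to two chemical treatments (plus a
    dose series) into directional three-digit patterns using exact
    nonparametric tests: a permutation Kruskal-Wallis screen with
    Monte-Carlo exact p-values, exact Wilcoxon rank-sum post hoc tests
    (full enumeration or the shift algorithm, with mid-rank ties), and
    Benjamini-Hochberg false-discovery-rate control. Patterns are
    aggregated into clusters and meta clusters, responses are classified
    for genotype (Nrf2) dependence and dose-maximal behaviour, and a
    synthetic-data generator with planted effect classes supports
    parameter-recovery testing. Includes Pfaffl-method relative qPCR
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
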