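Package: pollinet
Title: Inference for Quantitative Plant-Flower-Visitor Interaction Networks
Version: 0.1.0
Authors@R: person("pollinet", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative bipartite flower-visitation networks:
    weighted network metrics (connectance, weighted NODF nestedness,
    interaction evenness, H2' specialization, dependence asymmetry, Chao2
    sampling completeness), interaction-probability matrices encoding
    neutral (abundance) and biological-constraint (phenology, morphology)
    hypotheses, multinomial-likelihood AIC model ranking,
    probability-constrained null ensembles with percentile confidence
    intervals, a nectar-robber filter, and a synthetic-community generator
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
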