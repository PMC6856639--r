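Package: nicheweb
Title: Grinnellian and Eltonian Niches of Plants and Pollinators and Their
    Interconnectedness in Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three niche types for the taxa of a bipartite
    plant-flower-visitor community: the realized Grinnellian niche
    (abundance-weighted occupancy of a standardized temperature-by-aspect
    space), the fundamental Eltonian niche (morphological trait space), and
    the realized Eltonian niche (species-level roles in the interaction
    network: degree, species strength, betweenness, partner diversity, node
    specialization index and complementary specialization d').  Niche
    position is summarized as marginality (distance to the trophic-level
    centroid) and niche size as a dynamic-range-box volume.  The
    interconnectedness of the niche types is assessed with
    significance-filtered, r-squared-weighted correlation networks
    (modularity and eigenvalue-variance integration), and the environmental
    assortment of interactions is tested by comparing the
    interaction-weighted mean edge length in niche space against a
    Patefield fixed-margin null model.  A synthetic-community generator
    with known ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
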