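Package: miconet
Title: Soil Microbiome Co-Occurrence Networks, Diversity and Pathogen Guilds
Version: 0.1.0
Authors@R:
    person("miconet", "developers", email = "miconet@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for factorial soil-microbiome experiments:
    ensemble co-occurrence network inference over taxon count tables using
    five association measures (Spearman, Pearson, symmetrized Kullback-Leibler
    dissimilarity, Bray-Curtis dissimilarity, mutual information) with
    permutation null models and Brown's-method p-value combination; network
    topology indices and hub detection; alpha/beta diversity (rarefaction,
    Chao1, Shannon, Bray-Curtis, PCoA) with PERMANOVA and ANOSIM permutation
    tests; fungal trophic-guild pathogen scoring; balanced factorial
    general-linear-model tests and correlation screens; and a
    Dirichlet-multinomial synthetic community generator with planted
    associations and treatment effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
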