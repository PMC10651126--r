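Package: pdscape
Title: Spatial Phylogenetic Diversity of Continental Floras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the phylogenetic diversity of regional
    floras on dated ultrametric phylogenies. Implements Faith's PD, mean
    pairwise distance (MPD), rarefaction-standardized PD and MPD, relative
    phylogenetic diversity (RPD), and the PD deviation from species
    richness (PD_dev); PD-through-time curves with windowed accumulation
    rates; branch-length phylogenetic beta diversity (Sorensen and Simpson)
    through time; climate matching of spatial units by principal components
    of six bioclimatic variables; comparative statistics (ANCOVA with a
    region main effect, spatial autoregressive error regression with a
    residual contrast, t tests, Spearman correlation); and a synthetic-world
    generator that produces two-continent floras shaped by continental
    split, lineage extinction, immigration, and recent radiations, with
    stored ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    MASS,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    picante,
    optparse
Config/testthat/edition: 3
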