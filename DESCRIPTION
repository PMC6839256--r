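Package: hookmorph
Title: Geometric Morphometrics of Parasite Attachment Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based shape analysis of hook-like attachment structures
    (cymothoid isopod dactyli) and their relationship to parasitic attachment
    mode, size allometry and shared ancestry. Implements Generalised Procrustes
    Analysis with semi-landmark sliding by the Procrustes-distance criterion,
    digitisation-repeatability and outlier screening, principal component and
    phylogenetic principal component ordination with phylomorphospace
    projection, multivariate shape regression evaluated by the residual
    randomisation permutation procedure (RRPP), and phylogenetic generalised
    least squares with REML estimation of Pagel's lambda. Includes a synthetic
    landmark-data generator (TPS, metadata, Newick) emulating the sampling
    design of the motivating study, plus TPS file input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    phytools,
    jsonlite
Config/testthat/edition: 3
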