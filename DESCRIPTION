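Package: imagetx
Title: Imaging Transcriptomics of Brain Functional Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links coordinate-based neuroimaging meta-analysis to cortical
    gene expression. Implements effect-size (Hedges g) reconstruction of
    study maps from peak tables, DerSimonian-Laird random-effects voxel-wise
    combination with heterogeneity, small-study and jackknife diagnostics,
    Allen-Human-Brain-Atlas-style expression preprocessing (intensity-based
    probe filtering, RNA-seq-guided probe selection, scaled robust sigmoid
    normalization, differential-stability gene filtering), sphere-sampled
    gene-wise spatial correlation with Benjamini-Hochberg control, a
    variogram-matched spatially autocorrelated surrogate permutation test,
    and downstream gene-set overlap, hub-gene and behavioral-relevance
    characterization. A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
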