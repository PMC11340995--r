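Package: connharmony
Title: Harmonization of Structural Connectomes Across Diffusion MRI Acquisition Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes acquisition-parameter bias from structural connectomes
    (streamline-count connectivity matrices) with a per-connection linear
    model in spatial resolution, maximal b-value, and their interaction.
    Fitted on traveling or independent subjects, the model corrects unseen
    connectomes from one acquisition setting to another by an additive
    per-edge adjustment followed by integer rounding and clamping at zero.
    Includes the weighted nodal graph metrics (strength, closeness
    centrality, clustering coefficient, local efficiency), mass-univariate
    two-way ANOVA with Bonferroni correction for quantifying acquisition
    effects on edges and nodes, fingerprinting/identifiability evaluation
    (identification accuracy and differential identifiability), train/test
    PCA embeddings, and a seedable synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
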