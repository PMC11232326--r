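Package: mlrcomm
Title: Metabolite-Ligand-Receptor Cell-Cell Communication Inference
Version: 0.1.0
Authors@R: person("mlrcomm", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers metabolite-mediated cell-cell communication from
    single-cell expression data. Extracellular metabolite availability per
    sender cell type is estimated from enzyme (producer/consumer) and
    transporter expression, combined with receptor-complex expression in
    receiver cell types through a Euclidean-norm score, and assigned
    empirical significance by cell-label permutation. Includes a
    tab-delimited knowledgebase data model with validation, summarization
    and cross-species ortholog mapping, synthetic data generators (null and
    planted-signal), a results serializer, a bubble-plot visualization and
    a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    ggplot2,
    methods,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
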