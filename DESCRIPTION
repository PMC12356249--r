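Package: sstactivity
Title: Activity-Based Classification and Learning Plasticity of SST Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free classification of somatostatin (SST) interneuron
    subtypes from two-photon calcium imaging, and quantification of their
    learning-related response plasticity. Provides trace preprocessing
    (neuropil correction, motion-shift interpolation and trial rejection,
    trial-locked and sliding-percentile dF/F baselines), a first-order
    activity-feature grid (response probability, evoked-response metrics,
    spontaneous event detection by peak prominence), clustering-informed
    heuristic subtype assignment on a neighbour-graph embedding with
    silhouette-based model selection, confusion-matrix evaluation against
    genetic labels, training-epoch fold-change and group statistics, home-cage
    behavioural performance metrics, and a synthetic session generator with
    ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    data.table,
    jsonlite,
    kernlab,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
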