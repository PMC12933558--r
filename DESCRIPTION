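Package: ptmlri
Title: Ligand-Receptor Interaction Inference Refined by Post-Translational
    Modification Evidence
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers ligand-receptor interactions (LRIs) and downstream pathway
    activity from two-cluster differential proteomics, then refines each
    inference with site-level post-translational modification (PTM) evidence.
    Candidate LRIs come from a curated ligand-receptor table; receptor targets
    are derived by pathway-restricted traversal of a partially directed
    intracellular network; pathway significance uses a Monte-Carlo calibrated
    rank statistic of sorted target p-values. Site-level PTM changes, normalized
    by parent-protein abundance, are matched against a direction-aware
    PTM-pathway reference (built by diffing modification states across
    biochemical reactions) and scored for concordance, allowing PTM evidence to
    confirm, rescue, or contradict expression-based inferences. Includes
    cross-PTM-type crosstalk analysis, PhosphoSitePlus flat-file annotation, a
    synthetic-data generator with planted signal for end-to-end validation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
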