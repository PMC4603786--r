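Package: drugcast
Title: Ligand-Homology Virtual Target Screening and Drug Side-Effect Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-scale virtual target screening of small molecules by
    ligand homology: compounds are scored against protein targets through the
    modified Tanimoto (mTC) similarity to channel-partitioned template-ligand
    sets, with benchmark-mode exclusion of near-identical ligands and homologous
    template proteins. Protein-target side effects are inferred deterministically
    from drug side-effect tables by an intersection rule and propagated back to
    drugs by union over their targets; a killing index counts targets carrying
    serious side effects. Includes ligand-binding-pocket extraction from holo
    structures, a sequence-order-dependent triplet alignment of structures onto
    pockets, benchmark metrics (per-drug ROC AUC, enrichment factors,
    precision/recall cutoff curves), and a synthetic-world generator with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
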