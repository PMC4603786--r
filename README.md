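# drugcast

Ligand-homology virtual target screening and drug side-effect inference.

## What problem this solves

Most proteins in a proteome have no experimentally characterised
small-molecule binders, and most drugs have only one or a few annotated
targets, so neither classic ligand-based methods (which need known binders
of the target) nor docking (which needs a high-resolution structure) can
rank an arbitrary compound against an arbitrary protein. drugcast is for
computational chemists and drug-repurposing researchers who need exactly
that ranking: a target protein *inherits* template ligands from
evolutionarily related template proteins whose binders are known, and a
query compound is scored against the target by chemical similarity to the
inherited ligands.

The core score is the modified Tanimoto (mTC). Compounds are 1024-bit
fingerprints (Open Babel FP2, path-based), TC is the Tanimoto coefficient
|A∩B|/|A∪B|, and for a query *q* against a target's template ligands *L_l*
(with δ_l = 1 when *L_l* is an experimentally confirmed binder of the
target itself):

    mTC = max_l [ (1 − w)·TC(L_l, q) + w·δ_l ],   w = 0.1

computed per evidence channel (holo PDB, DrugBank-annotated virtual holo
templates, ChEMBL-annotated ones) with the best channel kept. Hits with
mTC ≥ 0.90 are flagged as predicted interactions. Benchmark mode removes
information leaks before scoring: template ligands with TC > 0.99 to the
query and ligands inherited from source proteins with sequence identity
above a cutoff (95% or 30%) to the target.

On top of screening, protein-target side effects are inferred from
drug–side-effect tables by an intersection rule (a target bound by k > 1
annotated drugs gets the side effects they all share), drug side effects
are predicted as the union over the drug's targets, and the *killing
index* κ counts a drug's targets carrying serious side effects (death,
cancer, heart failure, ...). Benchmark machinery — per-drug ROC AUC,
enrichment factors EF_x with ceiling top-fraction counting,
precision/recall-versus-cutoff curves — and a synthetic-world generator
with planted ground truth round out the package. The pocket module
extracts ligand-binding pockets from holo structures (4.5 Å heavy-atom /
8 Å Cα rules) and aligns Cα structures onto pockets by a
triplet-seeded, iteratively refined rigid superposition.

## Worked example

```r
library(drugcast)

world <- make_world(synth_params(), seed = 7)
#> Synthetic world (seed 7): 40 targets, 25 drugs, 246 template ligands,
#> 86 planted interactions

hits <- screen_proteome(
  world$template_ligands, world$compounds$fingerprint[[1]],
  fingerprints = world$compounds, targets = world$targets$target_id,
  query_id = "D001", mtc_cutoff = 0.90
)
glance(hits)
#>   query_id n_targets top_mtc     w mtc_cutoff n_predicted
#> 1 D001            40       1   0.1        0.9           5

truth <- world$planted_truth$target_id[world$planted_truth$drug_id == "D001"]
auc_per_drug(hits, truth)      # 1       — every true target outranks every decoy
enrichment_factor(hits, truth, x = 0.1)
# 8 — the top-10% window holds ceiling(0.1·40) = 4 of the 5 truths: (4/5)/0.1

glance(consistency_test(world$interactions, world$drug_se))
#>   mode        precision recall n_drugs_with_predictions n_drugs
#> 1 consistency         1  0.933                       25      25
glance(jackknife_test(world$interactions, world$drug_se))
#>   mode      precision recall n_drugs_with_predictions n_drugs
#> 1 jackknife     0.789  0.765                       24      25

tse <- infer_target_side_effects(world$interactions, world$drug_se)
head(killing_index(world$interactions, tse), 3)
#>   drug_id kappa n_targets
#> 1 D001        2         5
#> 2 D002        1         2
#> 3 D003        1         4
```

Reading the numbers: this is a zero-noise synthetic world, so the query's
template copies are identical to it; its 5 true targets all score mTC = 1
and are exactly the 5 flagged predicted interactions. The consistency test re-predicts each
drug from target side effects inferred from *all* drugs; the intersection
construction makes false positives impossible, hence precision exactly 1,
while recall < 1 reflects terms not shared by any co-binder. The
jackknife leaves the evaluated drug out and is the honest measure of
predictive power. D001's κ = 2 means two of its five targets carry at
least one serious side effect.

Screening a real molecule starts from SMILES instead:
`compute_fingerprint("CCO")` or `read_smiles()` +
`fingerprint_compounds()`. A thin command-line wrapper is installed at
`inst/cli/drugcast.R` (`synth`, `screen`, `sidefx` subcommands).

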