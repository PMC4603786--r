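---
title: "Ligand-homology target screening and side-effect inference: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-homology target screening and side-effect inference: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugcast)
library(dplyr)
```

## The problem

Most proteins in a proteome have no experimentally known small-molecule
binders, and most drugs have only a handful of annotated targets. drugcast
implements a ligand-homology strategy for working in that regime: a target
protein inherits "template ligands" from evolutionarily related template
proteins whose binders are known, and a query compound is scored against the
target by its chemical similarity to those inherited ligands. On top of the
resulting drug--target predictions, protein-target side effects are inferred
deterministically from drug--side-effect tables and propagated back to
drugs, and a *killing index* summarises how many of a drug's targets carry
serious side effects.

## The mTC score

Compounds are 1024-bit binary fingerprints; chemical similarity is the
Tanimoto coefficient $TC(a,b) = |a \wedge b| / |a \vee b|$ (defined as 0
when both fingerprints are empty, so featureless molecules never break a
ranking). Each target carries template-ligand sets from three evidence
channels -- holo PDB structures, and virtual holo templates annotated with
DrugBank or ChEMBL ligands. For a query $q$ and template ligands $L_l$ with
true-ligand indicator $\delta_l$ (1 when the ligand is an experimentally
confirmed binder of the target itself),

$$\mathrm{mTC} = \max_l \left[(1-w)\,TC(L_l, q) + w\,\delta_l\right],$$

computed per channel, with the best channel kept. The weight $w = 0.1$
(default) up-weights confirmed binders: an identical true ligand scores
exactly 1, $w = 0$ reduces to plain maximum Tanimoto, and the score always
stays in $[0,1]$. An empty template set scores 0 rather than being
unrankable, so every target appears in every ranking -- a requirement for
per-drug AUCs over a fixed library. Ranking ties break by ascending target
identifier, making screens deterministic and invariant to library order.

The fingerprint scheme is Open Babel's FP2 (hashed linear fragments,
path-based), with SMILES canonicalized before hashing; the scheme is
recorded in the fingerprint attribute, and every downstream score depends
only on the bit-vector contract, not on the hashing details. Predicted
interactions are hits with mTC at or above the cutoff (default 0.90,
inclusive).

## Benchmark-mode exclusions

Realistic benchmarking must not let the answer leak through the template
library. With an `exclusion_policy(enabled = TRUE)`, before scoring a
(query, target) pair we remove: template ligands with $TC > 0.99$ to the
query (strict inequality -- effectively the same molecule), template
ligands whose source template protein exceeds a sequence-identity cutoff to
the target (95% for the standard benchmark, 30% for the remote-homology
one; strict inequality), and any template-ligand record that is the query
itself annotated on the target. Sequence identity is computed from one
global Needleman--Wunsch alignment (BLOSUM62, gap open 11, extend 1) as
identical positions over the shorter sequence length -- the common
convention for identity-threshold filters; the scoring scheme is fixed but
the cutoffs are arguments. A source protein with no available sequence
leaves its ligands in place with a warning rather than silently excluding
them. `audit_exclusions()` re-checks any screen post hoc.

## Side-effect inference and the killing index

The inference rule is purely set-theoretic. If a target binds $k > 1$ drugs
with side-effect records, the target's side effects are the intersection of
those drugs' term sets; targets with fewer than two annotated binders or an
empty intersection are omitted. A drug's predicted side effects are the
union over its targets' inferred sets. Terms are free strings compared
case-insensitively after whitespace normalization; no ontology mapping is
attempted. Drugs that appear in the interaction table but not in the
side-effect table are ignored for inference -- treating them as empty sets
would annihilate every intersection they touch.

Two benchmarks probe the rule. The *consistency test* builds the target map
from all drugs and re-predicts each drug from it; because every term
attributed to a target is carried by all of its supporting drugs, every
prediction is a subset of the drug's known set -- zero false positives, by
construction (this is asserted, not assumed, in the test suite). The
*jackknife test* rebuilds the map with the evaluated drug's record removed,
measuring genuine predictive power. Macro averages are taken over drugs
with at least one predicted term and that count is reported; the
zero-included averages are emitted alongside, since which convention a
summary uses materially changes the numbers.

The killing index $\kappa$ of a drug counts its targets whose inferred set
contains at least one of eight serious terms (death, sudden death, sudden
cardiac death, cardiac death, cancer, hemorrhagic strokes, heart failure,
congestive heart failure; extensible). It counts targets, not terms: a
target carrying both "death" and "cancer" contributes 1, so $\kappa$ never
exceeds the drug's target count. `kappa_fraction_curve()` relates $\kappa$
to a withdrawn/illicit/investigational flag by the fraction of flagged
drugs among those with $\kappa \ge t$.

## Benchmark metrics

`auc_per_drug()` is the rank-based (Mann--Whitney) AUC with ties counted
one half; degenerate truth (none or all of the library) gives `NA` rather
than a fabricated value. `enrichment_factor()` uses ceiling rounding for
the top fraction -- the top 1% of 3,576 targets is 36 entries -- so
$EF_x \in [0, 1/x]$ with $EF_1 = 1$ for any ranking.
`precision_recall()` returns `NA` for undefined quantities (no predictions,
empty truth), never 0, and `cutoff_curve()` averages per-drug precision and
recall only over drugs that still have predictions at each cutoff,
reporting that count: as the cutoff passes a drug's best score the drug
drops out of the average, which is what produces the characteristic
high-cutoff drop in averaged precision.

Because interaction truth tables are incomplete, measured precision is
*observed* precision: a correct prediction missing from the labels counts
as a false positive. `observed_precision_by_truth_count()` bins per-drug
precision by the number of known targets; with labels hidden at rate $1-p$
a perfect predictor shows observed precision near $p$, and drugs with many
known targets suffer least. The synthetic generator's
`truth_completeness` parameter reproduces exactly this mechanism.

## Pocket extraction and structure--pocket alignment

A pocket model of a holo template is the ordered C$\alpha$ trace of
residues near the bound ligand: any residue with a heavy atom within 4.5 Å
of a ligand heavy atom, plus any residue whose C$\alpha$ lies within 8 Å of
a ligand heavy atom. Both cutoffs are arguments; coordinates are Å
throughout and residue numbering is 1-based chain order.

Alignment of a target C$\alpha$ structure onto a pocket is seeded by
exhaustive comparison of sequence-order-dependent C$\alpha$ triplets: a
(target, pocket) triplet pair is admissible when each of the three internal
distances agrees within 1 Å ("within 1 Å" is read per distance, not as an
aggregate). Each admissible seed is superposed by a least-squares rigid
(Kabsch) fit -- proper rotations only, degenerate (collinear) point sets
rejected -- the alignment is grown by pairing residues within 1 Å of each
other, re-superposed on the grown set, and iterated until the aligned set
stops changing (cap 100 iterations, keeping the best iterate if an
oscillation is cut). The best fixed point over all seeds wins.

Two numerical choices matter here. First, the growth step pairs residues by
an order-preserving dynamic program that maximizes the number of pairs and
then minimizes total distance. A simpler one-pass greedy sweep was tried
first and proved fragile: on chains that fold back near the pocket, an
early off-pocket residue can capture the first pocket residue, after which
order preservation forces a register shift and the refinement converges to
a visibly suboptimal fixed point (correct residues, RMSD ~0.3 Å instead of
0 on a rigid copy). The DP costs $O(nm)$ per iteration and removes the
failure mode. Second, triplet enumeration is $O(n^3 m^3)$ unbounded, so
target triplets are capped at a 30-residue sequence span, seeds whose
superpositions round to the same transform are deduplicated, and seeds are
refined in order of triplet-distance agreement with a 400-seed cap; all
caps are arguments and `max_span = Inf, max_seeds = Inf` recovers the
exhaustive search.

The alignment score is
$\sum_i \left[ 1/(1 + (d_i/d_0)^2) + c \cdot B62(a_i,b_i)/\max|B62| \right]$
with $d_0 = 3$ Å and $c = 0.5$: a structural term saturating at 1 per
residue plus a BLOSUM62 sequence term, reflecting that pocket hits should
be ranked by both structural and sequence similarity of the aligned
residues. The constants are exposed as arguments; correspondences, the
transform, and the RMSD over aligned pairs are all returned so the score
can be recomputed or replaced downstream. For multi-segment targets,
`best_segment_pocket()` aligns every (segment, pocket) pair and keeps the
best score, ties going to the earlier segment then the earlier pocket.

## The synthetic world

`make_world()` generates everything the pipeline consumes with planted
ground truth: latent target side-effect sets drawn from a term catalog
(serious terms injected at rate `serious_rate`), a long-tailed (log-normal)
targets-per-drug count echoing the heavy right tail of real drug
promiscuity (without targeting any particular mean), drug side-effect sets
built as the union of their targets' latent sets with optional term noise
and dropout, template-ligand sets containing bit-flipped copies of true
binders plus random decoy compounds, and protein sequences mutated from a
common ancestor so that pairwise identities are controlled (true-binder
source proteins default to 90% identity to their target -- between the two
standard exclusion cutoffs, so they survive a 95% benchmark but not a 30%
one). All randomness flows from a single seed; identical parameters and
seed give identical worlds, and `emit_fixtures()`/`read_fixtures()`
round-trip a world through plain-text TSV/FASTA files.

Default sizes (40 targets, 25 drugs, 60 decoys, 120-bit fingerprints, a
60-term catalog with 4 latent terms per target) are chosen as the smallest
worlds in which every mechanism is exercised -- multiple binders per
target, decoy contamination, serious-term injection -- while keeping the
full test suite and the acceptance script fast on a single CPU; the
catalog-to-drug ratio is of the same order as the SIDER2-scale ratio of
distinct terms to drugs.

Two things the generator deliberately does not emulate: real chemical
space (fingerprints are random bit vectors, not molecules, so screening
difficulty is controlled by the bit-flip rate alone) and realistic
side-effect frequency distributions. Passing tests therefore demonstrate
the correctness of the algorithms under the generative model's assumptions,
not the accuracy the method would achieve on real drug--target data.

### Identifiability of the intersection rule

One design point deserves emphasis. In a zero-noise world the intersection
rule recovers a target's latent side-effect set exactly only when the
target's binders share nothing beyond that set. Promiscuous binders break
this: if all binders of target $T$ also bind $T'$, the rule attributes
$T'$'s terms to $T$ as well -- not a bug but an identifiability limit of
the rule itself, and a real phenomenon when drug portfolios overlap. The
exact-recovery experiment in the acceptance suite therefore uses
single-target drugs (`promiscuity_meanlog = log(1), promiscuity_sdlog = 0`),
the regime in which the latent sets are identifiable; the long-tailed
default is used everywhere else, where only the subset guarantee (no false
positives in the consistency test) is asserted, because that guarantee is
unconditional.

## Known limitations

- The mTC functional form used here is the convex additive one; the score
  is isolated behind `mtc_score()` so an alternative weighting can be
  swapped in without touching the screening machinery.
- Binding affinity is out of scope: scores support relative ranking only.
- Side-effect predictions are binary sets; the method does not rank terms.
- The pocket aligner is a desk-scale reimplementation of a heuristic; with
  the default span/seed caps it is not guaranteed to find the globally
  best-scoring alignment on pathological inputs (use the `Inf` settings for
  the exhaustive search).

## A worked example

```{r example}
world <- make_world(synth_params(), seed = 7)
world

hits <- screen_proteome(
  world$template_ligands,
  world$compounds$fingerprint[[1]],
  fingerprints = world$compounds,
  targets = world$targets$target_id,
  query_id = "D001", mtc_cutoff = 0.90
)
glance(hits)

truth <- world$planted_truth$target_id[world$planted_truth$drug_id == "D001"]
auc_per_drug(hits, truth)
enrichment_factor(hits, truth, x = 0.1)

ct <- consistency_test(world$interactions, world$drug_se)
glance(ct)
jt <- jackknife_test(world$interactions, world$drug_se)
glance(jt)

tse <- infer_target_side_effects(world$interactions, world$drug_se)
ki <- killing_index(world$interactions, tse)
head(ki, 3)
```
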