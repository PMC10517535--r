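---
title: "Chemical-pair similarity learning for iterative virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-pair similarity learning for iterative virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecbscreen)
```

## The model

Most ligand-based screening models score *individual* compounds. ecbscreen
instead learns a similarity function over *pairs* of compounds: a binary
classifier is trained to decide whether two compounds are an evolutionarily
related chemical pair (ERCP) — a pair binding a common protein target
(target scope) or targets that share a protein family in some family
database such as PFAM, SMART or SUPERFAM (family scope). Negative examples
are formed by pairing known actives with randomly selected compounds, which
at library scale are almost certainly unrelated. A library compound is then
scored against the known actives of a focus target, and its compound-level
score is the *maximum* pair score over those references — "how strongly does
this compound look evolutionarily related to at least one known active?"

The classifier is a random forest (`ranger`) probability forest with its
default parameters: 500 trees, square-root-of-features candidate variables
per split, and a fixed seed (`num.threads = 1`) so that every model, score
and downstream report is a pure function of its inputs. One forest is
trained per evolutionary scope; an ensemble averages the member
probabilities with equal weights — no weighting scheme is assumed.

### Pair featurization

A pair must map to a feature vector that cannot leak argument order. For
each configured fingerprint kind we concatenate the bitwise **AND** of the
two fingerprints (the shared substructure content) followed by their
bitwise **XOR** (the differences); both operators are symmetric, so
`score(a, b) = score(b, a)` holds structurally rather than by convention.
The feature length is twice the summed fingerprint lengths, and the kinds
with their lengths are recorded in the model's `featureSpec` so a model can
refuse incompatible inputs after deserialization.

The default kinds for model training are `MACCS166` (the 166 MACCS keys)
plus `SUBSTRUCT_FP4` (Open Babel's FP4 SMARTS-pattern fingerprint, 512
bits). We call Open Babel's FP4 implementation directly rather than
shipping a private pattern catalog: it is the reference implementation of
that fingerprint, and a reimplementation could only drift from it. Two
fingerprint kinds have no installed reference implementation and are built
here on the heavy-atom molecular graph:

* `PATH5_2048` — linear subgraph paths of 1–5 bonds, each canonicalized as
  the lexicographically smaller direction of its (element, bond-order)
  token sequence and hashed onto 2048 bits. Branched subgraphs are not
  enumerated; for the small, mostly linear decorations that distinguish
  screening hits this loses little discrimination and keeps the
  implementation transparent.
* `FCFP6_LIKE` — a functional-class circular fingerprint, radius 3, 1024
  bits. Atoms are typed by a pharmacophoric class vector (donor-like N/O,
  acceptor, halogen, carbon, branching degree ≥ 3, ring membership) rather
  than element identity, then expanded by the usual circular-invariant
  iteration. Functional-class fingerprints differ across toolkits
  bit-for-bit; any model or filter therefore records the exact kind it was
  built with, and cross-toolkit bit compatibility is explicitly *not* a
  goal.

`MORGAN_R2_1024` is Open Babel's radius-2 circular fingerprint folded
modulo 1024.

## Iterative retraining with experimental feedback

A first screening round produces candidates; an assay (percent of control,
POC, at fixed concentration) sorts them into new actives (POC < 20%), new
inactives (POC > 80%) and an ambiguous middle that is excluded outright.
The thresholds are exclusive on both sides — a compound at exactly 20% or
80% stays ambiguous. Four pairing schemes turn these measurements into new
training pairs:

| scheme | pairs | label |
|--------|------------------------------|----------|
| PP | new actives × previous actives | positive |
| NP | new inactives × previous actives | negative |
| NN | new inactives × previous random negatives | negative |
| PN | new actives × new inactives | negative |

Only PP is positive: every other scheme pairs compounds with no shared
binding activity. PP pairs new actives with *known* actives; pairing new
actives among themselves is off by default (`includeInternalPP`) because a
freshly measured compound set is small and internally correlated. The
retrained model is a full refit on the union of base and scheme pairs —
forests are cheap at this scale, and a refit keeps the model a pure
function of its training set rather than of its training history.

The scientific point of NP pairs is the *near-miss false positive*: a
compound structurally close to the actives (shared scaffold) that the
assay nonetheless rejects. A model trained only against random negatives
has never seen a hard negative and scores such compounds highly; NP pairs
are precisely those hard negatives.

## Evaluation: common test set and AUCPR

Models trained with different scheme combinations have different
positive/negative balances, and the precision-recall baseline moves with
the class balance. Comparisons therefore use a *common test set*: compounds
(not pairs) are split into k = 7 folds, and every pair touching a test
compound — from the base data or from any candidate scheme — forms the test
set shared by all combinations in that fold. Scheme pairs touching test
compounds are excluded from retraining, and a hard assertion inside
`crossValidateSchemes()` guarantees that no training pair ever contains a
test compound. The fold seed is shared across combinations so their models
differ only by training data.

The metric is the area under the precision-recall curve computed as
step-wise average precision: scores are traversed in descending order with
tied scores grouped at a single threshold (forest probabilities tie
often), and the area is the sum of precision × recall-increment. No
interpolation is applied — linear interpolation between PR points is
optimistic and flatters exactly the models with few distinct scores.

## The screening pipeline

`screenLibrary()` keeps library compounds whose max-aggregated score
reaches the cutoff (default 0.8, *inclusive*: a compound exactly at the
cutoff survives). Post-processing mirrors a practical triage:

1. `similarityFilter()` — the highest Tanimoto similarity to any known
   active is taken as representative; hits *strictly above* the cutoff
   (default 0.47) are flagged `similarity`-excluded. Equality is kept:
   the exclusion reads "higher than", and the strictness is tested.
   Lowering the cutoff can only exclude more, never fewer.
2. `applyExclusionHook()` — external filters (e.g. a pharmacophore model
   living in other software) plug in as predicates. The PAINS hook is
   flag-only: likely assay-interference compounds are reported, not
   silently dropped. A small curated set of classic PAINS SMARTS ships
   with the package.
3. `butinaCluster()` — leader clustering at Tanimoto ≥ 0.6 (the cutoff is
   a similarity, not a distance): repeatedly, the unassigned compound with
   the most unassigned neighbors (ties by lexicographic id) claims itself
   and its unassigned neighbors. The leader is the cluster center — the
   minimal conserved core of its cluster — and `selectClusterCenters()`
   projects exactly one center per cluster back onto the hit table.
   Excluded hits are never clustered and can never become centers.
4. `noveltyReport()` and `substructureMatch()` — structural novelty of a
   final candidate is argued across several fingerprint systems plus a
   substructure search in which variable decorations (e.g. amino or halo
   groups) can be deleted from the core before matching.

Tanimoto similarity of two all-zero fingerprints is defined as 0, not NaN:
degenerate molecules must sink in a ranking, not poison it. Multi-fragment
(salt-form) SMILES are reduced to their largest organic fragment before any
fingerprinting, because vendor libraries ship salts.

## The synthetic data generator

No public compound/target database is bundled or downloaded; every claim
the tests make is made on synthetic universes whose ground truth is known
by construction. The generator has two modes.

**Bit mode** samples fingerprints directly, bypassing chemistry: each
target owns disjoint *scaffold*, *activity* and *poison* bit blocks
(roughly 18%, 6% and 6% of each fingerprint's length). Actives carry
scaffold + activity bits (each on with probability 0.9) over a background
bit rate of 0.05; near-miss inactives carry scaffold + activity + poison
bits — structurally the closest things to actives in the universe, yet
truly inactive; decoys are background noise only. This is exactly the
regime in which a model trained only on random negatives produces false
positives, and in which NP pairs should repair it: the base model sees the
shared scaffold and scores near-misses high; only the XOR-side poison bits
separate them, and only NP pairs label that direction negative.

**SMILES mode** assembles real structures: an active is a scaffold template
(five aryl amide/sulfonamide/ether cores) carrying an iodo activity group
plus a random decoration; a near-miss is the same scaffold without the
halogen; decoys are random fragment assemblies. This mode exercises every
chemistry code path (parsing, canonicalization, all five fingerprint kinds,
clustering, substructure search) and reproduces the qualitative similarity
ordering: within-scaffold > active-vs-near-miss > active-vs-decoy.

Defaults — fixed once, used by every simulation: 3 targets × 10 actives,
60 decoys, 20 near-misses attached to the first (focus) target; the
simulated assay round returns 4 new actives and 19 new inactives, the size
of the motivating single-target experiment; synthetic POC values are drawn
uniformly from [0, 15] for actives and [85, 100] for inactives so they
round-trip through the 20/80 labeling with margin; affinities are uniform
in (1, 100) nM, below the usual 100 nM "known active" bar. Two family
databases group targets into overlapping pairs so family-scope ERCPs always
exist.

What the generator does *not* emulate: realistic medicinal-chemistry
property distributions, activity cliffs other than the single planted
poison/halogen mechanism, assay noise beyond the POC margins, and any
3D information. Passing tests demonstrate that the machinery implements
the method correctly and that the NP mechanism works in the regime it was
designed for — not that the same effect sizes will appear on a particular
real target.

## Problem sizes and reproducibility

The simulation studies (`simulateRetrainingStudy()`,
`simulateScreeningStudy()`) use 10 replicate universes with the default
configuration, sevenfold cross-validation, MACCS166-only features and
500-tree forests; the screening study uses a 2,000-compound library with 10
planted actives. These sizes give stable qualitative conclusions (the NP >
base ordering reproduces in essentially every replicate) while keeping a
full run in the low minutes on one core. Every stochastic step takes an
explicit seed, sub-seeds are derived deterministically, and generator
outputs are pure functions of (configuration, seed) — the tests assert
byte-identical reruns.

## Known limitations

* Bit-for-bit compatibility with other toolkits' FCFP or path fingerprints
  is out of scope by design; the kind used is recorded in model metadata.
* `PATH5_2048` enumerates linear paths only.
* The functional-class atom typing is heuristic (no explicit hydrogens,
  no charge model); it is a class-typed fingerprint in spirit, not a
  pharmacophore perception engine.
* Pharmacophore filtering itself is a hook, not an implementation.
* Probability calibration of forest scores is not attempted; the 0.8
  screening cutoff is a rank threshold, not a calibrated probability.
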