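---
title: "Consensus virtual screening against GPCR panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus virtual screening against GPCR panels: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

G protein-coupled receptors share a seven-transmembrane architecture and
closely related orthosteric pockets, which makes off-target activity the
central risk in GPCR drug design: a compound built for one chemokine
receptor will often touch its subtype neighbours. `gpcrscreen` implements a
decision-support pipeline that scores a query compound against a whole panel
of receptors with three deliberately different predictors and only then
votes:

1. a **feed-forward multiclass classifier** assigning one of six activity
   classes (ranges of pChEMBL, with class 0 reserved for inactives),
2. a **gradient-boosted decision-tree regressor** predicting the pChEMBL
   value itself,
3. a **docking leg** scoring the compound in a ligand-centred cubic search
   box at each receptor's orthosteric and allosteric sites.

Because the legs disagree in method (ligand-based vs structure-based,
classification vs regression), their errors are largely uncorrelated, and a
k-of-3 vote over the receptor each leg nominates gives a usable selectivity
call.  Precision — TP/(TP+FP) over compounds with a correctly assigned
target or target class — is the evaluation currency throughout.

## One feature space for peptides and small molecules

The panel's most interesting receptors (chemokine CC/CXC, class B peptide
receptors) are activated endogenously by peptides, whose data would normally
be unusable beside small-molecule ChEMBL records.  The pipeline adopts the
message–address view of peptide agonism: a short N-terminal fragment carries
receptor activation while the rest of the chain handles binding orientation.
Peptides are therefore truncated to their **6-residue N-terminal fragment**
(`truncate_peptide()`; a C-terminal rule is available for receptor families
whose activating fragment sits at the other end), assembled into a SMILES by
amide condensation of residue blocks (`peptide_to_smiles()`), and from then
on treated exactly like small molecules.

Two conventions were genuinely open and are exposed as arguments rather than
hidden: the new C-terminus created by truncation is built as a free
carboxylic acid by default (`cterm = "amide"` caps it instead), and
L-configuration stereocentres are encoded by default (`stereo = FALSE`
drops them).  Residue blocks were checked against PubChem isomeric SMILES
for all twenty amino acids, and the condensation obeys the closed form
"sum of residue formulas minus one water per bond" (hexaglycine is
C12H20N6O7).

## Fingerprints and their decoding

Both ML legs consume **ECFP4 fingerprints** (Morgan radius 2, bond diameter
4) folded to 2048 bits by default.  The implementation enumerates atom
environments on the heavy-atom graph — initial invariants are element,
heavy-atom degree, attached hydrogens, formal charge, ring and aromatic
flags; neighbours are folded in over two iterations; environments whose bond
set duplicates one already emitted are discarded.  Distinct-environment
counts were validated molecule-by-molecule against the RDKit Morgan
implementation on a diverse drug-like set (the test suite repeats that
comparison), and fingerprints are invariant to how the input SMILES is
spelled.

Keeping the (atom, radius) provenance of every identifier lets any bit be
**decoded back into its chemical fragment** (`fragment_for_bit()`), with
attachment bonds — including double-bond attachments such as a carbonyl
oxygen just outside the environment — marked by `*`.  This is what makes the
regressor explainable: `importance_report()` joins split-gain rankings with
fragment renderings, so "the model cares about bit 14" becomes "the model
cares about the hydroxamic N environment".

Folding collisions are reported, not resolved; they are inherent to folded
fingerprints.  The folded length and the chirality flag are configuration
(`fp_spec()`), not claims about any external system; chirality-aware
hashing is not implemented and `use_chirality = TRUE` is rejected rather
than silently ignored.

## Curation, classes, splits

`curate_activities()` applies three admission rules in order: functional
assays only (`assay_type == "F"`), SMILES that parse to a molecule, and
chemical uniqueness on (canonical SMILES, receptor, site mode) with
first-occurrence-wins; each rule's removals are counted in a report.
Duplicates with conflicting potencies are not averaged — the first record
wins and the conflict is logged — because the curation contract is removal,
not aggregation.

pChEMBL is \(-\log_{10}\) molar potency; 0 marks a negative data point.
The six activity classes are `{0}`, `(0,5]`, `(5,6]`, `(6,7]`, `(7,8]`,
`(8,Inf)`: an explicit inactive class plus unit-width bins across the
pharmacologically standard 5–8 range.  The bin edges are a package choice
(config-overridable via `activity_class_scheme()`); the lower-exclusive /
upper-inclusive convention is stated so that pChEMBL = 5 falls in class 1
deterministically.  `split_dataset()` draws the 80/20 record-level random
split (`floor(0.8 n)` training records) and 10 cross-validation folds with
sizes within one of each other, all reproducible from one seed.

## The two model legs

One classifier/regressor pair is trained per (receptor, site mode) — never a
pooled multi-receptor model — because each receptor's training set carries
its own structure–activity logic.

The classifier is a dense feed-forward network with a softmax head and
categorical cross-entropy loss, trained full-batch with Adam.  Its
architecture is found by **randomized search**: depth 5–20 hidden layers,
width 16–2048 units (powers of two), activation from {relu, tanh, sigmoid},
learning rate log-uniform in [3e-4, 3e-2] by default.  Each trial is scored
by mean accuracy under 10-fold cross-validation and the winner is refit on
the full input.  The network trainer is implemented in-package as plain
matrix algebra behind a pluggable predictor contract; training uses
early stopping on the training loss (patience-based) and a divergence guard
that falls back to the best weights seen.  Deep sigmoid draws routinely fail
to train — that is expected, and the reason the search samples several
trials.

The regressor is a gradient-boosted decision-tree ensemble (xgboost
backend), tuned by randomized search over 50–50,000 trees (log-uniform),
shrinkage, depth and row/column subsampling, selected by mean 10-fold CV
RMSE.  Split-gain importance of the final ensemble drives the fragment
reports.  Selection metrics (accuracy / RMSE) and the trial count
(default 25) are recorded with every trained bundle so runs stay auditable.

## The docking leg

`make_box()` centres a cubic search box (30 Å edge by default) on the
centroid of the reference ligand's coordinates — box construction is
translation-equivariant and exact.  `prepare_ligand()` embeds a 3D
conformer, assigns Gasteiger charges and writes AutoDock-style united-atom
PDBQT via Open Babel; per-compound embedding failures are reported, not
fatal, since 3D generation is the step where real compound sets lose the
most records.  The engine itself is **optional at runtime**: the `"vina"`
backend shells out to an AutoDock Vina binary and parses its score table,
while the `"stub"` backend — the default in every automated test — returns a
deterministic score hashed from (canonical SMILES, receptor, site mode) into
\([-12, -2]\) kcal/mol.  The stub keeps the orchestration, box protocol and
parsing fully testable with no external binary, and doubles as a null
predictor: it carries no signal, which the evaluation tests exploit.
Engine seed (42) and exhaustiveness (8) defaults are local choices.

## Consensus and evaluation

`assign_targets()` gives each leg one nominated receptor: the classifier leg
takes the receptor with the highest predicted class (ties broken by the
probability mass above class 0, then lexicographically), the regressor leg
the highest predicted pChEMBL, the docking leg the best (lowest) score.  A
receptor present with both site modes is represented by its more active
entry, so consensus is per-receptor while the evaluation stays stratified by
site mode.  `agreement_k` is the size of the largest set of legs naming one
receptor; with the docking leg absent the vote runs over two legs.  All tie
breaks are deterministic.

`evaluate_decisions()` scores rule × measure × stratum: `all3`, `atleast2`,
`atleast1` and the three per-leg rules, for target and target-class
assignment.  Non-selective compounds may carry several truth rows; a leg is
then correct if it names any acceptable target.  TP counts necessarily nest
(`all3 <= atleast2 <= atleast1`), which the tests verify against a
brute-force counter.  `compare_to_known()` places a query's predicted
pChEMBL inside the reference distribution of known actives per receptor
(percentile and z-score), mirroring how screening results are read in
practice.

## What the synthetic generator emulates — and what it does not

All tests run on libraries from `planted_sar()` /
`generate_multireceptor_benchmark()`: carrier molecules graft a
receptor-specific pharmacophore (e.g. a hydroxamic acid or a sulfonamide)
onto random drug-like scaffolds, non-carriers draw decoy tails, and
pChEMBL = baseline + effect × carrier + Gaussian noise, clipped at zero.
Carrier status is re-verified with a SMARTS substructure oracle at
generation time.  Default conditions: baseline 5, effect size 3 (the lift
from "weakly active" to "highly active"), noise SD 0.1 for regression
checks and 0.2 for the end-to-end benchmark, 50 carriers and 50 non-carriers
per receptor plus 10 dual-pharmacophore (non-selective) compounds, with a
class-A and a class-B receptor in the registry.

This emulates exactly one property of real data — activity that tracks
shared substructures, differently per receptor — and none of the rest: no
assay noise structure, no activity cliffs, no scaffold bias, no realistic
chemistry distribution.  Passing tests therefore demonstrate that the
pipeline recovers a signal that is truly present and votes correctly on it;
they say nothing about accuracy on ChEMBL-scale data, which depends on the
data itself.

## Numerical choices and degenerate inputs

* Environment hashing uses an exact-in-double polynomial hash mod
  \(2^{31}-1\); folding is `hash mod n_bits`.
* Constant design matrices: the regressor warns and fits the mean; the
  classifier falls back to a single dummy column.
* Single-class labels are a hard error (nothing to classify), as are
  mismatched feature widths and fingerprint-spec mismatches between a
  bundle and a query.
* Every seeded helper saves and restores the caller's RNG state.
* Problem sizes in the test suite and acceptance script are desk-scale by
  design: n = 1000 compounds for the signal-recovery checks, 3–5 random
  search trials over 5–8 layers × 16–64 units, 50–500 trees.  These sizes
  make the planted signals comfortably learnable while keeping a full run
  in minutes; the model contracts are identical at any scale.

## Known limitations

* The fingerprint does not encode stereochemistry; enantiomers collide.
* Fragment rendering of charged or H-bearing environments reflects the
  fragment's own valence context, not the parent molecule's hydrogen count.
* The docking stub is a null model; real binding-mode signal requires an
  external engine and prepared receptor structures, both out of scope here.
* Receptor preparation (homology modelling, refinement) is consumed, not
  produced: the docking leg expects ready PDBQT files.
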