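---
title: "Triplet interaction fingerprints and neural rescoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet interaction fingerprints and neural rescoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tifpscreen)
```

## The problem

Docking engines place ligands into a binding pocket with useful accuracy,
but their scoring functions rank actives poorly, especially on polar and
flexible sites such as the S-adenosyl-L-methionine (SAM) cofactor pocket
of methyltransferases.  A practical remedy is target-family rescoring: a
classifier trained on known actives and inactives of the family, taking as
input not the raw pose but a fixed-length encoding of the protein-ligand
*interaction pattern*.  `tifpscreen` implements that pipeline end to end:
geometric interaction detection, a triplet pseudoatom fingerprint, a
feedforward softmax classifier with the full training protocol, the
screening metrics, and synthetic-data generators that let every stage be
validated without external structures or a docking engine.

## Interaction detection and pseudoatoms

Five interaction classes are detected between a ligand and its binding
site (the protein residues with any atom within 6 Å of any ligand atom,
kept whole; metals within the cutoff are retained too).  The class
definitions are geometric and configurable through
`interaction_rules()`:

| class | criterion (defaults) |
|---|---|
| hydrophobic (HYD) | apolar C/S pair at ≤ 4.5 Å |
| hydrogen bond (HBD/HBA) | donor-acceptor heavy atoms ≤ 3.5 Å, D-H···A ≥ 120° when the donor carries hydrogens |
| aromatic (ARO) | ring centroids ≤ 5.0 Å, interplane angle ≤ 30° (face) or ≥ 60° (edge) |
| ionic (ION_P/ION_N) | opposite formal charges ≤ 4.0 Å, charged groups collapsed to one center |
| metal complexation (MET) | metal to ligand N/O/S ≤ 2.8 Å |

The thresholds are standard structural-biology practice; the family-level
literature names the classes without publishing numeric criteria, so the
numbers above are this package's documented defaults rather than imported
constants.  Hydrogen bonds are split by direction (ligand donates, HBD;
ligand accepts, HBA) and ionic contacts by the ligand's charge sign,
giving seven pseudoatom types; `collapse_types = TRUE` folds them back to
the five classes.

Three simplifications are deliberate and make planted-fixture recovery
exact:

* aromatic carbons are excluded from the hydrophobic class (ring-ring
  contacts are ARO's job, and counting each stacked carbon pair as HYD
  would swamp the fingerprint);
* donors and acceptors are exclusive (donor = N/O with a bonded hydrogen,
  acceptor = N/O without); when a structure carries no hydrogens at all,
  every neutral N/O is treated as both and the angle test is skipped —
  direction is then genuinely ambiguous and both directed records are
  emitted;
* formally charged atoms participate only in the ionic class.

Each detected interaction becomes one typed point: the midpoint of the
two participating centers for HYD/ARO/ION/MET, the acceptor atom position
for hydrogen bonds.  The family literature states the placement menu
("geometric center, the acceptor atom, or the ligand atom") without
mapping rules to classes; the mapping above is this package's choice.

Aromatic rings are taken from input aromatic flags as connected aromatic
components (ring *systems*); only when flags are absent does the package
fall back to shortest-cycle perception over a distance-guessed bond graph
(5- or 6-cycles of C/N/O/S within 0.2 Å of a common plane).  A fused
system therefore contributes one centroid, which is the natural entity
for stacking geometry.

## The triplet fingerprint

Every unordered triple of pseudoatoms is a feature candidate: its three
types are paired with the distance bin of the *opposite* triangle side,
using six half-open ranges [0, 4), [4, 6), [6, 9), [9, 13), [13, 17) and
[17, ∞) Å.  Because a vertex permutation permutes the (type,
opposite-bin) pairs in the same way, sorting the three pairs
lexicographically yields the minimum over all six orderings — the
canonical key is provably input-order independent, and the test suite
checks it against a brute-force six-permutation enumerator.  Distances
are measured between pseudoatoms, not their parent atoms.

A corpus of complexes defines a `build_dictionary()` of the 211 most
common keys (ties broken lexicographically, inert slots padding short
corpora), and each complex becomes a length-211 vector of triplet counts.
The published fingerprint length is 211, but the defining key list was
never released; the dictionary is therefore a first-class serializable
artifact built from whatever corpus the user screens, with no pretence of
a hidden universal table.  Two vectorization modes exist because the
source material is ambiguous — triples "are counted", yet the result is
called a "bit" vector.  Counts are the default (they carry strictly more
information); `mode = "binary"` gives presence bits.  A docking score can
be appended as feature 212 (`append_descriptors()`) for hybrid
fingerprint-plus-docking models.

Bin boundaries follow the half-open convention (a 4.0 Å side falls in the
second bin): the published range labels overlap at their endpoints, so
the convention is fixed here and tested.  End-to-end fingerprints are
invariant under rigid motion and atom reordering provided no pairwise
distance sits within numerical noise of a bin edge.

## The classifier

`tifp_net()` fits a fully connected network: input (211, or 212 with the
docking-score descriptor) → 500 → 1000 → 2-unit softmax, ReLU activations
and dropout 0.1 on the hidden layers, trained with Adam (learning rate
0.001) on cross-entropy plus an L2 weight-decay penalty of 0.0001 — the
hyperparameters selected by the grid search below.  After every epoch the
validation PRC-AUC is computed; training stops once the running best has
not strictly improved for 15 consecutive epochs (the patience window),
and the returned model carries the parameters of the *best* validation
epoch, not the last.  With a validation curve peaking at epoch 9, training
halts at epoch 24 and returns the epoch-9 weights — the contract the
acceptance suite pins down.

Batch size (64) and the epoch cap (200) are package defaults chosen for
datasets of order 10^3 rows; the original training protocol does not
state them, nor its initialization scheme (He-scaled Gaussian here).  The
seed controls initialization, shuffling and dropout, and fixed seed plus
fixed data reproduces the training history bit for bit.  Class imbalance
is handled only through PRC-AUC model selection — no class weights or
oversampling — matching the protocol being reproduced.  The
`valid_metric` argument lets protocol tests drive early stopping with a
rigged curve; it is not meant for routine fitting.

## Metrics

`basic_metrics()` implements the four closed-form rates (recall = TP/(TP+FN),
precision = TP/(TP+FP), TPR = recall, FPR = FP/(FP+TN)) plus accuracy,
with zero denominators signalled as `NA` rather than silent zeros.
ROC-AUC uses the Mann-Whitney identity (ties half-credited) and is
cross-checked against trapezoidal curve integration; PRC-AUC is
step-wise average precision — linear interpolation of PR curves
over-estimates and is deliberately avoided, though other tooling may
differ.  The enrichment factor takes the standard hit-rate-ratio form

EF(f) = (actives in top ⌈fN⌉ / ⌈fN⌉) / (actives / N),

with ties broken by stable input order and the recall-ratio convention
available behind `method = "recall"`, since published EF values rarely
state which convention produced them.

## The experiment protocol

* **Labels.** Potencies at or below 10 µM are positive, above 50 µM
  negative; the (10, 50] µM gap is excluded — only the two end conditions
  are defined by the protocol.  Activities are stored in nM and
  `p_activity()` is 9 − log10(nM).
* **Poses.** `filter_poses()` keeps poses scoring ≤ −8.2 whose centroid
  lies within 8 Å of the reference pocket centroid (the operational
  reading of "bound another site"), then the best pose per molecule.
* **Splits.** "Proportion 1:10" is read as test:rest = 1:11ths, i.e.
  round(n/11) test samples (158 of 1740), drawn once; the remainder is
  reshuffled ten times into validation (round/9, 176) and training
  (1406).  The 10 %-of-n reading is available behind
  `test_rule = "fraction"` because the phrasing is ambiguous.  Rounding
  is round-half-to-even on the smaller part.
* **Grid search.** dropout {0.1, 0.2} × learning rate {10^-3, 5·10^-4,
  10^-4, 5·10^-5} × hidden sizes {[500,100], [100,500], [320,640],
  [500,1000]} — 32 combinations, each recorded with its stop epoch and
  train/validation recall, precision, ROC-AUC and PRC-AUC; the best
  combination maximizes validation PRC-AUC with ties going to lower
  dropout then lower learning rate.
* **Repeated training.** One model per split, a mean ± sd summary, and
  the best model by validation PRC-AUC promoted to test-set evaluation.
* **Diversity.** `pairwise_similarity()` computes all n(n−1)/2 Tanimoto
  coefficients of user-supplied fingerprint bitsets and their histogram;
  generating the circular (Morgan) bitsets themselves is left to standard
  cheminformatics tooling.

## Synthetic data: what it emulates and what it does not

`make_toy_complex()` plants each requested interaction as an isolated
atom group 25 Å from its neighbours, with geometry at least 0.3 Å / 10°
inside every default threshold and filler atoms far outside every rule's
range.  Detection therefore recovers exactly the planted records — the
round-trip is exact for 50 seeded specifications in the test suite.
These complexes validate geometry, typing and encoding; they are *not*
physically realistic proteins: no backbone, no sterics, no competing
near-threshold contacts.  Passing tests demonstrate correctness of the
geometric rules, not detection robustness on crystallographic noise.

`make_fingerprint_dataset()` emulates the class structure of the
screening corpus: 1740 samples, 446 positives (prevalence ≈ 0.256).
Features are independent Bernoulli activations — baseline probability
0.05, raised by 0.5 on 20 signal features for positives — carrying
Poisson-inflated counts in count mode.  The defaults were set so that the
construction's own bit-threshold oracle separates the classes nearly
perfectly (ROC-AUC ≈ 0.999), which is the generator's contract: the
planted signal, not the learner, is the ceiling.  Observed labels can
then be flipped at a fixed rate (`flip_noise`), and the generator returns
both the noisy labels (`y`, used for training) and the ground truth
(`y_true`).  Recovery experiments score held-out predictions against
`y_true`: with symmetric 5 % flips and this prevalence, even a perfect
classifier scored against the *noisy* labels is capped near ROC-AUC 0.93
by label contamination alone, so evaluating against ground truth is the
only reading under which near-perfect recovery is a meaningful target.
The independent-bit signal model is deliberately the simplest structure
that makes recovery quantifiable; real fingerprints are sparse,
correlated and block-structured, and no claim about real-data performance
follows from these tests.

## Numerical choices and problem sizes

* Distance comparisons are plain Euclidean in Å; bin edges half-open;
  triplet keys canonicalized by sorting, verified against permutation
  enumeration.
* Ring plane fits use the SVD of centered coordinates; normals are
  sign-canonicalized (positive leading nonzero component) so equality
  tests are stable.
* Cross-docking receptor selection averages over present RMSD entries by
  default (failed dockings carry no information); `na_action =
  "penalize"` substitutes a configurable penalty instead, since the
  source protocol does not say how failures entered its averages.  Pose
  RMSD uses stored atom correspondence with no symmetry correction and no
  re-superposition — correct for docked-versus-native poses sharing a
  receptor frame, and documented as a limitation otherwise.
* Simulation sizes in the tests and the acceptance script are chosen for
  single-CPU runs: the recovery and permutation experiments use a
  128×256-unit network with an epoch cap of 25 and patience 8 on the full
  1740-sample synthetic dataset; the 32-combination grid search runs on a
  240-sample dataset with a 4-epoch cap.  The full 500×1000 architecture
  (609,002 parameters) is exercised by the parameter-count and
  configuration tests and is the package default for real use.
* The permuted-label control is reported as the mean held-out ROC-AUC
  over five seeds.  A single permuted-label model is *not* a pure random
  ranker: its weights can align with informative features by chance, so
  individual-seed AUCs scatter around 0.5 with a standard deviation near
  0.07 on a 158-sample test set, while the five-seed mean concentrates
  within the chance band.

## Known limitations

* No pose generation: docking scores and poses are inputs, never
  computed.
* PDB input has no bond records; typing then relies on a 1.9 Å
  distance-based bond guess and suffers the no-hydrogen ambiguity above.
* The 211-key dictionary is corpus-dependent by design; fingerprints from
  different dictionaries are not comparable.
* π–cation interactions, halogen bonds and water-mediated contacts are
  out of scope — they are not part of the five-class scheme implemented
  here.
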