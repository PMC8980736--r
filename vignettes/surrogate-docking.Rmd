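---
title: "Surrogate docking: model, encodings and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate docking: model, encodings and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrodock)
```

## The problem and the modelling idea

Structure-based virtual screening scores a small molecule against a protein
pocket by sampling many ligand and protein conformations and evaluating each
with a force field. The cost per molecule (seconds to minutes) is what makes
billion-molecule screens infeasible. `surrodock` replaces the sampling +
scoring loop with a regression network trained on the *outputs* of such
docking runs: given only a coarse 3D image of the pocket and the 2D topology
of the ligand, it predicts run-level population parameters — seven summary
statistics for each of thirteen interaction-energy terms — together with the
binding affinity pK. Because the inputs deliberately withhold the pose (no
ligand coordinates, no orientation, no conformer), the network cannot learn a
pose-specific shortcut; it must internalize the effect of conformational
sampling. This also removes self-docking bias: no crystallographic bound
conformation is ever shown to the model.

## Pocket encoding

Atoms are read from PDB records (`read_structure()`, backed by bio3d).
Conventions, chosen where the underlying format forces a decision:

* **Alternate locations** — for each atom site the highest-occupancy record
  is kept; ties keep the first record in file order.
* **Element symbols** — taken from PDB columns 77–78 when present, otherwise
  inferred from the atom name. Protein atom names begin with the element
  letter (CA is Cα, not calcium), so two-letter symbols are only considered
  for HETATM records against a fixed metal/halogen list.
* **Pocket centre** — the unweighted centroid of the bound ligand's heavy
  atoms. A bounding-box centre would be dominated by single protruding
  substituents; the centroid is also what "centred at the ligand" most
  naturally denotes. An explicit `center` argument serves apo structures,
  where a pocket is chosen rather than observed.
* **Atom selection** — standard amino-acid residues only. Waters are always
  excluded; cofactors, ions and other HETATM entities are excluded by
  default but can be included (`include_hetero = TRUE`). Deposited
  hydrogens are encoded (channel H); no protonation is added.
* **Binning** — the cube `[center − 10 Å, center + 10 Å)` is half-open on
  every axis, i.e. voxel index `floor((x − (c − 10))/2)`. Atoms exactly on
  the upper face fall outside the selection, which is what prevents an
  index-10 overflow; the same half-open rule is used for selection and for
  binning, so the two can never disagree.
* **Channel 0 semantics** — an occupied voxel clears the "no atom" channel
  and sets one channel per element class present (channel-wise maximum over
  the atoms' one-hot encodings); an empty voxel sets only channel 0. Taken
  literally, a maximum over atom encodings could never clear a pre-set
  channel 0, so the encoding defines channel 0 as the complement of
  occupancy — the only reading under which it carries information.

Voxelization is exactly equivariant under joint translation of atoms and
centre. It is *not* rotation-invariant, and no rotational canonicalization
or augmentation is applied: coordinates are used as deposited. This is a
known representational limitation; symmetry-aware architectures are a
natural upgrade path but are out of scope here.

## Ligand encoding

SMILES parsing and aromaticity perception are delegated to Open Babel
(via ChemmineOB), with the molecule materialized as MOL2 and read back by
bio3d. Hydrogens are stripped; the graph retains element symbols and a bond
table (formal order 1–3 plus an aromatic/conjugated flag).

* The **aromatic/conjugated channel takes precedence** over formal order,
  since both are merged into one channel of the 5-channel adjacency tensor.
  MOL2 type `ar` maps to that channel; the amide type `am` maps to formal
  single order, because the flag adopted is the toolkit's "is aromatic"
  perception, not a broader conjugation analysis.
* **Pruning.** Molecules over 36 heavy atoms are reduced by repeatedly
  deleting the atom with the smallest total bond order — the sum of incident
  bond contributions with aromatic bonds counted 1.5 — recomputed after
  every removal, ties resolved toward the lowest original atom index. The
  1.5 convention keeps ring atoms (two aromatic bonds ⇒ 3.0) above terminal
  single-bonded atoms (1.0), so peripheral chains are consumed before ring
  systems. The procedure is deterministic, idempotent, and never increases
  the atom count. Fragments disconnected by pruning are retained.
* **Atom order** is the parser's native order (no canonical ranking). The
  encoding is therefore permutation-sensitive, like any flattened adjacency
  representation; this is accepted as part of the design.
* The 36-atom limit is not arbitrary: molecules above ~36 heavy atoms are
  very likely to exceed the 500 Da Lipinski cutoff anyway, and a larger
  fixed size would make the one-hot tensors extremely sparse.

## Regression targets

For each energy term the seven statistics are population moments
(divisor *n*): skew `m₃/m₂^1.5`, kurtosis `m₄/m₂² − 3` (excess). When
`m₂ < 10⁻¹²` — constant samples, including single-iteration runs — the
standard deviation, skew and kurtosis are defined as 0 rather than NaN, so
degenerate runs remain usable. The moment convention is configurable in
principle (it matters when retraining against a docking engine whose
pipeline used sample moments); the package uses population moments
throughout, and the test suite pins the convention against both a
brute-force Σ-loop oracle and e1071's type-1 estimators.

Affinity is `pK = −log₁₀(K / 1 M)` with K_D and K_I treated identically.
The sign deserves a note: affinity is sometimes written loosely as
"log₁₀ K", but the worked anchor — 10 nM ↔ pK ≈ 8 — requires the negative
sign, and that is what the package implements.

The flattened target vector is terms-major (7 statistics of term 1, then
term 2, …), 91 values, with pK appended: 92 in total. `E_without_VDWR` is
required and first; the other default term names are placeholders in the
style of force-field score decompositions, five of which are identically
zero in typical runs (docking tables flag such inactive columns on input).

## Architecture and training

Each subnetwork is a first projection (input → d) followed by `n − 1`
width-d layers; the predictor consumes the concatenated pair (2d → d); a
91-output linear head emits the statistics and a separate 1-output head
emits pK. Skip connections are parameter-free identity additions on the
shape-matched (d → d) layers; dropout follows the activation. This wiring is
the one whose trainable-parameter count

`N(n, d) = (3(n−1)+2)d² + (8000 + 6732 + 91 + 3n)d + 91`

reproduces the reference counts for (10, 1024), (6, 512) and (6, 256)
exactly; those published counts correspond to the model *excluding* the pK
head, whose d + 1 parameters are therefore counted separately
(`count_parameters(m, include_pk_head = TRUE)`). The (10, 2048) reference
row is not consistent with this reconstruction and is not used as a check.

Numerical choices, with defaults and rationale:

* **Spectral normalization** on every dense layer including the heads; one
  power-iteration update per training step; the iteration vectors are
  auxiliary state, excluded from parameter counts and gradients (the norm is
  treated as constant within a step). In evaluation the stored vector is
  used read-only, so prediction is deterministic and batch-consistent.
* **LeakyReLU slope 0.3** — the long-standing framework default of the era
  this architecture family comes from; configurable.
* **Initialization** — seeded uniform fan-based scheme
  (±√(6/(fan_in+fan_out))); biases zero.
* **Optimizer** — Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸), learning rate
  10⁻⁶ by default. That rate suits raw-energy targets at full scale;
  synthetic desk-scale studies use 10⁻³ via the config. Targets are not
  standardized.
* **Batch size 64, early stopping** on validation loss with patience 20;
  epochs bounded by config.
* **Loss** — mean over examples of the squared error summed across all 92
  outputs (energies and pK are deliberately trained jointly: the extra
  docking-derived targets act as a regularizer against overfitting the
  scarce affinities).
* **Divergence** — a non-finite loss aborts training with a diagnostic
  rather than continuing silently. A practical note: because spectral
  normalization bounds every layer's gain, even absurd learning rates tend
  to produce bounded (useless) predictions rather than NaNs.
* An observed training dynamic worth knowing: small/short runs fit the
  target *mean* first; the predictive spread is tiny during that phase and
  its correlation with truth is meaningless until variance fitting begins.
  The shipped configurations are sized past that phase.

Training is bit-reproducible given the seed (shuffling, dropout masks and
initialization all derive from it), and checkpoints reload to bit-identical
predictions (`save_checkpoint()` / `load_checkpoint()`, R serialization plus
a JSON sidecar with the configuration and schema).

## The synthetic oracle

Real training data needs months of docking CPU; the synthetic module
instead draws complexes from a generator with a *known* ground truth, so
recovery is measurable:

* `E_min = −(c_pᵀ W c_l)/s − v·b + μ₀`, where `c_p` counts occupied voxels
  per pocket channel, `c_l` counts ligand atoms per type channel, and `b`
  counts bonds per class. The form is bilinear in the encoded compositions
  **by design**: it guarantees the information needed for recovery survives
  the featurization, so a failed recovery indicts the pipeline, not the
  benchmark. A mildly nonlinear variant (`nonlinear = TRUE`) is available
  for stress testing.
* Docking iterations are `E_min + Gamma(k = 2, θ = 2)`: nonnegative noise
  makes the sample minimum a consistent estimator of `E_min`, mimicking
  "best pose found over iterations". Seven secondary terms are fixed affine
  transforms of the same samples plus Gaussian noise; five terms are
  identically zero, mirroring inactive force-field components.
* Affinity: `pK = clip(a − b·E_min + ε, 0, 14)` with `a = 1`, `b = 0.08`,
  `ε ~ N(0, 0.3²)` — a negative energy–affinity link, as tighter binders
  have lower interaction energies.
* Magnitudes (`W ~ U(0.5, 1.5)`, `s = 50`, `v ~ U(0.2, 0.8)`, `μ₀ = −5`)
  were chosen so that `E_min` spans roughly −10 to −110 kcal/mol and pK
  roughly 2–9 — the ranges typical of force-field interaction energies and
  curated affinity data.
* All randomness flows from one master seed through named substreams
  (params/pocket/ligand/run/pK), so each stage is independently
  reproducible.
* Pockets are uniform atom placements in the cube with protein-like element
  frequencies; ligands are random degree-capped spanning trees with extra
  cycle edges, bond-order upgrades and aromatic flags assigned within
  per-element valence caps (C 4, N 3, O 2, F 1, S 6, other 4; aromatic
  counts 1.5). Ligand sizes 5–45 deliberately straddle the 36-atom limit so
  pruning is exercised in-distribution.

What the generator does **not** emulate: real pockets have backbone
geometry, secondary structure and chemically coherent residue composition;
real ligands have realistic ring statistics, kekulized aromatic systems and
stereochemistry; real docking noise is pose-correlated rather than i.i.d.
Passing the synthetic recovery therefore shows the pipeline is
information-preserving, correctly wired and trainable — it does not certify
accuracy on crystallographic data, which requires the external datasets and
docking budget this package's scope excludes.

## Validation protocol and problem sizes

The study configuration used by the recovery check: 2,000 training and 500
held-out complexes from the same oracle (different master seeds, so held-out
pockets and ligands are genuinely unseen), a 4-block width-64 model,
learning rate 10⁻³, at most 100 epochs, fixed seeds throughout; success is
held-out Pearson r ≥ 0.8 against true minimum `E_without_VDWR` and ≥ 0.7
against noiseless pK. At these sizes the check measures genuine
generalization while staying a desk-scale computation (minutes on one CPU
core); the observed correlations run around 0.9. Unit tests use smaller
slices of the same generators; the invariant suites sweep 1,000 random
pockets and molecules.

## Screening

`screen_library()` featurizes each parseable molecule, predicts in batches,
and ranks by predicted pK descending with stable input-order tie-breaking;
parse failures are flagged records, never silent drops. Oversized molecules
are pruned like training data (a discard mode exists). Lipinski violations
count strict exceedances of MW > 500 Da, logP > 5, donors > 5,
acceptors > 10 — boundary values are compliant, and missing properties are
marked not-evaluable rather than counted. logP is taken from the library
file when supplied (screening libraries often ship curated values),
otherwise computed by Open Babel's estimator, with the provenance recorded
per record. QED is not computed: no established implementation exists in
the package's dependency set, and a bespoke one is explicitly avoided.
Recommended practice for real campaigns is to re-dock the top of the ranked
list with a physical engine before any experimental follow-up.

## Known limitations

* No rotational invariance of the pocket encoding; no permutation
  invariance of the ligand encoding.
* The coarse 2 Å grid cannot resolve sub-voxel geometry (e.g. hydrogen-bond
  directionality).
* The pruning metric ("least total bond order, aromatic = 1.5") is one
  defensible reading of a loosely specified rule; alternatives (Kekulé
  integer orders, random tie-breaks) would change which atoms survive on
  exotic molecules.
* The synthetic oracle's linearity makes it an easier learning problem than
  a physical force field; treat synthetic correlations as pipeline
  validation, not performance claims.
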