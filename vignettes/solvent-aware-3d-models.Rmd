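---
title: "Solvent-aware 3D models for chromophore optical properties: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvent-aware 3D models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(solvachrom)
```

# Scope and model overview

`solvachrom` predicts three optical properties of a chromophore–solvent
pair — the absorption maximum $\lambda_{abs}$ (nm), the emission maximum
$\lambda_{ems}$ (nm) and $\log_{10}$ of the photoluminescence quantum yield
— from the chromophore's 3D conformer and the solvent's 2D graph. The
package covers the full modelling pipeline: data curation from
SMILES/SDF/XYZ inputs, scaffold-grouped splitting, the neural architecture,
joint property + geometry training, evaluation, and a synthetic data
generator used for verification. It deliberately does **not** run any
quantum chemistry: multi-fidelity conformers (force-field, semi-empirical,
DFT in vacuum or implicit solvent) are consumed as files, never computed.

## The solvent encoder

The solvent is a small molecule drawn from a limited panel, so it is encoded
with a deliberately lightweight directed edge-message-passing network
(D-MPNN). Directed edge states are initialized from concatenated
source-atom and bond features, $h^0_{uv} = \mathrm{relu}(W_i[x_u; e_{uv}])$;
$T$ rounds update each edge from the incoming edges at its source excluding
the reverse edge,
$h^{t}_{uv} = \mathrm{relu}\!\big(h^0_{uv} + W_m \sum_{k \in N(u)\setminus v} h^{t-1}_{ku}\big)$;
atom states pool incoming edges through $W_a$ and the molecule embedding is
the mean over atoms. Mean aggregation makes the embedding invariant to atom
ordering (tested against alternative SMILES spellings) and bounded in scale.

The encoder is pretrained inside a dual-encoder 2D baseline: two D-MPNNs
with identical architecture but independent weights embed chromophore and
solvent, a feed-forward head regresses the targets from the concatenated
embeddings, and only TRAIN-subset records are ever touched (the access log
makes this auditable). After pretraining, the solvent branch is kept as a
frozen source of solvent embeddings; because it is deterministic, embeddings
may be cached by canonical key. Pretraining uses absorption only by
default — absorption labels are the most abundant — with multitarget
pretraining available as a switch.

## The invariant backbone

The chromophore conformer is processed by a global-attention encoder over
$N$ atoms plus one coordinate-free *virtual node* (row 0) whose final
embedding is the molecule-level representation. All geometric information
enters through interatomic distances: each pair is expanded in $K$ Gaussian
radial basis functions, $G_{ijk} = \exp(-(d_{ij}-\mu_k)^2/2\sigma^2)$, with
equally spaced centers and width equal to their spacing. A learned
projection of $G$ biases the attention scores per head, together with a
shortest-path bucket embedding (graph distance capped at 6, plus self and
far/disconnected buckets). The virtual node has no coordinates; its
attention biases to and from real atoms are learned per-layer scalars.
Blocks are pre-norm transformer layers (RMS normalization with learned
gains, scaled dot-product attention, 2× feed-forward expansion).

Three deliberate departures from a plain transformer:

* **Radial-distribution input channel.** Each atom's input embedding adds a
  learned projection of its summed Gaussian pair features
  $\mathrm{rdf}_i = \sum_j G_{ij\cdot}$ (a per-atom radial distribution
  fingerprint, in the spirit of continuous-filter inputs). Without it,
  geometry reaches the property head only by modulating attention scores —
  a path whose gradients proved too weak for desk-scale training to pick up
  torsional or bond-length-alternation signals at all; with it, models
  trained on clean reference geometries resolve both.

* **Size channel.** Softmax attention computes weighted means and is
  therefore size-blind, but a molecule-level readout needs the system size.
  The virtual node's input embedding is a learned projection of a small
  graph-summary vector (atom count, ring-atom count, terminal-atom count,
  element counts, all scaled by 1/10). For conjugated chromophores this
  makes the conjugation length linearly recoverable at the input.
* **Equivariant coordinate head.** The displacement of atom $i$ is
  $\Delta r_i = \sum_{j\ne i} c_{ij}\,(r_i - r_j)/d_{ij}$ where the scalar
  pair weights $c_{ij}$ come from a small MLP over the two atom embeddings
  and the pair's distance features. Scalars are rigid-motion invariant, unit
  difference vectors rotate with the input, so displacements are
  rotation-equivariant and translation-invariant *by construction*, not by
  training. The output weight vector is zero-initialized: an untrained model
  refines nothing. A guard aborts refinement if any per-atom displacement
  norm exceeds `max_displacement` (10 Å by default), which catches training
  instabilities early.

The backbone forward and backward passes are implemented twice: a reference
implementation in plain R and a line-for-line RcppArmadillo port used by
default (`options(solvachrom.compiled = FALSE)` selects the reference). The
test suite asserts agreement to 10⁻¹⁰ on random inputs, and verifies every
gradient against central finite differences.

## Fusion and the joint objective

Strategy `VIRTUAL_NODE` projects the solvent embedding onto the atom feature
width and sums it into the virtual node once, before the first attention
block, letting solvent context shape all intermediate representations.
`HEAD_CONCAT` keeps the backbone solvent-blind and concatenates the solvent
embedding at the regression head. `NONE` is the ablation.

Training instances are conformation pairs: a coarse input geometry and a
high-accuracy reference. The loss is

$$L = w_{prop}\,\underbrace{\tfrac{1}{|O|}\sum_{k\in O}\Big|\tfrac{\hat y_k - y_k}{s_k}\Big|}_{\text{masked L1}}
    \; + \; w_{coord}\,\underbrace{\tfrac{1}{N}\sum_i \lVert \hat r_i - r^{ref,al}_i\rVert}_{\text{aligned coordinate loss}}$$

where $O$ is the set of observed target slots (masked slots contribute
exactly zero gradient; a record with no observed targets contributes only
the coordinate term), $s_k$ are per-target normalization scales computed
from TRAIN records only, and $r^{ref,al}$ is the reference geometry after
Kabsch superposition onto the refined coordinates. Defaults
$w_{prop}=w_{coord}=1$.

Numerical choices worth stating:

* **Stop-gradient through the alignment.** The Kabsch transform minimizes
  the squared deviation while the loss is the mean per-atom distance, so the
  envelope theorem does not make the transform's sensitivity vanish exactly.
  The loss is *defined* with the alignment as a fixed preprocessing step and
  gradients flow only through the refined coordinates. This removes all
  rigid-body ambiguity at negligible bias and keeps the backward pass exact
  with respect to the stated definition (the finite-difference tests freeze
  the alignment accordingly).
* **Single-pass refinement during training.** With the default refinement
  depth of 1, one backbone pass produces both the displacement (supervised
  against the reference) and the virtual-node embedding read by the property
  head. Deeper refinement re-runs the backbone on updated coordinates at
  inference time (`refine_coordinates`); training does not backpropagate
  through coordinate re-featurization. Only the final refined geometry is
  supervised.
* Predictions are de-normalized before any metric, so MAEs are in nm.
* Atom indices are 1-based throughout, following R convention.

## Two-phase training

Phase 1 freezes both encoders (backbone and solvent encoder, plus the
solvent projection) and trains the regression head to convergence;
because everything upstream is frozen, head inputs are computed once and
cached, making this phase cheap. Phase 2 unfreezes the entire network for a
joint finetune (Adam, learning rates 10⁻³/3·10⁻⁴, batch 32 by default,
with optional per-epoch learning-rate decay and decoupled weight decay).
"Convergence" is operationalized as early stopping on the validation
metric — absorption MAE for single-target runs, the masked multitarget
validation loss for multitarget runs — with configurable patience, and the
best-validation checkpoint is returned. Freezing is bit-exact (asserted in
the tests), seeds fully determine the run, and per-group Adam step counts
are recorded in the returned training state.

## Scaffold splitting

Grouping is at the chromophore level: Bemis-Murcko frameworks are computed
by iteratively deleting terminal atoms until only ring systems and their
linkers remain (exocyclic multiply-bonded atoms retained; element and bond
identity kept; acyclic molecules map to a designated EMPTY scaffold), and
whole scaffold groups are assigned to one subset. Solvents are not
scaffold-constrained — the leakage risk being addressed is the same
chromophore appearing in both training and test through different solvents.
Assignment shuffles scaffolds with a seed and fills TRAIN to its
largest-remainder record quota, then VAL, then TEST; a scaffold overflowing
a quota goes to the next unfilled subset, and if the tail of this greedy
fill leaves VAL or TEST empty the smallest TRAIN scaffold is moved there.
k-fold partitioning balances record counts greedily over a seeded scaffold
order; validation scaffolds inside each fold are re-drawn per fold with the
fold index mixed into the seed.

## Dataset curation

`curate()` removes records whose conformer topology contradicts their 2D
graph, collapses byte-identical duplicates, and *flags* (never silently
drops) same-pair records with conflicting labels and protonation variants
sharing a neutral parent skeleton — mirroring a manual-review stance. Bond
orders are never perceived from geometry; topology consistency compares
element-labelled connectivity only, with bonds perceived by the
covalent-radius rule (default tolerance 0.4 Å). The topology check defaults
to the highest-fidelity conformer of each record: distance-based bond
perception is meaningful for optimized geometries, while force-field-level
geometries (or the generator's σ = 0.3 Å noise level) would fail it by
construction. PLQY values are stored as $\log_{10}$ (the spectroscopy
convention); entries outside (0, 1] are rejected at load with a report
entry.

# The synthetic generator

The generator emulates the statistical structure of a curated
chromophore–solvent dataset with multi-fidelity conformers; it is a
verification surrogate, **not** a physical model.

Chromophores are donor/acceptor-substituted diaryl polyenes: two terminal
rings from {benzene, pyridine, thiophene, furan} joined by $L$ vinylene
units, with optional amine (donor) and fluoro (acceptor) terminal
substituents, built as explicit graphs with idealized planar geometries
(standard bond lengths, 120° zig-zag, 5-rings slightly enlarged so
heteroatom 1–3 contacts stay clear of the bond-perception cutoff) and a
seeded inter-ring twist $\theta$ about the terminal single bond. This family
gives genuine scaffold diversity — the framework varies with (ring₁, ring₂,
$L$) — so splits and cross-validation are always feasible; duplicate
structures are redrawn.

The noiseless targets follow a closed-form solvatochromic surrogate in the
conjugation length $L$, solvent polarity $P \in [0,1]$ and twist $\theta$:

$$\lambda_{abs} = \lambda_0 + aL + bP - c\,(1-\cos\theta), \qquad
\lambda_{ems} = \lambda_{abs} + s_0 + s_1 P, \qquad
\mathrm{PLQY} = \big(1 + e^{-(k_0 - k_1(1-\cos\theta))}\big)^{-1}$$

with defaults $\lambda_0 = 250$, $a = 25$, $b = 60$, $c = 40$, $s_0 = 20$,
$s_1 = 30$ (nm where dimensioned), $k_0 = 2$, $k_1 = 6$. The family is
linear in $L$ and $P$ so that the solvent contribution is controllable and
exactly recoverable by regression (a generator test recovers $(a, b, -c)$
within three standard errors at $n = 2000$), and twist-penalized so that
geometry fidelity genuinely matters.

**Study conditions** (chosen once): $L \sim$ uniform {2..5}; $\theta \sim
U(0°, 90°)$; nine named solvents with Reichardt-style normalized polarities
(n-hexane 0.009 … water 1.0); wavelength label noise $\sigma_y = 5$ nm and
log-PLQY noise 0.05 (clamped so PLQY stays ≤ 1); missing-label
probabilities 5% / 35% / 50% for absorption / emission / PLQY, reflecting
the relative abundance of absorption data.

**The fidelity ladder** adds per-coordinate Gaussian noise
σ = 0.30 / 0.15 / 0.05 / 0.02 Å for `RDKIT` / `XTB` / `DFT_VAC` /
`DFT_IMP`. Two solvent effects live only in the implicit-solvent reference
level, which is therefore stored per record: the twist relaxes 20% of the
way toward a solvent-preferred value $\theta(1-P)$ (polar solvents
planarize), and the chain bond-length alternation shrinks with polarity,
$\delta = \delta_0 (1 - 0.6P)$ with $\delta_0 = 0.10$ Å (the force-field
level has no alternation at all). High-fidelity geometries consequently
*carry solvent information* — exactly the mechanism that makes
implicit-solvent conformers competitive with explicit solvent embeddings in
the benchmark grid, and makes the embedding close the gap between conformer
sources. Ground-truth targets are evaluated at the reference-level twist.

What passing tests on this surrogate do and do not show: they verify the
machinery — invariances, gradients, masking, splitting, the relative value
of solvent information and geometry fidelity under a known ground truth —
but say nothing about accuracy on real measured spectra, which depends on
data the package does not ship.

# Verification protocol and problem sizes

The acceptance tests run, per block: invariance sweeps (5 molecules × 20
rigid motions); oracle equivalence on ≥ 100 random instances per numerical
operation; split integrity over 50 seeds; bit-exact freezing and masked-slot
gradients; the solvent-ablation benchmark (500 chromophores × 4 polar/
nonpolar solvents = 2000 pairs, backbone width 64 / 2 layers, solvent term ≥
30% of absorption variance; the fusion model must reach held-out MAE ≤ 12 nm
and beat the ablation by ≥ 20%); refinement efficacy on (force-field,
reference) pairs (240 records); the 3-source × 2-regime benchmark grid over
three seeds (800 records each); and 5-fold cross-validation consistency.
These sizes were chosen so the whole suite verifies the mechanism at desk
scale on one CPU; all of them are configuration arguments, not limits of the
implementation.

# Known limitations

* Valence screening is a light rule table, not a full chemistry model;
  exotic coordination chemistry passes through with OTHER-bucket features.
* Aromaticity features are a conjugated-ring heuristic on the kekulized
  graph; structure identity always relies on canonical keys instead.
* The Weisfeiler–Lehman refinement used for order-independent topology
  comparison is not a complete isomorphism test (exact edge comparison is
  used whenever atom orders align, which covers the generator's data).
* Conformer ensembles are out of scope: one conformer per (molecule,
  fidelity level) within a record.
* No uncertainty estimation; no transfer of externally pretrained weights.
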