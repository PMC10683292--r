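---
title: "Methods: small-data NMR shift prediction with graph networks and HOSE codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-data NMR shift prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An NMR chemical shift is the resonance frequency of a nucleus, in ppm,
and is determined almost entirely by the atom's local chemical
environment: atoms a small number of bonds away dominate. This package
predicts per-atom shifts of small organic molecules in solution
(typical nuclei: 13C, 19F) from datasets of assigned spectra that are
*small* by machine-learning standards — hundreds to a few thousand
molecules, which is what real collections look like once you restrict
to a heteronucleus, a solvent, or a compound class.

Two predictors share one data model and one evaluation framework:

* `nmr_gnn()` — a message-passing graph network regressor sized for
  the small-data regime;
* `hose_model()` — a HOSE-code nearest-neighbour lookup, the classical
  baseline, which abstains when it has never seen an environment;
* `naive_shift_model()` — the constant training-mean predictor that
  anchors the MASE metric.

## Data model

A `shift_record` is one molecule plus one assigned spectrum: element
symbols, coordinates (possibly absent), formal charges, bonds with
order in {single, double, triple, aromatic}, and (atom, ppm)
assignments for one nucleus. Atom indices in records are 0-based,
matching the nmrshiftdb2 SD property convention; the only 1-based/0-based
conversion happens at the molfile parser boundary. `read_sd_dataset()`
reads V2000 SD files whose property blocks carry
`Spectrum <nucleus> <k>` tags with `shift;aux;atomindex` triples;
`deduplicate_spectra()` retains one spectrum per compound (uniform,
seeded) and `filter_by_solvent()` restricts to one solvent through a
synonym map ("CDCl3" and "Chloroform-D1" are the same thing). Records
whose property block marks them as ab-initio calculated are dropped;
spectra are otherwise assumed experimental.

## Featurization

Nodes carry a one-hot element encoding over the *training* vocabulary
followed by four scalars: Slater atomic radius (pm), neutron count,
Pauling electronegativity, and electron affinity (eV). Edges carry the
bond length (Å) and a one-hot bond type. Every chemical bond becomes
two directed edges with identical features. Choices worth making
explicit:

* **Neutron count** is mass number of the most abundant isotope minus
  atomic number; "number of neutrons" is otherwise ill-defined for an
  element.
* **Element properties are vendored** as a static table rather than
  queried from a library at run time, so feature vectors cannot drift
  with dependency versions.
* **Geometry.** When a record carries usable 3D coordinates the bond
  length is the Euclidean distance between atom centers. Records
  without geometry (2D depictions, generated molecules) fall back to
  the sum of the two elements' covalent radii — deterministic and
  chemically sensible. No conformer embedding is attempted: in this
  package's target regime the bond length mostly re-encodes the
  element pair and bond order, and a stochastic embedder would cost
  reproducibility.
* **Explicit hydrogens** are part of the graph; attached-H count
  conditions shifts strongly.
* **Standardization.** The scalar feature columns and the regression
  targets are z-scored with training-set statistics stored inside the
  fitted model; 13C (~0–200 ppm) and 19F (~−300–0 ppm) otherwise put
  the readout on wildly different scales.

## The graph network

Encoder MLPs map edge and node features into a hidden width
(`e_i^0 = λ^E(ε_i)`, `v_i^0 = λ^V(ν_i)`); the global state `u^0` starts
at zero. Each of `M` rounds applies one graph-network block with a
learned edge update, node update and global update, the global update
being fed by an *edge* aggregate as well as the node aggregate:

```
e'_k = MLP_E(e_k ‖ v_send(k) ‖ v_recv(k) ‖ u)
v'_i = MLP_V(mean of incoming e'_k ‖ v_i ‖ u)
u'   = MLP_U(mean of all e'_k ‖ mean of all v'_i ‖ u)
```

A readout MLP maps the final node states `v_i^M` to one shift per
atom; the global state is carried through the rounds but is not read
out. Design choices that the architecture itself does not fix:

* **Aggregation is the arithmetic mean** everywhere. Molecules in one
  dataset differ in size by an order of magnitude; sums would make the
  latent scale depend on atom count.
* **Blocks do not share parameters across rounds** (configurable with
  `share_blocks`); sharing them is a stricter prior that we found no
  need for.
* **MLPs are 2 layers, ReLU hidden, linear output.** The default
  hidden width is 32: at the few-hundred-molecule scale this package
  targets, width 64 triples the training cost without measurable
  accuracy benefit on held-out data, and small widths are the
  appropriate capacity for small data. It is a single number in
  `gnn_config()` if you disagree.
* **Loss is MAE on standardized targets** (the headline metric is
  MAE; `loss_name = "mse"` switches), optimized with AdamW —
  decoupled weight decay 0.01, learning rate 1e-3, defaults `M = 6`
  message-passing rounds. These three were selected by 4-fold
  cross-validation in the original study of this architecture and are
  exposed in `gnn_config()`; `tune_gnn()` re-runs such a search on any
  training split.
* **Early stopping.** 10% of the *training* molecules are carved out
  for validation (never the test set, which stays untouched). Patience
  is 15 epochs, an epoch counts as progress only when validation MAE
  improves by at least 0.001 ppm, and a 300-epoch cap applies; the
  best-validation weights are kept regardless of where stopping
  lands. Batch size 32 molecules, collated into one block-diagonal
  graph per batch.
* **Determinism.** Initialisation, the validation carve-out, and batch
  shuffling all derive from `config$seed`; training twice with one
  seed gives bit-identical models.
* **Degenerate inputs.** Empty graphs and feature-dimension mismatches
  are shape errors; a non-finite loss aborts training with
  diagnostics rather than returning a silently broken model. The
  network predicts a finite shift for every atom of the target
  element — it never abstains — but refuses molecules containing
  elements outside its training vocabulary.

The forward/backward pass exists twice: a base-R reference
implementation and an RcppArmadillo kernel used for training and
prediction. The test suite holds them to each other at 1e-10 and holds
the gradients to central finite differences; this is the package's
substitute for trusting an autodiff framework.

## HOSE codes

A HOSE code describes an atom's environment as concentric
bond-distance spheres, canonicalized so that isomorphic environments
give identical strings. This package defines its own fully specified
dialect (center `El-degree;`; spheres joined by `/`; sibling groups
under distinct parents joined by `;`, siblings by `,`; bond symbols
`""`/`=`/`%`/`*` for single/double/triple/aromatic; ring re-encounters
emitted as `&`). It is internally canonical but *not* byte-compatible
with the CDK implementation — compatibility is unverifiable from the
outside, and lookup only requires that the table be built and queried
with the same generator.

Canonical ordering: atoms get Morgan-style refinement ranks (element,
degree, bond orders, iterated neighbourhood signatures); spheres are
breadth-first shells, so an atom appears once, at its bond distance,
and any further edge to it is a ring closure; siblings are ordered by
(bond rank, element, recursive subtree string), compared level by
level. Level-wise comparison is what makes an `s`-sphere code a
literal prefix of the `(s+1)`-sphere code — the property the fallback
search relies on. Exact ties after all three keys mean the branches
are isomorphic, so their order cannot affect the emitted string.

Prediction tries the deepest sphere first (`S_max = 6`, the classical
choice, configurable) and falls back sphere by sphere; the first depth
with entries returns the *mean* of the recorded shifts. If even the
one-sphere environment is unseen the model returns a missing
prediction — this abstention is a feature, reported as
`missing_fraction()` per atom (headline) and per molecule, and is the
basis of `matched_only_evaluation()`, which re-scores all methods on
the test molecules where HOSE can predict everything. No direction is
asserted for that comparison; whether pruning helps is empirical.

## Metrics and protocol

For signed errors `d_i = predicted − true` pooled over test atoms:
MAE, RMSE, `σ` = *population* standard deviation of `d_i` (so
`RMSE² = mean(d)² + σ²` and `σ ≤ RMSE` identically), and
`MASE = MAE / MAE_naive` where the naive predictor is the constant
training-set mean shift evaluated on the same atoms. MASE = 1 means
"no better than knowing the nucleus's average"; the naive model scores
exactly 1 on itself by construction. The denominator choice makes MASE
scale-invariant across nuclei and solvents and makes MAE/MASE ratios
agree across methods within one experiment, which is how published
tables of this kind behave. (Published tables occasionally show
`σ > RMSE`, impossible under the population-σ definition; that
inconsistency is noted, not emulated.)

Evaluation always splits at the molecule level, 75:25 by default, with
no separate test-derived validation set. `learning_curve()` draws
nested training subsets (the size-100 subset is a prefix of the
size-250 subset within one seed) so curves are comparable across
sizes, fits every method on the identical subset, and averages over
split seeds (default 3).

## The synthetic generator

`generate_shift_dataset()` grows random valence-valid molecules
(random heavy-atom trees over a palette, one optional ring closure,
hydrogen fill) and assigns every target-element atom
`base + Σ contrib1[element of 1-bond neighbours] +
Σ contrib2[element of 2-bond neighbours] + aromatic bonus + noise`.
The default constants (base 100 ppm, O +40, N +20, H −2 at one bond,
smaller second-shell terms, 1 ppm noise) are arbitrary test constants
scaled loosely like 13C — not chemistry claims. What the generator
emulates is exactly the locality premise both predictors rest on: with
zero noise the shift is a deterministic function of the 2-bond
environment, so a HOSE match at depth ≥ 2 must be exact, and a network
with ≥ 2 message-passing rounds can in principle drive the error to
the noise floor. `oracle_shift()` recomputes the rule independently
and is the ground truth in tests.

What it does **not** emulate: real electronic effects, conformational
and solvent dependence, long-range (>2 bond) influences, aromatic ring
currents, measurement error structure, or the heavy-tailed diversity
of real chemical space. A model passing the synthetic recovery tests
is shown to learn local additive structure from small samples — not to
predict real spectra; for that, point the same pipeline at an
nmrshiftdb2 extract with `reproduce_benchmark()`.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` run entirely on generated
data, at sizes chosen to exercise the small-data regime on a single
CPU: recovery and comparison studies use 300 training molecules
(400 generated, 75:25 split); learning curves run sizes 50–800 over
5 seeds; HOSE canonicality is checked over 20 molecules × 100 random
relabelings; noiseless-exactness and coverage monotonicity use a
260-molecule pool. The acceptance script reports the study's headline
numbers (MAE/RMSE/MASE/σ per method, HOSE missing fraction) as JSON.

## Known limitations

* No stereochemistry anywhere: neither in features nor in HOSE codes
  (standard, not stereo-enhanced, codes).
* Shift assignment requires the target atom itself; coupled/2D data
  are out of scope, as are solids, macromolecules and inorganics.
* The canonicalization rests on Morgan-style refinement; on highly
  regular graphs outside the generator's molecule class, refinement
  can in principle leave non-equivalent atoms tied. Within tested
  chemistry (trees plus simple rings) codes are invariant under
  relabeling.
* V3000 molfiles and live database queries are unsupported; the
  parser targets the deposited V2000 exports.
* One model per nucleus: no transfer between nuclei, no ensembling,
  no uncertainty estimates.
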