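---
title: "spabind: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spabind: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spabind)
```

## The model

spabind predicts, residue by residue, whether a protein residue binds
RNA. The ground truth is geometric: in a solved protein–RNA complex, a
protein residue is an **interface residue** when the minimum Euclidean
distance over all pairs of heavy atoms between it and any RNA residue
is strictly below a cutoff (default 5 Å). Hydrogens never participate;
alternate locations are resolved to the highest-occupancy copy; only
the first model of multi-model files is read. The strict inequality at
the cutoff is deliberate — a residue at exactly 5.000 Å is *not*
labelled — and the tests pin this boundary.

Prediction uses features built over a **spatial window**: the target
residue plus its $w-1$ nearest protein residues of the same chain in
3D, sorted by ascending inter-residue distance, ties broken by
ascending sequence index so that featurisation is deterministic. The
window contains the target itself at position 0; this semantics is
forced by the reference dimensionalities ($20w = 300$ profile features
and $w = 15$ ASA features at $w = 15$).

Which inter-residue distance defines "nearest" is genuinely open — the
source method never states it. We default to Cα–Cα (the standard
coarse residue position, cheap and deterministic) and expose
`min_heavy` and all-atom `centroid` as alternatives through the
`metric` argument. Residues lacking a Cα fall back to their centroid
with a warning rather than aborting a chain.

## Feature encodings

* **SpaPF** — concatenated per-residue profile rows (20 columns each,
  fixed order `ARNDCQEGHILKMFPSTWYV`) of the window members, target
  first. Profiles are PSI-BLAST PSSMs when available; the
  `pseudo_profile()` fallback substitutes the published BLOSUM62 row of
  each residue so the pipeline runs without any database search. By
  default profile entries pass through a logistic squash
  $x \mapsto 1/(1+e^{-x})$ before featurisation: bounded features keep
  RBF-kernel distances on one scale. Raw mode is retained and used by
  the exactness tests.
* **SpawASA** — the solvent-accessible area of each window member,
  damped by distance. The damping form is not documented in the source
  method, only the idea of distance-weighted accessibility; we chose
  $ASA_j \cdot e^{-d_j/d_0}$ with $d_0 = 8$ Å because it is smooth,
  equals the raw ASA at the target ($d_0$ is config-exposed and
  $d_0 = \infty$ degenerates exactly to the unweighted ASA window,
  which the tests verify). This is an engineering choice, not a claim
  about the original formula.
* **SpaSecond** — helix/strand/coil occurrence frequencies within the
  window, i.e. a 3-vector summing to 1. Whether the target's own state
  should additionally appear as a separate component cannot be
  determined from the source; frequencies-only is implemented.
* **SeqProfile / SeqASA** — the sequence-window baselines: centred odd
  windows, zero-padded where they overhang a terminus.

Chains shorter than $w$ have their spatial window truncated to the
chain and the feature vector tail zero-padded, keeping dimensionality
fixed.

Annotations come from classic DSSP files (8-state codes collapsed
H,G,I→H; E,B→E; rest→C — the dominant convention) or from the built-in
Shrake–Rupley routine: van der Waals radii C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 Å, probe 1.4 Å, and a deterministic golden-section
spiral lattice of sphere points (default 960, ≈1% accuracy on the
analytic sphere) so results need no random seed. ASA is used raw in
Å², not relative accessibility — no normalisation is documented
upstream, and raw is the default with relative left to the caller.
Protein-only occlusion matches DSSP's convention; `include_rna = TRUE`
lets the RNA bury protein surface for sensitivity analyses.

## The hybrid classifier

Training is exactly a soft-margin RBF SVM. The dual QP is solved by a
compact in-package SMO (libsvm conventions: maximal-violating-pair
working-set selection, per-sample box constraints, stopping tolerance
$10^{-3}$ by default). The environment this package targets ships no R
SVM solver, so the solver is built in; the test suite cross-checks its
decision values against scikit-learn's SVC on small problems to
$10^{-3}$, and checks the tighter internal contract — the stored
support vectors, coefficients and bias reproduce the solver's decision
function through `decision_value()` to $10^{-6}$.

Prediction routes on the functional margin $|f(x)|$:

* $|f(x)| > T$ — the SVM sign decides (`routing = "svm"`);
* otherwise the $k$ nearest support vectors in the kernel-induced
  distance $\sqrt{2 - 2K(x, x_i)}$ vote, class $+1$ winning iff
  $C_1 \cdot \#\{+1\} > C_2 \cdot \#\{-1\}$; a tie falls back to the
  SVM sign (`routing = "knn"`).

Design choices where the source is silent or unreproducible:

* the printed form of the voting rule is not available; the weighted
  vote above follows the verbal description and the SVM-KNN
  literature, and is flagged here as a reconstruction;
* the KNN candidate pool is the support vectors (the "representative
  points" near the hyperplane); `knn_pool = "all"` switches to all
  training points for comparison;
* $T$ is never printed; default $T = 1$, the margin boundary;
* $k$ is never printed; default $k = 5$ (small, odd, standard);
* $C_1, C_2$ default to $1$ and $N_-/N_+$ of the training set — the
  documented imbalance rule; they weight the vote, not the SVM box
  constraints (an optional `svm_class_weights` argument exists but
  defaults to unweighted, since nothing indicates the SVM itself was
  class-weighted);
* with $T = 0$ the hybrid is pointwise the plain SVM, and the tests
  enforce this identity;
* scaling $C_1$ and $C_2$ together never changes a prediction
  (property-tested).

Default kernel parameters $C = 1$, $\gamma = 0.0625$ are the
documented optimum of the reference experiments and are the package
defaults.

## Evaluation

`compute_metrics()` reports total accuracy $Q$, sensitivity,
specificity and MCC from confusion counts. Zero-denominator metrics
are reported as `NA` — explicitly undefined, never silently zero.
Counts are cast to double before the MCC product, which otherwise
overflows 32-bit integers near $N \approx 500$. Pooled
cross-validation metrics are computed from summed confusion counts
across folds, not averaged per-fold metrics, matching the "total"
accuracy definition.

`cross_validate()` assigns every sample to exactly one test fold.
Residue-level stratified splitting is the default (consistent with the
era's practice); chain-level splitting assigns whole chains to folds.
The difference matters — see the leakage note below. Jackknife
(leave-one-out) is deliberately not offered.

## The synthetic world

`make_complex()` builds an ideal helical Cα trace (radius 2.3 Å, rise
1.5 Å, twist 100°/residue) with one pseudo side-chain carbon per
residue, and anchors one 3-atom pseudo-nucleotide radially outward
from each patch residue's side chain at exactly `rna_offset` Å. The
geometry guarantees that at offset 4 Å the patch and only the patch is
labelled at the 5 Å cutoff, and at 8 Å nothing is — the generator is a
controllable probe of the labelling rule, not a physical RNA model.

`make_profiles()` draws non-interface rows i.i.d. standard normal and
shifts interface rows by `profile_signal` on five fixed columns;
`profile_signal = 0` makes the classes identically distributed by
construction. `make_dataset()` builds several independent chains with
the patch at seed-dependent positions; the default patch fraction 0.4
reproduces the reference class imbalance $N_-/N_+ = 1.5$. Defaults of
6 chains × 60 residues give 360 samples — large enough for stable
cross-validation, small enough for second-scale tests.

What the generator does **not** emulate: real side-chain packing and
rotamers, sequence-dependent profile correlations, DSSP's actual
hydrogen-bond secondary-structure assignment (the helix fixture is
annotated all-H by construction), RNA conformational realism, and
homology between chains. A green end-to-end test therefore establishes
that the pipeline recovers a planted, profile-borne signal through
featurisation, training and evaluation — it says nothing about
accuracy on real complexes, which depends on real profiles and real
geometry.

### Leakage and the null model

Spatial windows of neighbouring residues share up to $w-1$ of their
$w$ profile rows. Under a residue-level split, a test residue's
near-duplicate feature vectors sit in the training set with the same
label, and an RBF SVM exploits this: even with `profile_signal = 0`
the pooled MCC reaches ≈ +0.2 systematically. That signal comes from
the evaluation protocol, not the features. The no-spurious-signal
property is therefore checked under the chain-level split, where the
null MCC fluctuates around 0 (|MCC| ≤ 0.12 over the seeds measured)
and the planted-signal case still scores Q ≈ 0.98, MCC ≈ 0.95. Users
evaluating on real data should prefer the chain split for the same
reason — residue-level numbers are optimistic whenever windows
overlap fold boundaries.

### Window width

The benefit of a wider spatial window appears only when a single
residue's own features are individually ambiguous: with a strong
planted signal (`profile_signal = 3`) the target row alone classifies
almost perfectly and wider windows merely add noise. The window-width
acceptance check therefore uses a weak-signal fixture
(`profile_signal = 1`, 8 chains × 60 residues, chain split), the
regime where aggregating 15 neighbours beats 3 — verified across ten
generator seeds. Generator defaults are unchanged by this; the fixture
is constructed for that property.

## Numerical choices and degenerate inputs

* SMO: stopping tolerance $10^{-3}$ (tests that compare against an
  external solver tighten it to $10^{-5}$), $10^7$ iteration cap with
  a warning on non-convergence; support vectors kept at
  $\alpha > 10^{-8}$.
* Kernel distances clamp $2 - 2K$ at 0 before the square root to
  absorb rounding.
* Neighbour ties (equidistant residues) break by ascending sequence
  index; KNN distance ties break by support-vector order. Both are
  deterministic.
* `k` larger than the candidate pool clamps with a warning.
* Single-class training sets, empty structures, zero-count confusion
  tables, and even sequence windows raise early, named errors.
* All randomness flows through explicit seeds (`fixture_spec$seed`,
  the CV `seed`); coordinate generation is seed-free pure geometry,
  and the sphere lattice is deterministic.

## Known limitations

* mmCIF parsing covers the `_atom_site` loop of standard coordinate
  files, not multi-datablock or quoted-whitespace edge cases.
* No biological-assembly expansion or symmetry mates; NMR ensembles
  use the first model only.
* The Shrake–Rupley fallback provides no secondary structure; without
  DSSP input, structures are annotated all-coil with a warning.
* Feature encodings are evaluated separately; concatenation across
  encodings and feature selection are out of scope.
* The SMO solver is quadratic in memory in the number of training
  samples (full kernel matrix); it is sized for the thousands-of-
  residues scale, not millions.
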