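# spabind

Prediction of RNA-binding residues on protein chains from the 3D
structure of protein–RNA complexes, using **spatial-adjacency feature
encodings** and a **hybrid SVM-KNN classifier**.

## The problem

Protein–RNA recognition underlies splicing, translation, viral assembly
and many regulatory processes, but experimentally mapping which protein
residues touch the RNA is slow and expensive. Given a solved complex,
the *interface residues* can be defined geometrically — a protein
residue is an interface residue when the closest distance between any
pair of heavy atoms from that residue and any RNA base is **strictly
less than 5 Å** — and a classifier can then be trained to recognise
such residues from features computable for proteins of unknown binding
mode.

The central idea implemented here is that a residue's context should be
taken from its **spatial neighbourhood**, not just its sequence window:
RNA-binding proteins act as folded 3D objects, so the residues that
surround a target in space carry more information than the residues
that happen to flank it in sequence.

## Features

For a target residue *i*, let its size-*w* spatial window be the target
plus its *w − 1* nearest protein residues, sorted by ascending 3D
distance (Cα–Cα by default). Three encodings are built over this
window, with two sequence-window baselines for comparison:

| encoding | dimension | content |
|---|---|---|
| `SpaPF` | 20·w | concatenated PSSM profile rows `(pssm_i, pssm_i,1, …, pssm_i,w−1)` in ascending-distance order |
| `SpawASA` | w | solvent-accessible areas `ASA_i,j` damped by distance, `ASA_i,j · exp(−d_j/d0)` |
| `SpaSecond` | 3 | helix/strand/coil occurrence frequencies `(f_H, f_E, f_C)` within the window |
| `SeqProfile` | 20·w | profile rows of the centred sequence window (zero-padded at termini) |
| `SeqASA` | w | raw ASA of the centred sequence window |

At the reference window *w = 15*, `SpaPF` is a 300-dimensional vector
and `SpawASA` a 15-dimensional one. Profiles come from PSI-BLAST ASCII
PSSM files (or a BLOSUM62 pseudo-profile fallback needing no database
search); ASA and secondary structure come from DSSP files or the
built-in Shrake–Rupley routine.

## Classifier

Training is a standard soft-margin RBF SVM (decision function
`f(x) = Σ_i a_i K(x, x_i) + b`, `K(x,y) = exp(−γ‖x−y‖²)`), solved by an
in-package SMO routine. Prediction is hybrid: when the functional
margin `|f(x)|` exceeds a threshold `T`, the SVM sign decides;
otherwise the sample lies near the hyperplane, where the SVM is least
reliable, and a **class-weighted k-nearest-neighbour vote among the
support vectors** decides instead, using the kernel-induced distance
`√(2 − 2K(x, x_i))`. The vote weights default to `C1 = 1` and
`C2 = N−/N+` (the class imbalance of the training set; 1.5 for the
dataset the defaults emulate), and the default kernel parameters are
`C = 1`, `γ = 0.0625`.

Evaluation is 5-fold cross-validation with accuracy `Q`, sensitivity,
specificity and Matthews correlation coefficient computed from pooled
confusion counts; folds split at residue level (stratified) or chain
level (leakage-controlled).

## Worked example

Everything below runs without any input files: the synthetic generator
builds helical protein chains with an RNA strand probing a chosen patch
of residues, plus matching profiles and annotations.

```r
library(spabind)

ds <- make_dataset(n_chains = 6, n_residues = 60, profile_signal = 3, seed = 1)
ft <- featurize_dataset(ds, encoding = "SpaPF", w = 15)
ft
#> feature_table: SpaPF (w=15), 360 residues x 300 features, 144 interface (40.0%)

cv <- cross_validate(ft, folds = 5, split_unit = "chain", seed = 1)
cv
#> 5-fold CV (chain-level split, seed 1)
#> pooled: Q=0.9833 Sen=0.9931 Spe=0.9769 MCC=0.9657 (TP=143 FP=5 TN=211 FN=1)

m <- svmknn_train(ft, C = 1, gamma = 0.0625, T = 1, k = 5)
m
#> svmknn_model: 189 SVs / 360 samples, C=1 gamma=0.0625, T=1 k=5 C1=1 C2=1.5 (pool: support_vectors)
p <- predict(m, ft$X)
sum(p$routing == "knn")
#> [1] 94
```

The 360 residues (40% interface, giving the reference class ratio
N−/N+ = 1.5) are classified almost perfectly because the generator
plants a clear profile signal on interface residues
(`profile_signal = 3`); with `profile_signal = 0` the pooled MCC drops
to ≈ 0 under the chain-level split. 94 of the 360 predictions fell
inside the margin band `|f(x)| ≤ 1` and were decided by the KNN vote.

Real structures go through the same path:

```r
s   <- read_structure("complex.pdb")          # or .cif
lab <- label_interface_residues(s, cutoff = 5)
p   <- scale_profile(read_pssm("chain.pssm", chain_id = "A"))
ann <- read_dssp("complex.dssp")
ft  <- featurize_complex(s, list(A = p), ann, encoding = "SpaPF", w = 15)
```

## Command line

```sh
spabind simulate  --n-chains 6 --seed 1 --out-dir ds/
spabind label     --structure ds/A.pdb --out labels.tsv
spabind featurize --structure ds/A.pdb --profile-tsv ds/A.profile.tsv \
                  --encoding SpaPF --w 15 --out feat.tsv
spabind train     --features feat.tsv --T 1 --k 5 --out model.json
spabind predict   --model model.json --features feat.tsv --out pred.tsv
spabind evaluate  --features feat.tsv --folds 5 --seed 1 --out metrics.json
spabind sweep     --dataset-dir ds/ --w-values 13,15,17,19 --out sweep.tsv
```

(`spabind` is the installed `exec/spabind` launcher; equivalently
`Rscript -e 'spabind::spabind_cli()' --args …` or calling
`spabind_cli(c("label", …))` from R.)

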