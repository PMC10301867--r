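---
title: "pocketgcn: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pocketgcn: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

pocketgcn predicts protein–ligand interaction from two graphs and
nothing else: no docking pose, no complex structure, no conformer
generation. The underlying assumption is that the identity and contact
topology of the pocket residues, together with the 2D chemistry of the
ligand, carry enough signal to separate binders from non-binders and to
rank binding strength. That assumption buys speed — a forward pass is a
handful of sparse matrix products — at the price of everything a pose
would tell you: steric fit, specific hydrogen-bond geometry,
displaceable waters.

## Pocket representation

A pocket is defined relative to a *reference ligand*: every residue
with at least one heavy atom within `cutoff_nm` of any ligand atom is
kept (inclusive boundary). Two cutoffs are used throughout: 0.6 nm
gives a tight first shell that works better for the binary
binder/non-binder question; 0.8 nm keeps a second shell whose
longer-range contacts help the affinity regression. Residue-residue
edges use a 0.5 nm minimum heavy-atom distance, also inclusive.
Distances are computed on heavy atoms only; deposited structures are
inconsistently protonated, and making hydrogens irrelevant keeps the
pocket invariant to that choice. Waters, ions, other hetero residues
and hydrogens are never pocket candidates; non-standard amino acids
(MSE, PTR, ...) are dropped with a warning rather than remapped,
because the node feature vocabulary is exactly the 20 standard
residues. Internally all lengths are Angstrom (the PDB native unit);
the nm cutoffs are multiplied by 10 at the API boundary.

## Node features

Pocket nodes carry either a 20-dimensional one-hot residue encoding
(alphabetical by 3-letter code, ALA first, VAL last) or a
30-dimensional *molecular vector*: the sum, over the residue's
circular-substructure sentence, of substructure embeddings trained
word2vec-style (skip-gram with negative sampling) on a SMILES corpus.
The free, neutral amino acid (backbone included) defines each residue's
chemistry; capping would be an equally defensible convention but the
free amino acid is simpler to state and reproduce. Substructure
identifiers unseen at training time contribute a zero vector, so
unknown chemistry is silent rather than noisy. The embedding dimension
defaults to 30 — small enough that a residue table is a 20×30 text
file — and the substructure radius to 1, the published mol2vec
convention. Window (5), negative samples (5), epochs (5) and
learning rate (0.025) follow common word2vec practice; none is
critical at desk scale because the table that ships with the package
(`inst/extdata/residue_vectors_synthetic.tsv`) is trained on a small
synthetic fragment-grammar corpus and is a stand-in: it exercises every
code path and gives distinct, reproducible residue vectors, but it does
not encode the chemistry a large real compound collection would.

Ligand nodes are heavy atoms in canonical order (the SMILES is
canonicalized before graph construction, so node order is deterministic
for any spelling of the same molecule) with the five-feature scheme:
atom-symbol one-hot over a fixed 43-element vocabulary plus an "other"
slot, heavy-neighbour count, attached hydrogens, implicit valence and
an aromatic flag — 48 columns in total. "Implicit valence" is read as
the hydrogen count supplied by the valence model; a `valence_gap` mode
(typical valence minus heavy-bond count) is available for users who
read it the other way. The worked examples that anchor this choice
(aromatic carbon in benzene → 1, methane carbon → 4, ethanol oxygen
→ 1) come out identically under both readings for neutral organics.
Bond types are not edge features; aromaticity lives on atoms.

## Network and training

Each branch applies two Kipf-style graph convolutions,
$H' = \mathrm{ReLU}(\hat A H W + b)$ with
$\hat A = D^{-1/2}(A+I)D^{-1/2}$, at widths 64 and 128, followed by
global max pooling (mean pooling is available by configuration). The
pooled 128-vectors are concatenated and passed through fully connected
layers 256 → 64 → 1 with ReLU and dropout 0.2 after each hidden layer.
The BC head applies a sigmoid and trains with binary cross-entropy; the
RG head is linear and trains with mean squared error. The heads are
fully independent models — no weight sharing.

Hidden widths, pooling, optimizer and learning rate are this package's
declared defaults, not reconstructions: Adam at 5e-4, batch size 128.
Batches are assembled once (block-diagonal normalized adjacency, cached)
and visited in a seeded random order each epoch; gradients are analytic
and are verified against central differences in the test suite. When a
test set is supplied the head's headline metric (AUC or Pearson r) is
evaluated on a cadence and the best-on-test parameters are returned,
which is the pragmatic reading of choosing the final model by test-set
convergence. All randomness — initialization, batch order, dropout —
derives from one seed, and the implementation restores the caller's RNG
state, so training histories reproduce exactly.

Numerical conventions worth stating: a single-node graph has
$\hat A = 1$ and passes through pooling unchanged; max pooling breaks
ties by first node, which makes scores deterministic but means the
subgradient at exact ties is one of the valid choices; BC scores are
clamped to $[10^{-12}, 1-10^{-12}]$ inside the loss; a non-finite
training loss aborts with a learning-rate hint rather than continuing.

## Data pipeline

Affinities arrive as molar Ki, Kd or IC50 and are pooled into one
target, `pKa = -log10(Kx)`; pooling the three measures trades
assay-type purity for dataset size, and the measure is kept as
provenance so a stratified evaluation remains possible. The energy
conversion `ΔG = RT·ln10·pKa` uses R = 1.987e-3 kcal/(mol·K) and
reports magnitudes by default (a `thermodynamic` flag negates).
Presumed non-binders are built by cross-combination — each pocket
paired with ligands native to other complexes — with exact-pair
exclusion, uniform seeded sampling, and global uniqueness of generated
keys. No similarity-based exclusion is applied: some cross-pairs may be
true binders, which is accepted label noise in this construction.
Splits are disjoint on (pocket, ligand) pair keys, not on protein
clusters, so homologous pockets can appear on both sides; class balance
is restored by replicating positives (factor 3 by default) rather than
discarding negatives.

## Metrics

The evaluation suite implements both bundles with documented tie
conventions: score ≥ threshold predicts positive; AUC is the normalized
Mann–Whitney statistic with ties credited 0.5; the concordance index
uses the same credit over ordered pairs, which makes CI equal AUC
exactly for binary labels; MCC with a zero denominator factor is 0;
precision with no predicted positives is 0 with a warning; Spearman
uses average ranks. Every metric is tested against an independent
brute-force implementation at 1e-9.

## Screening

The virtual-screening workflow streams a SMILES library against one
pocket in constant memory: parse, featurize, score with BC and RG,
filter (`bc_score ≥ 0.99` and `rg_score ≥ 8.6` by default — the BC
threshold reflecting that candidate lists in practice carry classifier
scores at essentially 1, the RG threshold a strong-binder pKa), rank by
RG score, cluster the survivors. Clustering is Ward's method on the
Euclidean embedding of 2048-bit radius-2 circular fingerprints (Ward's
criterion requires Euclidean geometry), cut at six groups; each group
is represented by its medoid under Tanimoto distance, the member
minimizing summed distance to the rest. Rows are re-ordered canonically
before clustering so the partition and medoids are invariant to input
order. Docking and simulation stages downstream of this triage are out
of scope; the candidate list (`candidates.smi`) is the hand-off point.

# The synthetic benchmark

`make_benchmark()` builds the package's study system: toy complexes
whose residues sit on three jittered shells around a planted ligand
(inner-shell atoms within 6 Å, middle within (6, 8], outer beyond 8 Å,
with safety margins so the 0.6/0.8 nm pockets recover the shells
exactly), and a fragment-grammar ligand library. Two latents drive the
planted signal: pocket hydrophobicity *h* (the probability each residue
is drawn from the hydrophobic set) and ligand aromaticity *a* (the
share of benzene fragments, `round(a·n_units)` of 3–6 fragments, a
deterministic share so the realized aromatic-atom fraction tracks the
latent tightly). Labels follow `pKa = 3 + 8·h·a + ε`,
`ε ~ N(0, 0.3)`, with the binary binder label `pKa ≥ 7`.

The signal deliberately rides on features the network actually sees —
residue identity and atom aromaticity — and not on graph size, so
learning it demonstrates that the representations are used; a
shuffled-label control trained identically stays at chance AUC. The
benchmark conditions used by the test suite are 500 complexes × 300
ligands with cross-negative ratio 3 (2,000 pairs, split 80/20), 100
training epochs for each head and 30 for the control, sizes at which
the whole learnability check runs in minutes on one CPU. What passing
shows: the full path from PDB text through pocket extraction,
featurization, batching, training and evaluation can recover a known
composition-level signal. What it does not show: performance on real
binding data, where the signal is weaker, noisier, and partly geometric
— nothing in the toy system tests shape complementarity, and its
chemistry spans a few fragments rather than drug space.

# Known limitations

- The shipped residue table is synthetic-corpus-trained; for real use,
  retrain `train_substructure_vectors()` on a large SMILES collection
  and rebuild the table.
- Pocket definition requires a bound reference ligand; apo pockets need
  an external pocket prediction first.
- mmCIF input, protonation, bond-type edge features and 3D ligand
  conformers are out of scope.
- Pair-level (not sequence-identity) splits overstate generalization
  across homologous targets.
- The skip-gram and GCN trainers are desk-scale: correct, reproducible
  and tested, but not tuned for corpora of millions of molecules.
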