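---
title: "Cutoff-scanning structural signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff-scanning structural signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsigna)
```

This vignette is the package's own account of the method it implements:
the model, the tunable parameters and why their defaults are what they
are, the numerical conventions, what the synthetic-data generators do and
do not emulate, and the design decisions taken where the method's public
description leaves room.

## The signature model

A peptide structure is reduced to a vector of pair counts. Each heavy
atom is a node labelled with a subset of eight pharmacophore categories —
acceptor, donor, aromatic, hydrophobic, negative, neutral, positive,
sulfide — assigned purely from its residue and atom name by a packaged,
editable typing table. For every unordered category pair $\{c_1, c_2\}$
(36 with repetition) and every cutoff $d = k\Delta$, $k = 1 \dots
L/\Delta$, the cumulative signature records the number of unordered atom
pairs within $d$ of each other in which one atom carries $c_1$ and the
other $c_2$ (for $c_1 = c_2$, both carry it). Distances are plain
Euclidean distances, so the signature is exactly invariant under rigid
motions — the test suite asserts bit-identity under random rotations and
translations.

The defaults, $\Delta = 0.2$ Å and $L = 20$ Å, give $36 \times 100 =
3{,}600$ features. 0.2 Å resolves bond-length-scale differences;
20 Å spans a whole peptide of a few dozen residues, so the long-cutoff
features converge to total pair counts per category pair and encode
composition while short cutoffs encode local geometry.

Conventions worth stating precisely:

* **Cumulative vs interval.** The cutoff-scanning lineage accumulates
  counts ($d \le k\Delta$); a band-count reading (counts in
  $((k-1)\Delta,\, k\Delta]$) is also natural. We default to cumulative
  and expose `mode = "interval"`; the two are related by a cumulative
  sum, which the tests verify, so no information hangs on the choice.
* **Bin edges.** A distance lands in bin $\lceil d/\Delta \rceil$ with
  the right edge closed ($d = k\Delta$ belongs to bin $k$); a $10^{-9}$
  relative epsilon guards against floating-point round-off at edges.
  Coincident distinct atoms cannot occur in sane input, so $d = 0$ needs
  no convention.
* **Unordered pairs, multi-label at most once.** Counting unordered
  category pairs is forced by the published vector length
  ($36 \times 100$); a multi-labelled atom pair increments a matching
  feature at most once, which keeps every feature bounded by
  $n(n-1)/2$ — a property test.
* **All atom pairs count.** No topological exclusion of bonded or
  intra-residue pairs: the short-cutoff features therefore largely
  reflect covalent geometry, which is deliberate — it is the simplest
  faithful reading and keeps the computation a pure function of
  coordinates and types.
* **Hydrogens are excluded.** X-ray depositions mostly lack them and NMR
  models carry them; mixing would make the two experiment types
  incomparable. They are parsed and flagged, just never counted.
* **NMR ensembles.** Model 1 is the working model everywhere; all
  models are retained by the parser and selectable.

The implementation computes one distance matrix and, per category pair,
a vectorized mask-and-tabulate; an independent naive triple-loop oracle
(atom pairs × category pairs × bins, written first) is held against it in
the tests for peptides of up to 50 atoms.

## Atom typing

The exact typing table behind the published signatures is not public, so
the packaged table is a reconstruction from standard pharmacophore
chemistry, and it is *data*, not code: a tab-separated file
(`residue, atom, categories`) that can be swapped wholesale. The
defaults: backbone N donor (except proline), backbone O acceptor,
carbonyl and amide carbons neutral, aliphatic carbons (Cα included)
hydrophobic, ring atoms of Phe/Tyr/Trp/His aromatic (carbons also
hydrophobic), carboxylate oxygens of Asp/Glu negative + acceptor,
side-chain nitrogens of Lys/Arg and the protonatable His ring nitrogens
positive + donor, hydroxyl oxygens donor + acceptor, Cys/Met sulfurs
sulfide, terminal OXT negative + acceptor. Multi-label assignment is
intentional: the lineage of pharmacophore-based signatures uses it, and a
single-label scheme is a file edit away. Atoms without a table entry
degrade to `{neutral}` with a warning tally rather than failing, so
modified residues never abort a batch. `validate_table()` checks a table
for completeness against the canonical heavy-atom dictionary of the 20
standard residues and hard-errors on categories outside the 8-member
universe.

## Complex extraction

The collection filter mirrors the database-construction criteria:
peptide = chain of 2–50 amino-acid residues (bounds inclusive; chain
length counts residues bearing a Cα, so modified amino acids deposited as
HETATM count, ions and ligands do not), at least two chains, experiment
X-ray or NMR. The stated X-ray rule, "resolution > 2.5 Å", would *keep
only low-quality structures*; we read it as a typo for the conventional
quality filter and default to resolution ≤ 2.5 Å, but the comparator is
an explicit field of `collection_criteria()` rather than a silent guess.

Entries are the Cartesian product of protein chains and peptide chains,
kept when at least one inter-chain heavy-atom pair lies within the
contact cutoff. The cutoff defaults to 5.0 Å — the conventional
non-covalent contact radius; the source description computes a "contact
interface" without printing a distance — and is a parameter everywhere it
appears. Peptide-only files (every chain 2–50 residues) yield no entries
since an entry needs a protein side.

Structure I/O is a fixed-column PDB v3.3 reader/writer of its own: the
pipeline needs string-level parsing, per-record skip-with-warning on
malformed lines, retention of all models, and a specific
altloc/water/hydrogen policy (keep the highest-occupancy altloc, ties
alphabetically; drop waters; flag hydrogens). A cross-check against an
independent PDB reader (`bio3d`) on a written fixture is part of the test
suite.

## Physicochemical properties

All sequence statistics use documented, configurable scales, since the
upstream database names the properties but not the definitions:

* molecular weight — average residue masses + one water;
* aromaticity — relative frequency of F/W/Y (Lobry–Gautier);
* instability index — Guruprasad dipeptide weights $(10/L)\sum
  \mathrm{DIWV}(x_i, x_{i+1})$, table shipped as data;
* isoelectric point — Henderson–Hasselbalch net charge over termini and
  D/E/C/Y/H/K/R with the EMBOSS pKa set, solved by 60 bisection steps on
  [0, 14] (interval $\ll 10^{-3}$ pH; tested against a $10^{-4}$-step
  grid scan of the same charge function);
* hydrophobic fraction — share of residues in {A, V, L, I, P, F, M, W}
  (the Kyte–Doolittle positive set).

Binding area is buried SASA, $\mathrm{SASA}(P) + \mathrm{SASA}(p) -
\mathrm{SASA}(Pp)$, reported both as the total and per side (half the
total) since "binding area of protein and peptide" is ambiguous between
the two. SASA is a built-in Shrake–Rupley implementation: each atom's
accessible sphere (van der Waals radius + 1.4 Å water probe) is sampled
on a fixed Fibonacci lattice of 960 points, making results deterministic;
the isolated-sphere closed form $4\pi(r + 1.4)^2$ is reproduced within
1%, and doubling the lattice changes a 6-residue peptide's total by well
under 0.5%. Because the lattice is fixed in space, SASA-derived
quantities are rigid-motion invariant only to lattice tolerance (a few
percent at 960 points), unlike the signatures' exact invariance.

## Evaluation protocol

`run_protocol()` reproduces the published validation recipe: a stratified
70/30 split per replicate (three replicates, seeds {1, 2, 3}, all
recorded in the report), seven classifier families with the protocol's
printed hyperparameters as defaults, and replicate-averaged macro
metrics. Stratification is our choice — the protocol doesn't state it,
but the datasets it describes are imbalanced and unstratified splits can
empty a small class's test stratum. Rounding `0.7·n` happens per class.
`evaluate_models()` is the fixed-split variant (replicates vary only the
model seed) for when the partition itself is under study.

Model mapping: SVM → `e1071` (linear, C = 1, tolerance 0.001, no
rescaling), neural network → `nnet` (one hidden layer, 300 units, L2
0.001, 200 iterations), gradient boosting → `xgboost` (100 trees, η =
0.1, depth 3), ridge logistic regression → `glmnet` (α = 0, λ = 1/n for
C = 1), decision tree → `rpart` (min leaf 2, min split 5; depth capped
at `rpart`'s maximum of 30, below the protocol's printed 100 — deeper
trees are unreachable at these sample sizes anyway; the GUI-specific
"stop at 95% majority" rule has no `rpart` equivalent and is not
emulated), random forest → `randomForest` (10 trees, node size 5). The
distance-weighted Manhattan 3-NN of the protocol exists in no installed
package and is implemented directly. Multi-class AUC is macro-averaged
one-vs-rest on predicted class probabilities, the common default where
the averaging is unstated; exact numeric parity with the original GUI
tool's internals is not promised.

Two practical notes. `nnet` optimizes with BFGS, which is impractical at
300 hidden units on 3,600-input signatures; the neural-network family is
intended for reduced-width inputs, and `nn_hidden` is exposed to shrink
the layer. And gradient boosting places split thresholds exactly at
observed class boundary values, so on *perfectly* separated clusters a
test point marginally outside its class's training range can still flip —
visible as the occasional single off-diagonal count in otherwise clean
confusion matrices.

## What the synthetic generators emulate — and what they don't

`make_synthetic_structure()` builds chains as gently wandering extended
backbones: consecutive Cα exactly 3.8 Å apart, N/C/O placed in a local
frame, side-chain heavy atoms (correct PDB names per residue) extending
perpendicular to the chain axis at bonded distances. The geometry is
chemically *plausible* — correct distance scales, no clashes by
construction — but not energy-minimized and never folded: no secondary
structure, no real rotamers, no packing. `make_synthetic_complex()`
translates the peptide so the minimum inter-chain heavy-atom distance
hits a requested value, which lets tests construct guaranteed-contact and
guaranteed-no-contact cases.

The labeled-dataset generator makes one template peptide per class
(distinct random sequence, length and backbone wander) and derives
members by adding isotropic Gaussian coordinate noise (default σ =
0.1 Å, a tight-ensemble scale). Class signal therefore exists in both the
geometry and the atom-type channels, by construction. The
`case-study-1` preset scales a five-class, 503:183:161:142:122
size-imbalanced dataset down to ≈250 peptides — sizes chosen to keep the
whole analysis in seconds on one CPU while preserving the imbalance
structure. A passing desk-scale experiment shows the pipeline is
self-consistent: signatures of structurally distinct classes are
separable by the protocol. It does **not** show that real sequence
clusters, whose members differ by real conformational and compositional
variation rather than additive Gaussian noise, reach any particular
accuracy — that experiment requires the real database and is out of
scope here.

Test problem sizes throughout are deliberately small (peptides of 5–50
atoms for oracle comparisons, 50-structure filter corpora, ≈250-peptide
classification runs); every size is stated in the tests themselves.

## Known limitations

* PDB format only; no mmCIF, no assembly expansion.
* Typing is protonation-blind (His is always treated as protonatable
  positive; no pH dependence) and covers the 20 standard residues plus
  OXT — ligand atoms are not typed.
* The typing table is a documented reconstruction, not the unpublished
  original; signatures are comparable *within* a table, and the table in
  force should be reported alongside any dataset.
* SASA is O(n²) per structure and intended for peptide-complex scale,
  not proteome scans.
* Interface records count heavy-atom proximity only; no hydrogen-bond or
  salt-bridge perception.
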