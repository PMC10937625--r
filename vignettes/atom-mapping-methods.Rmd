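---
title: "Atom-to-atom mapping with rxnmapr: models, templates, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-to-atom mapping with rxnmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnmapr)
library(dplyr)
```

## The problem

Atom-to-atom mapping (AAM) assigns every heavy atom of a reaction's
products to the reactant atom it originated from.  Downstream reaction
machine learning — retrosynthesis, outcome prediction, condition
prediction — extracts reaction centers and templates from mapped data, so a
mapping error (for example, attributing the hydroxyl oxygen of a hydrolysis
product to the ester's leaving-group oxygen instead of to water) silently
converts training data into chemically wrong supervision.  rxnmapr
implements a supervised graph-network mapper trained through a
human-in-the-loop active-learning workflow, with a *knowledge-based*
confidence notion: a predicted mapping is trusted only when the reaction
template it implies has already been verified by the labeling authority.

## Model

Reactants and products are handled as separate merged molecular graphs
(heavy atoms only; hydrogens are implicit atom attributes).  The network
has three stages:

1. **Message passing (3 rounds).**  Each atom starts from a fixed feature
   vector (element one-hot with an unknown slot, degree, formal charge, an
   approximate sp/sp2/sp3 hybridization derived from incident bond orders,
   aromaticity, implicit-H count, ring membership; bonds carry order
   one-hot, conjugation, ring flags).  Each round builds a message
   `relu(W_m [h_u ; e_uv])` per directed bond, sums messages at the target
   atom, and updates `h_v <- relu(W_u [h_v ; m_v])`.  Sum aggregation with
   bond features concatenated to the neighbour state is our choice within
   the generic message-passing family; isolated atoms (e.g. water) pass
   through their own transform with a zero message.
2. **Reaction cross-attention (3 blocks, 8 heads).**  Product atoms attend
   over *all* reactant atoms: per head, scores `Q K^T / sqrt(d/n)` are
   row-softmaxed and applied to values; head outputs are concatenated, then
   a gated residual (`g = sigmoid(W_g [h ; o] + b_g)`, update
   `LN(h + g ⊙ o)`) and a two-layer feed-forward net with its own residual
   and layer normalization complete the block.  The gated transform and the
   feed-forward net use distinct parameter sets.  Reactant features are not
   updated by attention — they enter the classifier straight from the MPNN,
   matching the architecture's information flow (products interrogate
   reactants, not vice versa).
3. **Classifier.**  One more attention head computes
   `(H_p W_q)(H_r W_k)^T / sqrt(d)`; a row-softmax yields the mapping
   probability matrix `P[u_p, u_r] = p(u_r | u_p)`.

Training minimizes the mean negative log-probability of the labeled atom
pairs with Adam (learning rate 1e-3, weight decay 1e-6, batch size 16),
gradient clipping at global norm 20, and a plateau schedule that halves the
learning rate when the monitored loss fails to decrease after an epoch.
The monitored loss is evaluated in inference mode (no dropout): monitoring
the noisy dropout loss would trigger the halving almost every epoch and
freeze the optimizer long before convergence.  Validation loss is monitored
when a validation set exists, else the training set.  One global seed
drives initialization, shuffling and dropout; two runs with the same seed
are bit-identical.  The whole network and its backpropagation are plain R
matrix algebra; the gradients are verified against central finite
differences in the test suite.

**Hidden width.**  The hidden dimension is not dictated by the
architecture; the package defaults to `d = 320` with a config override, and
the test suite and fixture studies use `d = 64`, which is ample for the
synthetic reaction classes and keeps single-CPU runtimes in minutes.

## Decoding

`decode_greedy()` is the plain highest-first procedure: all (product,
reactant) cells sorted by probability descending (ties broken by product
then reactant index), accepting a cell when both atoms are still free.  By
default a cell is only admissible when the two atoms share an element
(`enforce_element_match = TRUE`): the architecture does not forbid
cross-element assignments, but they are chemically meaningless and would
poison template extraction; the flag can be disabled to reproduce the raw
procedure.  Spectator reactant atoms receive no map number.  A
probability-product confidence (`confidence_score()`) is reported as a
diagnostic only — it is *not* the knowledge-based confidence.

Plain greedy has a structural blind spot that any per-atom probability
model shares: homotopic atoms (the two ortho carbons of a para-substituted
arene, two locally identical rings, a symmetric product with asymmetric
provenance) receive *identical* embeddings by symmetry, hence exactly tied
probability rows, and independent cell-by-cell acceptance can mix the two
orientations into a chemically wrong mapping.  `decode_consistent()` —
the default in `predict_mappings()` — therefore grows the assignment
region-wise: candidates adjacent to already-assigned pairs (in both
graphs) are preferred and scored `p * (1 + consistent neighbours)`;
a detached candidate wins only when its probability exceeds the best
frontier score by `seed_margin` (default 0.1), which keeps cross-molecule
provenance decisions — the hydrolysis oxygen coming from water — with the
network.  Finally, when a region *seed* itself is near-tied (within
`tie_eps`), the alternatives are decoded too and the mapping with the
fewest bond changes wins: minimal-chemical-distance tie resolution, the
classical criterion, needed for symmetric products such as
4,4''-disubstituted terphenyls where the tie is exact and only the global
bond-change count identifies the real mechanism.

## Templates and knowledge-based confidence

The extended-local reaction template (ELRT) of a mapped reaction is the
condensed-graph subgraph induced by the **center** — every atom whose bond
orders, formal charge, or implicit-H count change (H-count changes alone
count, so reductions have centers) — extended with the atoms of catalogue
**functional groups** that share an atom with, or are directly bonded to,
the center.  Center atoms keep full before/after labels; extension atoms
are generalized to element plus aromaticity, so substituent identity does
not fragment templates.  The pattern string is written from a canonical
ordering of this labelled graph (iterative refinement with
individualization on ties), making it invariant to input atom order and
map renumbering; the canonical string is the library key.  The notation is
deliberately compact and deterministic rather than standard SMARTS:
`C[...]` tokens are center atoms with `charge_before>charge_after` and
`H_before>H_after` fields, `X[...]` tokens are extension atoms, and bonds
carry `order_before>order_after` labels.

The shipped functional-group catalogue (a TSV configuration file, not
code) covers carbonyl, carboxylic acid, ester, amide, nitrile, nitro,
acetal/hemiacetal, imine, sulfonyl, boronic acid/ester, the four
organohalides, and aromatic ring heteroatoms — enough to distinguish the
hydrolysis/condensation chemistry where oxygen provenance matters.  Both
the catalogue and the extension rule are configuration, and our defaults
are a reimplementation choice, not a canonical definition.  Reagents and
catalysts are not incorporated into templates; patterns use a restricted
SMARTS subset (elements, aromaticity, charge, explicit H counts, bond
orders) matched by a small backtracking matcher.

A prediction is **confident** iff its extracted template is present *and
verified* in the template library; presence without verification (a
template seen only in model predictions) stays uncertain.  Verification is
monotone: once verified, always verified.

## The active-learning loop

Each iteration: (1) sample `k` reactions — uniformly at random in the
first iteration, afterwards one reaction per uncertain template in
descending order of how many reactions share the template (ties by pattern
string; when unique templates run out before `k`, further passes take a
second, third, ... reaction per template in the same order, preserving the
popularity prioritization); (2) the oracle labels them and the extracted
templates enter the library as verified; (3) the mapper is retrained from
fresh initialization — from the second iteration the human-labeled set is
augmented with up to 100 confident predictions per verified template
(pseudo-labels), split 9:1 into training/validation, human labels always
in training; (4) the whole pool is re-predicted and re-classified.
Per-iteration statistics record the verified-template count and the
**coverage** — the fraction of the pool whose predicted template is
verified.  The stopping rule is configuration (a fixed iteration count
here).  Warm-starting between iterations is available but off by default:
fresh initialization makes iterations independent of each other's
optimizer state.

## Synthetic data: what it emulates and what it does not

`generate_reactions()` instantiates eight hand-coded reaction classes —
ester hydrolysis, esterification, SN2 halide substitution, amide coupling,
nitro reduction, acetal hydrolysis, Suzuki-type biaryl coupling, imine
condensation — over a 10-fragment substituent vocabulary (alkyl, aryl,
benzyl, allyl), all valence-checked.  Ground-truth mappings are stored as
explicit atom-index pairs, independent of map numbers, and atom orders are
shuffled per record so no model can exploit positional regularities.  The
hydrolysis classes deliberately route the product oxygen from water, so
the classic wrong-provenance error is expressible and detectable.
Controlled corruptions provide wrong-provenance
(`wrong_atom_source`, never CGR-equivalent, never fewer bond changes),
homotopic-relabel and renumbering variants (always CGR-equivalent).

What the generator does **not** emulate: reagent/solvent context,
unbalanced or multi-step reactions, stereochemistry, atom-map noise, the
long-tailed template distribution of patent data.  Passing the fixture
studies therefore demonstrates that the machinery — learning, decoding,
template canonicalization, confidence, evaluation — is correct and
internally consistent; it does not certify accuracy on real patent
reactions, which additionally requires human labeling at scale.

## Evaluation

Mappings are compared through the condensed graph of reaction (CGR): the
superposition of reactant and product graphs through the mapping, atoms
labelled with element, charge-before/after and implicit-H-before/after,
bonds with order-before/after (0 = absent).  Two mappings are equivalent
iff their CGRs are isomorphic (decided by canonical certificates), so
homotopic re-assignments and renumberings never count as errors.  By
default the comparison is restricted to mapped atoms, matching an
evaluation of product-atom provenance; spectators can be included by
option.  Atom H-labels participate in equivalence but H-count changes are
not bond changes in `count_bond_changes()` (bond changes are order
changes on heavy-atom bonds; bonds between two spectator atoms have no
"after" side and are not counted).  Undefined ratios on empty subsets are
reported as `NA`, never 0.

Calibrated accuracy combines dataset-based and manually verified
accuracies: with confident ratio $r$,
$$A_{\mathrm{unconf}} = \frac{A_{\mathrm{overall}} - A_{\mathrm{conf}}\, r}{1 - r},
\qquad
A_{\mathrm{cal}} = A_{\mathrm{unconf}} (1 - r) + A_{\mathrm{manual}}\, r.$$
$A_{\mathrm{unconf}}$ is clamped into $[0,1]$ with a warning when
inconsistent inputs push it outside; at $r = 1$ the unconfident term has
weight zero and is defined as zero.

```{r calibrated}
calibrated_accuracy(0.915, 0.928, 0.970, 1.000) |>
  select(acc_unconf_dataset, acc_calibrated)
```

## Numerical choices and degenerate inputs

* Softmax rows are computed in max-shifted form; probability rows sum to 1
  within 1e-6.
* Greedy-decoding ties (exactly equal probabilities, which symmetric atoms
  produce) break deterministically by (product index, reactant index).
* Layer normalization uses eps = 1e-5; cross-entropy adds 1e-12 inside the
  log.
* A single-atom reactant set gives attention weight exactly 1; an empty
  reactant set is an error.
* Unknown elements map to a dedicated one-hot slot with a warning.
* Canonical labelling individualizes every atom of the first ambiguous
  refinement cell and keeps the lexicographically smallest certificate, so
  certificates are permutation-invariant even on symmetric graphs.
* `parse_rxn_smiles()` extracts a given mapping only from map numbers that
  occur exactly once on each side; a duplicated product map number is left
  to the dataset filters to flag rather than guessed at.

## Problem sizes used in the shipped studies

The end-to-end study trains on a 500-reaction pool over all eight classes
with `k = 20`, three iterations, `d = 64`, 30 epochs per iteration, and
evaluates on a 100-reaction held-out set; these sizes were fixed once as a
realistic single-CPU study and are deliberate package choices.  The
fragment vocabulary is small (10 fragments) so the template count is
finite and coverage is a meaningful saturation measure.

## Known limitations

* Stereochemistry is parsed over and dropped: mappings, templates and CGR
  equivalence are constitutional.  Retaining stereo would require
  neighbor-order parity re-canonicalization throughout.
* Aromatic perception is trusted from the input (lowercase atoms), not
  re-derived; kekulized inputs of aromatic rings will not match their
  aromatic-form counterparts.
* The restricted SMARTS subset of the group catalogue has no recursive or
  logical operators.
* Implicit-H assignment follows standard organic-subset valence rules;
  exotic valences must be written with explicit bracket H counts.
* The mapper is supervised: with an empty or tiny library everything is
  uncertain, which is the intended cold-start behaviour of the loop.
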