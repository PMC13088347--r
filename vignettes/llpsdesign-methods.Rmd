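---
title: "Methods: contact-graph scoring and mutation design for protein phase separation"
author: "llpsdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-graph scoring and mutation design for protein phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpsdesign)
```

# Overview

Many proteins demix into membraneless condensates by liquid–liquid phase
separation (LLPS), and single amino-acid changes can strengthen or abolish
that behaviour. `llpsdesign` implements a desk-scale pipeline for scoring
the phase-separation (PS) propensity of a (possibly mutated) protein and
for recommending mutations that shift it in a chosen direction:

1. **Contact maps.** A residue contact matrix (RCM) marks residue pairs
   whose Cα atoms lie within 10 Å. When no structure is available, a
   lightweight sequence-to-contact transformer predicts the map; it is
   trained with structure-derived RCMs as pseudo-labels rather than with
   multiple sequence alignments.
2. **PS scoring (PSDM).** The contact map becomes a residue graph (nodes:
   physicochemical features; edges: contacts plus guaranteed backbone
   links). A graph encoder — GIN and GAT message-passing blocks with an
   attention readout — feeds three classification towers trained jointly
   (twin-tower design) plus an NT-Xent contrastive term over augmented
   graph views. The PS-classification head emits the PS score in [0, 1].
3. **Mutation search.** A genetic algorithm (GA) searches mutation space
   with fitness `fit(x) = PSDM(x) − PSDM(x_org)`, the change in predicted
   PS score relative to the parent.
4. **Transfer learning.** For a specific protein with a small labeled
   mutant panel, the panel is balanced 1:1, lower encoder blocks are
   frozen, and the remaining parameters are fine-tuned.

Every stage is verifiable against brute-force oracles on synthetic
fixtures generated by the package itself; no external downloads are
required.

# The mutation grammar

Mutations use the compact token notation common in figure legends:
`R106C` (arginine 106 → cysteine), `H5-` (histidine 5 deleted), `A326P`.
Deletion hyphens are often typographic in published text, so all Unicode
dash variants are normalized to the ASCII hyphen on input; output is
always ASCII. Positions are 1-based everywhere in the public interface
(internal matrix indices are 0-based at the C level of R's own matrices;
the boundary never leaks). Multi-site sets apply in descending position
order so deletions cannot shift the coordinates of other entries, and two
edits at one position are rejected. Only the 20 canonical amino acids are
modeled; insertions are out of scope.

# Contact maps and residue graphs

"Within 10 Å" is read inclusively: a pair at exactly the threshold is a
contact, and the tie behaviour is tested. The diagonal is fixed to 1 —
the self-distance satisfies any threshold — but is excluded from losses
and evaluation as it carries no information. Residues without observed
coordinates are *masked*, never zero-filled: an absent coordinate must
not be mistaken for an absent contact. When a structure's author
numbering has gaps, placeholder residues are inserted unresolved.
Alternate locations resolve to the highest-occupancy conformer, first in
file order on ties.

Graphs take the off-diagonal contacts (masked pairs excluded) united with
backbone edges between sequential neighbours. Backbone edges are always
present so the graph stays connected for message passing even when
interior residues are unresolved. Node features are a 20-dim one-hot
encoding plus four z-scored scalar scales: Kyte–Doolittle hydropathy,
formal side-chain charge at pH 7, aromaticity, and TOP-IDP disorder
propensity. The published description of the upstream feature set is not
specific, so this standard, swappable set is the package's own documented
choice — `buildResidueGraph()` accepts any per-amino-acid table.

# The contact predictor

The transformer is deliberately small: learned residue embeddings plus
fixed sinusoidal positional encodings, two post-norm-free self-attention
layers (4 heads, width 32, feed-forward width 64), and a pairwise head
`z_ij = h_i^T B h_j + b + r(|i−j|)` with a learned relative-position bias
`r` clipped at separation 32 — a standard structural prior that lets the
model express banded contact patterns directly. Pairwise logits are
averaged with their transpose *before* the sigmoid, so the output map is
symmetric by construction regardless of attention asymmetry. Training is
per-pair binary cross-entropy over off-diagonal unmasked pairs with a
positive-class weight defaulting to the per-example non-contact/contact
ratio (contacts are sparse). All backpropagation in the package is
hand-derived analytic matrix calculus, verified against numerical
differentiation in the test suite.

Evaluation uses precision@k: rank eligible upper-triangle pairs with
sequence separation at least `minSeparation` (default 6, the medium/long
range convention; use 0 against raw RCMs) and report the fraction of the
top k that are true contacts, ties broken by (lower i, lower j) so the
statistic is deterministic.

# The PS discriminator

The encoder default is hidden width 64 and depth 3 (GIN → GAT → GIN),
with an attention-weighted mean readout. Ablation flags replace disabled
block types with the remaining type (or plain mean pooling for the
readout); the ablation harness trains and reports all configurations but
the package asserts no ordering among them — on real data the full
composition is a claim, not a property.

"Twin tower" is realized as towers sharing one encoder:

* the **target tower** classifies whether a single mutation causes a
  *significant PS change*. A change is a property of a *pair* of
  sequences, not of one graph, so this tower is Siamese: it scores
  `sigmoid(w · |g(x) − g(x_org)| + b)` on the absolute difference of the
  mutant and parent embeddings. This was the main genuinely open design
  point: a single-graph head cannot express a change label at all.
* the **pathogenicity tower** (aux 1) and the **PS-classification tower**
  (aux 2) are ordinary linear-plus-sigmoid heads on the embedding. The
  aux-2 head doubles as the absolute PS score used by `scorePS()` and by
  the GA fitness, which keeps `PSDM(x)` a property of one protein as the
  fitness definition requires.

Positive pairs for the contrastive term are two stochastic augmentations
of the same graph: non-backbone edge dropout (p = 0.2) and node-feature
masking (p = 0.1); backbone edges are never dropped so views stay
connected. The loss is NT-Xent at temperature 0.5 over within-batch
negatives. Default loss weights are 1.0 / 0.5 / 0.5 / 0.5
(target / aux1 / aux2 / contrastive): target-dominant, all configurable,
and a zero weight removes its term exactly — zero-weight training is
loss-identical to plain supervised training, which is tested.

Training uses Adam (lr 1e-2) on minibatches of 16 target records for 30
epochs, with a stratified internal 80/20 split providing per-epoch
validation AUROC. Classification-head weight vectors carry a small L1
penalty (0.02), applied as a proximal soft-threshold after each step.
Everything is seeded; identical seeds give bitwise identical models.

The target head additionally passes a **deployment gate**: after training,
its validation AUROC must be significantly above chance (one-sided
Mann–Whitney normal approximation, alpha = 0.01) or the head abstains to
the constant predictor (all-0.5 scores). The rationale is that a ranking
head indistinguishable from noise on validation should not ship rankings
at all: a scoring direction fit to noise still generalizes along the
dominant embedding axis with a random sign, so an ungated
label-randomized control can drift far from AUROC 0.5 in either
direction while carrying no information. With the gate, permutation
controls sit at exactly 0.5 (the tie convention), and genuinely trained
heads pass with z-scores far above the cutoff.

# Genetic algorithm

Fitness is exactly `PSDM(x) − PSDM(x_org)`; it is 0 at the parent and
bounded in [−1, 1]. With `direction = "decrease"` the GA maximizes the
negation but always reports the signed quantity. Selection is tournament
(size 3); crossover lets a child inherit each parental edit independently
with probability 0.5, position conflicts resolved in favour of the fitter
parent, capped at `maxEdits`; mutation adds, removes or resamples one
edit. Elites (5%) pass unchanged, so best-of-generation fitness is
non-decreasing — asserted on every run. Ties break toward fewer edits and
then lexicographic token order, encoding the preference for single or
few-site mutants. Fitness values are cached by canonical token set, so no
candidate is ever scored twice. An exhaustive single-site scan (19L
substitutions + L deletions) provides the verification oracle; on a
length-8 toy problem the GA must recover its argmax.

An optional exchangeability-biased substitution sampler ("natural
mutation patterns") is a hook left off by default: no specific prior is
defensible from the available description, so the package provides the
mechanism and not a guess. Mixed substitution/deletion candidates are
permitted but flagged in CLI output.

# Transfer learning

A protein-specific panel (`parent_id,token,label`) is balanced 1:1 by
undersampling the majority class — no duplication artifacts — then split
80/20 stratified. The input projection and the first 2 of 3 encoder
blocks are frozen (the published protocol freezes "partial underlying
parameters" without numbers; 2-of-3 is this package's documented choice),
and the last block, readout and target tower are tuned with Adam. Frozen
parameters are bitwise identical afterwards, which is tested, and the
auxiliary towers are left untouched by default.

Panels of ~100 tuning records overfit easily, so a stratified quarter of
the tuning split is reserved for checkpoint selection: the deployed model
is the per-epoch snapshot with the best selection-split AUROC (BCE loss as
tiebreak), and the unmodified starting model competes — fine-tuning can
therefore return the base model unchanged, but cannot silently return a
worse one. Held-out evaluation reports AUROC/F1 for base and tuned models
on identical records; the held-out split is seen by neither tuning nor
selection, and tune/held-out disjointness is enforced through record
keys, not assumed.

# Synthetic fixtures: what they emulate and what they do not

The ground-truth scoring rule is deliberately simple and *declared*:

```
score = logistic(8·f_arom + 4·f_GSwin − 3·f_|charge| − 2)
```

with `f_arom` the aromatic (F/W/Y) fraction, `f_GSwin` the best G/S
fraction over any 8-residue window (a low-complexity surrogate), and
`f_|charge|` the absolute net charge per residue. It is loosely motivated
by the known drivers of LLPS — aromatic stickers, low-complexity
stretches, net-charge effects — but it is a test oracle, not a scientific
claim. A mutation is a "significant PS change" when it moves the score by
at least 0.1.

Generated datasets:

* **Target task**: single-edit mutants of parents constructed near the
  rule's decision boundary (logit in [−0.7, 0.7], length 24). Classes
  alternate, and the edit of the wanted class is drawn uniformly from the
  parent's full single-site edit space; negatives are kept at
  |Δscore| ≤ 0.05 so the two classes do not crowd the significance
  boundary — the acceptance benchmark is specified as a *separable*
  dataset, and the margin is what makes it one. Balance is verified to
  lie in 40–60%.
* **Aux tasks**: sequences labeled by the rule directly (PS surrogate)
  and by a mildly perturbed rule (pathogenicity surrogate; weights
  6/5/4 instead of 8/4/3).
* **Retraining panel**: 138 single-site mutants of one parent, exactly
  69 positive / 69 negative, labeled by a *shifted* rule (aromatic weight
  − 4, charge weight + 2) so the pretrained model is measurably
  mis-calibrated on the target protein: aromatic edits matter less and
  charge edits more than the base model learned. All single-site
  candidates are enumerated, and within each class the edits whose
  significance status *differs* between base and shifted rules are
  sampled first — the panel exists to expose protein-specific behaviour
  the base model has not seen, and a panel dominated by
  rule-concordant edits would leave nothing to transfer. Sampling is
  without replacement, so tokens are distinct and valid by construction.

Structures come from two toy families: ideal helices (rise 1.5 Å,
100°/residue, radius 2.3 Å — under the 10 Å rule their contact map is
exactly the band |i−j| ≤ 6, derived in closed form and cross-checked
against the distance oracle) and self-avoiding random chains (step 3.8 Å,
exclusion 3 Å). Labeled-dataset graphs carry the helix band structure:
the contacts are positional, and the discriminative signal lives in the
node features. That is the principal idealization: in real proteins the
contact topology itself is sequence-dependent and informative, mutations
perturb structure, and PS labels come from noisy experiments. Passing
tests therefore demonstrate that the machinery — graph encoding,
twin-tower optimization, GA search, freezing — is correct and recovers a
known rule at desk scale; they say nothing about predictive accuracy on
real proteins, which would require the original large-scale corpora.

# Numerical choices and degenerate inputs

* Analytic gradients throughout; numerical-differentiation checks at
  eps = 1e-6 in the tests (ReLU kinks make larger eps unreliable).
* AUROC uses the Mann–Whitney rank form with half-credit for ties; F1
  uses threshold 0.5 (inclusive) unless overridden, and is 0 when
  positives exist but nothing is predicted positive.
* NT-Xent guards normalization with a 1e-12 floor; contrastive batches
  need at least 2 pairs.
* Single-residue graphs encode without error; empty graphs are
  structural errors. Single-class datasets are errors everywhere a
  classifier is trained or evaluated.
* GA tie-breaks are total and deterministic, so a constant scorer yields
  a reproducible ranking.
* Problem sizes used in the shipped experiments (200 + 100 + 100 training
  records of length 24, 50 contact-training helices of length 30–60,
  five seeds per stochastic claim) were chosen as the smallest scale at
  which the statistical assertions are stable.

# Known limitations

* The contact predictor's relative-position bias can express banded maps
  on its own; on the helix benchmark this means positional structure
  dominates. The bilinear term exists for sequence-dependent structure,
  but the shipped benchmark does not exercise it deeply.
* The encoder's block order (GIN → GAT → GIN) and the freeze depth are
  package choices among reasonable alternatives; both are configurable.
* No insertions, multi-residue indels, or HGVS notation; no mmCIF,
  multi-model ensembles, or non-Cα contact definitions; no multi-objective
  search or epistasis modeling.
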