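---
title: "Probing fingerprint space with a recurrent decoder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing fingerprint space with a recurrent decoder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(profis)
```

This vignette explains the models implemented in `profis`, the
assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic fixtures do and do not establish
about behavior on real chemical data. It states no empirical number that
the test suite or `scripts/acceptance.R` does not itself compute.

## The generative model

Each molecule is a pair (x̄, s): a d-dimensional binary fingerprint and a
tokenized sequential representation s = (s₁…s_k) with k = 100 and pad
tokens after the end marker. Two fingerprint types are supported: ECFP4
(radius-2 circular, folded by bitwise OR to a configurable width, default
2048) and a 4860-bit substructure-key fingerprint in the Klekota–Roth
layout. The encoder φ is a two-layer ReLU network (reference sizes 1024,
1024) with parallel linear heads for μ and log σ² (width 32, the latent
dimension); z = μ + σ⊙ε with ε ~ N(0, I) keeps the sampling step
differentiable. The decoder is a stacked GRU (reference: 3 layers of
width 512) whose input at every timestep is the concatenation of ω(z), a
single affine map of the latent vector, and a learned embedding of the
previous token; hidden states are initialized to zero, and an affine
softmax head ψ converts the top hidden state into token probabilities.

How z enters the GRU is a wiring decision: conditioning at *every*
timestep (rather than only through the initial hidden state) was chosen
because an autoregressive decoder with zero-initialized hidden state can
otherwise learn to ignore the latent entirely — exactly the failure mode
the KL-annealing schedule targets.

The previous-token embedding width and ω's output width are free
parameters (defaults 128/128 at reference scale, 48/48 in the test
configuration); the encoder input width adapts to the configured
fingerprint folding.

## Loss, annealing, and a scale decision

The loss is `L = CE + β_t · KLD` with
`KLD = ½ Σ_dim(μ² + σ² − log σ² − 1)` summed over latent dimensions and
averaged over the batch, and β = 0.1 after annealing. β_t follows a
monotone half-cosine ramp `β·½(1 − cos(π·epoch/50))` over the first 50
epochs — the functional form of the "cosine schedule" was itself a
choice; a monotone ramp was preferred to a cyclical one because the
training runs here are short.

CE is masked over pad positions. One deliberate deviation from a
per-token convention: CE is **summed over the non-pad positions of each
sequence and averaged over the batch**, not averaged per token. The two
terms of the loss must live on the same per-sample scale for β to mean
anything: with a per-token mean, a 40-token sequence contributes ~0.2
nats of achievable reconstruction gain against a weighted KL cost of
~0.4 nats for the ~4 nats of information needed to identify one of 50
training molecules — posterior collapse is then the *global optimum*,
and a fitted model decodes a single averaged string with near-zero KL
divergence regardless of its input. With the
per-sequence sum the trade-off is ~8 nats of gain against the same 0.4
nat cost and the latent is used. `ce_reduction = "per_token"` remains
available in the configuration for monitoring.

Optimization is Adam (default learning rate 1e-3; the overfit test
configuration uses 3e-3) with global-norm gradient clipping at 5 —
"Adam" is all the reference protocol pins down, so the rate and clip are
package defaults, not claims. Training is bit-for-bit reproducible under
a seed: weight initialization, batch shuffling and reparametrization
noise all flow through R's RNG.

## Sequence notations

Three output notations are implemented with reference vocabularies of
29 (SMILES), 46 (DeepSMILES) and 28 (SELFIES) structure tokens; the
specials `<pad>`, `<start>`, `<end>` are recorded separately in the
vocabulary files, so either accounting convention (with or without
specials) is recoverable. Vocabularies can also be built from a corpus
(order of first appearance, two-character halogens and bracket atoms
atomic); by construction the corpus then tokenizes without
out-of-vocabulary errors. Strings longer than the fixed length are
rejected with a signalled condition rather than silently truncated.

The DeepSMILES codec rewrites branches (one close symbol per atom popped
from the attachment stack, no open symbol) and rings (a single ring-size
token at the closing atom). The SELFIES codec implements a
derivation-rule dialect: bond orders are capped to the remaining valence
of both partners, impossible branch or ring instructions are skipped
(their size operands are still consumed), and operand tokens are read as
base-16 digits through a fixed overload table. Decoding is therefore
total — every token sequence yields a chemically valid molecule. The
empty derivation (a sequence with no effective atom token) falls back to
methane; this convention keeps totality exact rather than approximate.
Aromatic rings are carried in Kekulé form, as the dialect has no
aromatic tokens; round-tripping through canonicalization restores the
aromatic notation.

## Validity accounting

OpenBabel, the canonicalization backend, is deliberately permissive: it
repairs unbalanced parentheses and accepts hypervalent atoms. Output
validity — the quantity the notation comparison turns on — therefore
uses a strict in-package arbiter: a SMILES string is valid iff it lexes,
parses with balanced parentheses and matched ring bonds, every written
aromatic system kekulizes (perfect-matching test; no Hückel electron
count — small anti-aromatic rings are accepted), and no atom exceeds its
allowed valence (standard valence ladders, charge-adjusted). DeepSMILES
strings are decoded first and inherit the same check; SELFIES strings
are valid by construction.

## Molecule preparation

Standardization keeps the fragment with the most heavy atoms (ties:
lexicographically smallest canonical string), neutralizes charges via
OpenBabel's transformation, strips stereochemistry, and canonicalizes;
the operation is idempotent. The training filter demands MW in
[200, 450] g/mol and zero violations of the four classic rule-of-five
criteria (MW ≤ 500, clogP ≤ 5, HBD ≤ 5, HBA ≤ 10) — the "no violations"
reading is the strictest sensible one. Donor/acceptor counts use the
classic N/O convention computed on the bond graph; clogP and TPSA are
OpenBabel's additive models.

Bemis–Murcko scaffolds are computed by iterative pruning of non-ring
terminal atoms, then re-attachment of atoms multiply bonded to the
framework (so linker carbonyl oxygens survive, matching common toolkit
behavior); acyclic molecules map to the empty scaffold and form one
shared split group, which avoids leaking the no-ring class across
partitions. The scaffold split draws groups in seeded random order and
appends a group to the training set only when the result stays within
the target fraction (prospective check), so the training set never
exceeds the cap and all-singleton corpora split exactly 9:1.

## Fingerprints

The 4860 substructure keys shipped here are a **synthetic stand-in** for
the published Klekota–Roth key list, which is not redistributed with the
package: a deterministic enumeration of linear C/N/O/S chains with
single/double bond patterns plus aromatic-ring and functional-group
motifs, truncated to exactly 4860 patterns. The length contract, the
key-semantics (bit i ⇔ key i matches) and every downstream operation are
unchanged; absolute bit patterns differ from the published keys, so
cross-toolkit fingerprint comparisons are out of scope. Matching uses
OpenBabel's SMARTS engine; its aromaticity perception model is the
recorded dialect. Tanimoto distance defines the all-zero/all-zero pair
as distance 0 to preserve the identity axiom. Bit-flip noising draws
exactly k positions without replacement, so the Hamming displacement is
exact.

## Latent QSAR and the applicability domain

Activity labels derive from K_i: active ≤ 100 nM, excluded ≥ 10 µM
(strict), inactive between. The classifier suite (SVM with Platt-scaled
probabilities, probability random forest, gradient-boosted trees, MLP)
is evaluated by nested 5-fold cross-validation: outer folds are
scaffold-grouped — the splitting philosophy of the data preparation,
applied to evaluation as well so that scaffold memorization cannot
inflate the estimates — and an inner 5-fold grid search picks
hyperparameters refit on each outer-training split. Reported error bars
are standard deviations over the five outer folds. The hyperparameter
grids are compact package defaults (two values per axis), overridable
per call.

The applicability-domain score follows the SCAvg idea: the mean cosine
similarity of a query embedding to its three nearest training neighbors.
Because that quantity is a *similarity* while the narrative treats it as
a *distance to model*, the package reports `DM = 1 − SCAvg`, so low DM
means in-domain and the bin edges 0.05/0.10/0.15 keep their intended
orientation. Bins are half-open `[low, high)`; empty bins are reported
with n = 0, never as errors.

## Bayesian latent search

The search box is μ ± k·σ per latent dimension of a reference embedding
set (k = 2 by default; 1–3 in the bounds sweep); zero-variance
dimensions are widened by a small ε with a warning. The optimizer is a
Gaussian-process surrogate (squared-exponential kernel, lengthscale 0.2×
the original box width per dimension, jitter 1e-6 on the diagonal) with
expected-improvement acquisition maximized over a random candidate pool
(uniform in the active box plus local perturbations of the incumbent),
after 4 Latin-hypercube initial probes and for 20 acquisition
iterations. With sequential domain reduction, three improvement-less
iterations contract the box width by 0.9 around the incumbent, clipped
to the original box; the box never grows, and probes never leave the
active box. Probes whose objective is non-finite are discarded with a
warning.

One protocol ambiguity: a large candidate library cannot come from
incumbents alone (each search yields one). The package runs many
independent seeded searches and harvests every probe whose predicted
activity exceeds a configurable floor (default 0.8) along with each
incumbent, then decodes, checks validity and deduplicates on canonical
SMILES. Both accountings (all probes vs incumbents) remain available
from the returned probe logs.

## Synthetic fixtures: what they emulate and what they do not

`make_corpus()` assembles molecules from a fragment grammar (aromatic
and saturated rings as templates with an explicit substitution hole,
linkers and terminal decorations that concatenate head-to-tail), then
canonicalizes, deduplicates and rejects molecules outside the
200–450 g/mol window. Validity is guaranteed by construction and every
emitted string is already standardized, so the corpus exercises the full
preparation pipeline as a fixed point. `make_activity_dataset()` plants
a known generative rule — pKi = 5.5 + 3·[piperazine present] + N(0, 0.3)
— chosen so that the active/inactive boundary at pKi 7 sits 1.5 noise
standard deviations from the inactive mode: labels track the
pharmacophore almost deterministically, which is what makes the
"separable dataset" checks meaningful. A zero effect size gives the
matching null dataset. Piperazine presence is *measured* by substructure
matching on the assembled molecule, not assumed from the construction.

These fixtures establish mechanism correctness (the pipeline trains,
embeds, searches and decodes as specified), not chemical realism: the
fragment space is far smaller than a screening library, property
distributions are narrower than real corpora, and a 50-molecule overfit
model says nothing about generalization to unseen scaffolds — a
limitation measured directly: an encoder trained on 50 molecules embeds
*unseen* same-family molecules with only moderately separable latents.
For that reason the cross-validation checks run on a synthetic latent
dataset whose separability is keyed to the fixtures' activity labels
(two displaced Gaussian clusters), the regime the nested-CV machinery is
specified against; encoder-quality questions at scale are a training
budget issue, not a pipeline one.

## Problem sizes and numerical choices

The test and acceptance configurations are small by design: 512-bit
folded ECFP4, 16 latent dimensions, a 2×128 GRU, 50-molecule training
sets and 200 epochs (batch 25, Adam 3e-3) — enough for ≥ 90% exact
greedy reconstruction, which is the regime the analog-noise and
latent-continuity checks require. The cross-validation dataset uses 400
molecules so that the permutation control's fold-mean ROC-AUC
concentrates well inside its chance band. The applicability-domain
fixture uses 4 latent dimensions and 600 training points: nearest-
neighbor cosine similarities concentrate near 1 only when the training
cloud is angularly dense, and low dimension is what populates the
sub-0.05 DM bin; displacement radii 0.15/0.9/1.3/2.5 then spread test
points across all four bins. Trend assertions (analog distance and
validity vs bits flipped; library validity vs bounds multiplier)
aggregate medians over five seeds and test non-strict monotonicity —
an overfit decoder can hold validity at 1.0 across small noise levels,
and a constant series satisfies (and should satisfy) a non-increasing
trend.

Degenerate inputs are handled explicitly: empty validity sets, zero-norm
latent vectors, single-class folds, unparseable molecules, infeasible
fixture specifications and over-length token strings all raise typed
conditions (`profis_*` classes) rather than propagating NA.

## QED

The drug-likeness score uses the published ADS desirability parameter
sets and mean weights over the eight standard descriptors. Two
approximations are recorded: clogP is OpenBabel's additive model (not
Crippen's), and the structural-alerts descriptor counts a compact
curated alert subset rather than the full published alert list, so
absolute QED values can differ from other toolkits by roughly ±0.2 on
individual molecules. The filter semantics (QED > 0.5, clogP < 8,
largest smallest-ring ≤ 7, read as "rings of more than 7 atoms are
artifacts to remove") are unaffected.

## Known limitations

* The SMILES dialect covers the organic subset plus common bracket atoms
  (charges ±2, explicit H); isotopes parse but are not retained, and
  stereochemistry is stripped by design.
* Kekulization accepts any perfect-matching aromatic assignment; exotic
  aromatic systems a Hückel-counting toolkit would reject may pass.
* The substructure-key set is synthetic (see above); models trained on
  it are internally consistent but not comparable to published
  Klekota–Roth fingerprints bit-for-bit.
* The GRU/encoder stack runs on BLAS matrix operations in R; it is
  sized for method validation, not for corpus-scale training.
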