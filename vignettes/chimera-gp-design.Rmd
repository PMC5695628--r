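---
title: "Gaussian process models for recombination chimera libraries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian process models for recombination chimera libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraGP)
```

## The problem

Integral membrane proteins such as channelrhodopsins must be expressed,
folded into the bilayer, and trafficked to the plasma membrane before they
can function; small sequence changes routinely abolish localization.
Structure-guided (SCHEMA) recombination of a few homologous parents produces
large libraries of chimeras — one parent choice per sequence block — in
which most variants fail to localize, and the goal is to model expression
and plasma-membrane localization well enough to (i) classify which of the
~10^5 library members will perform at least as well as the weakest parent,
(ii) predict quantitatively optimal localizers, (iii) read out which
residues and residue contacts drive the property, and (iv) transfer the
model to homologs outside the library via single-block swaps.

`chimeraGP` implements this loop: library representation and enumeration,
binary sequence/structure feature encoding from a residue contact map,
Gaussian process (GP) regression and Laplace-approximate GP classification
with marginal-likelihood hyperparameter selection, an L1 → Bayesian-ridge
interpretation pipeline, and acquisition-based design (LCB/UCB ranking,
probability-threshold exploration sets, greedy mutual-information
training-set selection). A synthetic generator reproduces the statistical
shape of such a campaign so that every stage is testable without external
data.

## Model

A chimera is encoded as a binary vector `x`: one indicator per (alignment
position, residue) over the residues observed among the parents at that
position, concatenated with one indicator per (contact, residue pair) for
every contact in a reference contact map (heavy-atom distance ≤ 4.5 Å,
alignment-adjacent pairs excluded by default). Gaps contribute no feature
and void their contacts. Two variants' shared-position and shared-contact
counts are exactly the dot products of the two parts of their vectors,
which is what the kernels consume.

Three kernels are available, selected (together with their
hyperparameters) by maximizing the log marginal likelihood:

* linear: `k(x, x') = σp² xᵀx'` — an additive landscape;
* squared exponential: `k = σp² exp(−d²/(2l))`, `d` the Euclidean distance;
* Matérn ν = 5/2: `k = σp² (1 + √5 d/l + 5d²/(3l²)) exp(−√5 d/l)`.

Regression follows the standard GP posterior (predictive mean
`k*ᵀ(K+σn²I)⁻¹y`, variance `k** − k*ᵀ(K+σn²I)⁻¹k*`) through a cached
Cholesky factorization; the marginal likelihood is
`−½yᵀ(K+σn²I)⁻¹y − ½log|K+σn²I| − (n/2)log2π` with `n` the number of
observations. Binary classification uses a logistic likelihood on labels
±1 with Laplace's approximation: damped Newton iteration to a gradient
norm below 1e−6 for the mode, the standard stabilized `B = I + W^½KW^½`
factorization, and predictive class probabilities by Gauss–Hermite
integration of the sigmoid over the latent predictive Gaussian. There is
no noise hyperparameter in classification.

Measurements are modeled on the log2 scale; below-detection (`ND`) values
are imputed at half the smallest detected value and flagged. The 'high'
class threshold for a property is the measured value of the
lowest-performing parent — a variant is 'high' if it does at least as well
as the worst parent, ties included.

## Tunable parameters

* `threshold` (contact map): 4.5 Å heavy-atom distance; `min_separation`
  2 alignment positions. Backbone-adjacent contacts are always present
  and duplicate sequence information, so they are excluded by default
  (toggleable).
* Hyperparameters `σp²`, `l`, `σn²` are optimized in log space (bounds
  1e−6…1e6; noise floor 1e−8) by L-BFGS with analytic gradients for
  regression and finite differences for the Laplace objective; 10
  restarts by default, the first from data-scale heuristics and the rest
  log-uniform over [1e−3, 1e3] under a fixed seed (default 0). All
  restarts are recorded on the fitted object.
* A fixed jitter of 1e−8 is added to covariance diagonals before
  factorization: binary encodings routinely contain duplicated rows.
* Acquisition: `lcb = mean − κ·sd`, `ucb = mean + κ·sd`, κ = 1 by
  default ("mean minus/plus one standard deviation"); ties broken by
  fewer mutations from the nearest parent, then lexicographic id, so
  rankings are reproducible. `top_fraction` keeps
  `floor(fraction × library size)` candidates (0.1% of 118,098 → 118).
* Exploration sets: candidacy at predicted probability > 0.4; library
  summary fractions at > 0.5; both are arguments with these defaults. An
  optional minimum pairwise mutation distance enforces diversity (off by
  default; the size and diversity of an exploration set are a user's
  budget decision).
* L1 selection: 100 log-spaced regularization values from λ_max (empty
  model) down to λ_max·1e−4, chosen by leave-one-out squared error on the
  log2 scale; run on the covarying-collapsed matrix (columns identical
  over the training set merged, constant columns flagged and excluded
  from modeling). Bayesian ridge re-weighting uses evidence iterations
  with Gamma(1e−6, 1e−6) hyperpriors, 300 iterations maximum, tolerance
  1e−3 on the weight change — fixed constants rather than a library's
  implicit defaults, for reproducibility.

## Leave-one-out and its small-sample behaviour

LOO predictions reuse the full fit's hyperparameters and centering
constant and are computed exactly from the factorization
(`μᵢ = yᵢ − [C⁻¹y]ᵢ/[C⁻¹]ᵢᵢ`, `vᵢ = 1/[C⁻¹]ᵢᵢ`); a test verifies equality
with explicit refits. One consequence worth knowing: under a null
(shuffled) response, LOO Pearson R is not centred at zero but mildly
negative — centering forces residuals to sum to zero, so each held-out
prediction leans away from its target. The tests therefore check the
one-sided property (no positive signal under shuffling, R ≈ 1 on noiseless
additive data) rather than a symmetric band around zero.

## When does the kernel form matter?

The full encoding contains the contact-pair indicators, so a *linear*
kernel over sequence+structure features already represents contact
epistasis — that is precisely why the structure kernel works for
classification. A nonlinear kernel only becomes necessary when the
interaction is not itself a feature. The kernel-form experiment in the
tests and acceptance script therefore plants purely contact-epistatic
landscapes and fits models on the *sequence features only*: there the
Matérn 5/2 kernel beats the linear kernel in LOO R in 20/20 seeded
replicates, while on the full encoding the two are indistinguishable.

## Mutual-information training-set selection

Greedy selection adds, at each step, the candidate `y` maximizing
`½ log(σ²_{y|A} / σ²_{y|Ā})` under the GP prior, where `A` is the current
selection and `Ā` the unselected remainder — the candidate whose
measurement most reduces the predictive entropy of the rest of the
library. It matches exhaustive best subsets (in mutual-information value)
for sizes 1–2 on small pools. With short-lengthscale kernels the
criterion deliberately avoids uninformative extreme points (the classic
sensor-placement boundary effect), so "selected sets are more spread than
random" holds robustly under the linear-kernel prior (the natural choice
before any data exist) and only approximately under strongly local
kernels.

## The synthetic generator

`generate_parents()` draws parents around a target pairwise identity
(default 0.5, emulating parents at 45–55% identity) by mixing conserved
and free positions; `generate_block_design()` produces contiguous designs
or segment-shuffled non-contiguous ones; `generate_contacts()` samples
pairs with sequence-separation decay at a target degree (default 4
contacts/residue). `simulate_landscape()` draws a campaign shaped like the
real one — the parents, all single-block swaps of every design, and 103
random multi-block swaps (226 rows at the default scale) — and computes
log2 responses as a sparse additive + contact-epistatic model
(|weight| uniform in [1, 2] log2 units, random signs, Gaussian noise
sd 0.5, intercept 2) emitted on the linear scale in the standard
measurements dialect. Localization carries the full landscape; expression
an additive-only one, echoing the observation that expression is the
simpler property.

What the generator does *not* emulate: correlation between mutation load
and failure (real localization collapses in highly mutated chimeras,
synthetic effects are drawn independently of mutation count), measurement
heteroscedasticity, biased training-set composition, or any biophysics of
membrane insertion. Passing tests on synthetic data therefore demonstrate
the correctness of the machinery (encodings, posteriors, selection,
ranking) and realistic statistical behaviour, not that the real campaign's
headline accuracies would be reproduced; those depend on the real
measurements and the crystal-structure contact map.

## Numerical choices and degenerate inputs

Responses are centred by the training mean (restored at prediction);
real encodings always contain constant-one columns (conserved positions),
so the constant is representable and centering is benign. Noiseless
interpolation is supported (`σn² = 0` plus jitter). Duplicate rows with
conflicting responses push `σn²` strictly positive at the optimum.
Single-class label sets are rejected when fitting hyperparameters; the
fixed-hyperparameter Laplace path accepts them (needed for 1–2-point
posterior checks). Sequences with residues outside the encoding's
alphabet activate no stored column; their count is carried per row and
enters kernel norms exactly, so an external homolog can be scored against
a frozen model without distorting distances (for best results build the
encoding with `extra_sequences = homolog`).

## Problem sizes

The test suite and acceptance script run the full pipeline at the
study scale — 300-position alignment, two ten-block designs (118,098
chimeras), ~600 contacts, 226 measured chimeras — for enumeration,
ranking, classification scans and interpretation, and use a reduced
60-position, six-block system (115 chimeras measured) for the replicated
experiments: 20 seeded landscapes for the kernel-form comparison and
100 replicates × 4 sizes for the learning curve, with 2–5 optimizer
restarts in replicated fits. These sizes give stable statistics while
keeping a full run in minutes on one core.

## Known limitations

* The Laplace approximation is accurate here (within 0.02 of exact
  quadrature on 1–2-point posteriors) but can be biased toward 0.5 for
  extreme kernel variances; no expectation-propagation or MCMC fallback
  is provided.
* Kernel choice is by marginal likelihood over three fixed forms; no ARD
  lengthscales or kernel composition.
* The L1 step inherits lasso's behaviour under correlated columns: one
  member of a correlated (but not identical) pair may be selected
  arbitrarily. Exactly identical columns are handled by the covarying
  collapse.
* Weight maps attribute a group's weight equally to all member features;
  within-group attribution is not identifiable from the library by
  construction.
* The mutual-information selector recomputes conditional variances per
  step (adequate for pools up to a few thousand; larger pools are
  down-sampled with a seed).
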