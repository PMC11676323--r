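---
title: "Methods: knowledge-primed multitask networks for microbiome phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-primed multitask networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `microkpnnmt`, the
assumptions behind it, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## The model

### Input and masked trunk

The input is a sample × species matrix of relative abundances. Quality
control works on the percent scale — samples whose abundances sum to less
than 90% are dropped (`filter_samples()`), as are phenotypes with fewer
than 50 samples (`filter_rare_phenotypes()`) — and rows are renormalised to
proportions immediately before entering the model (`renormalize` flag of
`microbiome_dataset()`, default on). Separating QC from model conditioning
means the quality filter and the model input scale can be changed
independently.

The first hidden layer is a *masked linear* layer,

$$ h = \mathrm{ReLU}\big((W \odot M)^\top x + b\big), $$

where the binary mask $M$ is constructed from three knowledge sources
(`build_hidden_schema()`, `build_mask()`):

* two nodes per metabolite in a producer/consumer species–metabolite edge
  list (producers feed the production node, consumers the consumption
  node);
* one node per genus in a species→genus map. The taxonomic rank is fixed
  to genus in this version: it is the rank that has worked robustly for
  knowledge-primed microbiome networks and it removes a rank-search
  hyperparameter;
* one node per community from a precomputed community-membership table
  (community inference itself — co-occurrence network construction, Leiden
  clustering — is out of scope; the table is consumed as given).

Species that a source does not annotate are collected in one catch-all
"unknown" node per source. The alternatives — dropping unannotated species
or densely connecting them — either destroy information or destroy
sparsity; the catch-all preserves an information path for every species
while keeping the layer interpretable. Unknown nodes with no members are
omitted. Node order (metabolites sorted, production before consumption;
then genera; then communities; then unknown nodes) is deterministic so that
masks, checkpoints and attribution tables are reproducible.

One corner case: a metabolite whose consumers (or producers) all fall
outside the input species list still contributes both nodes, one of which
then has no connections; the package warns when this happens. The
synthetic generator always emits both roles for every metabolite.

### Decoders and metadata fusion

Each metadata task has a dedicated decoder: a *single affine map* from $h$
to the task's logits, softmax for age (6 classes), BMI (4) and body site,
and a single sigmoid unit for gender. The phrase "one fully connected
layer with dimensions matching the masked layer" admits a second reading —
an extra $H$-wide intermediate layer — but the single affine map is the
smallest architecture consistent with it, and is what this package
implements; an intermediate-layer variant is deliberately not offered in
v1 to keep the gradient code small and fully tested.

The disease decoder is an affine map plus softmax over the concatenation
of $h$ with the four *fused* metadata blocks, in fixed order (age, gender,
BMI, body site). Fusion is per sample and per task: an observed value
enters as its exact one-hot (gender: a 0/1 scalar) and is a constant with
respect to gradients; a missing value is replaced by the decoder's
probability vector. Probability vectors rather than hard labels are the
default (`fusion = "probabilities"`) because they are differentiable and
preserve the decoder's uncertainty; `"hard_one_hot"` is available for
users who want test-time behaviour to match a label-feeding deployment.
By default the disease loss backpropagates through predicted metadata into
the metadata decoders and the trunk (`grad_through_predicted`), realising
the multitask coupling; switching it off makes the metadata decoders learn
only from their own supervised terms.

### Loss and optimisation

The training objective is the sample-count-weighted multitask loss

$$ L \;=\; \sum_{t}\frac{n}{n_t}\sum_{i:\,t\text{ observed}}
   \mathrm{CE}(\hat y_{t,i}, y_{t,i}) \;+\; \sum_{i}
   \mathrm{CE}(\hat y_{\mathrm{dis},i}, y_{\mathrm{dis},i}), $$

with binary cross-entropy for gender. The per-task sums are *sums*, not
means, scaled by $n/n_t$ — the literal reading of the weighting — with the
weights computed once from the optimisation split. A task with no observed
labels is dropped from the loss with a warning. Cross-entropies are
evaluated from logits via log-sum-exp for numerical stability; the
user-facing `multitask_loss()` clamps probabilities at $10^{-12}$.

Optimisation is AdamW (learning rate 0.001, batch size 16, decoupled
weight decay 0.01) with gradients derived analytically; the mask is
applied to the trunk gradient and re-applied to the weights after every
update, so masked positions are *exactly* zero at all times, not merely
small. Training is bitwise reproducible given `train_config(seed = )` and
single-threaded BLAS.

Early stopping holds out a stratified 10% of the training split and keeps
the best-scoring weights, stopping after 10 epochs without improvement
(200 epochs maximum). The monitored quantity is the **disease validation
cross-entropy**, not the total multitask loss. This was a deliberate
choice made after observing the failure mode of the total-loss monitor:
with $n/n_{\mathrm{bmi}}$ weights around 15–20 and only a handful of
BMI-labelled samples in a 10% holdout, the weighted BMI term dominates the
monitor and rises (rare-task overfitting) while the disease task is still
improving, so the "best" state is the first epoch. Monitoring the primary
task avoids hostage-taking by rare auxiliary tasks;
`train_config(monitor = "total")` restores the total-loss monitor. Task
weights are computed on the 90% optimisation split only, since the holdout
plays no role in gradient computation.

### Evaluation

All metrics are computed per class and macro-averaged, so rare phenotypes
count as much as common ones: accuracy, macro F1, macro one-vs-rest AUC
and macro AUPRC (average precision). The AUC estimator is the exact
rank/Mann–Whitney statistic with ties credited one half — not trapezoidal
interpolation of an ROC polyline — so tied scores are handled exactly.
Degenerate classes follow conservative conventions: a class with no true
positives contributes F1 = 0; a class lacking positives (AUPRC) or lacking
either positives or negatives (AUC) is skipped with a warning. "Averaged"
is read as unweighted (no support weighting). Every metric is verified in
the test suite against an independent brute-force oracle (pairwise
counting for AUC, explicit threshold sweeps for AUPRC) on randomised
instances.

### Interpretation

Two path-attribution methods are implemented on the analytic gradients:

* **Integrated gradients** for input species (and, in
  `metadata_impact()`, for the fused metadata blocks actually consumed by
  the disease decoder, which is the quantity one wants when asking how
  metadata influence disease prediction);
* **Layer conductance** at the knowledge-primed hidden layer for the
  metadata tasks, so importances attach to *named* nodes.

The path integral uses the midpoint Riemann rule with 50 steps by default;
midpoint makes attribution exact for locally linear models at any step
count and gives completeness gaps far below $10^{-2}$ at 200 steps on
trained models (both properties are tested). The baseline is the
zero-abundance vector with all metadata treated as missing — an
"absence of signal" reference — and is configurable. Signed attributions
are converted to importances by absolute value, then averaged over all
evaluation samples, over the classes within a task, and over independently
initialised training restarts (the aggregation is exchangeable in restart
order, and per-restart raw scores are retained in the report). Global
scores aggregate over all evaluation samples rather than per-class sample
subsets; the per-class rows of `metadata_impact()` expose the finer
breakdown.

## The synthetic-data generator

`sim_spec()` / `simulate_dataset()` generate a complete study — abundance
matrix, metadata with missingness, the three knowledge tables, and a
ground-truth record — with planted, recoverable structure:

1. metadata categories are drawn from configurable marginals; the default
   missingness rates (age 81%, gender 30%, BMI 94% missing, body site
   always observed) mirror the availability pattern of large public
   microbiome compendia;
2. the phenotype is drawn from a logit table over (age class, body site)
   with strength `meta_effect`, so metadata carry phenotype information of
   their own — the ingredient that makes metadata fusion matter;
3. abundances are a gamma (Dirichlet-style) draw around a fixed log-normal
   per-species mean profile, multiplied by `exp(effect)` for the species
   of the sample's planted drivers (one driver genus per non-healthy
   phenotype, per age class, per BMI class and for the male gender; one
   driver community per body site), by a per-project log-normal offset
   (`project_sd`), and by log-normal noise; each sample is renormalised to
   100%.

The baseline concentration `base_shape` (default 5) matters: it sets the
sample-to-sample compositional dispersion against which the planted
log-fold effects must compete. An early unit-shape version of the
generator produced baselines so overdispersed that even an oracle
classifier on the true driver features could not recover the planted
signal, which defeats the generator's purpose; shape 5 leaves visible
scatter while keeping strong effects genuinely recoverable.

Scenario conventions used by the acceptance checks, chosen once:

* *strong-signal study*: `effect_disease = 4, effect_metadata = 1,
  noise_sd = 0.2` — disease-dominant planting. Metadata driver shifts act
  on large blocks of species and perturb the compositional denominator;
  making them as large as the disease effect turns a signal-recovery test
  into a confound-robustness test, so the nuisance shifts are kept mild.
* *null study*: all of `effect_disease`, `effect_metadata`, `meta_effect`
  at 0 — abundances and labels are independent, and cross-validated
  performance is compared against a label-permutation chance distribution.
* *distribution-shift study* (`make_shift_scenario()`): `project_sd = 2`
  with `meta_effect = 3` — projects carry strong private per-species
  offsets while the metadata→phenotype mechanism is shared, emulating
  testing on studies absent from training. Under this shift a
  metadata-fused model retains a transferable channel that an
  abundance-only model lacks.

What the generator does *not* emulate: real microbiome ecology
(species–species interactions, zero inflation calibrated to real data),
non-random missingness (masking is missing-at-random; real metadata
missingness is study-driven), or realistic taxonomies. Passing tests on
these simulations therefore demonstrate that the *mechanisms* — masked
connectivity, weighted multitask loss, fusion, attribution — behave as
specified, not that any particular real-data accuracy will be achieved.

## Problem sizes and degenerate inputs

The shipped studies are desk-scale by design: 600 samples × 50 species for
cross-validation, 900 samples across 6 projects for the shift scenario,
150–300 samples for the attribution studies; five folds or five restarts
throughout. These sizes keep a full pipeline run in minutes on one CPU
while leaving every planted effect recoverable.

Degenerate inputs are handled explicitly: empty knowledge files yield
catch-all-only schemas; a task with 100% missingness is dropped from the
loss with a warning; `max_epochs = 0` returns the initialised model;
classes smaller than the fold count trigger a warning; prediction ties
break toward the lowest class index and gender thresholds at 0.5 (ties to
female, the first level). Non-finite training losses abort with a
diagnostic rather than silently diverging.

## Known limitations

* Single-label phenotype prediction only; no multi-disease outputs and no
  prediction-confidence calibration or out-of-distribution rejection.
* The decoder architecture is fixed to single affine maps (see above).
* The hidden layer uses the genus rank only.
* Sum-reduction of the loss couples the effective learning rate to the
  batch size; the defaults (16, 0.001) are tuned to each other.
* Training is pure R: fast at desk scale, but not intended for
  corpus-scale (tens of thousands of samples × thousands of species) runs.
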