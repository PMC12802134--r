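---
title: "Interpretable rule networks for paired microbiome-metabolome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable rule networks for paired microbiome-metabolome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrules)
```

## The model

mmrules predicts a binary host phenotype (case vs control) from two paired
tables — microbial relative abundances and metabolite levels — with a
four-layer differentiable network whose fitted form reads as a short list
of logical rules.

**Layer 1 — feature aggregation.** Each *detector* is a soft ball in a
Euclidean embedding of the features: a learned center $\gamma$ and radius
$\kappa$ give every feature an inclusion weight
$u_i = \sigma((\kappa - \varepsilon_i)/\tau_u)$, where $\varepsilon_i$ is
the feature's embedded distance to the center. Metabolite detectors output
the weighted *mean* of standardized log levels of their members; taxa
detectors output the weighted *sum* of relative abundances. The embeddings
come from principal coordinate analysis of patristic distances (taxa) and
molecular-fingerprint distances (metabolites), so detectors correspond to
phylogenetically or chemically coherent groups.

**Layer 2 — detector activation.** A soft threshold unit
$g = \sigma((a - \eta)/\tau_g)$ turns each aggregate $a$ into an
approximately binary statement "the group's aggregate exceeds $\eta$".

**Layer 3 — detector selection and logical AND.** Each rule $k$ owns $J$
candidate metabolite detectors and $L$ candidate taxa detectors. Relaxed
Bernoulli selectors $z_{kj} \in (0,1)$ choose a sparse subset, and the rule
activation is the soft conjunction
$r_k = \prod_j \big(1 - z_{kj}(1 - g_{kj})\big)$ — the empty conjunction is
true.

**Layer 4 — rule selection and weighted OR.** Rule selectors $q_k$ and
weights $\beta_k$ combine the rules into
$Y = \sigma\!\big(\sum_k q_k \beta_k r_k + \beta_0\big)$; an active rule
multiplies the odds of the case label by $e^{\beta_k}$.

Priors: diffuse Normal(0, $10^4$) on centers, weights and intercept;
calibrated Log-Normal on radii (below); uniform on thresholds (taxa on
$[0,1]$, metabolites on the observed range padded by 1% of the range on
each side); BinaryConcrete (location $1/J$, $1/L$, $1/K$) on the selector
values, encoding a prior expectation of roughly one rule with one detector
per modality.

## Radius-prior calibration

Detector radii should match the scale at which biologically related
features cluster. For each metabolite chemical sub-class (or taxonomic
family) with at least three members we compute the median within-group
pairwise embedding distance $h_c$; the radius prior is
LogNormal$(\mathrm{median}_c(h_c), \mathrm{variance}_c(h_c))$ with the two
statistics used directly as the log-scale location and squared scale
(sample variance, $n-1$ denominator). A `natural_scale` switch instead
moment-matches the Log-Normal on the radius scale; the default is the
literal log-scale reading. Degenerate calibration (a single eligible group)
floors the variance at $10^{-4}$ with a warning. When no grouping table is
available the pipeline falls back to k-means pseudo-groups in the
embedding (about six features per group) and says so.

## Embedding dimensionality

Taxa: the smallest dimension whose embedded pairwise-distance distribution
is not significantly different from the input distances (two-sample
Kolmogorov-Smirnov test on all upper-triangle pairs, $\alpha = 0.05$),
searched upward from 1; if no dimension passes — common for strongly
non-Euclidean patristic matrices — the maximum ($N-1$) is used with a
warning. Metabolites: the smallest number of axes explaining 95% of the
positive eigenvalue mass. Axes with non-positive eigenvalues are discarded
(classical MDS treatment of non-Euclidean inputs such as Tanimoto
distances), and each axis' sign is fixed by making its first nonzero
coordinate positive so runs are reproducible across platforms.

## Inference

MAP estimation with full-batch Adam: learning rate 0.001 for all parameter
groups except taxa thresholds (0.0001, matching their narrow $[0,1]$
scale), 5000 epochs by default, radii clamped positive and thresholds
projected into their uniform supports after every step. Five temperatures
anneal linearly: $\tau_u$ and $\tau^T_g$ from $10^{-2}$ to $10^{-3}$,
$\tau^M_g$, $\tau_z$ and $\tau_q$ from 1 to 0.1 (the metabolite aggregate
range is an order of magnitude wider than the taxa one). Convergence is
recorded when the trailing 100-epoch loss decrease falls below 0.01. Ten
random restarts are run by default and the lowest-loss fit reported; the
per-epoch loss and gradient are computed in compiled code
(RcppArmadillo), with a pure-R reference implementation kept as the
correctness oracle in the test suite.

**Staged sparsity.** Treating selectors as deterministic transforms
$z = \sigma(\ell/\tau_z)$ of free logits and switching the BinaryConcrete
prior on from the first epoch makes MAP optimization collapse: at
initialization every rule activation is $\approx 0.003$ (a soft AND over
twenty half-selected detectors), so likelihood gradients on the selectors
are orders of magnitude smaller than the constant sparsity push, and under
Adam's per-coordinate normalization every selector dies before any
detector becomes informative — a co-collapse we observed at all learning
rates and epoch counts. The package therefore stages the optimization:
the BinaryConcrete terms carry weight 0 for the first `sparsity_warmup`
fraction of training (default 0.5) and ramp linearly to full weight at
`sparsity_full` (default 0.8), while the selector temperatures $\tau_z,
\tau_q$ are held at 1 during the warmup and annealed to 0.1 over the
remainder. The warmup lets the likelihood organize detectors, thresholds
and weights; the ramp then prunes weakly supported structure while
annealing saturates the survivors. Both knobs are ordinary `mm_fit_config()`
fields.

## Rule extraction

A fitted network discretizes at a cut of 0.5 (configurable): rules with
relaxed selector value above the cut are kept, detectors likewise, and a
feature is a member when its soft-inclusion weight exceeds the cut at the
final temperatures (equivalently, it lies within the radius). Three
degenerate cases follow the network's zero-temperature limit rather than
being dropped silently: a selected rule with no selected detectors is an
always-true rule, so its weight folds into the intercept; a selected
metabolite detector with no feature inside its radius keeps its single
nearest feature (the limit of the weighted mean); a selected taxa detector
with no members aggregates to zero, making its rule constant-false when
its threshold is non-negative. Metabolite thresholds are reported in
standardized log units; the stored per-feature log mean and sd re-express
them in raw units on request.

## The semi-synthetic benchmark

The generator injects known group differences into a baseline cohort so
detection power can be measured against ground truth. Five scenarios
perturb: (1) one metabolite group; (2) two metabolite groups, with the
control arm split into two subgroups that each receive a doubled
(2$\mu_1$) version of one group's perturbation so the expected total
perturbation per subject is constant; (3) one taxonomic clade; (4) two
clades, subgrouped as in (2); (5) one clade and one metabolite group —
cases receive both, control subgroup 1 the clade only, control subgroup 2
the metabolite group only, each doubled, with the other modality left at
baseline for the non-designated subgroup (the doubling analogy carried
over from scenario 2).

Metabolite perturbation is hierarchical on the standardized log scale:
perturbed entries draw from Normal($\mu^M_1 = 0.724$, 1.5) for cases and
Normal($\mu^M_0 = -0.203$, 1.5) for controls (values transported from
class-conditional detector means of rules fitted to real cohorts); all
entries then receive Normal(0, $\sigma^2_{\mathrm{meas}} = 0.024$)
measurement noise and are mapped back to the raw scale with the baseline's
per-metabolite log mean and sd. Taxa perturbation draws a clade log-mass
(cases $\mu^T_1 = -3$, controls $\mu^T_0 = -6$, sd 1.5), allocates it
proportionally to the subject's baseline within-clade composition (equally
if absent), renormalizes, jitters every taxon with a truncated Normal
(sd = 0.3 x mean, truncated to $[0,1]$, inverse-CDF sampling), and draws
counts from a Dirichlet-multinomial (concentration 286 x composition) at
the subject's original depth. Perturbed metabolite groups are sampled by
the model's own radius prior around a random seed metabolite and rejected
above 15% of the metabolites; clades are drawn uniformly among internal
nodes with 5-30 leaf descendants. Subject draws are nested across sample
sizes so power curves reuse subjects.

**The fabricated baseline.** When no real cohort is supplied,
`fabricate_baseline()` builds one: 67 subjects; 120 taxa on a random
coalescent tree, counts from a log-normal composition pushed through a
multinomial at depths of 8000-20000; 120 metabolites with log-normal
levels, a rank-3 latent-factor correlation, and 3% non-detects per
metabolite; a 5-dimensional clustered chemical embedding whose 12 clusters
double as sub-classes for prior calibration. The feature counts emulate a
shotgun-metagenomics + LC-MS/MS cohort. What it does *not* emulate:
real phylogenetic signal in abundances (taxa are exchangeable given the
tree), realistic chemical-class structure (clusters are isotropic
Gaussians), batch effects, or compositional zero-inflation beyond the
simple non-detect rule — so passing benchmarks here demonstrate correct
mechanics and detectable-signal recovery, not field performance.

## Numerical choices

Weighted-mean denominators carry an $\varepsilon = 10^{-10}$ guard; the
soft-AND is computed in log space with factors clamped at $10^{-300}$;
distances in gradient denominators are clamped at $10^{-12}$. K-means
initialization uses one cluster per detector slot of a rule, shared across
the K rules (the Normal(0,1) weight initialization breaks the symmetry);
radii start at each cluster's maximal member distance and thresholds at
the cohort mean of the cluster's aggregate. Ties in multi-restart
selection go to the smaller seed. Rule-set similarity uses exact
maximum-weight bipartite matching (bitmask dynamic program) up to 15
detectors on the smaller side and a greedy fallback beyond.

## Problem sizes used by the test suite

The packaged checks run the scenario-1 benchmark on ten datasets of 64
subjects from the default baseline: cross-validated detection power at
2000 epochs with 3 restarts per fold, and full-data fits for rule
extraction at 2500 epochs with 4 restarts (the staged schedule scales
with the epoch count; full-size analyses use the 5000-epoch, 10-restart
default). Simulator moment checks
use $10^5$ Monte-Carlo draws and 3-standard-error bands; structural bounds
are checked over 1000 sampled groups and clades.

## Known limitations

Cross-sectional only — no longitudinal structure. No covariate
adjustment. The InfoMax fingerprint backend (pretrained graph encoder) is
not bundled and errors clearly when requested. CACTVS fingerprints are
decoded from cached provider records, never recomputed, so metabolites
without a cached record fall back to unresolved and are excluded with a
warning. MAP point estimation gives no posterior uncertainty on rules;
run-to-run variability should be assessed with `ruleset_similarity()`
across restarts, and findings interpreted on consistently recovered
detectors.
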