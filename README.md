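# mmrules

Interpretable rule networks for paired microbiome–metabolome
classification.

## What problem this solves, and for whom

Microbiome studies increasingly measure two molecular layers per subject —
microbial composition (16S or shotgun sequencing) and metabolite levels
(LC-MS/MS) — and ask whether a host phenotype (disease vs healthy) can be
predicted from them, and *why*. Black-box classifiers answer only the
first question. `mmrules` is for researchers who need the second: it fits
a sparsity-biased differentiable rule network whose trained form reads
directly as English-language rules over biologically coherent groups of
taxa and metabolites.

## The model

A *detector* is a learned ball (center γ, radius κ) in a Euclidean
embedding of the features — principal coordinates of patristic distances
for taxa, of molecular-fingerprint distances (PubChem CACTVS, Morgan, MQN,
MAP4) for metabolites — so each detector corresponds to a phylogenetically
or chemically related group. Each detector aggregates its members (summed
relative abundance for taxa, mean standardized log level for metabolites)
and thresholds the aggregate:

    u_i = σ((κ − ε_i)/τ_u)            soft membership of feature i
    g   = σ((a − η)/τ_g)              detector activation
    r_k = Π_j (1 − z_kj (1 − g_kj))   soft AND over selected detectors
    Y   = σ(Σ_k q_k β_k r_k + β_0)    weighted OR → case probability

Selectors z, q carry BinaryConcrete priors with locations 1/J, 1/L, 1/K
(a prior expectation of about one rule with one detector per modality),
detector radii carry a Log-Normal prior calibrated from chemical
sub-classes / taxonomic families, and everything is trained by MAP with
Adam under linear temperature annealing, so activations and selections
harden into discrete decisions. An active rule multiplies the odds of the
case label by exp(β_k). The package also ships the five-scenario
semi-synthetic benchmark generator (known perturbed metabolite groups and
taxonomic clades injected into a baseline cohort) used to validate
detection power end to end.

## Worked example

Generate a scenario-1 benchmark dataset (one perturbed metabolite group)
from a fabricated 67-subject baseline cohort, fit, and read the rules:

```r
library(mmrules)

baseline <- fabricate_baseline(seed = 42)
ds <- generate_scenario(baseline,
                        scenario_config(scenario = 1, n_subjects = 64,
                                        seed = 42))

taxa      <- filter_taxa(ds$taxa)              # counts >= 10 in >= 10%
metab     <- filter_metabolites(ds$metab)      # detected in >= 15%
aligned   <- align_inputs(taxa, metab, ds$labels)
taxa_rel  <- to_relative_abundance(aligned$taxa)
metab_std <- transform_metabolites(aligned$metab)

D_taxa <- patristic_distances(baseline$tree, colnames(taxa_rel$values))
emb_T  <- pcoa_embed(D_taxa, select_dims_taxa(D_taxa))
emb_M  <- baseline$metab_emb                   # chemical embedding
prior_M <- calibrate_radius_prior(emb_M, baseline$subclasses)
prior_T <- calibrate_radius_prior(emb_T, groups = NULL)  # or a taxonomy table

data <- prepare_model_data(taxa_rel, metab_std, aligned$labels,
                           emb_M, emb_T, mm_hyperparams())
fit  <- multi_seed_fit(data, mm_hyperparams(), prior_M, prior_T,
                       mm_fit_config(epochs = 2000, seeds = 3))
glance(fit)
#> # A tibble: 1 × 6
#>   final_loss converged epochs  seed n_rules n_subjects
#>        <dbl> <lgl>      <int> <int>   <int>      <int>
#> 1     62189. FALSE       2000     2      10         64

rules <- extract_rules(fit)
writeLines(render_rules(rules, case_label = "case")[1])
#> IF mean standardized level of {metab004, metab005, metab014, metab031,
#>   metab032, metab043, metab045, metab068, metab100} > -0.1645
#>   THEN odds of case x57 (increased by 57-fold)

ds$truth$metab_groups[[1]]
#> "metab004" "metab005" "metab014" "metab031" "metab032" "metab043"
#> "metab045" "metab068" "metab074" "metab100"
```

The strongest rule's metabolite detector recovers 9 of the 10 truly
perturbed metabolites (Jaccard 0.9): when that group's mean standardized
level exceeds its learned threshold, the odds of the case label increase
57-fold. `tidy(rules)` returns the same structure as a tibble (one
row per detector), `predict(fit, ...)` gives per-subject case
probabilities, `cross_validate()` produces stratified held-out
predictions with per-fold AUCs, and `autoplot()` methods draw the loss
trace and the held-out probability distributions. A command-line wrapper
(`inst/scripts/mmrules`) exposes `run`, `simulate`, `report`, and
`stability` subcommands over the same functions.

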