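# Shared fixtures, built in code. Heavy scenario-1 fits used by the
# end-to-end acceptance checks are memoised in this environment so the
# benchmark, fidelity, and stability tests share one set of trained models.

fixture_env <- new.env(parent = emptyenv())

# small paired tables with known content
tiny_tables <- function() {
  counts <- matrix(c(12, 0, 5,
                     30, 2, 0,
                     8, 15, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("taxA", "taxB", "taxC")))
  levels <- matrix(c(2.5, 0, 1.1,
                     3.0, 4.2, 0,
                     1.9, 5.0, 2.2), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("m1", "m2", "m3")))
  list(taxa = feature_table(counts, "taxa", "raw"),
       metab = feature_table(levels, "metabolite", "raw"),
       labels = tibble::tibble(subject_id = c("s1", "s2", "s3"),
                               label = c(0L, 1L, 1L)))
}

# random model-ready data for network-level tests
random_model_data <- function(S = 12, NM = 8, NT = 10, DM = 3, DT = 2,
                              seed = 1) {
  withr::with_seed(seed, {
    XT <- matrix(rexp(S * NT), S, NT)
    XT <- XT / rowSums(XT)
    dimnames(XT) <- list(sprintf("s%02d", 1:S), sprintf("t%02d", 1:NT))
    XM <- matrix(rnorm(S * NM), S, NM,
                 dimnames = list(sprintf("s%02d", 1:S), sprintf("m%02d", 1:NM)))
    list(XM = XM, XT = XT,
         EM = matrix(rnorm(NM * DM), NM, DM),
         ET = matrix(rnorm(NT * DT), NT, DT),
         y = rep(c(0, 1), length.out = S),
         eta_M_bounds = c(-4, 4))
  })
}

test_lognormal_prior <- function(loc = 0.2, s2 = 0.3) {
  structure(list(log_location = loc, log_scale2 = s2,
                 source_groups_used = 3L),
            class = "lognormal_prior")
}

flatten_params <- function(p) unlist(p)

unflatten_params <- function(v, proto) {
  out <- proto
  pos <- 1
  for (nm in names(proto)) {
    n <- length(proto[[nm]])
    x <- v[pos:(pos + n - 1)]
    if (is.matrix(proto[[nm]])) dim(x) <- dim(proto[[nm]])
    out[[nm]] <- x
    pos <- pos + n
  }
  out
}

# baseline cohort shared by the synthetic-data tests (module scale)
get_baseline <- function() {
  if (is.null(fixture_env$baseline)) {
    fixture_env$baseline <- fabricate_baseline(seed = 7)
  }
  fixture_env$baseline
}

# preprocessing + embeddings + priors for one scenario-1 dataset
prep_scenario1 <- function(dsseed, n = 64) {
  baseline <- get_baseline()
  if (is.null(fixture_env$prior_M)) {
    fixture_env$prior_M <- calibrate_radius_prior(baseline$metab_emb,
                                                  baseline$subclasses)
  }
  ds <- generate_scenario(baseline,
                          scenario_config(1, n, seed = dsseed),
                          radius_prior = fixture_env$prior_M)
  al <- align_inputs(filter_taxa(ds$taxa), filter_metabolites(ds$metab),
                     ds$labels)
  taxa_rel <- to_relative_abundance(al$taxa)
  metab_raw <- feature_table(al$metab$values, "metabolite", "raw")
  metab_std <- transform_metabolites(al$metab)
  if (is.null(fixture_env$emb_T_cache)) fixture_env$emb_T_cache <- list()
  key <- paste(sort(colnames(taxa_rel$values)), collapse = "|")
  if (is.null(fixture_env$emb_T_cache[[key]])) {
    DT <- patristic_distances(baseline$tree, colnames(taxa_rel$values))
    emb_T <- suppressWarnings(pcoa_embed(DT, suppressWarnings(
      select_dims_taxa(DT))))
    fixture_env$emb_T_cache[[key]] <-
      list(emb_T = emb_T,
           prior_T = calibrate_radius_prior(emb_T,
                                            mmrules:::pseudo_groups(emb_T)))
  }
  cache <- fixture_env$emb_T_cache[[key]]
  list(ds = ds, labels = al$labels, taxa_rel = taxa_rel,
       metab_raw = metab_raw, metab_std = metab_std,
       emb_M = baseline$metab_emb, emb_T = cache$emb_T,
       prior_M = fixture_env$prior_M, prior_T = cache$prior_T)
}

# benchmark configurations for the end-to-end checks, reduced in scale
# relative to the full 5000-epoch, 10-restart default: cross-validation at
# 2000 epochs / 3 restarts per fold, full-data rule-extraction fits at
# 2500 epochs / 4 restarts
benchmark_config <- function() {
  mm_fit_config(epochs = 2000, seeds = 3)
}

benchmark_fit_config <- function() {
  mm_fit_config(epochs = 2500, seeds = 4)
}

benchmark_seeds <- function() 11:20

# scenario-1 benchmark: per dataset, a 5-fold CV and a full-data multi-seed
# fit (memoised; shared by the AUC, fidelity, and recovery tests)
get_benchmark <- function() {
  if (!is.null(fixture_env$benchmark)) return(fixture_env$benchmark)
  cfg <- benchmark_config()
  fit_cfg <- benchmark_fit_config()
  hp <- mm_hyperparams()
  runs <- lapply(benchmark_seeds(), function(dsseed) {
    pp <- prep_scenario1(dsseed)
    cv <- cross_validate(pp$taxa_rel, pp$metab_raw, pp$labels,
                         pp$emb_M, pp$emb_T, hp, pp$prior_M, pp$prior_T, cfg)
    data <- prepare_model_data(pp$taxa_rel, pp$metab_std, pp$labels,
                               pp$emb_M, pp$emb_T, hp)
    fit <- multi_seed_fit(data, hp, pp$prior_M, pp$prior_T, fit_cfg)
    net <- predict(fit, pp$taxa_rel, pp$metab_std)
    rs <- suppressWarnings(extract_rules(fit))
    hard <- evaluate_ruleset(rs, pp$taxa_rel, pp$metab_std)
    truth <- pp$ds$truth$metab_groups[[1]]
    td <- tidy(rs)
    best_jac <- if (nrow(td) > 0) {
      max(vapply(td$members, function(m) {
        length(intersect(m, truth)) / length(union(m, truth))
      }, numeric(1)))
    } else 0
    list(cv_auc = cv$mean_auc,
         agree = hard$class == as.integer(net$p_case > 0.5),
         best_jac = best_jac)
  })
  fixture_env$benchmark <- runs
  runs
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

make_ruleset <- function(rules, intercept = 0) {
  structure(list(rules = rules, intercept = intercept),
            class = "mm_ruleset")
}

make_detector <- function(ids, modality = "metabolite", threshold = 0) {
  list(modality = modality, member_ids = ids, threshold = threshold,
       aggregate = if (modality == "metabolite") "mean standardized level"
       else "summed relative abundance",
       direction = "greater than")
}
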