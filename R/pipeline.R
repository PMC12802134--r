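#' Run the full analysis pipeline
#'
#' Wires ingestion, filtering, distance computation, embedding, prior
#' calibration, cross-validated fitting, and rule reporting into one call,
#' writing all artifacts into a run directory: `predictions.csv`,
#' `rules.txt`, `rules.json`, `loss_trace.csv`, and `config.json` (the
#' resolved configuration snapshot). The snapshot plus the seed reproduce
#' every output.
#'
#' @param config named list (see Details) or path to a flat `key = value`
#'   config file parsed by [read_run_config()].
#'
#' @details Recognised keys: `taxa_table`, `metab_table`, `labels`
#'   (paths, required); `tree` (Newick) or `taxa_distances` (square CSV);
#'   `metab_ids` (id table) or `metab_distances` (square CSV, with
#'   `metab_similarities = TRUE` if values are similarities);
#'   `metab_subclasses` and `taxa_families` (two-column grouping CSVs,
#'   optional — pseudo-groups from embedding clusters are used otherwise);
#'   `fingerprint` (default `cactvs`); `cactvs_cache` (directory);
#'   `min_count`, `min_frac`, `min_presence_frac` (filters); `K`, `J`, `L`;
#'   `epochs`, `seeds`, `cv_folds`, `loo`, `early_stop`; `seed` (global);
#'   `out_dir` (required).
#' @return the run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  cfg <- config
  req <- function(key) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
    cfg[[key]]
  }
  out_dir <- req("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  num <- function(key, default) as.numeric(cfg[[key]] %||% default)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  labels <- stage("labels", read_labels(req("labels")))
  taxa <- stage("taxa ingestion",
                read_feature_table(req("taxa_table"), "taxa",
                                   label_ids = labels$subject_id))
  metab <- stage("metabolite ingestion",
                 read_feature_table(req("metab_table"), "metabolite",
                                    label_ids = labels$subject_id))
  taxa <- stage("taxa filter",
                filter_taxa(taxa, num("min_count", 10), num("min_frac", 0.10)))
  metab <- stage("metabolite filter",
                 filter_metabolites(metab, num("min_presence_frac", 0.15)))
  aligned <- stage("alignment", align_inputs(taxa, metab, labels))
  taxa_rel <- to_relative_abundance(aligned$taxa)
  # ---- distances & embeddings --------------------------------------------
  DT <- stage("taxa distances", {
    if (!is.null(cfg$taxa_distances)) {
      read_metabolite_distances(cfg$taxa_distances)
    } else {
      patristic_distances(req("tree"), colnames(taxa_rel$values))
    }
  })
  keepT <- intersect(colnames(taxa_rel$values), rownames(DT))
  taxa_rel <- feature_table(taxa_rel$values[, keepT, drop = FALSE], "taxa",
                            "relative_abundance")
  DM <- stage("metabolite distances", {
    if (!is.null(cfg$metab_distances)) {
      read_metabolite_distances(cfg$metab_distances,
                                similarities = isTRUE(cfg$metab_similarities))
    } else {
      ids <- readr::read_csv(req("metab_ids"), col_types = readr::cols(),
                             show_col_types = FALSE)
      resolved <- resolve_structures(ids, cache_dir = cfg$cactvs_cache)
      build_metabolite_distances(resolved, cfg$fingerprint %||% "cactvs")
    }
  })
  metab_kept <- intersect(colnames(aligned$metab$values), rownames(DM))
  metab_raw <- feature_table(
    aligned$metab$values[, metab_kept, drop = FALSE], "metabolite", "raw")
  dims_T <- select_dims_taxa(DT)
  dims_M <- select_dims_metab(DM)
  emb_T <- pcoa_embed(DT, dims_T)
  emb_M <- pcoa_embed(DM, dims_M)
  prior_T <- stage("taxa radius prior",
                   radius_prior_from(emb_T, cfg$taxa_families))
  prior_M <- stage("metabolite radius prior",
                   radius_prior_from(emb_M, cfg$metab_subclasses))
  hp <- mm_hyperparams(K = num("K", 10), J = num("J", 10), L = num("L", 10))
  fit_cfg <- mm_fit_config(epochs = num("epochs", 5000),
                           seeds = num("seeds", 10),
                           cv_folds = num("cv_folds", 5),
                           loo = isTRUE(cfg$loo),
                           early_stop = isTRUE(cfg$early_stop),
                           fold_seed = seed)
  # ---- cross-validated predictions ---------------------------------------
  cv <- stage("cross-validation",
              cross_validate(taxa_rel, metab_raw, aligned$labels,
                             emb_M, emb_T, hp, prior_M, prior_T, fit_cfg))
  readr::write_csv(cv$predictions, file.path(out_dir, "predictions.csv"))
  # ---- full-data fit and rule report -------------------------------------
  metab_std <- transform_metabolites(metab_raw)
  data <- prepare_model_data(taxa_rel, metab_std, aligned$labels,
                             emb_M, emb_T, hp)
  fit <- stage("fit", multi_seed_fit(data, hp, prior_M, prior_T, fit_cfg,
                                     seeds = seed * 1000L +
                                       seq_len(fit_cfg$seeds)))
  readr::write_csv(tibble::tibble(epoch = seq_along(fit$loss_trace),
                                  loss = fit$loss_trace),
                   file.path(out_dir, "loss_trace.csv"))
  rules <- suppressWarnings(extract_rules(fit))
  writeLines(render_rules(rules), file.path(out_dir, "rules.txt"))
  export_rules(rules, file.path(out_dir, "rules.json"))
  snapshot <- cfg
  snapshot$seed <- seed
  snapshot$mean_cv_auc <- cv$mean_auc
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("run complete: mean CV AUC %.3f, %d rule(s); artifacts in %s",
                  cv$mean_auc, length(rules$rules), out_dir))
  invisible(out_dir)
}

radius_prior_from <- function(emb, grouping_path) {
  groups <- if (!is.null(grouping_path)) {
    readr::read_csv(grouping_path, col_types = readr::cols(),
                    show_col_types = FALSE)
  } else NULL
  calibrate_radius_prior(emb, groups)
}

# fallback biological grouping: k-means clusters in the embedding, sized so
# the average cluster has ~6 members
pseudo_groups <- function(emb, target_size = 6) {
  n <- nrow(emb$coords)
  k <- max(2, round(n / target_size))
  cl <- with_local_seed(760817L,
                        stats::kmeans(emb$coords, centers = k,
                                      nstart = 5, iter.max = 50)$cluster)
  stats::setNames(sprintf("cluster%02d", cl), emb$labels)
}

#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; `true`/`false`
#' become logicals, numbers become numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (grepl("^-?[0-9.eE+]+$", val) &&
               !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
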