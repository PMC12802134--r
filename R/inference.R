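#' Fit configuration
#'
#' @param epochs training epochs (default 5000; convergence is typically
#'   reached well within this).
#' @param lr_default Adam learning rate for all parameters (0.001).
#' @param lr_eta_T learning rate for taxa detector thresholds (0.0001; the
#'   taxa aggregate lives on the narrow \[0,1\] scale).
#' @param seeds number of random restarts; the lowest-loss fit is reported.
#' @param convergence_window,convergence_delta training has converged when
#'   the loss decrease over the trailing window falls below delta.
#' @param early_stop stop at convergence instead of running all epochs.
#' @param sparsity_warmup fraction of training during which the
#'   BinaryConcrete selector priors are held off (weight 0) before ramping
#'   linearly to full weight at `sparsity_full`; lets informative detectors
#'   form before sparsity pressure prunes the network.
#' @param sparsity_full fraction of training at which the selector priors
#'   reach full weight.
#' @param cv_folds folds for [cross_validate()]; set `loo = TRUE` for
#'   leave-one-out.
#' @param fold_seed seed for the stratified fold split (kept separate from
#'   the model seeds).
#' @return list of class `mm_fit_config`.
#' @export
mm_fit_config <- function(epochs = 5000, lr_default = 0.001,
                          lr_eta_T = 0.0001, seeds = 10,
                          convergence_window = 100, convergence_delta = 0.01,
                          early_stop = FALSE, cv_folds = 5, loo = FALSE,
                          fold_seed = 1L, sparsity_warmup = 0.5,
                          sparsity_full = 0.8) {
  stopifnot(epochs >= convergence_window, seeds >= 1,
            sparsity_warmup >= 0, sparsity_full >= sparsity_warmup,
            sparsity_full <= 1)
  structure(list(epochs = as.integer(epochs), lr_default = lr_default,
                 lr_eta_T = lr_eta_T, seeds = as.integer(seeds),
                 convergence_window = as.integer(convergence_window),
                 convergence_delta = convergence_delta,
                 early_stop = early_stop, cv_folds = as.integer(cv_folds),
                 loo = loo, fold_seed = as.integer(fold_seed),
                 sparsity_warmup = sparsity_warmup,
                 sparsity_full = sparsity_full),
            class = "mm_fit_config")
}

# run expr with a local RNG state so package internals never perturb the
# caller's stream
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Assemble model-ready data
#'
#' Bundles the aligned relative-abundance taxa table, log-standardized
#' metabolite table, labels, and the two embeddings into the flat structure
#' the optimizer consumes, including the padded uniform support of the
#' metabolite thresholds.
#'
#' @param taxa `feature_table` in `relative_abundance` state.
#' @param metab `feature_table` in `log_standardized` state.
#' @param labels tibble (`subject_id`, `label`), aligned.
#' @param emb_M,emb_T [pcoa_embed()] results whose labels cover the feature
#'   ids of the two tables.
#' @param hp [mm_hyperparams()] (supplies the threshold padding).
#' @return list used by [negative_log_posterior()] and [fit_rules()].
#' @export
prepare_model_data <- function(taxa, metab, labels, emb_M, emb_T,
                               hp = mm_hyperparams()) {
  stopifnot(taxa$transform_state == "relative_abundance",
            metab$transform_state == "log_standardized")
  stopifnot(identical(rownames(taxa$values), labels$subject_id),
            identical(rownames(metab$values), labels$subject_id))
  fM <- colnames(metab$values); fT <- colnames(taxa$values)
  if (!all(fM %in% emb_M$labels)) stop("metabolite embedding missing features")
  if (!all(fT %in% emb_T$labels)) stop("taxa embedding missing features")
  XM <- metab$values
  rng <- range(XM)
  pad <- hp$eta_pad * diff(rng)
  EM <- emb_M$coords[fM, , drop = FALSE]
  ET <- emb_T$coords[fT, , drop = FALSE]
  list(XM = XM, XT = taxa$values,
       EM = EM, ET = ET,
       EM2 = rowSums(EM^2), ET2 = rowSums(ET^2),
       y = as.numeric(labels$label),
       subject_ids = labels$subject_id,
       eta_M_bounds = c(rng[1] - pad, rng[2] + pad),
       log_mean = metab$log_mean, log_sd = metab$log_sd)
}

#' Initialize model parameters
#'
#' Detector centers and radii come from k-means on the embedding
#' coordinates with as many clusters as detectors (reduced with a warning
#' when features are fewer): centers are the centroids and each radius is
#' the maximum distance from the centroid to its assigned members, so the
#' initial groups are exactly the k-means clusters. Activation thresholds
#' start at the cohort mean of each initial group's aggregate. Weights and
#' intercept draw from a standard Normal; all selector logits start at 0 so
#' every selector value is 0.5.
#'
#' @param data [prepare_model_data()] output.
#' @param hp [mm_hyperparams()].
#' @param seed RNG seed; same seed gives bit-identical initialization.
#' @return an `mm_params` list.
#' @export
initialize_params <- function(data, hp, seed = 1L) {
  with_local_seed(seed, {
    initM <- kmeans_detectors(data$EM, data$XM, hp$J, hp$K, mean_agg = TRUE)
    initT <- kmeans_detectors(data$ET, data$XT, hp$L, hp$K, mean_agg = FALSE)
    new_model_params(
      centers_M = initM$centers, radii_M = initM$radii, eta_M = initM$eta,
      centers_T = initT$centers, radii_T = initT$radii, eta_T = initT$eta,
      det_logits_M = matrix(0, hp$K, hp$J),
      det_logits_T = matrix(0, hp$K, hp$L),
      rule_logits = rep(0, hp$K),
      beta = stats::rnorm(hp$K), beta0 = stats::rnorm(1)
    )
  })
}

# k-means with one cluster per detector slot of a rule; all K rules share
# the same detector initialization (symmetry is broken by the random
# prediction-layer weights)
kmeans_detectors <- function(E, X, det_per_rule, K, mean_agg) {
  n_feat <- nrow(E)
  n_distinct <- nrow(unique(E))
  k <- det_per_rule
  if (k >= n_distinct) {
    if (k > n_distinct) {
      warning("reducing k-means clusters from ", k, " to ", n_distinct,
              " (fewer distinct features than detectors per rule)")
    }
    uE <- unique(E)
    km <- list(cluster = apply(cross_dist(E, uE), 1, which.min),
               centers = uE)
    k <- n_distinct
  } else {
    km <- stats::kmeans(E, centers = k, nstart = 10, iter.max = 100)
  }
  centers <- km$centers
  # singleton clusters get a scale-aware radius (half the gap to the
  # nearest other centroid) so their detector starts clearly inclusive
  centroid_gap <- if (k > 1) cross_dist(centers, centers) else
    matrix(0, 1, 1)
  diag(centroid_gap) <- Inf
  radii <- vapply(seq_len(k), function(c) {
    members <- which(km$cluster == c)
    d <- sqrt(rowSums(sweep(E[members, , drop = FALSE], 2, centers[c, ])^2))
    if (length(members) > 1 && max(d) > 1e-3) return(max(d))
    if (k > 1) max(min(centroid_gap[c, ]) / 2, 1e-3) else 1
  }, numeric(1))
  eta <- vapply(seq_len(k), function(c) {
    members <- which(km$cluster == c)
    agg <- if (mean_agg) rowMeans(X[, members, drop = FALSE])
    else rowSums(X[, members, drop = FALSE])
    mean(agg)
  }, numeric(1))
  idx <- rep_len(seq_len(k), det_per_rule)  # pad if k was reduced
  idx <- rep(idx, K)                        # tile across rules
  list(centers = centers[idx, , drop = FALSE], radii = radii[idx],
       eta = eta[idx])
}

#' Train the rule network by MAP estimation
#'
#' Full-batch Adam on [negative_log_posterior()] with two learning-rate
#' groups and linear annealing of all five temperatures. Radii are kept
#' positive and thresholds are projected back into their uniform supports
#' after every step.
#'
#' @param data [prepare_model_data()] output.
#' @param hp [mm_hyperparams()].
#' @param prior_M,prior_T radius priors from [calibrate_radius_prior()].
#' @param config [mm_fit_config()].
#' @param seed initialization / restart seed.
#' @return object of class `mm_fit`: `params`, `loss_trace`, `converged`,
#'   `seed`, `final_loss`, `final_temps`, plus data metadata for reporting.
#' @export
fit_rules <- function(data, hp = mm_hyperparams(), prior_M, prior_T,
                      config = mm_fit_config(), seed = 1L) {
  params <- initialize_params(data, hp, seed)
  E <- config$epochs
  m <- lapply(params, function(x) x * 0)  # Adam moments
  v <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  lrs <- lapply(params, function(x) config$lr_default)
  lrs$eta_T <- config$lr_eta_T
  loss_trace <- numeric(E)
  converged <- FALSE
  conv_epoch <- NA_integer_
  names_p <- names(params)
  for (e in seq_len(E)) {
    temps <- anneal_temperatures(e - 1, E, config$sparsity_warmup)
    frac <- if (E <= 1) 1 else (e - 1) / (E - 1)
    bc_w <- if (config$sparsity_full <= config$sparsity_warmup) 1 else
      min(1, max(0, (frac - config$sparsity_warmup) /
                   (config$sparsity_full - config$sparsity_warmup)))
    out <- .mm_nlp_grad_cpp(params, data, hp, prior_M, prior_T, temps,
                            bc_w, TRUE)
    loss_trace[e] <- out$loss
    g <- out$grads
    for (nm in names_p) {  # C++ returns column matrices for vector params
      if (!is.matrix(params[[nm]])) g[[nm]] <- as.numeric(g[[nm]])
    }
    for (nm in names_p) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^e)
      vhat <- v[[nm]] / (1 - b2^e)
      params[[nm]] <- params[[nm]] - lrs[[nm]] * mhat / (sqrt(vhat) + adam_eps)
    }
    # projection steps keep parameters inside their prior supports
    params$radii_M <- pmax(params$radii_M, 1e-6)
    params$radii_T <- pmax(params$radii_T, 1e-6)
    params$eta_T <- pmin(pmax(params$eta_T, 0), 1)
    params$eta_M <- pmin(pmax(params$eta_M, data$eta_M_bounds[1]),
                         data$eta_M_bounds[2])
    w <- config$convergence_window
    if (!converged && e > w &&
        loss_trace[e - w] - loss_trace[e] < config$convergence_delta) {
      converged <- TRUE
      conv_epoch <- e
      if (config$early_stop) {
        loss_trace <- loss_trace[seq_len(e)]
        break
      }
    }
  }
  final_temps <- anneal_temperatures(length(loss_trace) - 1, E,
                                     config$sparsity_warmup)
  structure(list(params = params, loss_trace = loss_trace,
                 converged = converged, convergence_epoch = conv_epoch,
                 seed = seed, final_loss = loss_trace[length(loss_trace)],
                 final_temps = final_temps, hp = hp,
                 prior_M = prior_M, prior_T = prior_T,
                 feature_ids_M = colnames(data$XM),
                 feature_ids_T = colnames(data$XT),
                 EM = data$EM, ET = data$ET,
                 eta_M_bounds = data$eta_M_bounds,
                 log_mean = data$log_mean, log_sd = data$log_sd,
                 n_subjects = length(data$y)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> seed %d, %d epochs, final loss %.3f (%s)\n",
              x$seed, length(x$loss_trace), x$final_loss,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict case probabilities from a fitted model
#'
#' @param object an `mm_fit`.
#' @param taxa,metab aligned feature tables in `relative_abundance` /
#'   `log_standardized` state (features must match the training features).
#' @param ... unused.
#' @return tibble (`subject_id`, `p_case`).
#' @export
predict.mm_fit <- function(object, taxa, metab, ...) {
  data <- list(XM = metab$values[, object$feature_ids_M, drop = FALSE],
               XT = taxa$values[, object$feature_ids_T, drop = FALSE],
               EM = object$EM, ET = object$ET,
               y = rep(0, nrow(taxa$values)),
               eta_M_bounds = object$eta_M_bounds)
  fwd <- model_forward(object$params, data, object$final_temps, object$hp)
  tibble::tibble(subject_id = rownames(taxa$values), p_case = fwd$Y)
}

#' Multi-restart MAP fit
#'
#' Runs [fit_rules()] once per seed and returns the fit with the lowest
#' final loss (ties broken by the smaller seed).
#'
#' @inheritParams fit_rules
#' @param seeds explicit seed vector; defaults to `1:config$seeds`.
#' @return the winning `mm_fit`, with attribute `all_losses`.
#' @export
multi_seed_fit <- function(data, hp = mm_hyperparams(), prior_M, prior_T,
                           config = mm_fit_config(), seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(config$seeds)
  fits <- lapply(sort(seeds), function(s) {
    tryCatch(fit_rules(data, hp, prior_M, prior_T, config, seed = s),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all seeds failed")
  losses <- vapply(fits, function(f) f$final_loss, numeric(1))
  best <- fits[[which.min(losses)]]
  attr(best, "all_losses") <- losses
  best
}

#' Stratified cross-validated predictions
#'
#' Splits subjects into stratified folds (leave-one-out if requested),
#' re-fits the metabolite log-standardization on each training fold and
#' applies it to the held-out subjects, trains a multi-seed fit per fold,
#' and pools held-out predictions. AUC is computed per fold and over the
#' pooled predictions.
#'
#' @param taxa `relative_abundance` feature table (all subjects).
#' @param metab_raw raw (filtered, untransformed) metabolite feature table.
#' @param labels aligned label tibble.
#' @param emb_M,emb_T feature embeddings.
#' @param hp,config,prior_M,prior_T as in [fit_rules()].
#' @return list of class `mm_cv`: `predictions` tibble
#'   (`subject_id`, `fold`, `p_case`, `label`), `auc_per_fold`, `mean_auc`,
#'   `pooled_auc`.
#' @export
cross_validate <- function(taxa, metab_raw, labels, emb_M, emb_T,
                           hp = mm_hyperparams(), prior_M, prior_T,
                           config = mm_fit_config()) {
  stopifnot(metab_raw$transform_state == "raw")
  y <- labels$label
  n <- length(y)
  folds <- if (config$loo) seq_len(n) else
    stratified_folds(y, config$cv_folds, config$fold_seed)
  preds <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(unique(y[train_idx])) < 2) {
      stop("training fold ", f, " lost a class; use fewer folds")
    }
    sub <- function(ft, idx, ...) {
      feature_table(ft$values[idx, , drop = FALSE], ft$modality,
                    ft$transform_state, ...)
    }
    metab_tr <- transform_metabolites(sub(metab_raw, train_idx))
    # held-out subjects standardized with training statistics only
    z_te <- scale_with(metab_raw$values[test_idx, , drop = FALSE],
                       metab_tr$log_mean, metab_tr$log_sd)
    metab_te <- feature_table(z_te, "metabolite", "log_standardized",
                              log_mean = metab_tr$log_mean,
                              log_sd = metab_tr$log_sd)
    taxa_tr <- sub(taxa, train_idx); taxa_te <- sub(taxa, test_idx)
    lab_tr <- labels[train_idx, ]
    data_tr <- prepare_model_data(taxa_tr, metab_tr, lab_tr, emb_M, emb_T, hp)
    fit <- multi_seed_fit(data_tr, hp, prior_M, prior_T, config)
    p <- predict.mm_fit(fit, taxa_te, metab_te)
    preds[[f]] <- dplyr::mutate(p, fold = f, label = y[test_idx])
  }
  predictions <- dplyr::bind_rows(preds)
  per_fold <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(auc = safe_auc(.data$label, .data$p_case),
                     .groups = "drop")
  structure(list(predictions = predictions,
                 auc_per_fold = per_fold,
                 mean_auc = mean(per_fold$auc, na.rm = TRUE),
                 pooled_auc = safe_auc(predictions$label,
                                       predictions$p_case)),
            class = "mm_cv")
}

#' @export
print.mm_cv <- function(x, ...) {
  cat(sprintf("<mm_cv> %d held-out predictions, mean fold AUC %.3f (pooled %.3f)\n",
              nrow(x$predictions), x$mean_auc, x$pooled_auc))
  invisible(x)
}

safe_auc <- function(label, p) {
  if (length(unique(label)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(label, p, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

scale_with <- function(raw, log_mean, log_sd) {
  v <- apply(raw, 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) > 0) col[col <= 0] <- min(pos) / 2
    else col[col <= 0] <- 1e-12
    col
  })
  if (is.null(dim(v))) v <- matrix(v, nrow = nrow(raw), dimnames = dimnames(raw))
  z <- sweep(sweep(log(v), 2, log_mean), 2, log_sd, "/")
  rownames(z) <- rownames(raw)
  z
}

stratified_folds <- function(y, k, fold_seed) {
  with_local_seed(fold_seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Jaccard similarity between two rule sets
#'
#' Detectors of the two rule sets are optimally matched (maximum-weight
#' bipartite assignment, exact for up to 15 detectors on the smaller side)
#' with the Jaccard similarity of their member-feature sets as edge weight.
#' The score is the summed similarity of matched pairs divided by the
#' larger detector count, so unmatched detectors contribute zero.
#'
#' @param a,b `mm_ruleset` objects (see [extract_rules()]).
#' @return similarity in \[0, 1\]; two empty rule sets score 1.
#' @export
ruleset_similarity <- function(a, b) {
  da <- all_detectors(a); db <- all_detectors(b)
  if (length(da) == 0 && length(db) == 0) return(1)
  if (length(da) == 0 || length(db) == 0) return(0)
  if (length(da) > length(db)) { tmp <- da; da <- db; db <- tmp }
  m <- length(da); M <- length(db)
  Jm <- matrix(0, m, M)
  for (i in seq_len(m)) {
    for (j in seq_len(M)) {
      Jm[i, j] <- jaccard(da[[i]], db[[j]])
    }
  }
  best <- assignment_max(Jm)
  best / M
}

all_detectors <- function(rs) {
  unlist(lapply(rs$rules, function(r) {
    lapply(r$detectors, function(d) d$member_ids)
  }), recursive = FALSE)
}

jaccard <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0) return(1)
  length(intersect(x, y)) / u
}

# maximum-weight assignment of rows (m) to distinct columns (M >= m);
# exact bitmask DP for m <= 15, greedy beyond
assignment_max <- function(W) {
  m <- nrow(W); M <- ncol(W)
  if (m > 15) {
    warning("large detector sets; using greedy matching")
    total <- 0
    used <- logical(M)
    for (o in order(-W)) {
      i <- (o - 1) %% m + 1; j <- (o - 1) %/% m + 1
      if (!is.na(W[i, j]) && !used[j]) {
        total <- total + W[i, j]
        used[j] <- TRUE
        W[i, ] <- NA
      }
    }
    return(total)
  }
  nmask <- bitwShiftL(1L, m)
  dp <- rep(-Inf, nmask)
  dp[1] <- 0
  for (j in seq_len(M)) {
    dp_new <- dp
    for (i in seq_len(m)) {
      bit <- bitwShiftL(1L, i - 1L)
      has <- which(bitwAnd(seq_len(nmask) - 1L, bit) > 0L)
      cand <- dp[has - bit] + W[i, j]
      dp_new[has] <- pmax(dp_new[has], cand)
    }
    dp <- dp_new
  }
  max(dp)
}
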