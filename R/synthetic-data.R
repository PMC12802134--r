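#' Semi-synthetic benchmark configuration
#'
#' Parameters of the five perturbation scenarios. The metabolite effect
#' means are the class-conditional means of a detector's standardized
#' log-level aggregate estimated from real rule fits (-0.203 for controls,
#' 0.724 for cases); taxa clade log-masses use -6 (controls) and -3
#' (cases). All biological draws share sd 1.5; the measurement-noise
#' variance 0.024 on the standardized log scale comes from technical
#' replicates. `theta` is the truncated-normal jitter coefficient, and
#' `dmd_alpha` the Dirichlet-multinomial concentration for count
#' overdispersion.
#'
#' @param scenario integer 1-5: (1) one metabolite group, (2) two
#'   metabolite groups with control subgrouping, (3) one taxa clade,
#'   (4) two taxa clades, (5) one clade plus one metabolite group.
#' @param n_subjects even number of synthetic subjects.
#' @param seed RNG seed; every draw is deterministic given it.
#' @param mu0_M,mu1_M,sigma0_M,sigma1_M metabolite effect distribution.
#' @param mu0_T,mu1_T,sigma_T taxa clade log-mass distribution.
#' @param sigma_meas2 measurement-noise variance (standardized log scale).
#' @param theta truncated-normal jitter fraction.
#' @param dmd_alpha Dirichlet-multinomial concentration.
#' @param max_metab_frac maximum perturbed-group fraction of metabolites.
#' @param clade_min,clade_max perturbed-clade size bounds.
#' @return list of class `mm_scenario_config`.
#' @export
scenario_config <- function(scenario = 1, n_subjects = 64, seed = 1L,
                            mu0_M = -0.203, mu1_M = 0.724,
                            sigma0_M = 1.5, sigma1_M = 1.5,
                            mu0_T = -6, mu1_T = -3, sigma_T = 1.5,
                            sigma_meas2 = 0.024, theta = 0.3,
                            dmd_alpha = 286, max_metab_frac = 0.15,
                            clade_min = 5, clade_max = 30) {
  stopifnot(scenario %in% 1:5, n_subjects %% 2 == 0, n_subjects >= 4,
            sigma0_M > 0, sigma1_M > 0, sigma_T > 0, sigma_meas2 > 0,
            clade_min <= clade_max)
  structure(as.list(environment()), class = "mm_scenario_config")
}

#' Fabricate a synthetic baseline cohort
#'
#' Stands in for a real control cohort when none is supplied: a random
#' coalescent tree with branch lengths; taxa counts from a log-normal
#' composition pushed through a multinomial at per-subject sequencing
#' depths; metabolite levels log-normal with a low-rank latent-factor
#' correlation and a small fraction of non-detects (zeros); and metabolite
#' embedding coordinates generated directly as clustered points (bypassing
#' fingerprints), with the cluster labels serving as chemical sub-classes
#' for radius-prior calibration.
#'
#' @param n_subjects cohort size (default 67).
#' @param n_taxa,n_metab feature counts.
#' @param seed RNG seed.
#' @param depth_range sequencing-depth range, sampled per subject.
#' @param n_subclasses metabolite sub-class count.
#' @param embed_dim metabolite embedding dimensionality.
#' @return list of class `mm_baseline`: `taxa` (raw counts
#'   `feature_table`), `metab` (raw levels), `tree` (phylo), `metab_emb`
#'   (embedding), `subclasses` (named vector), `metab_std`
#'   (log-standardized `feature_table` of the cohort), `depths`.
#' @export
fabricate_baseline <- function(n_subjects = 67, n_taxa = 120, n_metab = 120,
                               seed = 1L, depth_range = c(8000, 20000),
                               n_subclasses = 12, embed_dim = 5) {
  stopifnot(n_taxa >= 30, n_metab >= 10, n_subjects >= 4)
  with_local_seed(seed, {
    sids <- sprintf("subj%03d", seq_len(n_subjects))
    taxa_ids <- sprintf("taxon%03d", seq_len(n_taxa))
    metab_ids <- sprintf("metab%03d", seq_len(n_metab))
    tree <- ape::rcoal(n_taxa, tip.label = taxa_ids)
    # taxa: log-normal composition x multinomial
    base_log <- stats::rnorm(n_taxa, 0, 1.5)
    depths <- sample(depth_range[1]:depth_range[2], n_subjects,
                     replace = TRUE)
    counts <- t(vapply(seq_len(n_subjects), function(s) {
      lw <- base_log + stats::rnorm(n_taxa, 0, 0.7)
      w <- exp(lw) / sum(exp(lw))
      as.integer(stats::rmultinom(1, depths[s], w))
    }, integer(n_taxa)))
    dimnames(counts) <- list(sids, taxa_ids)
    # metabolites: log-normal with low-rank correlation
    mu_m <- stats::rnorm(n_metab, 7, 1.5)
    loadings <- matrix(stats::rnorm(n_metab * 3, 0, 0.6), n_metab, 3)
    factors <- matrix(stats::rnorm(n_subjects * 3), n_subjects, 3)
    log_levels <- sweep(factors %*% t(loadings), 2, mu_m, "+") +
      matrix(stats::rnorm(n_subjects * n_metab, 0, 0.8), n_subjects)
    levels <- exp(log_levels)
    # non-detects: zero the lowest 3% of each metabolite's values
    for (j in seq_len(n_metab)) {
      thr <- stats::quantile(levels[, j], 0.03)
      levels[levels[, j] <= thr, j] <- 0
    }
    dimnames(levels) <- list(sids, metab_ids)
    # metabolite embedding: clustered coordinates + sub-class labels
    centers <- matrix(stats::rnorm(n_subclasses * embed_dim, 0, 2),
                      n_subclasses, embed_dim)
    cls <- sample(rep_len(seq_len(n_subclasses), n_metab))
    coords <- centers[cls, ] +
      matrix(stats::rnorm(n_metab * embed_dim, 0, 0.5), n_metab)
    rownames(coords) <- metab_ids
    emb <- structure(list(coords = coords,
                          eigenvalues = sort(apply(coords, 2, stats::var) *
                                               (n_metab - 1),
                                             decreasing = TRUE),
                          labels = metab_ids),
                     class = "pcoa_embedding")
    taxa_ft <- feature_table(counts, "taxa", "raw")
    metab_ft <- feature_table(levels, "metabolite", "raw")
    list(taxa = taxa_ft, metab = metab_ft, tree = tree, metab_emb = emb,
         subclasses = stats::setNames(sprintf("class%02d", cls), metab_ids),
         metab_std = transform_metabolites(metab_ft),
         depths = stats::setNames(depths, sids))
  })
}

#' Nested subject sampling
#'
#' Samples `n` baseline subjects uniformly (with replacement only when `n`
#' exceeds the baseline size) and splits them evenly into cases and
#' controls. Draws are nested: under one seed, the subjects for a smaller
#' `n` are a prefix-subsample of those for any larger `n`, so power
#' comparisons across sample sizes reuse subjects.
#'
#' @param baseline_n baseline cohort size.
#' @param n even number of subjects to draw.
#' @param seed RNG seed.
#' @return list with `idx` (baseline row indices, length `n`), `label`
#'   (1 = case for the first half, 0 = control).
#' @export
sample_subjects <- function(baseline_n, n, seed = 1L) {
  if (n %% 2 != 0) stop("n must be even")
  master_len <- max(1000, n)
  master <- with_local_seed(seed, sample.int(baseline_n, master_len,
                                             replace = TRUE))
  idx <- if (n > baseline_n) master[seq_len(n)] else {
    distinct <- unique(master)
    if (length(distinct) < n) stop("baseline too small for distinct draw")
    distinct[seq_len(n)]
  }
  list(idx = idx, label = rep(c(1L, 0L), each = n / 2))
}

#' Sample a metabolite perturbation group
#'
#' Picks a seed metabolite uniformly at random, draws a radius from the
#' calibrated Log-Normal prior, and takes every metabolite within that
#' embedding distance. Groups larger than `max_frac` of the metabolites are
#' rejected and redrawn (at most 1000 tries).
#'
#' @param emb metabolite embedding.
#' @param prior [calibrate_radius_prior()] result.
#' @param max_frac maximum group fraction (default 0.15).
#' @param seed RNG seed.
#' @param exclude optional ids the group must not overlap (used to draw a
#'   second disjoint group).
#' @return character vector of member ids (always contains the seed
#'   metabolite).
#' @export
sample_metabolite_group <- function(emb, prior, max_frac = 0.15, seed = 1L,
                                    exclude = character()) {
  n <- nrow(emb$coords)
  cap <- floor(max_frac * n)
  with_local_seed(seed, {
    for (try in seq_len(1000)) {
      p <- sample.int(n, 1)
      if (emb$labels[p] %in% exclude) next
      kappa <- stats::rlnorm(1, prior$log_location, sqrt(prior$log_scale2))
      d <- sqrt(colSums((t(emb$coords) - emb$coords[p, ])^2))
      H <- emb$labels[d <= kappa]
      if (length(H) >= 1 && length(H) <= cap &&
          length(intersect(H, exclude)) == 0) {
        return(H)
      }
    }
    stop("1000 rejections exceeded while sampling a metabolite group; ",
         "check the radius prior calibration")
  })
}

#' Sample a taxonomic clade to perturb
#'
#' Uniform draw over the tree's internal nodes whose leaf-descendant count
#' lies within the size bounds.
#'
#' @param tree a phylo object.
#' @param seed RNG seed.
#' @param clade_min,clade_max inclusive leaf-count bounds (defaults 5, 30).
#' @param exclude leaf ids the clade must not overlap.
#' @return character vector of leaf labels.
#' @export
sample_taxa_clade <- function(tree, seed = 1L, clade_min = 5,
                              clade_max = 30, exclude = character()) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  leaf_sets <- lapply(internal, function(nd) {
    tree$tip.label[clade_leaves(tree, nd)]
  })
  sizes <- lengths(leaf_sets)
  eligible <- which(sizes >= clade_min & sizes <= clade_max &
                      !vapply(leaf_sets, function(s)
                        any(s %in% exclude), logical(1)))
  if (length(eligible) == 0) stop("no clade with ", clade_min, "-",
                                  clade_max, " leaves")
  pick <- with_local_seed(seed, eligible[sample.int(length(eligible), 1)])
  leaf_sets[[pick]]
}

# tip indices descending from an internal node (iterative DFS on the edge
# table; avoids a phangorn dependency for one primitive)
clade_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- node
  tips <- integer(0)
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(nd)]]
    if (is.null(kids)) tips <- c(tips, nd)
    else stack <- c(stack, kids)
  }
  sort(tips[tips <= ntip])
}

#' Perturb metabolite levels for sampled subjects
#'
#' Hierarchical draw on the standardized log scale: metabolites in the
#' perturbed set get class-conditional Normal draws (cases mu1; in
#' subgrouped scenarios the designated control subgroup gets a doubled mean
#' 2*mu1 and the other subgroup mu0); all other metabolites keep the
#' subject's original standardized value. Every entry then receives
#' Normal(0, sigma_meas2) measurement noise and is mapped back to the raw
#' scale with the baseline's per-metabolite log mean and sd.
#'
#' @param z subjects x metabolites standardized log matrix (sampled rows).
#' @param H member ids of the perturbed group.
#' @param subject_class character vector per subject: `"case"`,
#'   `"control"`, `"control1"`, `"control2"`.
#' @param cfg [scenario_config()].
#' @param log_mean,log_sd baseline standardization statistics.
#' @param class_means named numeric vector mapping each subject class to
#'   its biological-draw mean; classes mapped to `NA` (or absent) keep
#'   their baseline values. Defaults to case = `mu1_M`, every control
#'   class = `mu0_M`.
#' @return list: `levels` (raw-scale matrix), `p` (biological-layer draws),
#'   `eps` (measurement noise).
#' @export
perturb_metabolites <- function(z, H, subject_class, cfg, log_mean, log_sd,
                                class_means = NULL) {
  if (is.null(log_mean) || is.null(log_sd)) {
    stop("baseline standardization statistics (log_mean/log_sd) missing")
  }
  if (is.null(class_means)) {
    class_means <- c(case = cfg$mu1_M, control = cfg$mu0_M,
                     control1 = cfg$mu0_M, control2 = cfg$mu0_M)
  }
  S <- nrow(z)
  p <- z
  cols <- match(H, colnames(z))
  if (anyNA(cols)) stop("perturbed metabolite absent from table")
  if (length(cols) > 0) {
    for (s in seq_len(S)) {
      cl <- subject_class[s]
      mu <- if (cl %in% names(class_means)) class_means[[cl]] else NA_real_
      if (is.na(mu)) next
      sdv <- if (cl == "case") cfg$sigma1_M else cfg$sigma0_M
      p[s, cols] <- stats::rnorm(length(cols), mu, sdv)
    }
  }
  eps <- matrix(stats::rnorm(length(p), 0, sqrt(cfg$sigma_meas2)),
                nrow = S, dimnames = dimnames(p))
  yprime <- p + eps
  levels <- untransform_metabolites(yprime, log_mean[colnames(z)],
                                    log_sd[colnames(z)])
  list(levels = levels, p = p, eps = eps)
}

#' Perturb taxa counts for sampled subjects
#'
#' Draws a clade log-mass per subject (cases mu1_T; a designated control
#' subgroup may get 2*mu1_T), allocates the clade mass proportionally to
#' the subject's baseline within-clade composition (equally if the clade is
#' absent), renormalizes the composition, jitters each taxon with a
#' truncated Normal (sd = theta * mean, truncated to \[0, 1\]), and draws
#' counts from a Dirichlet-multinomial at the subject's original depth.
#'
#' @param w subjects x taxa relative-abundance matrix (sampled rows).
#' @param C leaf ids of the perturbed clade (may be empty: pure
#'   count-noise bootstrap).
#' @param subject_class per-subject class as in [perturb_metabolites()].
#' @param cfg [scenario_config()].
#' @param depths per-subject total counts.
#' @param class_means named numeric vector mapping each subject class to
#'   its clade log-mass mean; classes mapped to `NA` (or absent) keep
#'   their baseline composition. Defaults to case = `mu1_T`, every
#'   control class = `mu0_T`.
#' @return list: `counts` (integer matrix), `log_mass` (per-subject clade
#'   log-mass draws, NA for subjects without a perturbation).
#' @export
perturb_taxa <- function(w, C, subject_class, cfg, depths,
                         class_means = NULL) {
  if (is.null(class_means)) {
    class_means <- c(case = cfg$mu1_T, control = cfg$mu0_T,
                     control1 = cfg$mu0_T, control2 = cfg$mu0_T)
  }
  S <- nrow(w); N <- ncol(w)
  cols <- match(C, colnames(w))
  if (anyNA(cols)) stop("clade member absent from table")
  gamma <- w
  log_mass <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    cl <- subject_class[s]
    mu <- if (cl %in% names(class_means)) class_means[[cl]] else NA_real_
    if (length(cols) > 0 && !is.na(mu)) {
      lm <- stats::rnorm(1, mu, cfg$sigma_T)
      log_mass[s] <- lm
      mass <- exp(lm)
      wsum <- sum(w[s, cols])
      gamma[s, cols] <- if (wsum > 0) mass * w[s, cols] / wsum
      else mass / length(cols)
    }
    gamma[s, ] <- gamma[s, ] / sum(gamma[s, ])
  }
  phi <- rtrunc_norm01(gamma, cfg$theta)
  counts <- matrix(0L, S, N, dimnames = dimnames(w))
  for (s in seq_len(S)) {
    shape <- cfg$dmd_alpha * phi[s, ]
    gam <- stats::rgamma(N, shape = shape, rate = 1)
    if (sum(gam) <= 0) gam <- phi[s, ]
    counts[s, ] <- as.integer(stats::rmultinom(1, depths[s], gam / sum(gam)))
  }
  list(counts = counts, log_mass = log_mass)
}

# elementwise truncated Normal(mean, (theta*mean)^2) on [0,1] by inverse
# CDF; zero means stay exactly zero
rtrunc_norm01 <- function(mean_mat, theta) {
  out <- mean_mat
  pos <- which(mean_mat > 0)
  if (length(pos) == 0) return(out)
  mu <- mean_mat[pos]
  sdv <- theta * mu
  a <- stats::pnorm(-1 / theta)                 # (0 - mu) / (theta mu)
  b <- stats::pnorm((1 - mu) / sdv)
  u <- stats::runif(length(pos), a, b)
  out[pos] <- mu + sdv * stats::qnorm(u)
  pmin(pmax(out, 0), 1)
}

#' Generate one semi-synthetic dataset
#'
#' Composes subject sampling, group/clade sampling, and the two
#' perturbation kernels according to the scenario. Controls are split
#' evenly into two subgroups for scenarios 2, 4, and 5. The ground truth
#' (perturbed sets, subgroup assignment, and the biological-layer draws) is
#' recorded alongside the data.
#'
#' @param baseline an [fabricate_baseline()] cohort (or any list with the
#'   same fields built from real data).
#' @param cfg a [scenario_config()].
#' @param radius_prior optional precomputed radius prior; calibrated from
#'   the baseline's sub-classes when omitted.
#' @return list of class `mm_synthetic`: `taxa` (raw counts), `metab` (raw
#'   levels), `labels`, `truth`.
#' @export
generate_scenario <- function(baseline, cfg, radius_prior = NULL) {
  if (is.null(radius_prior)) {
    radius_prior <- calibrate_radius_prior(baseline$metab_emb,
                                           baseline$subclasses)
  }
  seed <- cfg$seed
  n <- cfg$n_subjects
  draw <- sample_subjects(nrow(baseline$taxa$values), n, seed)
  sids <- sprintf("sim%04d", seq_len(n))
  label <- draw$label
  subject_class <- ifelse(label == 1, "case", "control")
  if (cfg$scenario %in% c(2, 4, 5)) {
    ctrl <- which(label == 0)
    subject_class[ctrl] <- rep(c("control1", "control2"),
                               length.out = length(ctrl))
  }
  w_all <- to_relative_abundance(baseline$taxa)$values
  w <- w_all[draw$idx, , drop = FALSE]
  z <- baseline$metab_std$values[draw$idx, , drop = FALSE]
  depths <- rowSums(baseline$taxa$values)[draw$idx]
  rownames(w) <- rownames(z) <- sids
  lm_stats <- list(mean = baseline$metab_std$log_mean,
                   sd = baseline$metab_std$log_sd)
  truth <- list(metab_groups = list(), taxa_clades = list(),
                assignment = tibble::tibble(subject_id = sids,
                                            class = subject_class,
                                            label = label))
  with_local_seed(seed + 500009L, {
    # metabolite side: per-scenario class -> biological-draw mean maps;
    # NA means "keep baseline values" (scenario 5's taxa-only subgroup)
    metab_means <- switch(as.character(cfg$scenario),
      "1" = , "3" = , "4" = NULL,  # defaults (1) or no group (3, 4)
      "2" = list(c(case = cfg$mu1_M, control1 = 2 * cfg$mu1_M,
                   control2 = cfg$mu0_M),
                 c(case = cfg$mu1_M, control1 = cfg$mu0_M,
                   control2 = 2 * cfg$mu1_M)),
      "5" = list(c(case = cfg$mu1_M, control1 = NA_real_,
                   control2 = 2 * cfg$mu1_M)))
    if (cfg$scenario %in% c(1, 2, 5)) {
      H1 <- sample_metabolite_group(baseline$metab_emb, radius_prior,
                                    cfg$max_metab_frac, seed + 1L)
      truth$metab_groups <- list(H1)
      pm <- perturb_metabolites(z, H1, subject_class, cfg,
                                lm_stats$mean, lm_stats$sd,
                                class_means = if (is.list(metab_means))
                                  metab_means[[1]] else NULL)
      if (cfg$scenario == 2) {
        H2 <- sample_metabolite_group(baseline$metab_emb, radius_prior,
                                      cfg$max_metab_frac, seed + 2L,
                                      exclude = H1)
        truth$metab_groups <- list(H1, H2)
        # chain on the first pass's biological layer; the final noise and
        # un-transform come from this second pass
        pm <- perturb_metabolites(pm$p, H2, subject_class, cfg,
                                  lm_stats$mean, lm_stats$sd,
                                  class_means = metab_means[[2]])
      }
      metab_out <- pm$levels
      truth$metab_p <- pm$p
    } else {
      pm <- perturb_metabolites(z, character(0), subject_class, cfg,
                                lm_stats$mean, lm_stats$sd)
      metab_out <- pm$levels
      truth$metab_p <- pm$p
    }
    # taxa side
    taxa_means <- switch(as.character(cfg$scenario),
      "3" = NULL,  # defaults: case mu1_T, controls mu0_T
      "4" = list(c(case = cfg$mu1_T, control1 = 2 * cfg$mu1_T,
                   control2 = cfg$mu0_T),
                 c(case = cfg$mu1_T, control1 = cfg$mu0_T,
                   control2 = 2 * cfg$mu1_T)),
      "5" = list(c(case = cfg$mu1_T, control1 = 2 * cfg$mu1_T,
                   control2 = NA_real_)),
      NULL)
    if (cfg$scenario %in% c(3, 4, 5)) {
      C1 <- sample_taxa_clade(baseline$tree, seed + 3L, cfg$clade_min,
                              cfg$clade_max)
      truth$taxa_clades <- list(C1)
      pt <- perturb_taxa(w, C1, subject_class, cfg, depths,
                         class_means = if (is.list(taxa_means))
                           taxa_means[[1]] else NULL)
      if (cfg$scenario == 4) {
        C2 <- sample_taxa_clade(baseline$tree, seed + 4L, cfg$clade_min,
                                cfg$clade_max, exclude = C1)
        truth$taxa_clades <- list(C1, C2)
        w2 <- pt$counts / rowSums(pt$counts)
        pt2 <- perturb_taxa(w2, C2, subject_class, cfg, depths,
                            class_means = taxa_means[[2]])
        pt <- list(counts = pt2$counts,
                   log_mass = cbind(clade1 = pt$log_mass,
                                    clade2 = pt2$log_mass))
      }
      taxa_out <- pt$counts
      truth$taxa_log_mass <- pt$log_mass
    } else {
      pt <- perturb_taxa(w, character(0), subject_class, cfg, depths)
      taxa_out <- pt$counts
    }
    labels <- tibble::tibble(subject_id = sids, label = label)
    structure(list(
      taxa = feature_table(taxa_out, "taxa", "raw"),
      metab = feature_table(metab_out, "metabolite", "raw"),
      labels = labels, truth = truth, cfg = cfg,
      baseline_idx = draw$idx
    ), class = "mm_synthetic")
  })
}

#' @export
print.mm_synthetic <- function(x, ...) {
  cat(sprintf("<mm_synthetic> scenario %d: %d subjects, %d taxa, %d metabolites\n",
              x$cfg$scenario, nrow(x$taxa$values), ncol(x$taxa$values),
              ncol(x$metab$values)))
  invisible(x)
}

#' Class-mean fold-change of a detector output
#'
#' Ratio of the control-class mean to the case-class mean of a per-subject
#' detector output; the statistic used to transport effect sizes from real
#' rule fits into the simulator.
#'
#' @param g per-subject detector outputs.
#' @param labels 0/1 labels (0 = control).
#' @return the fold change.
#' @export
fold_change_stat <- function(g, labels) {
  stopifnot(length(g) == length(labels))
  if (!any(labels == 0) || !any(labels == 1)) stop("both classes required")
  denom <- mean(g[labels == 1])
  if (denom == 0) stop("zero case-class mean")
  mean(g[labels == 0]) / denom
}

#' Write a synthetic dataset to plain-text files
#'
#' @param ds an `mm_synthetic`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Writes taxa counts, metabolite levels,
#'   labels, truth (JSON), and the baseline tree is the caller's to save.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(ds$taxa, file.path(dir, "taxa_counts.csv"))
  write_feature_table(ds$metab, file.path(dir, "metabolite_levels.csv"))
  readr::write_csv(ds$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(
    list(metab_groups = ds$truth$metab_groups,
         taxa_clades = ds$truth$taxa_clades,
         assignment = ds$truth$assignment),
    file.path(dir, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}
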