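test_that("the fabricated cohort is deterministic and well-formed", {
  b1 <- fabricate_baseline(n_subjects = 20, n_taxa = 40, n_metab = 30,
                           seed = 3)
  b2 <- fabricate_baseline(n_subjects = 20, n_taxa = 40, n_metab = 30,
                           seed = 3)
  expect_identical(b1$taxa$values, b2$taxa$values)
  expect_identical(b1$metab$values, b2$metab$values)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  # rows sum to the recorded sequencing depths
  expect_equal(unname(rowSums(b1$taxa$values)), unname(b1$depths))
  expect_true(all(b1$metab$values >= 0))
  expect_true(all(is.finite(b1$metab_emb$coords)))
  # the induced metabolite distances satisfy the container invariants
  D <- as.matrix(dist(b1$metab_emb$coords))
  expect_s3_class(dist_matrix(D), "dist_matrix")
  expect_equal(sort(unique(unname(b1$subclasses))),
               sort(unique(unname(b1$subclasses))))
})

test_that("subject draws are nested across sample sizes", {
  expect_error(sample_subjects(67, 7), "even")
  d36 <- sample_subjects(67, 36, seed = 5)
  d48 <- sample_subjects(67, 48, seed = 5)
  d200 <- sample_subjects(67, 200, seed = 5)
  expect_true(all(d36$idx %in% d48$idx))
  expect_true(all(d48$idx %in% d200$idx))
  expect_equal(sum(d36$label), 18)
  # n <= baseline: distinct subjects; n > baseline: resampling allowed
  expect_false(anyDuplicated(d48$idx) > 0)
  expect_true(anyDuplicated(d200$idx) > 0)
  expect_false(identical(sample_subjects(67, 36, seed = 6)$idx, d36$idx))
})

test_that("metabolite perturbation groups respect prior and size cap", {
  baseline <- get_baseline()
  prior <- calibrate_radius_prior(baseline$metab_emb, baseline$subclasses)
  n_metab <- length(baseline$metab_emb$labels)
  cap <- floor(0.15 * n_metab)
  sizes <- vapply(1:200, function(s) {
    length(sample_metabolite_group(baseline$metab_emb, prior, seed = s))
  }, numeric(1))
  expect_true(all(sizes >= 1 & sizes <= cap))
  # a vanishing radius prior gives singleton groups
  tiny <- test_lognormal_prior(loc = -20, s2 = 1e-4)
  expect_length(sample_metabolite_group(baseline$metab_emb, tiny, seed = 2),
                1)
})

test_that("sampled clades stay inside the size bounds and cover eligible nodes", {
  baseline <- get_baseline()
  sizes <- vapply(1:300, function(s) {
    length(sample_taxa_clade(baseline$tree, seed = s))
  }, numeric(1))
  expect_true(all(sizes >= 5 & sizes <= 30))
  # a caterpillar tree with one eligible clade always returns it
  txt <- "(((((((t1:1,t2:1):1,t3:1):1,t4:1):1,t5:1):1,t6:1):1,t7:1):1,t8:1);"
  cat_tree <- ape::read.tree(text = txt)
  for (s in 1:5) {
    C <- sample_taxa_clade(cat_tree, seed = s, clade_min = 5, clade_max = 5)
    expect_setequal(C, c("t1", "t2", "t3", "t4", "t5"))
  }
  expect_error(sample_taxa_clade(cat_tree, clade_min = 2, clade_max = 2,
                                 exclude = cat_tree$tip.label), "no clade")
})

test_that("clade draws are uniform over eligible nodes", {
  withr::with_seed(77, {
    tree <- ape::rcoal(40)
    draws <- vapply(1:2000, function(s) {
      paste(sort(sample_taxa_clade(tree, seed = s)), collapse = "|")
    }, character(1))
    tab <- table(draws)
    expect_gt(length(tab), 1)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 1e-4)
  })
})

test_that("perturbed metabolites collapse to the exact degenerate limit", {
  baseline <- get_baseline()
  z <- baseline$metab_std$values[1:6, , drop = FALSE]
  H <- colnames(z)[1:3]
  cfg <- scenario_config(1, 6, seed = 1, sigma0_M = 1e-12, sigma1_M = 1e-12,
                         sigma_meas2 = 1e-24)
  cls <- c("case", "case", "case", "control", "control", "control")
  out <- withr::with_seed(1, perturb_metabolites(
    z, H, cls, cfg, baseline$metab_std$log_mean, baseline$metab_std$log_sd))
  expected_case <- exp(0.724 * baseline$metab_std$log_sd[H] +
                         baseline$metab_std$log_mean[H])
  expect_equal(out$levels[1, H], expected_case, tolerance = 1e-6)
  expected_ctrl <- exp(-0.203 * baseline$metab_std$log_sd[H] +
                         baseline$metab_std$log_mean[H])
  expect_equal(out$levels[4, H], expected_ctrl, tolerance = 1e-6)
})

test_that("unperturbed metabolites keep their values plus measurement noise", {
  baseline <- get_baseline()
  z <- baseline$metab_std$values[1:40, , drop = FALSE]
  H <- colnames(z)[1]
  cfg <- scenario_config(1, 40, seed = 1)
  cls <- rep(c("case", "control"), each = 20)
  out <- withr::with_seed(2, perturb_metabolites(
    z, H, cls, cfg, baseline$metab_std$log_mean, baseline$metab_std$log_sd))
  others <- setdiff(colnames(z), H)
  expect_equal(out$p[, others], z[, others])
  diffs <- log(out$levels[, others]) -
    (sweep(sweep(z[, others], 2, baseline$metab_std$log_sd[others], "*"),
           2, baseline$metab_std$log_mean[others], "+"))
  sd_hat <- sd(as.numeric(diffs) / rep(baseline$metab_std$log_sd[others],
                                       each = 40))
  expect_equal(sd_hat, sqrt(0.024), tolerance = 0.05)
})

test_that("taxa perturbation conserves depths and its log-mass calibration", {
  baseline <- get_baseline()
  w <- to_relative_abundance(baseline$taxa)$values[1:10, , drop = FALSE]
  depths <- rowSums(baseline$taxa$values)[1:10]
  C <- sample_taxa_clade(baseline$tree, seed = 3)
  cfg <- scenario_config(3, 10, seed = 1)
  cls <- rep(c("case", "control"), each = 5)
  out <- withr::with_seed(3, perturb_taxa(w, C, cls, cfg, depths))
  expect_equal(unname(rowSums(out$counts)), unname(depths))
  expect_true(all(out$counts >= 0))
  expect_true(all(is.finite(out$log_mass)))
  # empty clade: a pure count-noise bootstrap with no mass draw
  out0 <- withr::with_seed(4, perturb_taxa(w, character(0), cls, cfg, depths))
  expect_true(all(is.na(out0$log_mass)))
  expect_equal(unname(rowSums(out0$counts)), unname(depths))
})

test_that("each scenario records the ground truth it injected", {
  baseline <- get_baseline()
  for (sc in 1:5) {
    ds <- generate_scenario(baseline, scenario_config(sc, 20, seed = 30 + sc))
    expect_s3_class(ds$taxa, "feature_table")
    expect_true(all(ds$metab$values > 0))
    expect_equal(sum(ds$labels$label), 10)
    n_groups <- length(ds$truth$metab_groups)
    n_clades <- length(ds$truth$taxa_clades)
    expect_equal(n_groups, c(1, 2, 0, 0, 1)[sc])
    expect_equal(n_clades, c(0, 0, 1, 2, 1)[sc])
    if (sc == 2) {
      expect_length(intersect(ds$truth$metab_groups[[1]],
                              ds$truth$metab_groups[[2]]), 0)
    }
    if (sc %in% c(2, 4, 5)) {
      cls <- ds$truth$assignment$class
      expect_setequal(unique(cls[ds$labels$label == 0]),
                      c("control1", "control2"))
      expect_true(all(cls[ds$labels$label == 1] == "case"))
    }
    # reproducibility
    ds2 <- generate_scenario(baseline,
                             scenario_config(sc, 20, seed = 30 + sc))
    expect_identical(ds$taxa$values, ds2$taxa$values)
    expect_identical(ds$metab$values, ds2$metab$values)
  }
})

test_that("the benchmark grid covers the published sample sizes", {
  baseline <- get_baseline()
  for (n in c(36, 48, 64, 128, 300, 1000)) {
    ds <- generate_scenario(baseline, scenario_config(1, n, seed = 90))
    expect_equal(nrow(ds$taxa$values), n)
    expect_equal(nrow(ds$metab$values), n)
    expect_equal(sum(ds$labels$label), n / 2)
  }
})

test_that("fold-change statistic matches its two-mean oracle", {
  expect_equal(fold_change_stat(c(2, 2, 2, 2), c(0, 0, 1, 1)), 1)
  expect_equal(fold_change_stat(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  withr::with_seed(83, {
    g <- rnorm(30, 5)
    y <- rep(c(0, 1), 15)
    expect_equal(fold_change_stat(g, y),
                 mean(g[y == 0]) / mean(g[y == 1]))
  })
  expect_error(fold_change_stat(c(1, 2), c(1, 1)), "both classes")
})

test_that("synthetic datasets serialize to plain-text artifacts", {
  baseline <- get_baseline()
  ds <- generate_scenario(baseline, scenario_config(1, 12, seed = 55))
  dir <- withr::local_tempdir()
  write_synthetic(ds, dir)
  expect_true(file.exists(file.path(dir, "taxa_counts.csv")))
  expect_true(file.exists(file.path(dir, "metabolite_levels.csv")))
  labs <- readr::read_csv(file.path(dir, "labels.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(labs), 12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$metab_groups, 1)
})
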