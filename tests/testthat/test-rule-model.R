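test_that("soft inclusion follows its sigmoid form", {
  coords <- matrix(c(0, 0, 3, 0), 2, 2, byrow = TRUE)
  # feature exactly on the radius -> 0.5
  expect_equal(soft_inclusion(c(0, 0), 3, coords, 0.1)[2], 0.5)
  # radius - distance = tau -> sigmoid(1)
  expect_equal(soft_inclusion(c(0, 0), 3.1, coords, 0.1)[2],
               1 / (1 + exp(-1)))
  # near-zero temperature -> hard membership
  u <- soft_inclusion(c(0, 0), 2, coords, 1e-6)
  expect_equal(u, c(1, 0), tolerance = 1e-12)
  expect_error(soft_inclusion(c(0, 0), 1, coords, 0), "positive")
})

test_that("aggregates match selection identities and loop oracles", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40), 8, 5)
    onehot <- c(0, 0, 1, 0, 0)
    expect_equal(aggregate_metabolites(onehot, X), X[, 3], tolerance = 1e-9)
    expect_equal(aggregate_metabolites(rep(1, 5), X), rowMeans(X),
                 tolerance = 1e-9)
    u <- runif(5)
    oracle <- numeric(8)
    for (s in 1:8) {
      num <- 0
      for (i in 1:5) num <- num + u[i] * X[s, i]
      oracle[s] <- num / sum(u)
    }
    expect_equal(aggregate_metabolites(u, X), oracle, tolerance = 1e-10)
    W <- matrix(rexp(40), 8, 5)
    W <- W / rowSums(W)
    expect_equal(aggregate_taxa(rep(1, 5), W), rowSums(W))
    expect_equal(aggregate_taxa(rep(0, 5), W), rep(0, 8))
    oracle_t <- numeric(8)
    for (s in 1:8) for (i in 1:5) {
      oracle_t[s] <- oracle_t[s] + W[s, i] * u[i]
    }
    expect_equal(aggregate_taxa(u, W), oracle_t, tolerance = 1e-12)
  })
})

test_that("detector activation is a calibrated threshold unit", {
  expect_equal(detector_activation(2, 2, 0.5), 0.5)
  expect_equal(detector_activation(2 + 2 * 0.3, 2, 0.3),
               1 / (1 + exp(-2)))
  a <- seq(-2, 2, length.out = 50)
  g <- detector_activation(a, 0.3, 0.7)
  expect_true(all(diff(g) > 0))
  expect_error(detector_activation(1, 0, -1), "positive")
})

test_that("soft-AND equals the boolean conjunction on all binary inputs", {
  grid <- as.matrix(expand.grid(rep(list(0:1), 10)))
  for (row in seq_len(nrow(grid))) {
    g <- grid[row, 1:5]
    z <- grid[row, 6:10]
    r <- rule_activation(g, z)
    selected <- which(z == 1)
    oracle <- if (length(selected) == 0) 1 else as.numeric(all(g[selected] == 1))
    expect_identical(r, oracle)
  }
  # empty selection is the empty conjunction
  expect_equal(rule_activation(c(0, 0), c(0, 0)), 1)
  expect_equal(rule_activation(c(1, 0), c(1, 1)), 0)
})

test_that("rule activation is monotone in selectors and activations", {
  withr::with_seed(6, {
    g <- runif(4, 0.1, 0.9)
    z <- runif(4)
    base <- rule_activation(g, z)
    for (j in 1:4) {
      z_up <- z; z_up[j] <- min(1, z[j] + 0.1)
      expect_lte(rule_activation(g, z_up), base + 1e-12)
      g_up <- g; g_up[j] <- min(1, g[j] + 0.05)
      expect_gte(rule_activation(g_up, z), base - 1e-12)
    }
  })
})

test_that("prediction layer renders odds in log-linear form", {
  expect_equal(predict_rules(rep(1, 3), rep(0, 3), rnorm(3), 0), 0.5)
  # a single active rule with weight ln(24) multiplies the odds by 24
  p <- predict_rules(1, 1, log(24), 0)
  expect_equal(p / (1 - p), 24, tolerance = 1e-9)
  withr::with_seed(7, {
    r <- matrix(runif(12), 4, 3)
    q <- runif(3); beta <- rnorm(3); b0 <- rnorm(1)
    p <- predict_rules(r, q, beta, b0)
    expect_equal(log(p / (1 - p)), as.numeric(r %*% (q * beta)) + b0,
                 tolerance = 1e-9)
    # permutation equivariance over subjects
    perm <- c(3, 1, 4, 2)
    expect_equal(predict_rules(r[perm, ], q, beta, b0), p[perm])
  })
})

test_that("relaxed selectors saturate as temperature falls", {
  expect_equal(selector_value(0, 0.3), 0.5)
  expect_equal(selector_value(0.2, 0.2), 1 / (1 + exp(-1)))
  expect_equal(selector_value(1, 0.1), 1 / (1 + exp(-10)))
  expect_error(selector_value(1, 0), "positive")
})

test_that("BinaryConcrete density matches an independent transcription", {
  # literal density: tau*alpha*x^(-tau-1)*(1-x)^(-tau-1) /
  #                  (alpha*x^-tau + (1-x)^-tau)^2
  literal <- function(x, alpha, tau) {
    log(tau * alpha * x^(-tau - 1) * (1 - x)^(-tau - 1) /
          (alpha * x^(-tau) + (1 - x)^(-tau))^2)
  }
  for (x in c(0.1, 0.25, 0.5, 0.8, 0.97)) {
    for (alpha in c(0.1, 1, 3)) {
      for (tau in c(0.5, 1, 2)) {
        expect_equal(dbinary_concrete(x, alpha, tau), literal(x, alpha, tau),
                     tolerance = 1e-10)
      }
    }
  }
  # normalization: integrates to ~1
  # Riemann normalization check (coarse: the density spikes at 0 and 1)
  xs <- seq(1e-5, 1 - 1e-5, length.out = 20001)
  dens <- exp(dbinary_concrete(xs, 0.1, 0.5))
  expect_equal(sum(dens) * diff(xs)[1], 1, tolerance = 0.05)
})

test_that("log prior responds to shrinkage and is flat in thresholds", {
  data <- random_model_data()
  hp <- mm_hyperparams(K = 3, J = 2, L = 2)
  pr <- test_lognormal_prior()
  params <- initialize_params(data, hp, seed = 2)
  temps <- anneal_temperatures(10, 100)
  lp1 <- log_prior(params, hp, pr, pr, temps, data$eta_M_bounds)
  hp_wide <- mm_hyperparams(K = 3, J = 2, L = 2, center_prior_var = 2e4)
  lp2 <- log_prior(params, hp_wide, pr, pr, temps, data$eta_M_bounds)
  # nonzero centers are less penalized under the wider prior, net of the
  # normalizing constant difference
  shrink1 <- lp1 + 0.5 * length(params$centers_M) * log(2 * pi * 1e4) +
    0.5 * length(params$centers_T) * log(2 * pi * 1e4)
  expect_true(is.finite(lp1) && is.finite(lp2))
  # uniform thresholds: moving eta inside its support leaves the prior fixed
  shifted <- params
  shifted$eta_M <- params$eta_M + 0.05
  expect_equal(log_prior(shifted, hp, pr, pr, temps, data$eta_M_bounds), lp1)
})

test_that("negative log posterior behaves at its likelihood limits", {
  data <- random_model_data(S = 8, NM = 5, NT = 6)
  hp <- mm_hyperparams(K = 2, J = 2, L = 2)
  pr <- test_lognormal_prior()
  params <- initialize_params(data, hp, seed = 3)
  temps <- list(tau_u = 0.5, tau_g_T = 0.3, tau_g_M = 0.8, tau_z = 0.7,
                tau_q = 0.6)
  # with rules silenced, moving beta0 toward the empirical log odds lowers
  # the loss (1-D line search oracle)
  params$rule_logits <- rep(-50, hp$K)
  emp <- qlogis(mean(data$y))
  candidates <- seq(-3, 3, length.out = 121)
  losses <- vapply(candidates, function(b0) {
    p2 <- params; p2$beta0 <- b0
    negative_log_posterior(p2, data, hp, pr, pr, temps)
  }, numeric(1))
  expect_lt(abs(candidates[which.min(losses)] - emp), 0.15)
})

test_that("analytic gradients match central finite differences", {
  data <- random_model_data(S = 10, NM = 6, NT = 7, seed = 12)
  hp <- mm_hyperparams(K = 3, J = 2, L = 2)
  prA <- test_lognormal_prior(0.2, 0.3)
  prB <- test_lognormal_prior(-0.1, 0.5)
  params <- initialize_params(data, hp, seed = 5)
  temps <- list(tau_u = 0.5, tau_g_T = 0.3, tau_g_M = 0.8, tau_z = 0.7,
                tau_q = 0.6)
  out <- negative_log_posterior(params, data, hp, prA, prB, temps,
                                grad = TRUE, bc_weight = 0.8)
  v0 <- flatten_params(params)
  g_an <- flatten_params(out$grads)
  h <- 1e-4
  g_fd <- vapply(seq_along(v0), function(i) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (negative_log_posterior(unflatten_params(vp, params), data, hp, prA,
                            prB, temps, bc_weight = 0.8) -
       negative_log_posterior(unflatten_params(vm, params), data, hp, prA,
                              prB, temps, bc_weight = 0.8)) / (2 * h)
  }, numeric(1))
  rel <- abs(g_fd - g_an) / pmax(1e-4, abs(g_fd) + abs(g_an))
  expect_lt(max(rel), 1e-3)
})

test_that("compiled kernel reproduces the reference implementation", {
  for (seed in 1:3) {
    data <- random_model_data(S = 9, NM = 5, NT = 8, seed = seed)
    hp <- mm_hyperparams(K = 4, J = 3, L = 2)
    prA <- test_lognormal_prior(0.2, 0.3)
    prB <- test_lognormal_prior(-0.1, 0.5)
    params <- initialize_params(data, hp, seed = seed + 10)
    temps <- list(tau_u = 0.4, tau_g_T = 0.2, tau_g_M = 0.9, tau_z = 0.8,
                  tau_q = 0.5)
    ref <- negative_log_posterior(params, data, hp, prA, prB, temps,
                                  grad = TRUE, bc_weight = 0.6)
    cpp <- mmrules:::.mm_nlp_grad_cpp(params, data, hp, prA, prB, temps,
                                      0.6, TRUE)
    expect_equal(cpp$loss, ref$loss, tolerance = 1e-10)
    for (nm in names(ref$grads)) {
      scale <- 1 + max(abs(ref$grads[[nm]]))
      expect_lt(max(abs(ref$grads[[nm]] - cpp$grads[[nm]])) / scale, 1e-6)
    }
  }
})

test_that("every layer output stays in its stated range", {
  data <- random_model_data(S = 15, NM = 7, NT = 9, seed = 31)
  hp <- mm_hyperparams(K = 3, J = 3, L = 3)
  params <- initialize_params(data, hp, seed = 8)
  params$beta <- params$beta * 10  # stress the prediction layer
  for (epoch in c(0, 250, 499)) {
    temps <- anneal_temperatures(epoch, 500)
    fwd <- mmrules:::model_forward(params, data, temps, hp)
    # saturation to exactly 0/1 in floating point is expected at the
    # sharp end of the schedule
    expect_true(all(fwd$uM >= 0 & fwd$uM <= 1))
    expect_true(all(fwd$gM >= 0 & fwd$gM <= 1))
    expect_true(all(fwd$gT >= 0 & fwd$gT <= 1))
    expect_true(all(fwd$r >= 0 & fwd$r <= 1))
    expect_true(all(fwd$Y > 0 & fwd$Y < 1))
    expect_true(all(is.finite(fwd$f)))
  }
})
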