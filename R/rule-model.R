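#' Model hyperparameters
#'
#' Fixed sizes and prior settings of the rule network: `K` candidate rules,
#' `J` metabolite detectors and `L` taxa detectors per rule. BinaryConcrete
#' selector locations default to 1/J, 1/L and 1/K, encoding a prior
#' expectation of about one active detector per modality per rule and one
#' active rule. Centers and regression weights get diffuse Normal(0, 1e4)
#' priors. `eta_pad` is the fraction of the metabolite data range padded
#' onto the uniform threshold support on each side.
#'
#' @param K,J,L network capacity (default 10 each).
#' @param alpha_z_M,alpha_z_T,alpha_q BinaryConcrete locations.
#' @param center_prior_var,weight_prior_var diffuse prior variances.
#' @param eta_pad threshold-support padding fraction (default 0.01).
#' @return list of class `mm_hyperparams`.
#' @export
mm_hyperparams <- function(K = 10, J = 10, L = 10,
                           alpha_z_M = 1 / J, alpha_z_T = 1 / L,
                           alpha_q = 1 / K,
                           center_prior_var = 1e4, weight_prior_var = 1e4,
                           eta_pad = 0.01) {
  stopifnot(K >= 1, J >= 1, L >= 1,
            alpha_z_M > 0, alpha_z_M <= 1, alpha_z_T > 0, alpha_z_T <= 1,
            alpha_q > 0, alpha_q <= 1)
  structure(list(K = as.integer(K), J = as.integer(J), L = as.integer(L),
                 alpha_z_M = alpha_z_M, alpha_z_T = alpha_z_T,
                 alpha_q = alpha_q, center_prior_var = center_prior_var,
                 weight_prior_var = weight_prior_var, eta_pad = eta_pad),
            class = "mm_hyperparams")
}

#' Temperature annealing schedule
#'
#' All five relaxation temperatures decrease linearly over training:
#' feature-inclusion `tau_u` and taxa-activation `tau_g_T` from 1e-2 to
#' 1e-3; metabolite-activation `tau_g_M`, detector-selection `tau_z`, and
#' rule-selection `tau_q` from 1 to 0.1 (the metabolite aggregate range is
#' an order of magnitude wider than the taxa one, hence the warmer
#' schedule).
#'
#' @param epoch 0-based epoch index.
#' @param n_epochs total epochs; a single-epoch schedule uses the start
#'   values.
#' @param selector_hold fraction of training during which the selector
#'   temperatures (`tau_z`, `tau_q`) are held at their start value before
#'   annealing begins (matched to the sparsity-prior warmup so selectors
#'   stay responsive until selection pressure arrives); 0 anneals them over
#'   the whole run.
#' @return named list of the five temperatures.
#' @export
anneal_temperatures <- function(epoch, n_epochs, selector_hold = 0) {
  frac <- if (n_epochs <= 1) 0 else epoch / (n_epochs - 1)
  lin <- function(from, to) from + (to - from) * frac
  sel_frac <- if (selector_hold >= 1) 0 else
    max(0, (frac - selector_hold) / (1 - selector_hold))
  sel <- function(from, to) from + (to - from) * sel_frac
  list(tau_u = lin(1e-2, 1e-3), tau_g_T = lin(1e-2, 1e-3),
       tau_g_M = lin(1, 0.1), tau_z = sel(1, 0.1), tau_q = sel(1, 0.1))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Soft feature inclusion
#'
#' Degree to which each embedded feature belongs to a detector with the
#' given center and radius: `sigmoid((radius - distance) / tau_u)` where
#' distance is Euclidean in the embedding.
#'
#' @param center numeric vector (embedding coordinates of the detector).
#' @param radius positive radius.
#' @param coords N x D embedding matrix.
#' @param tau_u positive temperature.
#' @return inclusion weights in (0, 1), one per feature.
#' @export
soft_inclusion <- function(center, radius, coords, tau_u) {
  if (tau_u <= 0) stop("tau_u must be positive")
  d <- sqrt(rowSums(sweep(coords, 2, center)^2))
  sigmoid((radius - d) / tau_u)
}

#' Detector aggregates
#'
#' Metabolite detectors average the standardized levels of their member
#' metabolites (weighted mean); taxa detectors sum the relative abundances
#' of their members (weighted sum). A small epsilon guards the weighted
#' mean's denominator when a detector's soft support vanishes.
#'
#' @param u inclusion weights (length N).
#' @param X subjects x features data matrix.
#' @param eps denominator guard.
#' @return one aggregate value per subject.
#' @export
aggregate_metabolites <- function(u, X, eps = 1e-10) {
  as.numeric(X %*% u) / (sum(u) + eps)
}

#' @rdname aggregate_metabolites
#' @export
aggregate_taxa <- function(u, X) {
  as.numeric(X %*% u)
}

#' Detector activation
#'
#' Soft threshold unit: `sigmoid((a - eta) / tau_g)`.
#'
#' @param a aggregate values.
#' @param eta threshold.
#' @param tau_g positive temperature.
#' @return activations in (0, 1).
#' @export
detector_activation <- function(a, eta, tau_g) {
  if (tau_g <= 0) stop("tau_g must be positive")
  sigmoid((a - eta) / tau_g)
}

#' Soft logical-AND rule activation
#'
#' `r = prod_j (1 - z_j (1 - g_j))`: with binary selectors z this is the
#' conjunction of the selected detector activations; unselected detectors
#' contribute factor 1 (the empty conjunction is true).
#'
#' @param g detector activations (vector, or subjects x detectors matrix).
#' @param z detector selector values in \[0, 1\].
#' @return rule activation(s) in \[0, 1\].
#' @export
rule_activation <- function(g, z) {
  if (is.matrix(g)) {
    if (ncol(g) != length(z)) stop("length mismatch")
    t <- 1 - sweep(1 - g, 2, z, "*")
    apply(t, 1, prod)
  } else {
    if (length(g) != length(z)) stop("length mismatch")
    prod(1 - z * (1 - g))
  }
}

#' Weighted-OR prediction layer
#'
#' `Y = sigmoid(sum_k q_k beta_k r_k + beta0)`: selected rules contribute
#' their weight to the log odds of the case label.
#'
#' @param r subjects x K rule activations (or length-K vector).
#' @param q rule selector values.
#' @param beta rule weights.
#' @param beta0 intercept.
#' @return case probability per subject.
#' @export
predict_rules <- function(r, q, beta, beta0) {
  if (!is.matrix(r)) r <- matrix(r, nrow = 1)
  sigmoid(as.numeric(r %*% (q * beta)) + beta0)
}

#' Deterministic relaxed selector
#'
#' MAP treatment of the BinaryConcrete selection variables: each selector is
#' a deterministic transform `sigmoid(logit / tau)` of a free logit, so the
#' optimization is reproducible; the BinaryConcrete log-density still enters
#' the prior. As tau decreases the selector saturates towards 0/1.
#'
#' @param logit free parameter.
#' @param tau positive temperature.
#' @return selector value in (0, 1).
#' @export
selector_value <- function(logit, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  sigmoid(logit / tau)
}

#' BinaryConcrete log-density
#'
#' Standard two-parameter (location `alpha`, temperature `tau`) relaxed
#' Bernoulli density on (0, 1):
#' `log p(x) = log tau + log alpha - (tau + 1)(log x + log(1 - x))
#'  - 2 log(alpha x^-tau + (1 - x)^-tau)`.
#'
#' @param x value(s) in (0, 1).
#' @param alpha location parameter.
#' @param tau temperature parameter.
#' @return log-density, vectorized over `x`.
#' @export
dbinary_concrete <- function(x, alpha, tau) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  A <- log(alpha) - tau * log(x)
  B <- -tau * log(1 - x)
  m <- pmax(A, B)
  lse <- m + log(exp(A - m) + exp(B - m))
  log(tau) + log(alpha) - (tau + 1) * (log(x) + log1p(-x)) - 2 * lse
}

# derivative of dbinary_concrete w.r.t. x
dbinary_concrete_grad <- function(x, alpha, tau) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  A <- log(alpha) - tau * log(x)
  B <- -tau * log(1 - x)
  w1 <- 1 / (1 + exp(B - A))
  w2 <- 1 - w1
  -(tau + 1) * (1 / x - 1 / (1 - x)) - 2 * tau * (w2 / (1 - x) - w1 / x)
}

# ---- Parameter container --------------------------------------------------

# Detector (k, j) lives at flat row (k - 1) * J + j; all detector-indexed
# arrays use that layout.
new_model_params <- function(centers_M, radii_M, eta_M, centers_T, radii_T,
                             eta_T, det_logits_M, det_logits_T, rule_logits,
                             beta, beta0) {
  p <- list(centers_M = centers_M, radii_M = radii_M, eta_M = eta_M,
            centers_T = centers_T, radii_T = radii_T, eta_T = eta_T,
            det_logits_M = det_logits_M, det_logits_T = det_logits_T,
            rule_logits = rule_logits, beta = beta, beta0 = beta0)
  stopifnot(all(vapply(p, function(x) all(is.finite(x)), logical(1))))
  stopifnot(all(radii_M > 0), all(radii_T > 0))
  structure(p, class = "mm_params")
}

# ---- Forward pass ---------------------------------------------------------

# data: list(XM [S x NM standardized], XT [S x NT rel. abundance],
#            EM [NM x DM], ET [NT x DT], y in {0,1}^S, eta_M_bounds c(lo, hi))
model_forward <- function(params, data, temps, hp, eps_den = 1e-10) {
  K <- hp$K; J <- hp$J; L <- hp$L
  S <- nrow(data$XM)
  EM2 <- data$EM2 %||% rowSums(data$EM^2)
  ET2 <- data$ET2 %||% rowSums(data$ET^2)
  # metabolite branch: KJ detectors x NM features
  epsM <- cross_dist(params$centers_M, data$EM, B2 = EM2)
  uM <- sigmoid((params$radii_M - epsM) / temps$tau_u)
  denM <- rowSums(uM) + eps_den
  aM <- (data$XM %*% t(uM)) / rep(denM, each = S)
  gM <- sigmoid((aM - rep(params$eta_M, each = S)) / temps$tau_g_M)
  # taxa branch
  epsT <- cross_dist(params$centers_T, data$ET, B2 = ET2)
  uT <- sigmoid((params$radii_T - epsT) / temps$tau_u)
  aT <- data$XT %*% t(uT)
  gT <- sigmoid((aT - rep(params$eta_T, each = S)) / temps$tau_g_T)
  # selectors
  zM <- sigmoid(as.numeric(t(params$det_logits_M)) / temps$tau_z)  # KJ flat
  zT <- sigmoid(as.numeric(t(params$det_logits_T)) / temps$tau_z)  # KL flat
  q <- sigmoid(params$rule_logits / temps$tau_q)
  # soft-AND in log space, blockwise per rule (block-indicator matmul)
  tM <- 1 - (1 - gM) * rep(zM, each = S)
  tT <- 1 - (1 - gT) * rep(zT, each = S)
  logtM <- log(pmax(tM, 1e-300)); logtT <- log(pmax(tT, 1e-300))
  logr <- logtM %*% block_indicator(K, J) + logtT %*% block_indicator(K, L)
  r <- exp(logr)
  f <- as.numeric(r %*% (q * params$beta)) + params$beta0
  Y <- sigmoid(f)
  list(epsM = epsM, uM = uM, denM = denM, aM = aM, gM = gM,
       epsT = epsT, uT = uT, aT = aT, gT = gT,
       zM = zM, zT = zT, q = q, tM = tM, tT = tT,
       logtM = logtM, logtT = logtT, logr = logr, r = r, f = f, Y = Y)
}

# KJ x K 0/1 matrix mapping detector columns to their rule block
block_indicator <- function(K, J) {
  out <- matrix(0, K * J, K)
  out[cbind(seq_len(K * J), rep(seq_len(K), each = J))] <- 1
  out
}

# Euclidean distances between rows of A [m x d] and rows of B [n x d];
# B2 = rowSums(B^2) may be precomputed
cross_dist <- function(A, B, B2 = NULL) {
  if (is.null(B2)) B2 <- rowSums(B^2)
  d2 <- -2 * A %*% t(B)
  d2 <- d2 + rowSums(A^2)            # recycles down columns: + |A_i|^2
  d2 <- d2 + rep(B2, each = nrow(d2))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# ---- Priors ---------------------------------------------------------------

#' Log prior density of the model parameters
#'
#' Sum of: diffuse Normal log-densities on detector centers and on
#' (beta, beta0); calibrated Log-Normal log-densities on detector radii;
#' uniform log-densities on thresholds (constant inside their supports:
#' \[0,1\] for taxa, the padded data range for metabolites); and
#' BinaryConcrete log-densities on the relaxed detector and rule selector
#' values at the current temperatures.
#'
#' @param params model parameter list.
#' @param hp [mm_hyperparams()].
#' @param prior_M,prior_T [calibrate_radius_prior()] results for the two
#'   modalities.
#' @param temps [anneal_temperatures()] output.
#' @param eta_M_bounds length-2 support of the metabolite thresholds.
#' @param bc_weight weight in \[0, 1\] on the BinaryConcrete selector
#'   terms; the optimizer ramps this from 0 to 1 over a warmup phase so
#'   informative detectors can form before sparsity pressure prunes them.
#' @return scalar log prior.
#' @export
log_prior <- function(params, hp, prior_M, prior_T, temps, eta_M_bounds,
                      bc_weight = 1) {
  lp <- 0
  norm_lp <- function(x, var) {
    -0.5 * length(x) * log(2 * pi * var) - sum(x^2) / (2 * var)
  }
  lnorm_lp <- function(x, mu, s2) {
    lx <- log(x)
    -0.5 * length(x) * log(2 * pi * s2) - sum(lx) -
      sum((lx - mu)^2) / (2 * s2)
  }
  lp <- lp + norm_lp(params$centers_M, hp$center_prior_var) +
    norm_lp(params$centers_T, hp$center_prior_var)
  lp <- lp + lnorm_lp(params$radii_M, prior_M$log_location,
                      prior_M$log_scale2) +
    lnorm_lp(params$radii_T, prior_T$log_location, prior_T$log_scale2)
  # uniform thresholds: constant inside support (parameters are projected
  # back into support after each step, so no out-of-bounds penalty arises)
  lp <- lp - length(params$eta_M) * log(diff(eta_M_bounds)) +
    length(params$eta_T) * 0
  zM <- sigmoid(as.numeric(t(params$det_logits_M)) / temps$tau_z)
  zT <- sigmoid(as.numeric(t(params$det_logits_T)) / temps$tau_z)
  q <- sigmoid(params$rule_logits / temps$tau_q)
  lp <- lp + bc_weight *
    (sum(dbinary_concrete(zM, hp$alpha_z_M, temps$tau_z)) +
     sum(dbinary_concrete(zT, hp$alpha_z_T, temps$tau_z)) +
     sum(dbinary_concrete(q, hp$alpha_q, temps$tau_q)))
  lp <- lp + norm_lp(params$beta, hp$weight_prior_var) +
    norm_lp(params$beta0, hp$weight_prior_var)
  if (!is.finite(lp)) stop("non-finite log prior")
  lp
}

#' Negative log posterior (MAP training loss)
#'
#' Bernoulli negative log-likelihood of the labels under the network's
#' predictions minus [log_prior()].
#'
#' @inheritParams log_prior
#' @param data model-ready data list as built by [prepare_model_data()].
#' @param grad also return the analytic gradient (used by the optimizer).
#' @return scalar loss, or (with `grad = TRUE`) list `(loss, grads, fwd)`.
#' @export
negative_log_posterior <- function(params, data, hp, prior_M, prior_T, temps,
                                   grad = FALSE, bc_weight = 1) {
  fwd <- model_forward(params, data, temps, hp)
  y <- data$y
  # stable -log p(y | f)
  nll <- sum(pmax(fwd$f, 0) - y * fwd$f + log1p(exp(-abs(fwd$f))))
  lp <- log_prior(params, hp, prior_M, prior_T, temps, data$eta_M_bounds,
                  bc_weight)
  loss <- nll - lp
  if (!is.finite(loss)) stop("non-finite loss (nll=", nll, ", log_prior=", lp, ")")
  if (!grad) return(loss)
  list(loss = loss, grads = model_backward(params, data, hp, prior_M,
                                           prior_T, temps, fwd, bc_weight),
       fwd = fwd)
}

# Analytic gradient of the training loss (nll - log_prior) w.r.t. every
# free parameter. Verified against central finite differences in the tests.
model_backward <- function(params, data, hp, prior_M, prior_T, temps, fwd,
                           bc_weight = 1) {
  K <- hp$K; J <- hp$J; L <- hp$L
  S <- nrow(data$XM)
  df <- fwd$Y - data$y                       # d nll / d f
  dbeta0 <- sum(df)
  rtdf <- as.numeric(crossprod(fwd$r, df))
  dbeta <- rtdf * fwd$q
  dq <- rtdf * params$beta
  dr <- tcrossprod(df, fwd$q * params$beta)  # S x K
  # expand to detector level: dt = dr * r / t  (log-space for safety)
  colM <- rep(seq_len(K), each = J); colT <- rep(seq_len(K), each = L)
  dtM <- dr[, colM, drop = FALSE] *
    exp(fwd$logr[, colM, drop = FALSE] - fwd$logtM)
  dtT <- dr[, colT, drop = FALSE] *
    exp(fwd$logr[, colT, drop = FALSE] - fwd$logtT)
  # t = 1 - z (1 - g)
  dzM_lik <- -colSums(dtM * (1 - fwd$gM))
  dzT_lik <- -colSums(dtT * (1 - fwd$gT))
  dgM <- dtM * rep(fwd$zM, each = S)
  dgT <- dtT * rep(fwd$zT, each = S)
  # g = sigmoid((a - eta) / tau_g)
  daM <- dgM * fwd$gM * (1 - fwd$gM) / temps$tau_g_M
  daT <- dgT * fwd$gT * (1 - fwd$gT) / temps$tau_g_T
  detaM <- -colSums(daM)
  detaT <- -colSums(daT)
  # metabolite aggregate: weighted mean
  cM <- colSums(daM * fwd$aM)
  duM <- (crossprod(daM, data$XM) - cM) / fwd$denM
  # taxa aggregate: weighted sum
  duT <- crossprod(daT, data$XT)
  # u = sigmoid((kappa - eps) / tau_u)
  dpreM <- duM * fwd$uM * (1 - fwd$uM) / temps$tau_u
  dpreT <- duT * fwd$uT * (1 - fwd$uT) / temps$tau_u
  dradM <- rowSums(dpreM); dradT <- rowSums(dpreT)
  wM <- -dpreM / pmax(fwd$epsM, 1e-12)
  wT <- -dpreT / pmax(fwd$epsT, 1e-12)
  dcenM <- rowSums(wM) * params$centers_M - wM %*% data$EM
  dcenT <- rowSums(wT) * params$centers_T - wT %*% data$ET
  # ---- subtract prior gradients (loss = nll - log_prior) -----------------
  dcenM <- dcenM + params$centers_M / hp$center_prior_var
  dcenT <- dcenT + params$centers_T / hp$center_prior_var
  lnorm_grad <- function(kap, pr) {
    -1 / kap - (log(kap) - pr$log_location) / (pr$log_scale2 * kap)
  }
  dradM <- dradM - lnorm_grad(params$radii_M, prior_M)
  dradT <- dradT - lnorm_grad(params$radii_T, prior_T)
  # selectors: likelihood + prior, chained through z = sigmoid(logit / tau)
  zM <- fwd$zM; zT <- fwd$zT; q <- fwd$q
  dzM <- dzM_lik -
    bc_weight * dbinary_concrete_grad(zM, hp$alpha_z_M, temps$tau_z)
  dzT <- dzT_lik -
    bc_weight * dbinary_concrete_grad(zT, hp$alpha_z_T, temps$tau_z)
  dq <- dq - bc_weight * dbinary_concrete_grad(q, hp$alpha_q, temps$tau_q)
  dlogitM <- dzM * zM * (1 - zM) / temps$tau_z
  dlogitT <- dzT * zT * (1 - zT) / temps$tau_z
  dlogitq <- dq * q * (1 - q) / temps$tau_q
  dbeta <- dbeta + params$beta / hp$weight_prior_var
  dbeta0 <- dbeta0 + params$beta0 / hp$weight_prior_var
  list(centers_M = dcenM, radii_M = dradM, eta_M = detaM,
       centers_T = dcenT, radii_T = dradT, eta_T = detaT,
       det_logits_M = matrix(dlogitM, K, J, byrow = TRUE),
       det_logits_T = matrix(dlogitT, K, L, byrow = TRUE),
       rule_logits = dlogitq, beta = dbeta, beta0 = dbeta0)
}
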