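// Negative log posterior and analytic gradient of the rule network.
// Mirrors the reference R implementation (negative_log_posterior /
// model_backward); equivalence is asserted in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
static inline vec sigv(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// distances between rows of A (m x d) and rows of B (n x d)
static mat cross_dist(const mat& A, const mat& B, const vec& B2) {
  mat d2 = -2.0 * A * B.t();
  d2.each_col() += sum(square(A), 1);
  d2.each_row() += B2.t();
  d2.elem(find(d2 < 0)).zeros();
  return sqrt(d2);
}

static double bc_logdens_sum(const vec& x, double alpha, double tau) {
  vec xc = clamp(x, 1e-12, 1.0 - 1e-12);
  vec A = std::log(alpha) - tau * log(xc);
  vec B = -tau * log(1.0 - xc);
  vec m = max(A, B);
  vec lse = m + log(exp(A - m) + exp(B - m));
  return accu(std::log(tau) + std::log(alpha)
              - (tau + 1.0) * (log(xc) + log1p(-xc)) - 2.0 * lse);
}

static vec bc_logdens_grad(const vec& x, double alpha, double tau) {
  vec xc = clamp(x, 1e-12, 1.0 - 1e-12);
  vec A = std::log(alpha) - tau * log(xc);
  vec B = -tau * log(1.0 - xc);
  vec w1 = 1.0 / (1.0 + exp(B - A));
  vec w2 = 1.0 - w1;
  return -(tau + 1.0) * (1.0 / xc - 1.0 / (1.0 - xc))
         - 2.0 * tau * (w2 / (1.0 - xc) - w1 / xc);
}

// [[Rcpp::export(name = ".mm_nlp_grad_cpp")]]
Rcpp::List mm_nlp_grad_cpp(const Rcpp::List& params, const Rcpp::List& data,
                           const Rcpp::List& hp, const Rcpp::List& prior_M,
                           const Rcpp::List& prior_T, const Rcpp::List& temps,
                           double bc_weight, bool want_grad) {
  const mat centers_M = params["centers_M"], centers_T = params["centers_T"];
  const vec radii_M = params["radii_M"], radii_T = params["radii_T"];
  const vec eta_M = params["eta_M"], eta_T = params["eta_T"];
  const mat det_logits_M = params["det_logits_M"];
  const mat det_logits_T = params["det_logits_T"];
  const vec rule_logits = params["rule_logits"], beta = params["beta"];
  const double beta0 = Rcpp::as<double>(params["beta0"]);

  const mat XM = data["XM"], XT = data["XT"], EM = data["EM"], ET = data["ET"];
  const vec y = data["y"], eta_M_bounds = data["eta_M_bounds"];
  vec EM2 = data.containsElementNamed("EM2") ?
    Rcpp::as<vec>(data["EM2"]) : vec(sum(square(EM), 1));
  vec ET2 = data.containsElementNamed("ET2") ?
    Rcpp::as<vec>(data["ET2"]) : vec(sum(square(ET), 1));

  const int K = hp["K"], J = hp["J"], L = hp["L"];
  const double alpha_z_M = hp["alpha_z_M"], alpha_z_T = hp["alpha_z_T"],
    alpha_q = hp["alpha_q"], center_var = hp["center_prior_var"],
    weight_var = hp["weight_prior_var"];
  const double locM = prior_M["log_location"], s2M = prior_M["log_scale2"];
  const double locT = prior_T["log_location"], s2T = prior_T["log_scale2"];
  const double tau_u = temps["tau_u"], tau_g_T = temps["tau_g_T"],
    tau_g_M = temps["tau_g_M"], tau_z = temps["tau_z"], tau_q = temps["tau_q"];

  const int S = XM.n_rows;

  // ---- forward ----------------------------------------------------------
  mat epsM = cross_dist(centers_M, EM, EM2);
  mat uM = sigm((-(epsM.each_col() - radii_M)) / tau_u);
  vec denM = sum(uM, 1) + 1e-10;
  mat aM = XM * uM.t();
  aM.each_row() /= denM.t();
  mat gM = sigm((aM.each_row() - eta_M.t()) / tau_g_M);

  mat epsT = cross_dist(centers_T, ET, ET2);
  mat uT = sigm((-(epsT.each_col() - radii_T)) / tau_u);
  mat aT = XT * uT.t();
  mat gT = sigm((aT.each_row() - eta_T.t()) / tau_g_T);

  vec zM = sigv(vectorise(det_logits_M.t()) / tau_z);  // (k,j) flat
  vec zT = sigv(vectorise(det_logits_T.t()) / tau_z);
  vec q = sigv(rule_logits / tau_q);

  mat oneM = 1.0 - gM; oneM.each_row() %= zM.t();
  mat tM = 1.0 - oneM;
  mat oneT = 1.0 - gT; oneT.each_row() %= zT.t();
  mat tT = 1.0 - oneT;
  mat logtM = log(clamp(tM, 1e-300, 1.0));
  mat logtT = log(clamp(tT, 1e-300, 1.0));
  mat logr(S, K);
  for (int k = 0; k < K; ++k) {
    logr.col(k) = sum(logtM.cols(k * J, k * J + J - 1), 1)
                + sum(logtT.cols(k * L, k * L + L - 1), 1);
  }
  mat r = exp(logr);
  vec f = r * (q % beta) + beta0;
  vec Y = sigv(f);

  double nll = accu(clamp(f, 0.0, datum::inf) - y % f
                    + log1p(exp(-abs(f))));

  // ---- log prior --------------------------------------------------------
  auto norm_lp = [](double ss, int n, double var) {
    return -0.5 * n * std::log(2.0 * datum::pi * var) - ss / (2.0 * var);
  };
  double lp = 0.0;
  lp += norm_lp(accu(square(centers_M)), centers_M.n_elem, center_var);
  lp += norm_lp(accu(square(centers_T)), centers_T.n_elem, center_var);
  vec lrM = log(radii_M), lrT = log(radii_T);
  lp += -0.5 * lrM.n_elem * std::log(2.0 * datum::pi * s2M) - accu(lrM)
        - accu(square(lrM - locM)) / (2.0 * s2M);
  lp += -0.5 * lrT.n_elem * std::log(2.0 * datum::pi * s2T) - accu(lrT)
        - accu(square(lrT - locT)) / (2.0 * s2T);
  lp += -double(eta_M.n_elem)
        * std::log(eta_M_bounds(1) - eta_M_bounds(0));
  lp += bc_weight * (bc_logdens_sum(zM, alpha_z_M, tau_z)
                     + bc_logdens_sum(zT, alpha_z_T, tau_z)
                     + bc_logdens_sum(q, alpha_q, tau_q));
  lp += norm_lp(accu(square(beta)), beta.n_elem, weight_var);
  lp += norm_lp(beta0 * beta0, 1, weight_var);

  double loss = nll - lp;
  if (!std::isfinite(loss)) Rcpp::stop("non-finite loss");
  if (!want_grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);

  // ---- backward ---------------------------------------------------------
  vec df = Y - y;
  double dbeta0 = accu(df);
  vec rtdf = r.t() * df;
  vec dbeta = rtdf % q;
  vec dq = rtdf % beta;
  mat dr = df * (q % beta).t();  // S x K

  mat dtM(S, K * J), dtT(S, K * L);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < J; ++j) {
      dtM.col(k * J + j) =
        dr.col(k) % exp(logr.col(k) - logtM.col(k * J + j));
    }
    for (int l = 0; l < L; ++l) {
      dtT.col(k * L + l) =
        dr.col(k) % exp(logr.col(k) - logtT.col(k * L + l));
    }
  }
  vec dzM = -sum(dtM % (1.0 - gM), 0).t();
  vec dzT = -sum(dtT % (1.0 - gT), 0).t();
  mat dgM = dtM.each_row() % zM.t();
  mat dgT = dtT.each_row() % zT.t();
  mat daM = dgM % gM % (1.0 - gM) / tau_g_M;
  mat daT = dgT % gT % (1.0 - gT) / tau_g_T;
  vec detaM = -sum(daM, 0).t();
  vec detaT = -sum(daT, 0).t();
  vec cM = sum(daM % aM, 0).t();
  mat duM = (daM.t() * XM);
  duM.each_col() -= cM;
  duM.each_col() /= denM;
  mat duT = daT.t() * XT;
  mat dpreM = duM % uM % (1.0 - uM) / tau_u;
  mat dpreT = duT % uT % (1.0 - uT) / tau_u;
  vec dradM = sum(dpreM, 1);
  vec dradT = sum(dpreT, 1);
  mat wM = -dpreM / clamp(epsM, 1e-12, datum::inf);
  mat wT = -dpreT / clamp(epsT, 1e-12, datum::inf);
  mat dcenM = centers_M.each_col() % sum(wM, 1);
  dcenM -= wM * EM;
  mat dcenT = centers_T.each_col() % sum(wT, 1);
  dcenT -= wT * ET;

  // prior gradients (loss = nll - log_prior)
  dcenM += centers_M / center_var;
  dcenT += centers_T / center_var;
  dradM -= (-1.0 / radii_M - (lrM - locM) / (s2M * radii_M));
  dradT -= (-1.0 / radii_T - (lrT - locT) / (s2T * radii_T));
  dzM -= bc_weight * bc_logdens_grad(zM, alpha_z_M, tau_z);
  dzT -= bc_weight * bc_logdens_grad(zT, alpha_z_T, tau_z);
  dq -= bc_weight * bc_logdens_grad(q, alpha_q, tau_q);
  vec dlogitM = dzM % zM % (1.0 - zM) / tau_z;
  vec dlogitT = dzT % zT % (1.0 - zT) / tau_z;
  vec dlogitq = dq % q % (1.0 - q) / tau_q;
  dbeta += beta / weight_var;
  dbeta0 += beta0 / weight_var;

  // reshape flat (k,j) selector gradients back to K x J / K x L
  mat gM_logits(J, K, fill::zeros), gT_logits(L, K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < J; ++j) gM_logits(j, k) = dlogitM(k * J + j);
    for (int l = 0; l < L; ++l) gT_logits(l, k) = dlogitT(k * L + l);
  }

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("centers_M") = dcenM, Rcpp::Named("radii_M") = dradM,
      Rcpp::Named("eta_M") = detaM, Rcpp::Named("centers_T") = dcenT,
      Rcpp::Named("radii_T") = dradT, Rcpp::Named("eta_T") = detaT,
      Rcpp::Named("det_logits_M") = mat(gM_logits.t()),
      Rcpp::Named("det_logits_T") = mat(gT_logits.t()),
      Rcpp::Named("rule_logits") = dlogitq,
      Rcpp::Named("beta") = dbeta, Rcpp::Named("beta0") = dbeta0));
}
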