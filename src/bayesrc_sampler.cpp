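#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the four-component Bayesian mixture model of SNP
// effects with per-class mixing proportions (BayesRC).
//
// Model: y = W theta + X beta + e,  e ~ N(0, sigma_e2 I)
//        beta_j | k_j ~ N(0, gamma[k_j] * sigma_g2),  gamma[0] = 0
//        k_j | pi^(c(j)) ~ Categorical(pi^(c(j)))
//        pi^(c) ~ Dirichlet(alpha)
//        sigma_g2, sigma_e2 ~ scaled-inverse-chi-square(df, scale)
//
// X columns must be centered/scaled by the caller. The residual
// r = y - W theta - X beta is maintained incrementally (axpy updates,
// O(n) per SNP per sweep) and recomputed from scratch every
// check_every iterations as a conservation diagnostic.
//
// Uses R's RNG throughout, so set.seed() on the R side gives
// bit-reproducible chains.

static inline double dot(const double* a, const double* b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// [[Rcpp::export(name = ".bayesrc_chain_cpp")]]
List bayesrc_chain_cpp(NumericMatrix X, NumericMatrix W, NumericVector y,
                       IntegerVector cls, int n_class,
                       NumericVector gamma_, NumericVector alpha,
                       int n_iter, int burn_in,
                       NumericMatrix pi_init, bool fix_pi,
                       double sigma_g2_init, double sigma_e2_init,
                       bool fix_sigma_g2, bool fix_sigma_e2,
                       double df_prior, double scale_g, double scale_e,
                       NumericVector beta_init, IntegerVector k_init,
                       NumericVector theta_init,
                       bool store_samples, int check_every) {
  const int n = y.size();
  const int m = X.ncol();
  const int p = W.ncol();
  const int K = gamma_.size();  // 4

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<int> kcomp(k_init.begin(), k_init.end());
  std::vector<double> theta(theta_init.begin(), theta_init.end());
  NumericMatrix pi(clone(pi_init));  // n_class x K
  double sgg = sigma_g2_init, sge = sigma_e2_init;

  std::vector<double> xtx(m), wtw(p);
  for (int j = 0; j < m; ++j) xtx[j] = dot(&X(0, j), &X(0, j), n);
  for (int c = 0; c < p; ++c) wtw[c] = dot(&W(0, c), &W(0, c), n);

  // residual and fixed-effect fit
  std::vector<double> r(n), fitW(n, 0.0);
  for (int c = 0; c < p; ++c)
    if (theta[c] != 0.0)
      for (int i = 0; i < n; ++i) fitW[i] += W(i, c) * theta[c];
  for (int i = 0; i < n; ++i) r[i] = y[i] - fitW[i];
  for (int j = 0; j < m; ++j)
    if (beta[j] != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * beta[j];

  // accumulators (post burn-in)
  std::vector<double> beta_sum(m, 0.0), theta_sum(p, 0.0);
  std::vector<double> occ(m * K, 0.0);
  NumericMatrix pi_sum(n_class, K);
  std::vector<double> comp_count_sum(n_class * K, 0.0);
  double sgg_sum = 0, sge_sum = 0, varg_sum = 0, h2_sum = 0;
  int n_keep = 0;
  double max_resid_err = 0.0;

  int n_store = store_samples ? (n_iter - burn_in) : 0;
  NumericMatrix beta_store(n_store > 0 ? n_store : 1,
                           n_store > 0 ? m : 1);
  IntegerMatrix k_store(n_store > 0 ? n_store : 1,
                        n_store > 0 ? m : 1);

  std::vector<double> lw(K), prob(K);
  std::vector<int> count(n_class * K);

  for (int it = 0; it < n_iter; ++it) {
    // (a) fixed effects, scalar Gibbs per column (flat prior)
    for (int c = 0; c < p; ++c) {
      const double* w = &W(0, c);
      double old = theta[c];
      for (int i = 0; i < n; ++i) r[i] += w[i] * old;
      double rhs = dot(w, r.data(), n);
      double mu = rhs / wtw[c];
      double nw = mu + sqrt(sge / wtw[c]) * norm_rand();
      theta[c] = nw;
      for (int i = 0; i < n; ++i) {
        r[i] -= w[i] * nw;
        fitW[i] += w[i] * (nw - old);
      }
    }

    // (b) SNP effects and component indicators
    std::fill(count.begin(), count.end(), 0);
    for (int j = 0; j < m; ++j) {
      const double* x = &X(0, j);
      double old = beta[j];
      if (old != 0.0)
        for (int i = 0; i < n; ++i) r[i] += x[i] * old;
      double rhs = dot(x, r.data(), n);
      int c = cls[j];
      lw[0] = log(pi(c, 0));
      double maxlw = lw[0];
      for (int k = 1; k < K; ++k) {
        double v = gamma_[k] * sgg;
        double lhs = xtx[j] / sge + 1.0 / v;
        lw[k] = log(pi(c, k)) - 0.5 * log(v * lhs) +
          0.5 * (rhs / sge) * (rhs / sge) / lhs;
        if (lw[k] > maxlw) maxlw = lw[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { prob[k] = exp(lw[k] - maxlw); tot += prob[k]; }
      double u = unif_rand() * tot;
      int knew = 0;
      double cum = 0.0;
      for (int k = 0; k < K; ++k) { cum += prob[k]; if (u <= cum) { knew = k; break; } }
      double bnew = 0.0;
      if (knew > 0) {
        double v = gamma_[knew] * sgg;
        double lhs = xtx[j] / sge + 1.0 / v;
        double mu = (rhs / sge) / lhs;
        bnew = mu + sqrt(1.0 / lhs) * norm_rand();
        for (int i = 0; i < n; ++i) r[i] -= x[i] * bnew;
      }
      beta[j] = bnew;
      kcomp[j] = knew;
      count[c * K + knew] += 1;
    }

    // (c) per-class mixing proportions ~ Dirichlet(alpha + counts)
    if (!fix_pi) {
      for (int c = 0; c < n_class; ++c) {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha[k] + count[c * K + k], 1.0);
          pi(c, k) = g;
          tot += g;
        }
        for (int k = 0; k < K; ++k) pi(c, k) /= tot;
      }
    }

    // (d) variance components, scaled-inverse-chi-square conditionals
    if (!fix_sigma_g2) {
      double ssb = 0.0;
      int mnz = 0;
      for (int j = 0; j < m; ++j)
        if (kcomp[j] > 0) { ssb += beta[j] * beta[j] / gamma_[kcomp[j]]; ++mnz; }
      sgg = (df_prior * scale_g + ssb) / R::rchisq(df_prior + mnz);
    }
    if (!fix_sigma_e2) {
      double sse = dot(r.data(), r.data(), n);
      sge = (df_prior * scale_e + sse) / R::rchisq(df_prior + n);
    }
    if (!R_finite(sge) || !R_finite(sgg))
      stop("non-finite variance at iteration %d", it + 1);

    // residual conservation diagnostic
    if (check_every > 0 && ((it + 1) % check_every == 0)) {
      double err = 0.0;
      for (int i = 0; i < n; ++i) {
        double ri = y[i] - fitW[i];
        for (int j = 0; j < m; ++j)
          if (beta[j] != 0.0) ri -= X(i, j) * beta[j];
        double d = fabs(ri - r[i]);
        if (d > err) err = d;
        if (!R_finite(r[i]))
          stop("non-finite residual at iteration %d", it + 1);
      }
      if (err > max_resid_err) max_resid_err = err;
    }

    if (it >= burn_in) {
      ++n_keep;
      double sg = 0.0, sg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = y[i] - fitW[i] - r[i];
        sg += gi; sg2 += gi * gi;
      }
      double varg = (sg2 - sg * sg / n) / (n - 1);
      varg_sum += varg;
      h2_sum += varg / (varg + sge);
      sgg_sum += sgg; sge_sum += sge;
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        occ[j * K + kcomp[j]] += 1.0;
      }
      for (int c = 0; c < p; ++c) theta_sum[c] += theta[c];
      for (int c = 0; c < n_class; ++c)
        for (int k = 0; k < K; ++k) {
          pi_sum(c, k) += pi(c, k);
          comp_count_sum[c * K + k] += count[c * K + k];
        }
      if (store_samples) {
        int row = n_keep - 1;
        for (int j = 0; j < m; ++j) {
          beta_store(row, j) = beta[j];
          k_store(row, j) = kcomp[j];
        }
      }
    }
  }

  NumericVector beta_mean(m), theta_mean(p);
  NumericMatrix occ_mean(m, K), pi_mean(n_class, K),
    comp_counts(n_class, K);
  for (int j = 0; j < m; ++j) {
    beta_mean[j] = beta_sum[j] / n_keep;
    for (int k = 0; k < K; ++k) occ_mean(j, k) = occ[j * K + k] / n_keep;
  }
  for (int c = 0; c < p; ++c) theta_mean[c] = theta_sum[c] / n_keep;
  for (int c = 0; c < n_class; ++c)
    for (int k = 0; k < K; ++k) {
      pi_mean(c, k) = pi_sum(c, k) / n_keep;
      comp_counts(c, k) = comp_count_sum[c * K + k] / n_keep;
    }

  List state = List::create(
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["k"] = IntegerVector(kcomp.begin(), kcomp.end()),
    _["pi"] = pi, _["theta"] = NumericVector(theta.begin(), theta.end()),
    _["sigma_g2"] = sgg, _["sigma_e2"] = sge,
    _["residual"] = NumericVector(r.begin(), r.end()));
  List out = List::create(
    _["beta_mean"] = beta_mean, _["occupancy"] = occ_mean,
    _["pi_mean"] = pi_mean, _["comp_counts"] = comp_counts,
    _["theta_mean"] = theta_mean,
    _["sigma_g2_mean"] = sgg_sum / n_keep,
    _["sigma_e2_mean"] = sge_sum / n_keep,
    _["genic_var_mean"] = varg_sum / n_keep,
    _["h2_mean"] = h2_sum / n_keep,
    _["n_kept"] = n_keep, _["max_resid_err"] = max_resid_err,
    _["state"] = state);
  if (store_samples) {
    out["beta_samples"] = beta_store;
    out["k_samples"] = k_store;
  }
  return out;
}
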