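// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// probit-binomial signal detection model.
//
// Likelihood per measurement cell m:
//   H_m  ~ Binomial(n_tri,  Phi( 0.5 d'_m - bias_m))
//   FA_m ~ Binomial(n_ntri, Phi(-0.5 d'_m - bias_m))
// Latent layer:
//   d'_m   ~ N(mu_m,  sigma_d[att(m)]^2)
//   bias_m ~ N(mub_m, sigma_b[att(m)]^2)
// ANOVA structure (cell-indicator coding, over-parameterized; inference is
// reported through the recentered re-expression on the R side):
//   mu_m = beta0 + b_att[a] (+ b_timb[t] + b_ati[a,t]) + b_subj[s]
// Priors: beta0 ~ N(0, prior_var0); coefficients ~ N(0, sigma_beta_g^2);
// sigma_d, sigma_b ~ Unif(0, sigma_upper); sigma_beta ~ Gamma(shape, rate)
// on the standard deviation.
//
// Update scheme per iteration: random-walk MH for each latent (d'_m,
// bias_m) component; exact conjugate Gibbs draws for beta0 and every
// Gaussian coefficient; log-scale random-walk MH for every standard
// deviation. Proposal scales adapt toward 0.44 acceptance in batches of 50
// iterations, during burn-in only.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double cell_loglik(double d, double b, int H, int ntri,
                                 int FA, int nntri) {
  double qh = 0.5 * d - b;
  double qf = -0.5 * d - b;
  return H * R::pnorm(qh, 0.0, 1.0, 1, 1) +
         (ntri - H) * R::pnorm(qh, 0.0, 1.0, 0, 1) +
         FA * R::pnorm(qf, 0.0, 1.0, 1, 1) +
         (nntri - FA) * R::pnorm(qf, 0.0, 1.0, 0, 1);
}

struct AdaptScale {
  std::vector<double> ls;    // log proposal scales
  std::vector<int> acc;      // acceptances in current batch
  explicit AdaptScale(int n, double init = -0.7) : ls(n, init), acc(n, 0) {}
  void adapt(double delta) {
    for (size_t i = 0; i < ls.size(); ++i) {
      ls[i] += (acc[i] > 22 ? delta : -delta);  // 22/50 = 0.44 target
      acc[i] = 0;
    }
  }
};

// Conjugate draw for one Gaussian coefficient shared by the cells in idx:
// latent[m] ~ N(mu[m], sd_res[att[m]]^2), coefficient prior N(0, 1/prec0).
// mu is updated in place for the affected cells.
static double gibbs_coef(const std::vector<int>& idx, double coef,
                         std::vector<double>& mu,
                         const std::vector<double>& latent,
                         const std::vector<double>& sd_res,
                         const std::vector<int>& att, double prec0) {
  double A = prec0, B = 0.0;
  for (int m : idx) {
    double w = 1.0 / (sd_res[att[m]] * sd_res[att[m]]);
    B += w * (latent[m] - mu[m] + coef);
    A += w;
  }
  double newv = B / A + R::rnorm(0.0, 1.0) / std::sqrt(A);
  double delta = newv - coef;
  for (int m : idx) mu[m] += delta;
  return newv;
}

// Log-scale random-walk MH for a residual standard deviation with a
// Unif(0, upper) prior; returns the (possibly unchanged) value.
static double mh_sigma_unif(const std::vector<int>& idx, double sigma,
                            const std::vector<double>& mu,
                            const std::vector<double>& latent,
                            double upper, double scale, int& acc) {
  double prop = sigma * std::exp(scale * R::rnorm(0.0, 1.0));
  if (prop >= upper) return sigma;
  double lr = std::log(prop) - std::log(sigma);  // Jacobian
  for (int m : idx) {
    lr += R::dnorm(latent[m], mu[m], prop, 1) -
          R::dnorm(latent[m], mu[m], sigma, 1);
  }
  if (std::log(R::runif(0.0, 1.0)) < lr) { ++acc; return prop; }
  return sigma;
}

// Log-scale random-walk MH for a coefficient-group standard deviation with
// a Gamma(shape, rate) prior on the sd itself.
static double mh_sigma_gamma(const std::vector<double>& coefs, double sigma,
                             double shape, double rate, double scale,
                             int& acc) {
  double prop = sigma * std::exp(scale * R::rnorm(0.0, 1.0));
  double gscale = 1.0 / rate;
  double lr = std::log(prop) - std::log(sigma) +
              R::dgamma(prop, shape, gscale, 1) -
              R::dgamma(sigma, shape, gscale, 1);
  for (double c : coefs) {
    lr += R::dnorm(c, 0.0, prop, 1) - R::dnorm(c, 0.0, sigma, 1);
  }
  if (std::log(R::runif(0.0, 1.0)) < lr) { ++acc; return prop; }
  return sigma;
}

// Non-centered update for a residual standard deviation: propose sigma on
// the log scale and move the group's latents with their standardized
// residuals held fixed (d -> mu + (d - mu) * sigma'/sigma). In that
// parameterization the latent priors cancel, so only the binomial
// likelihood and the log-scale Jacobian enter. Breaks the funnel coupling
// between sigma and near-ceiling latents.
static void mh_sigma_rescale(double& sigma, const std::vector<int>& idx,
                             const std::vector<double>& mu,
                             std::vector<double>& latent,
                             const std::vector<double>& other,
                             bool latent_is_d, IntegerVector H,
                             IntegerVector ntri, IntegerVector FA,
                             IntegerVector nntri, double upper, double scale,
                             int& acc) {
  double prop = sigma * std::exp(scale * R::rnorm(0.0, 1.0));
  if (prop >= upper) return;
  double ratio = prop / sigma;
  double lr = std::log(prop) - std::log(sigma);
  std::vector<double> lat_new(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    int m = idx[i];
    lat_new[i] = mu[m] + (latent[m] - mu[m]) * ratio;
    double d0 = latent_is_d ? latent[m] : other[m];
    double b0 = latent_is_d ? other[m] : latent[m];
    double d1 = latent_is_d ? lat_new[i] : other[m];
    double b1 = latent_is_d ? other[m] : lat_new[i];
    lr += cell_loglik(d1, b1, H[m], ntri[m], FA[m], nntri[m]) -
          cell_loglik(d0, b0, H[m], ntri[m], FA[m], nntri[m]);
  }
  if (std::log(R::runif(0.0, 1.0)) < lr) {
    sigma = prop;
    for (size_t i = 0; i < idx.size(); ++i) latent[idx[i]] = lat_new[i];
    ++acc;
  }
}

// Translation MH move along a flat direction of the over-parameterized
// ANOVA coding: shift `a` by delta and every element of b[idx] by -delta.
// All cell means are unchanged, so only the Gaussian priors enter the
// acceptance ratio. These moves decorrelate the intercept from the effect
// blocks, which plain Gibbs traverses slowly.
static void mh_translate(double& a, double sd_a, std::vector<double>& b,
                         const std::vector<int>& idx, double sd_b,
                         double scale, int& acc) {
  double delta = scale * R::rnorm(0.0, 1.0);
  double lr = R::dnorm(a + delta, 0.0, sd_a, 1) - R::dnorm(a, 0.0, sd_a, 1);
  for (int j : idx) {
    lr += R::dnorm(b[j] - delta, 0.0, sd_b, 1) - R::dnorm(b[j], 0.0, sd_b, 1);
  }
  if (std::log(R::runif(0.0, 1.0)) < lr) {
    a += delta;
    for (int j : idx) b[j] -= delta;
    ++acc;
  }
}

// Joint shift of one coefficient and the latent values of the cells it
// feeds (latents track their mean, so the latent priors are unchanged and
// only the coefficient prior and the binomial likelihood enter). Near
// ceiling the likelihood is nearly flat in the latent, which makes this
// direction broad; single-site updates traverse it slowly.
static void mh_shift_group(double& coef, double sd_coef,
                           const std::vector<int>& idx,
                           std::vector<double>& latent,
                           std::vector<double>& mu,
                           const std::vector<double>& other,
                           bool latent_is_d, IntegerVector H,
                           IntegerVector ntri, IntegerVector FA,
                           IntegerVector nntri, double scale, int& acc) {
  double delta = scale * R::rnorm(0.0, 1.0);
  double lr = R::dnorm(coef + delta, 0.0, sd_coef, 1) -
              R::dnorm(coef, 0.0, sd_coef, 1);
  for (int m : idx) {
    double d0 = latent_is_d ? latent[m] : other[m];
    double b0 = latent_is_d ? other[m] : latent[m];
    double d1 = latent_is_d ? latent[m] + delta : other[m];
    double b1 = latent_is_d ? other[m] : latent[m] + delta;
    lr += cell_loglik(d1, b1, H[m], ntri[m], FA[m], nntri[m]) -
          cell_loglik(d0, b0, H[m], ntri[m], FA[m], nntri[m]);
  }
  if (std::log(R::runif(0.0, 1.0)) < lr) {
    coef += delta;
    for (int m : idx) { latent[m] += delta; mu[m] += delta; }
    ++acc;
  }
}

// [[Rcpp::export]]
NumericMatrix mcmc_sdt_chain(IntegerVector H, IntegerVector ntri,
                             IntegerVector FA, IntegerVector nntri,
                             IntegerVector att1, IntegerVector timb1,
                             IntegerVector subj1, int n_subj, bool has_timb,
                             int n_samples, int burn_in, double prior_var0,
                             double sigma_upper, double gamma_shape,
                             double gamma_rate, NumericVector d_init,
                             NumericVector b_init) {
  const int M = H.size();
  std::vector<int> att(M), timb(M), subj(M), ati(M);
  for (int m = 0; m < M; ++m) {
    att[m] = att1[m] - 1;
    timb[m] = has_timb ? timb1[m] - 1 : 0;
    subj[m] = subj1[m] - 1;
    ati[m] = att[m] * 3 + timb[m];
  }

  // index lists per factor level
  std::vector<int> all_idx(M);
  for (int m = 0; m < M; ++m) all_idx[m] = m;
  std::vector<std::vector<int> > idx_att(3), idx_timb(3), idx_ati(9),
      idx_subj(n_subj);
  for (int m = 0; m < M; ++m) {
    idx_att[att[m]].push_back(m);
    if (has_timb) {
      idx_timb[timb[m]].push_back(m);
      idx_ati[ati[m]].push_back(m);
    }
    idx_subj[subj[m]].push_back(m);
  }

  // state: d-prime side and mirrored bias side
  std::vector<double> d(d_init.begin(), d_init.end());
  std::vector<double> bi(b_init.begin(), b_init.end());
  double beta0 = 0.0, c0 = 0.0;
  std::vector<double> batt(3, 0.0), btimb(3, 0.0), bati(9, 0.0),
      bsubj(n_subj, 0.0);
  std::vector<double> gatt(3, 0.0), gtimb(3, 0.0), gati(9, 0.0),
      gsubj(n_subj, 0.0);
  std::vector<double> sd_d(3, 1.0), sd_b(3, 1.0);
  const int n_sb = has_timb ? 4 : 2;  // att (, timb, ati), subj
  std::vector<double> sb(n_sb, 1.0), sg(n_sb, 1.0);

  std::vector<double> mu_d(M), mu_b(M);
  for (int m = 0; m < M; ++m) {
    mu_d[m] = beta0 + batt[att[m]] + bsubj[subj[m]] +
              (has_timb ? btimb[timb[m]] + bati[ati[m]] : 0.0);
    mu_b[m] = c0 + gatt[att[m]] + gsubj[subj[m]] +
              (has_timb ? gtimb[timb[m]] + gati[ati[m]] : 0.0);
  }

  AdaptScale a_d(M), a_bi(M), a_sdd(3), a_sdb(3), a_sb(n_sb), a_sg(n_sb);

  // index sets for the translation moves
  std::vector<int> seq3(3), seqS(n_subj);
  for (int k = 0; k < 3; ++k) seq3[k] = k;
  for (int k = 0; k < n_subj; ++k) seqS[k] = k;
  std::vector<std::vector<int> > ati_row(3), ati_col(3);
  for (int a = 0; a < 3; ++a) {
    for (int t = 0; t < 3; ++t) {
      ati_row[a].push_back(a * 3 + t);
      ati_col[t].push_back(a * 3 + t);
    }
  }
  const int n_tr = has_timb ? 9 : 2;  // translation moves per side
  AdaptScale a_trd(n_tr, 0.0), a_trb(n_tr, 0.0);
  // joint coefficient+latent shifts: one per subject plus one global, per side
  AdaptScale a_shd(n_subj + 1, -0.7), a_shb(n_subj + 1, -0.7);
  // non-centered sigma rescales, one per attention group per side
  AdaptScale a_rsd(3, -0.7), a_rsb(3, -0.7);

  const int n_coef = 1 + 3 + (has_timb ? 12 : 0) + n_subj;
  const int side = n_coef + 3 + n_sb;          // coefficients + sd_res + sd_beta
  const int n_par = 2 * M + 2 * side;
  NumericMatrix out(n_samples, n_par);

  const int n_iter = burn_in + n_samples;
  int batch = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // --- latent cells -----------------------------------------------------
    for (int m = 0; m < M; ++m) {
      double ll0 = cell_loglik(d[m], bi[m], H[m], ntri[m], FA[m], nntri[m]);
      double prop = d[m] + std::exp(a_d.ls[m]) * R::rnorm(0.0, 1.0);
      double lr = cell_loglik(prop, bi[m], H[m], ntri[m], FA[m], nntri[m]) -
                  ll0 +
                  R::dnorm(prop, mu_d[m], sd_d[att[m]], 1) -
                  R::dnorm(d[m], mu_d[m], sd_d[att[m]], 1);
      if (std::log(R::runif(0.0, 1.0)) < lr) { d[m] = prop; ++a_d.acc[m]; }

      ll0 = cell_loglik(d[m], bi[m], H[m], ntri[m], FA[m], nntri[m]);
      prop = bi[m] + std::exp(a_bi.ls[m]) * R::rnorm(0.0, 1.0);
      lr = cell_loglik(d[m], prop, H[m], ntri[m], FA[m], nntri[m]) - ll0 +
           R::dnorm(prop, mu_b[m], sd_b[att[m]], 1) -
           R::dnorm(bi[m], mu_b[m], sd_b[att[m]], 1);
      if (std::log(R::runif(0.0, 1.0)) < lr) { bi[m] = prop; ++a_bi.acc[m]; }
    }

    // --- Gaussian coefficients (conjugate Gibbs) --------------------------
    beta0 = gibbs_coef(all_idx, beta0, mu_d, d, sd_d, att, 1.0 / prior_var0);
    c0 = gibbs_coef(all_idx, c0, mu_b, bi, sd_b, att, 1.0 / prior_var0);
    for (int k = 0; k < 3; ++k) {
      batt[k] = gibbs_coef(idx_att[k], batt[k], mu_d, d, sd_d, att,
                           1.0 / (sb[0] * sb[0]));
      gatt[k] = gibbs_coef(idx_att[k], gatt[k], mu_b, bi, sd_b, att,
                           1.0 / (sg[0] * sg[0]));
    }
    if (has_timb) {
      for (int k = 0; k < 3; ++k) {
        btimb[k] = gibbs_coef(idx_timb[k], btimb[k], mu_d, d, sd_d, att,
                              1.0 / (sb[1] * sb[1]));
        gtimb[k] = gibbs_coef(idx_timb[k], gtimb[k], mu_b, bi, sd_b, att,
                              1.0 / (sg[1] * sg[1]));
      }
      for (int k = 0; k < 9; ++k) {
        bati[k] = gibbs_coef(idx_ati[k], bati[k], mu_d, d, sd_d, att,
                             1.0 / (sb[2] * sb[2]));
        gati[k] = gibbs_coef(idx_ati[k], gati[k], mu_b, bi, sd_b, att,
                             1.0 / (sg[2] * sg[2]));
      }
    }
    const int j_subj = has_timb ? 3 : 1;
    for (int k = 0; k < n_subj; ++k) {
      bsubj[k] = gibbs_coef(idx_subj[k], bsubj[k], mu_d, d, sd_d, att,
                            1.0 / (sb[j_subj] * sb[j_subj]));
      gsubj[k] = gibbs_coef(idx_subj[k], gsubj[k], mu_b, bi, sd_b, att,
                            1.0 / (sg[j_subj] * sg[j_subj]));
    }

    // --- translation moves along flat directions ---------------------------
    {
      double sd0 = std::sqrt(prior_var0);
      int t = 0;
      mh_translate(beta0, sd0, batt, seq3, sb[0], std::exp(a_trd.ls[t]),
                   a_trd.acc[t]);
      mh_translate(c0, sd0, gatt, seq3, sg[0], std::exp(a_trb.ls[t]),
                   a_trb.acc[t]);
      ++t;
      mh_translate(beta0, sd0, bsubj, seqS, sb[j_subj],
                   std::exp(a_trd.ls[t]), a_trd.acc[t]);
      mh_translate(c0, sd0, gsubj, seqS, sg[j_subj], std::exp(a_trb.ls[t]),
                   a_trb.acc[t]);
      ++t;
      if (has_timb) {
        mh_translate(beta0, sd0, btimb, seq3, sb[1], std::exp(a_trd.ls[t]),
                     a_trd.acc[t]);
        mh_translate(c0, sd0, gtimb, seq3, sg[1], std::exp(a_trb.ls[t]),
                     a_trb.acc[t]);
        ++t;
        for (int k = 0; k < 3; ++k) {
          mh_translate(batt[k], sb[0], bati, ati_row[k], sb[2],
                       std::exp(a_trd.ls[t]), a_trd.acc[t]);
          mh_translate(gatt[k], sg[0], gati, ati_row[k], sg[2],
                       std::exp(a_trb.ls[t]), a_trb.acc[t]);
          ++t;
        }
        for (int k = 0; k < 3; ++k) {
          mh_translate(btimb[k], sb[1], bati, ati_col[k], sb[2],
                       std::exp(a_trd.ls[t]), a_trd.acc[t]);
          mh_translate(gtimb[k], sg[1], gati, ati_col[k], sg[2],
                       std::exp(a_trb.ls[t]), a_trb.acc[t]);
          ++t;
        }
      }
    }

    // --- joint coefficient + latent shifts ----------------------------------
    {
      double sd0 = std::sqrt(prior_var0);
      for (int s = 0; s < n_subj; ++s) {
        mh_shift_group(bsubj[s], sb[j_subj], idx_subj[s], d, mu_d, bi, true,
                       H, ntri, FA, nntri, std::exp(a_shd.ls[s]),
                       a_shd.acc[s]);
        mh_shift_group(gsubj[s], sg[j_subj], idx_subj[s], bi, mu_b, d, false,
                       H, ntri, FA, nntri, std::exp(a_shb.ls[s]),
                       a_shb.acc[s]);
      }
      mh_shift_group(beta0, sd0, all_idx, d, mu_d, bi, true, H, ntri, FA,
                     nntri, std::exp(a_shd.ls[n_subj]), a_shd.acc[n_subj]);
      mh_shift_group(c0, sd0, all_idx, bi, mu_b, d, false, H, ntri, FA,
                     nntri, std::exp(a_shb.ls[n_subj]), a_shb.acc[n_subj]);
    }

    // --- residual standard deviations (Unif(0, upper) prior) --------------
    for (int k = 0; k < 3; ++k) {
      sd_d[k] = mh_sigma_unif(idx_att[k], sd_d[k], mu_d, d, sigma_upper,
                              std::exp(a_sdd.ls[k]), a_sdd.acc[k]);
      sd_b[k] = mh_sigma_unif(idx_att[k], sd_b[k], mu_b, bi, sigma_upper,
                              std::exp(a_sdb.ls[k]), a_sdb.acc[k]);
    }

    for (int k = 0; k < 3; ++k) {
      mh_sigma_rescale(sd_d[k], idx_att[k], mu_d, d, bi, true, H, ntri, FA,
                       nntri, sigma_upper, std::exp(a_rsd.ls[k]),
                       a_rsd.acc[k]);
      mh_sigma_rescale(sd_b[k], idx_att[k], mu_b, bi, d, false, H, ntri, FA,
                       nntri, sigma_upper, std::exp(a_rsb.ls[k]),
                       a_rsb.acc[k]);
    }

    // --- coefficient-group standard deviations (Gamma prior on sd) --------
    std::vector<double> grp;
    for (int j = 0; j < n_sb; ++j) {
      if (has_timb) {
        if (j == 0) grp = batt;
        else if (j == 1) grp = btimb;
        else if (j == 2) grp = bati;
        else grp = bsubj;
      } else {
        grp = (j == 0) ? batt : bsubj;
      }
      sb[j] = mh_sigma_gamma(grp, sb[j], gamma_shape, gamma_rate,
                             std::exp(a_sb.ls[j]), a_sb.acc[j]);
      if (has_timb) {
        if (j == 0) grp = gatt;
        else if (j == 1) grp = gtimb;
        else if (j == 2) grp = gati;
        else grp = gsubj;
      } else {
        grp = (j == 0) ? gatt : gsubj;
      }
      sg[j] = mh_sigma_gamma(grp, sg[j], gamma_shape, gamma_rate,
                             std::exp(a_sg.ls[j]), a_sg.acc[j]);
    }

    // --- adaptation (burn-in only) -----------------------------------------
    if (it <= burn_in && it % 50 == 0) {
      ++batch;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      a_d.adapt(delta); a_bi.adapt(delta);
      a_sdd.adapt(delta); a_sdb.adapt(delta);
      a_sb.adapt(delta); a_sg.adapt(delta);
      a_trd.adapt(delta); a_trb.adapt(delta);
      a_shd.adapt(delta); a_shb.adapt(delta);
      a_rsd.adapt(delta); a_rsb.adapt(delta);
    }

    // --- store --------------------------------------------------------------
    if (it > burn_in) {
      int row = it - burn_in - 1;
      int c = 0;
      for (int m = 0; m < M; ++m) out(row, c++) = d[m];
      for (int m = 0; m < M; ++m) out(row, c++) = bi[m];
      out(row, c++) = beta0;
      for (int k = 0; k < 3; ++k) out(row, c++) = batt[k];
      if (has_timb) {
        for (int k = 0; k < 3; ++k) out(row, c++) = btimb[k];
        for (int k = 0; k < 9; ++k) out(row, c++) = bati[k];
      }
      for (int k = 0; k < n_subj; ++k) out(row, c++) = bsubj[k];
      for (int k = 0; k < 3; ++k) out(row, c++) = sd_d[k];
      for (int j = 0; j < n_sb; ++j) out(row, c++) = sb[j];
      out(row, c++) = c0;
      for (int k = 0; k < 3; ++k) out(row, c++) = gatt[k];
      if (has_timb) {
        for (int k = 0; k < 3; ++k) out(row, c++) = gtimb[k];
        for (int k = 0; k < 9; ++k) out(row, c++) = gati[k];
      }
      for (int k = 0; k < n_subj; ++k) out(row, c++) = gsubj[k];
      for (int k = 0; k < 3; ++k) out(row, c++) = sd_b[k];
      for (int j = 0; j < n_sb; ++j) out(row, c++) = sg[j];
    }

    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
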