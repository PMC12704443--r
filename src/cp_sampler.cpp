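// Partially collapsed Gibbs sampler for the dual-trend state-space
// change-point model.
//
// Latent course per participant: mu[n, t] = mu1[n] + sum_{s < t} d[s],
// where the effective increment series d switches from the shared
// pre-trend to the shared post-trend at the change point tau (1-based
// index of the first observation governed by the post series):
//   d[s] = dpre[s]   for s <= tau - 2
//   d[s] = dpost[s]  for s >= tau - 1
// so the post series starts from the value the pre series has reached
// at the change point and the latent course is continuous, with a trend
// break between steps tau-1 and tau.  Observations are
// Y[n,t] ~ Normal(mu[n,t], sig_y[n]).  Each trend series is a Gaussian
// random walk over all steps with innovation scale sig_dpre / sig_dpost
// (half-Cauchy(0, 2.5) priors; increments on the inactive side of the
// break are informed by the prior alone), observation noise is
// per-participant half-Cauchy(0, 5), participant initial levels have
// vague Normal priors, and tau is uniform over interior steps.
//
// Conditional on tau and the scales the model is linear-Gaussian, so
// per sweep: (1) tau moves by Metropolis under the collapsed marginal
// likelihood with levels and trends integrated out analytically (this
// avoids the mode-sticking of a tau | theta draw); (2) the trend
// innovation scales also move under the collapsed marginal (removing
// the scale/increment funnel); (3) levels and both trend series are
// redrawn jointly from their exact multivariate normal conditional;
// (4) observation noise takes log-scale random-walk Metropolis steps
// with burn-in-only adaptation.  The per-candidate conditional
// log-likelihoods defining the marginalized likelihood are exposed
// (cpp_cp_marg_loglik) and give the Rao-Blackwellized change-point mass
// accumulated at record time.  Uses R's RNG throughout, so set.seed()
// before the call makes a chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double half_cauchy_log(double x, double scale) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0) - std::log(M_PI * scale) -
         std::log1p((x / scale) * (x / scale));
}

// Per-candidate change-point log-likelihoods given all continuous
// parameters; entry j corresponds to tau = j + 2 (interior candidates
// 2..T-1).  Uses sufficient statistics so the cost is O(nT + T^2).
static arma::vec tau_loglik(const arma::mat &Y, const arma::vec &mu1,
                            const arma::vec &cpre, const arma::vec &cpost,
                            const arma::vec &sy) {
  int n = Y.n_rows, T = Y.n_cols;
  arma::vec w = 1.0 / arma::square(sy);
  double W = arma::sum(w);
  double K = 0.0;                        // per-time normalizing constant
  for (int i = 0; i < n; ++i)
    K += -0.5 * std::log(2.0 * M_PI) - std::log(sy[i]);
  arma::vec q(T), Sw2(T);
  for (int t = 0; t < T; ++t) {
    double qq = 0, ss = 0;
    for (int i = 0; i < n; ++i) {
      double r = Y(i, t) - mu1[i];
      qq += w[i] * r * r;
      ss += w[i] * r;
    }
    q[t] = qq; Sw2[t] = ss;
  }
  // pre-model column log-likelihoods and their prefix sums
  arma::vec A(T);
  for (int t = 0; t < T; ++t)
    A[t] = K - 0.5 * (q[t] - 2 * cpre[t] * Sw2[t] + cpre[t] * cpre[t] * W);
  arma::vec preA = arma::cumsum(A);
  arma::vec ll(T - 2);
  for (int tau = 2; tau <= T - 1; ++tau) {
    // post mean at time t: cpre[tau-2] + cpost[t] - cpost[tau-2]
    // (0-based: the break is after step index tau-2)
    double shift = cpre[tau - 2] - cpost[tau - 2];
    double s_post = 0.0;
    for (int t = tau - 1; t < T; ++t) {
      double m = cpost[t] + shift;
      s_post += K - 0.5 * (q[t] - 2 * m * Sw2[t] + m * m * W);
    }
    ll[tau - 2] = preA[tau - 2] + s_post;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_cp_marg_loglik(const arma::mat &Y, const arma::vec &mu1,
                          const arma::vec &dpre, const arma::vec &dpost,
                          const arma::vec &sy) {
  int T = Y.n_cols;
  arma::vec cpre(T, arma::fill::zeros), cpost(T, arma::fill::zeros);
  for (int t = 1; t < T; ++t) {
    cpre[t] = cpre[t - 1] + dpre[t - 1];
    cpost[t] = cpost[t - 1] + dpost[t - 1];
  }
  arma::vec ll = tau_loglik(Y, mu1, cpre, cpost, sy);
  double m = ll.max();
  return m + std::log(arma::sum(arma::exp(ll - m))) -
         std::log((double)(T - 2));
}

struct GaussBlock {
  arma::mat R;        // upper Cholesky of the conditional precision
  arma::vec mean;
  double mll;         // collapsed log marginal (tau-free constants dropped)
};

// Joint Gaussian conditional of theta = (mu1, dpre, dpost) given tau and
// the scales, plus its collapsed marginal likelihood
// 0.5 * b' Lam^-1 b - 0.5 * log det Lam.  Step s (1-based increment
// index) is governed by the pre series for s <= tau - 2 and by the post
// series for s >= tau - 1; every observation with t > s uses the
// governing increment, so the data weight of step s is (T - s).
static bool build_block(const arma::mat &Y, const arma::vec &suf,
                        const arma::vec &w, double W,
                        const arma::vec &m0v, const arma::vec &s0v,
                        double sdp, double sdq, double delta1_sd,
                        int tau, GaussBlock &out) {
  int n = Y.n_rows, T = Y.n_cols, nd = T - 1, p = n + 2 * nd;
  arma::mat Lam(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    Lam(i, i) = w[i] * T + 1.0 / (s0v[i] * s0v[i]);
    b[i] = w[i] * arma::sum(Y.row(i)) + m0v[i] / (s0v[i] * s0v[i]);
  }
  // active column of step s: pre column for s <= tau-2, else post column
  std::vector<int> col(nd + 1);
  for (int s = 1; s <= nd; ++s)
    col[s] = (s <= tau - 2) ? (n + s - 1) : (n + nd + s - 1);
  for (int s = 1; s <= nd; ++s) {
    int cs = col[s];
    for (int i = 0; i < n; ++i) {
      Lam(i, cs) += w[i] * (T - s);
      Lam(cs, i) = Lam(i, cs);
    }
    b[cs] += suf[s + 1];
    for (int r = s; r <= nd; ++r) {
      double v = W * (T - r);
      Lam(cs, col[r]) += v;
      if (col[r] != cs) Lam(col[r], cs) = Lam(cs, col[r]);
    }
  }
  // random-walk prior precision over each full trend series
  for (int series = 0; series < 2; ++series) {
    int off = n + series * nd;
    double sv = series == 0 ? sdp : sdq;
    double qq = 1.0 / (sv * sv);
    Lam(off, off) += 1.0 / (delta1_sd * delta1_sd);
    for (int s = 1; s < nd; ++s) {
      Lam(off + s - 1, off + s - 1) += qq;
      Lam(off + s, off + s) += qq;
      Lam(off + s - 1, off + s) -= qq;
      Lam(off + s, off + s - 1) -= qq;
    }
  }
  if (!arma::chol(out.R, Lam)) return false;
  out.mean = arma::solve(arma::trimatu(out.R),
                         arma::solve(arma::trimatl(out.R.t()), b));
  double logdet = 2.0 * arma::sum(arma::log(out.R.diag()));
  out.mll = 0.5 * arma::dot(b, out.mean) - 0.5 * logdet;
  return true;
}

// Collapsed per-candidate log marginal likelihood (levels and trends
// integrated out) given the scales; exposed for testing.
// [[Rcpp::export]]
NumericVector cpp_cp_collapsed_ll(const arma::mat &Y, NumericVector sy,
                                  double sdp, double sdq,
                                  NumericVector m0, NumericVector s0,
                                  double delta1_sd) {
  int n = Y.n_rows, T = Y.n_cols;
  arma::vec syv(sy.begin(), n), m0v(m0.begin(), n), s0v(s0.begin(), n);
  arma::vec w = 1.0 / arma::square(syv);
  double W = arma::sum(w);
  arma::vec Sw(T), suf(T + 2, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += w[i] * Y(i, t);
    Sw[t] = s;
  }
  for (int t = T; t >= 1; --t) suf[t] = suf[t + 1] + Sw[t - 1];
  NumericVector out(T - 2);
  for (int tau = 2; tau <= T - 1; ++tau) {
    GaussBlock g;
    if (!build_block(Y, suf, w, W, m0v, s0v, sdp, sdq, delta1_sd, tau, g))
      out[tau - 2] = NA_REAL;
    else out[tau - 2] = g.mll;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cp_sampler(const arma::mat &Y, int iter, int burnin, int thin,
                    NumericVector mu1_init, NumericVector sy_init,
                    double sdp_init, double sdq_init, int tau_init,
                    NumericVector m0, NumericVector s0,
                    double delta1_sd, double scale_dd, double scale_dy,
                    int tau_moves = 4) {
  int n = Y.n_rows, T = Y.n_cols;
  if (T < 10) stop("need at least 10 time steps");
  if (iter <= burnin) stop("iter must exceed burnin");
  int nd = T - 1, p = n + 2 * nd;
  arma::vec mu1(mu1_init.begin(), n), sy(sy_init.begin(), n);
  double sdp = sdp_init, sdq = sdq_init;
  int tau = std::min(std::max(tau_init, 2), T - 1);
  arma::vec dpre(nd, arma::fill::zeros), dpost(nd, arma::fill::zeros);
  arma::vec m0v(m0.begin(), n), s0v(s0.begin(), n);

  int n_ret = (iter - burnin) / thin;
  int n_par = 2 * n + 2 * nd + 2;
  NumericMatrix draws(n_ret, n_par);
  IntegerVector tau_draws(n_ret);
  NumericVector tau_prob(T);
  double ls_sdp = 0.4, ls_sdq = 0.4;
  arma::vec ls_sy(n, arma::fill::value(0.25));
  int acc_sdp = 0, acc_sdq = 0; arma::ivec acc_sy(n, arma::fill::zeros);
  int batch = 50, rec = 0;
  arma::vec cpre(T), cpost(T), theta(p);

  for (int it = 0; it < iter; ++it) {
    arma::vec w = 1.0 / arma::square(sy);
    double W = arma::sum(w);
    arma::vec Sw(T), suf(T + 2, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      double s = 0;
      for (int i = 0; i < n; ++i) s += w[i] * Y(i, t);
      Sw[t] = s;
    }
    for (int t = T; t >= 1; --t) suf[t] = suf[t + 1] + Sw[t - 1];
    GaussBlock cur;
    if (!build_block(Y, suf, w, W, m0v, s0v, sdp, sdq, delta1_sd, tau, cur))
      stop("non-positive-definite conditional precision");
    // ---- collapsed update of tau ------------------------------------
    if (it % 10 == 0) {
      // exact categorical draw over all interior candidates (one
      // Cholesky each); guarantees mixing across distant tau modes
      std::vector<GaussBlock> blocks(T - 2);
      arma::vec mls(T - 2);
      for (int tc = 2; tc <= T - 1; ++tc) {
        if (!build_block(Y, suf, w, W, m0v, s0v, sdp, sdq, delta1_sd,
                         tc, blocks[tc - 2])) { mls[tc - 2] = R_NegInf; continue; }
        mls[tc - 2] = blocks[tc - 2].mll;
      }
      double mmax = mls.max();
      arma::vec pw = arma::exp(mls - mmax);
      double tot = arma::sum(pw);
      double u = unif_rand() * tot, csum = 0;
      int pick = T - 1;
      for (int j = 0; j < (int)pw.n_elem; ++j) {
        csum += pw[j];
        if (csum >= u) { pick = j + 2; break; }
      }
      tau = pick; cur = blocks[tau - 2];
    } else {
      // cheap Metropolis moves between candidates
      for (int mv = 0; mv < tau_moves; ++mv) {
        int tau_p = 2 + (int)std::floor(unif_rand() * (T - 2));
        if (tau_p > T - 1) tau_p = T - 1;
        if (tau_p == tau) continue;
        GaussBlock prop;
        if (!build_block(Y, suf, w, W, m0v, s0v, sdp, sdq, delta1_sd,
                         tau_p, prop)) continue;
        if (std::log(unif_rand()) < prop.mll - cur.mll) {
          tau = tau_p; cur = prop;
        }
      }
    }
    // ---- collapsed Metropolis moves on the trend scales -------------
    for (int series = 0; series < 2; ++series) {
      double &sv = series == 0 ? sdp : sdq;
      double &lsv = series == 0 ? ls_sdp : ls_sdq;
      int &accv = series == 0 ? acc_sdp : acc_sdq;
      double old = sv;
      double prop = old * std::exp(R::norm_rand() * lsv);
      GaussBlock gp;
      bool ok = build_block(Y, suf, w, W, m0v, s0v,
                            series == 0 ? prop : sdp,
                            series == 0 ? sdq : prop,
                            delta1_sd, tau, gp);
      if (ok) {
        // (nd - 1) * log(scale): normalization of the random-walk
        // prior, which the collapsed mll (posterior logdet only) does
        // not carry; plus half-Cauchy prior and proposal Jacobian
        double lr = gp.mll - cur.mll -
          (nd - 1) * (std::log(prop) - std::log(old)) +
          half_cauchy_log(prop, scale_dd) - half_cauchy_log(old, scale_dd) +
          std::log(prop) - std::log(old);
        if (std::log(unif_rand()) < lr) { sv = prop; cur = gp; ++accv; }
      }
    }
    // ---- joint mode-jump move on (tau, trend scales) ----------------
    // An unidentified scale (e.g. the pre scale when tau sits at the
    // first candidate) drifts under its prior, and large values pin the
    // tau conditional to the same candidate - a metastable mode.  An
    // independence proposal over (tau, sdp, sdq), accepted under the
    // collapsed posterior, lets the chain jump between such modes.
    for (int mv = 0; mv < 2; ++mv) {
      int tau_p = 2 + (int)std::floor(unif_rand() * (T - 2));
      if (tau_p > T - 1) tau_p = T - 1;
      // log-normal proposal spanning roughly 1e-4 .. 10
      const double mlog = std::log(0.02), slog = 2.5;
      double sp_p = std::exp(mlog + slog * R::norm_rand());
      double sq_p = std::exp(mlog + slog * R::norm_rand());
      GaussBlock gp;
      if (!build_block(Y, suf, w, W, m0v, s0v, sp_p, sq_p, delta1_sd,
                       tau_p, gp)) continue;
      double g_new = gp.mll - (nd - 1) * (std::log(sp_p) + std::log(sq_p)) +
        half_cauchy_log(sp_p, scale_dd) + half_cauchy_log(sq_p, scale_dd);
      double g_old = cur.mll - (nd - 1) * (std::log(sdp) + std::log(sdq)) +
        half_cauchy_log(sdp, scale_dd) + half_cauchy_log(sdq, scale_dd);
      double lq_new = R::dnorm(std::log(sp_p), mlog, slog, 1) - std::log(sp_p) +
        R::dnorm(std::log(sq_p), mlog, slog, 1) - std::log(sq_p);
      double lq_old = R::dnorm(std::log(sdp), mlog, slog, 1) - std::log(sdp) +
        R::dnorm(std::log(sdq), mlog, slog, 1) - std::log(sdq);
      if (std::log(unif_rand()) < g_new - g_old + lq_old - lq_new) {
        tau = tau_p; sdp = sp_p; sdq = sq_p; cur = gp;
      }
    }
    // ---- collapsed global rescale of the observation noise ----------
    // A common multiplicative move on all sig_y under the collapsed
    // marginal (theta integrated), so a badly scaled noise level can
    // relax without dragging the trend draws with it.  The full
    // marginal's -T * sum(log sy) normalization (dropped from mll) and
    // the data quadratic -0.5 * sum_i w_i sum_t Y^2 must enter the
    // ratio because both depend on sy.
    {
      double eps = R::norm_rand() * 0.3;
      double f = std::exp(eps);
      arma::vec sy_p = sy * f;
      arma::vec w_p = 1.0 / arma::square(sy_p);
      double W_p = arma::sum(w_p);
      arma::vec Sw_p(T), suf_p(T + 2, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        double s = 0;
        for (int i = 0; i < n; ++i) s += w_p[i] * Y(i, t);
        Sw_p[t] = s;
      }
      for (int t = T; t >= 1; --t) suf_p[t] = suf_p[t + 1] + Sw_p[t - 1];
      GaussBlock gp;
      if (build_block(Y, suf_p, w_p, W_p, m0v, s0v, sdp, sdq, delta1_sd,
                      tau, gp)) {
        double quad = 0;
        for (int i = 0; i < n; ++i) {
          double s2 = 0;
          for (int t = 0; t < T; ++t) s2 += Y(i, t) * Y(i, t);
          quad += s2 / (sy[i] * sy[i]);
        }
        double lr = gp.mll - cur.mll -
          0.5 * quad * (1.0 / (f * f) - 1.0) -
          n * T * eps;                   // -T * sum log sy_i change
        for (int i = 0; i < n; ++i)
          lr += half_cauchy_log(sy_p[i], scale_dy) -
            half_cauchy_log(sy[i], scale_dy);
        lr += n * eps;                   // log-scale proposal Jacobian
        if (std::log(unif_rand()) < lr) {
          sy = sy_p; w = w_p; W = W_p; Sw = Sw_p; suf = suf_p; cur = gp;
        }
      }
    }
    // ---- joint Gaussian draw of (mu1, dpre, dpost) | tau, scales ----
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
    theta = cur.mean + arma::solve(arma::trimatu(cur.R), z);
    mu1 = theta.subvec(0, n - 1);
    dpre = theta.subvec(n, n + nd - 1);
    dpost = theta.subvec(n + nd, p - 1);
    cpre[0] = 0; cpost[0] = 0;
    for (int t = 1; t < T; ++t) {
      cpre[t] = cpre[t - 1] + dpre[t - 1];
      cpost[t] = cpost[t - 1] + dpost[t - 1];
    }
    // ---- observation noise scales (log-scale Metropolis) -----------
    double shift = cpre[tau - 2] - cpost[tau - 2];
    for (int i = 0; i < n; ++i) {
      double sse = 0;
      for (int t = 0; t < T; ++t) {
        double m = (t + 1) <= (tau - 1) ? cpre[t] : (cpost[t] + shift);
        double r_ = Y(i, t) - mu1[i] - m;
        sse += r_ * r_;
      }
      double old = sy[i];
      double prop = old * std::exp(R::norm_rand() * ls_sy[i]);
      double lp_old = -T * std::log(old) - sse / (2 * old * old) +
        half_cauchy_log(old, scale_dy) + std::log(old);
      double lp_new = -T * std::log(prop) - sse / (2 * prop * prop) +
        half_cauchy_log(prop, scale_dy) + std::log(prop);
      if (std::log(unif_rand()) < lp_new - lp_old) { sy[i] = prop; ++acc_sy[i]; }
    }
    // ---- burn-in adaptation ----------------------------------------
    if (it < burnin && (it + 1) % batch == 0) {
      double f = (double)batch;
      ls_sdp *= std::exp(acc_sdp / f > 0.44 ? 0.12 : -0.12);
      ls_sdq *= std::exp(acc_sdq / f > 0.44 ? 0.12 : -0.12);
      for (int i = 0; i < n; ++i)
        ls_sy[i] *= std::exp(acc_sy[i] / f > 0.44 ? 0.12 : -0.12);
      acc_sdp = acc_sdq = 0; acc_sy.zeros();
    }
    // ---- record ----------------------------------------------------
    if (it >= burnin && (it - burnin) % thin == 0 && rec < n_ret) {
      int q = 0;
      for (int i = 0; i < n; ++i) draws(rec, q++) = mu1[i];
      for (int s = 0; s < nd; ++s) draws(rec, q++) = dpre[s];
      for (int s = 0; s < nd; ++s) draws(rec, q++) = dpost[s];
      draws(rec, q++) = sdp;
      draws(rec, q++) = sdq;
      for (int i = 0; i < n; ++i) draws(rec, q++) = sy[i];
      tau_draws[rec] = tau;
      // Rao-Blackwellized change-point mass given the current draw
      arma::vec ll2 = tau_loglik(Y, mu1, cpre, cpost, sy);
      double m2 = ll2.max();
      arma::vec w2 = arma::exp(ll2 - m2);
      w2 /= arma::sum(w2);
      for (int j = 0; j < (int)w2.n_elem; ++j) tau_prob[j + 1] += w2[j];
      ++rec;
    }
  }
  for (int t = 0; t < T; ++t) tau_prob[t] /= (double)n_ret;
  return List::create(_["draws"] = draws, _["tau"] = tau_draws,
                      _["tau_prob"] = tau_prob);
}
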