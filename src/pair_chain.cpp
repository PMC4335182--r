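#include <Rcpp.h>
using namespace Rcpp;

// Link families share the code used by alphaLink() on the R side:
//   0 = constant   alpha(pi) = coef
//   1 = exp-base   alpha(pi) = coef * (base^pi - 1)
//   2 = power      alpha(pi) = coef * pi^p
static inline double alpha_link_c(double pi, int fam, double par, double coef) {
  switch (fam) {
  case 0:  return coef;
  case 1:  return coef * (std::pow(par, pi) - 1.0);
  default: return coef * std::pow(pi, par);
  }
}

// Full conditional of pi up to an additive constant (log scale).
static double log_cond_pi(double pi, double logtheta1,
                          double Ssum, double NM,
                          double alpha0, double beta0,
                          double alpha1, double arest,
                          int fam, double par, double coef) {
  if (pi <= 0.0 || pi >= 1.0) return R_NegInf;
  double a = alpha_link_c(pi, fam, par, coef);
  return R::lgammafn(a + alpha1 + arest) - R::lgammafn(a + alpha1)
       + (Ssum + alpha0 - 1.0) * std::log(pi)
       + (NM - Ssum + beta0 - 1.0) * std::log1p(-pi)
       + a * logtheta1;
}

static void draw_theta(double *theta, const double *Zsum, double a,
                       const double *alphas) {
  double g[4], s = 0.0;
  g[0] = R::rgamma(Zsum[0] + a + alphas[0], 1.0);
  for (int i = 1; i < 4; ++i) g[i] = R::rgamma(Zsum[i] + alphas[i], 1.0);
  for (int i = 0; i < 4; ++i) s += g[i];
  for (int i = 0; i < 4; ++i) theta[i] = g[i] / s;
}

// Gibbs sampler with embedded Metropolis step for one region pair.
// Zsum: column sums of the N x 4 joint-activation counts; Ssum: sum of the
// per-subject tractography counts; NM = N * M. Proposal scale is adapted in
// batches of 50 during burn-in only (vanishing adaptation), then frozen.
// [[Rcpp::export]]
List pair_chain_cpp(NumericVector Zsum, double Ssum, double NM,
                    double alpha0, double beta0, NumericVector alphas,
                    int fam, double par, double coef,
                    int nIter, int nBurnin, int thin,
                    double jumpSd, double targetAcc, bool adapt) {
  const double a1 = alphas[0];
  const double arest = alphas[1] + alphas[2] + alphas[3];
  const int nKept = nIter / thin;
  NumericMatrix theta_out(nKept, 4);
  NumericVector pi_out(nKept);

  double zs[4], al[4];
  for (int i = 0; i < 4; ++i) { zs[i] = Zsum[i]; al[i] = alphas[i]; }

  double pi = (Ssum + alpha0) / (NM + alpha0 + beta0);
  if (pi <= 0.0) pi = 0.5;          // NM = 0 with alpha0 = 0 cannot occur (validity)
  double theta[4];
  draw_theta(theta, zs, alpha_link_c(pi, fam, par, coef), al);

  int kept = 0, accPost = 0, accBatch = 0, batch = 0;
  const int total = nBurnin + nIter;
  double lcur = log_cond_pi(pi, std::log(theta[0]), Ssum, NM,
                            alpha0, beta0, a1, arest, fam, par, coef);

  for (int t = 1; t <= total; ++t) {
    // theta | pi
    draw_theta(theta, zs, alpha_link_c(pi, fam, par, coef), al);
    double logtheta1 = std::log(theta[0]);
    lcur = log_cond_pi(pi, logtheta1, Ssum, NM,
                       alpha0, beta0, a1, arest, fam, par, coef);

    // pi | theta: Normal random-walk proposal, out-of-bounds rejected
    double prop = R::rnorm(pi, jumpSd);
    bool acc = false;
    if (prop > 0.0 && prop < 1.0) {
      double lprop = log_cond_pi(prop, logtheta1, Ssum, NM,
                                 alpha0, beta0, a1, arest, fam, par, coef);
      double lr = lprop - lcur;
      if (lr == lr && (lr >= 0.0 || R::runif(0.0, 1.0) < std::exp(lr))) {
        pi = prop;
        lcur = lprop;
        acc = true;
      }
    }

    if (t <= nBurnin) {
      if (adapt) {
        accBatch += acc ? 1 : 0;
        if (t % 50 == 0) {
          ++batch;
          double rate = accBatch / 50.0;
          double delta = std::min(0.25, 1.0 / std::sqrt((double)batch));
          jumpSd *= std::exp(rate > targetAcc ? delta : -delta);
          accBatch = 0;
        }
      }
    } else {
      accPost += acc ? 1 : 0;
      if ((t - nBurnin) % thin == 0) {
        for (int i = 0; i < 4; ++i) theta_out(kept, i) = theta[i];
        pi_out[kept] = pi;
        ++kept;
      }
    }
  }

  return List::create(_["theta"] = theta_out,
                      _["pi"] = pi_out,
                      _["acceptance_rate"] = accPost / (double)nIter,
                      _["jump_sd"] = jumpSd);
}
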