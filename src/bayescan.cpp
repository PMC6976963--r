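#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet-multinomial (beta-binomial) log-likelihood of one locus x pop
// cell given ancestral frequency p and theta = exp(-(alpha + beta)).
static inline double ll_one(int a, int n, double p, double theta) {
  if (n == 0) return 0.0;
  double tp = theta * p, tq = theta * (1.0 - p);
  return R::lgammafn(theta) - R::lgammafn(theta + n)
       + R::lgammafn(tp + a) - R::lgammafn(tp)
       + R::lgammafn(tq + (n - a)) - R::lgammafn(tq);
}

static inline double theta_of(double alpha_eff, double beta) {
  double x = alpha_eff + beta;
  if (x > 30.0) x = 30.0;
  if (x < -30.0) x = -30.0;
  return std::exp(-x);
}

static inline double logit(double p) { return std::log(p / (1.0 - p)); }
static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Reversible-jump MCMC for the logistic F_ST decomposition
// logit(F_ij) = alpha_i + beta_j with spike-and-slab alpha (prior odds for
// neutrality), uniform ancestral frequencies and N(beta_mu, beta_sd) beta.
// Pilot phase runs with all alpha included: adapts random-walk widths to
// acceptance in [0.25, 0.45] and calibrates per-locus independence
// proposals used by the jump moves.
// [[Rcpp::export]]
List bayescan_mcmc(IntegerMatrix a, IntegerMatrix n, double prior_odds,
                   int n_pilot, int pilot_len, int burn, int iters, int thin,
                   double alpha_prior_sd, double beta_mu, double beta_sd) {
  const int L = a.nrow(), J = a.ncol();
  const double log_pi_birth = -std::log(prior_odds); // log(pi/(1-pi))

  std::vector<double> p(L), alpha(L, 0.0), beta(J, beta_mu);
  std::vector<int> delta(L, 1);
  std::vector<double> sd_p(L, 0.5), sd_a(L, 0.5), sd_b(J, 0.2);
  std::vector<double> prop_m(L, 0.0), prop_s(L, 1.0);

  // init p at pooled sample frequency, shrunk away from the boundary
  for (int i = 0; i < L; ++i) {
    double num = 1.0, den = 2.0;
    for (int j = 0; j < J; ++j) { num += a(i, j); den += n(i, j); }
    p[i] = num / den;
  }

  NumericMatrix ll(L, J);
  std::vector<double> llrow(L, 0.0);
  auto refresh_row = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) {
      ll(i, j) = ll_one(a(i, j), n(i, j), p[i],
                        theta_of(delta[i] * alpha[i], beta[j]));
      s += ll(i, j);
    }
    llrow[i] = s;
  };
  for (int i = 0; i < L; ++i) refresh_row(i);

  std::vector<int> acc_p(L, 0), try_p(L, 0), acc_a(L, 0), try_a(L, 0);
  std::vector<int> acc_b(J, 0), try_b(J, 0);

  auto update_p = [&](int i) {
    double cur = logit(p[i]);
    double prop = cur + R::norm_rand() * sd_p[i];
    double pnew = inv_logit(prop);
    if (pnew < 1e-12 || pnew > 1.0 - 1e-12) return;
    double lnew = 0.0;
    std::vector<double> th(J);
    for (int j = 0; j < J; ++j) {
      th[j] = theta_of(delta[i] * alpha[i], beta[j]);
      lnew += ll_one(a(i, j), n(i, j), pnew, th[j]);
    }
    // uniform prior on p; symmetric RW on logit scale needs the Jacobian
    double lacc = lnew - llrow[i]
      + std::log(pnew * (1.0 - pnew)) - std::log(p[i] * (1.0 - p[i]));
    ++try_p[i];
    if (std::log(R::unif_rand()) < lacc) {
      ++acc_p[i];
      p[i] = pnew;
      double s = 0.0;
      for (int j = 0; j < J; ++j) {
        ll(i, j) = ll_one(a(i, j), n(i, j), p[i], th[j]);
        s += ll(i, j);
      }
      llrow[i] = s;
    }
  };

  auto update_alpha = [&](int i) {
    if (!delta[i]) return;
    double anew = alpha[i] + R::norm_rand() * sd_a[i];
    double lnew = 0.0;
    for (int j = 0; j < J; ++j)
      lnew += ll_one(a(i, j), n(i, j), p[i], theta_of(anew, beta[j]));
    double lacc = lnew - llrow[i]
      + R::dnorm(anew, 0.0, alpha_prior_sd, 1)
      - R::dnorm(alpha[i], 0.0, alpha_prior_sd, 1);
    ++try_a[i];
    if (std::log(R::unif_rand()) < lacc) {
      ++acc_a[i];
      alpha[i] = anew;
      refresh_row(i);
    }
  };

  auto update_beta = [&](int j) {
    double bnew = beta[j] + R::norm_rand() * sd_b[j];
    double lnew = 0.0;
    std::vector<double> col(L);
    for (int i = 0; i < L; ++i) {
      col[i] = ll_one(a(i, j), n(i, j), p[i],
                      theta_of(delta[i] * alpha[i], bnew));
      lnew += col[i];
    }
    double lold = 0.0;
    for (int i = 0; i < L; ++i) lold += ll(i, j);
    double lacc = lnew - lold
      + R::dnorm(bnew, beta_mu, beta_sd, 1)
      - R::dnorm(beta[j], beta_mu, beta_sd, 1);
    ++try_b[j];
    if (std::log(R::unif_rand()) < lacc) {
      ++acc_b[j];
      beta[j] = bnew;
      for (int i = 0; i < L; ++i) {
        llrow[i] += col[i] - ll(i, j);
        ll(i, j) = col[i];
      }
    }
  };

  auto rj_move = [&](int i) {
    if (delta[i]) { // death: drop alpha_i
      double lnew = 0.0;
      for (int j = 0; j < J; ++j)
        lnew += ll_one(a(i, j), n(i, j), p[i], theta_of(0.0, beta[j]));
      double lacc = lnew - llrow[i] - log_pi_birth
        + R::dnorm(alpha[i], prop_m[i], prop_s[i], 1)
        - R::dnorm(alpha[i], 0.0, alpha_prior_sd, 1);
      if (std::log(R::unif_rand()) < lacc) {
        delta[i] = 0;
        refresh_row(i);
      }
    } else { // birth: draw alpha_i from the calibrated proposal
      double anew = prop_m[i] + R::norm_rand() * prop_s[i];
      double lnew = 0.0;
      for (int j = 0; j < J; ++j)
        lnew += ll_one(a(i, j), n(i, j), p[i], theta_of(anew, beta[j]));
      double lacc = lnew - llrow[i] + log_pi_birth
        + R::dnorm(anew, 0.0, alpha_prior_sd, 1)
        - R::dnorm(anew, prop_m[i], prop_s[i], 1);
      if (std::log(R::unif_rand()) < lacc) {
        delta[i] = 1;
        alpha[i] = anew;
        refresh_row(i);
      }
    }
  };

  auto sweep = [&](bool with_rj) {
    for (int i = 0; i < L; ++i) update_p(i);
    for (int i = 0; i < L; ++i) update_alpha(i);
    if (with_rj) for (int i = 0; i < L; ++i) rj_move(i);
    for (int j = 0; j < J; ++j) update_beta(j);
  };

  // ---- pilot phase: all alpha in, adapt proposal widths ----
  std::vector<double> a_sum(L, 0.0), a_sumsq(L, 0.0);
  int a_count = 0;
  for (int r = 0; r < n_pilot; ++r) {
    std::fill(acc_p.begin(), acc_p.end(), 0);
    std::fill(try_p.begin(), try_p.end(), 0);
    std::fill(acc_a.begin(), acc_a.end(), 0);
    std::fill(try_a.begin(), try_a.end(), 0);
    std::fill(acc_b.begin(), acc_b.end(), 0);
    std::fill(try_b.begin(), try_b.end(), 0);
    for (int t = 0; t < pilot_len; ++t) {
      sweep(false);
      if (r >= n_pilot / 2) {
        for (int i = 0; i < L; ++i) {
          a_sum[i] += alpha[i];
          a_sumsq[i] += alpha[i] * alpha[i];
        }
        ++a_count;
      }
    }
    auto tune = [](double &sd, int acc, int tries) {
      if (tries == 0) return;
      double rate = (double)acc / tries;
      if (rate > 0.45) sd *= 1.3;
      else if (rate < 0.25) sd /= 1.3;
    };
    for (int i = 0; i < L; ++i) { tune(sd_p[i], acc_p[i], try_p[i]);
                                  tune(sd_a[i], acc_a[i], try_a[i]); }
    for (int j = 0; j < J; ++j) tune(sd_b[j], acc_b[j], try_b[j]);
  }
  for (int i = 0; i < L; ++i) {
    if (a_count > 1) {
      prop_m[i] = a_sum[i] / a_count;
      double var = a_sumsq[i] / a_count - prop_m[i] * prop_m[i];
      prop_s[i] = std::sqrt(std::max(var, 0.01));
    }
  }

  // ---- burn-in with jumps, starting from the neutral configuration ----
  std::fill(delta.begin(), delta.end(), 0);
  for (int i = 0; i < L; ++i) refresh_row(i);
  for (int t = 0; t < burn; ++t) sweep(true);

  // ---- sampling ----
  std::vector<double> post_prob(L, 0.0), alpha_mean(L, 0.0);
  std::vector<double> beta_mean(J, 0.0);
  std::vector<double> beta_first(J, 0.0), beta_second(J, 0.0);
  int kept = 0, kept_first = 0, kept_second = 0;
  for (int t = 0; t < iters; ++t) {
    sweep(true);
    if ((t + 1) % thin == 0) {
      ++kept;
      for (int i = 0; i < L; ++i) {
        post_prob[i] += delta[i];
        alpha_mean[i] += delta[i] * alpha[i];
      }
      for (int j = 0; j < J; ++j) {
        beta_mean[j] += beta[j];
        if (t < iters / 2) beta_first[j] += beta[j];
        else beta_second[j] += beta[j];
      }
      if (t < iters / 2) ++kept_first; else ++kept_second;
    }
  }
  double split_disagreement = 0.0;
  for (int j = 0; j < J; ++j) {
    beta_mean[j] /= kept;
    double b1 = kept_first ? beta_first[j] / kept_first : 0.0;
    double b2 = kept_second ? beta_second[j] / kept_second : 0.0;
    split_disagreement = std::max(split_disagreement, std::fabs(b1 - b2));
  }
  NumericVector pp(L), am(L);
  for (int i = 0; i < L; ++i) {
    pp[i] = post_prob[i] / kept;
    am[i] = alpha_mean[i] / kept;
  }
  return List::create(
    _["post_prob"] = pp,
    _["alpha_mean"] = am,
    _["beta_mean"] = NumericVector(beta_mean.begin(), beta_mean.end()),
    _["split_disagreement"] = split_disagreement,
    _["kept_samples"] = kept,
    _["proposal_mean"] = NumericVector(prop_m.begin(), prop_m.end()),
    _["proposal_sd"] = NumericVector(prop_s.begin(), prop_s.end())
  );
}
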