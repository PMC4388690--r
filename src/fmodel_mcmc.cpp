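#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical island F-model with reversible-jump moves on the per-locus,
// per-group selection effects alpha. Logit-transformed differentiation
// decomposes as logit(F_SC) = alpha_g(locus) + beta(pop) within a group and
// logit(F_CT) = beta_ct(group) above it. Population allele frequencies are
// integrated out analytically, leaving a beta-binomial likelihood per
// (locus, population) given the group pool frequency.

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double logistic(double x) {
  return 1.0 / (1.0 + std::exp(-clamp(x, -30.0, 30.0)));
}

static inline double lbeta_fast(double a, double b) {
  return std::lgamma(a) + std::lgamma(b) - std::lgamma(a + b);
}

// log Beta(x; a, b) density with the lgamma(a + b) term supplied by the
// caller (a + b is constant across loci within a sweep)
static inline double dbeta_log(double x, double a, double b, double lg_ab) {
  return (a - 1.0) * std::log(x) + (b - 1.0) * std::log1p(-x) -
         std::lgamma(a) - std::lgamma(b) + lg_ab;
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672741780329736406;
}

// beta-binomial log-likelihood without the binomial coefficient (constant
// in all Metropolis ratios); theta = (1 - F) / F
static inline double bb_ll(int a, int n, double pt, double f) {
  if (n == 0) return 0.0;
  double theta = (1.0 - f) / f;
  double s1 = theta * pt, s2 = theta * (1.0 - pt);
  return lbeta_fast(s1 + a, s2 + (n - a)) - lbeta_fast(s1, s2);
}

static inline double reflect01(double x) {
  // reflect a random-walk proposal back into (0,1)
  while (x <= 0.0 || x >= 1.0) {
    if (x <= 0.0) x = -x;
    if (x >= 1.0) x = 2.0 - x;
  }
  return clamp(x, 1e-9, 1.0 - 1e-9);
}

struct Scales {
  double p, pt, alpha, beta, beta_ct;
};

// [[Rcpp::export]]
List cpp_fmodel_scan(IntegerMatrix alt, IntegerMatrix tot, IntegerVector group,
                     int pilot_runs, int pilot_length, int burn_in,
                     int n_samples, int thinning,
                     double prior_odds, double alpha_sd,
                     double beta_mean, double beta_sd,
                     NumericVector gh_nodes, NumericVector gh_weights) {
  const int L = alt.nrow(), J = alt.ncol(), G = 2;
  const double log_prior_odds = std::log(prior_odds);

  // --- state ---
  std::vector<double> p(L), beta(J, beta_mean), beta_ct(G, beta_mean);
  std::vector<std::vector<double>> pt(G, std::vector<double>(L));
  std::vector<std::vector<double>> alpha(G, std::vector<double>(L, 0.0));
  std::vector<std::vector<char>> inc(G, std::vector<char>(L, 0));

  // init frequencies at pooled empirical values
  std::vector<std::vector<int>> pops_in(G);
  for (int j = 0; j < J; ++j) pops_in[group[j]].push_back(j);
  for (int i = 0; i < L; ++i) {
    double A = 0, N = 0;
    for (int j = 0; j < J; ++j) { A += alt(i, j); N += tot(i, j); }
    p[i] = clamp(N > 0 ? A / N : 0.5, 0.05, 0.95);
    for (int g = 0; g < G; ++g) {
      double Ag = 0, Ng = 0;
      for (int j : pops_in[g]) { Ag += alt(i, j); Ng += tot(i, j); }
      pt[g][i] = clamp(Ng > 0 ? Ag / Ng : p[i], 0.02, 0.98);
    }
  }

  // --- caches ---
  // ll_pop(i,j): beta-binomial loglik of pop j at locus i given pt, alpha, beta
  NumericMatrix ll_pop(L, J);
  // lp_pt[g][i]: log Beta density of pool freq given ancestral p and beta_ct
  std::vector<std::vector<double>> lp_pt(G, std::vector<double>(L));
  double theta_ct[2], lg_tct[2];
  for (int g = 0; g < G; ++g) {
    double f = logistic(beta_ct[g]);
    theta_ct[g] = (1.0 - f) / f;
    lg_tct[g] = std::lgamma(theta_ct[g]);
  }
  auto refresh_ll_pop = [&](int i, int j) {
    int g = group[j];
    double a_eff = inc[g][i] ? alpha[g][i] : 0.0;
    ll_pop(i, j) = bb_ll(alt(i, j), tot(i, j), pt[g][i],
                         logistic(a_eff + beta[j]));
  };
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < J; ++j) refresh_ll_pop(i, j);
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < L; ++i)
      lp_pt[g][i] = dbeta_log(pt[g][i], theta_ct[g] * p[i],
                              theta_ct[g] * (1.0 - p[i]), lg_tct[g]);

  Scales sc = {0.2, 0.1, 1.0, 0.2, 0.2};

  // samplers ------------------------------------------------------------
  long acc_p = 0, try_p = 0, acc_pt = 0, try_pt = 0, acc_a = 0, try_a = 0,
       acc_b = 0, try_b = 0, acc_bc = 0, try_bc = 0;

  std::vector<double> cand_ll(J);

  // Rao-Blackwellised accumulation at retained samples: conditional on the
  // current pool frequencies and population effects, the inclusion
  // probability of each group's locus effect integrates the likelihood
  // over the alpha prior (Gauss-Hermite nodes pre-scaled by the caller);
  // the two groups are conditionally independent, so the four model
  // probabilities are products of the per-group inclusion probabilities.
  const int K = gh_nodes.size();
  auto sweep = [&](bool count_rj, std::vector<std::vector<double>>* post_acc,
                   std::vector<std::vector<double>>* alpha_acc,
                   std::vector<std::vector<double>>* pinc_acc) {
    // ancestral frequencies
    for (int i = 0; i < L; ++i) {
      ++try_p;
      double pp = reflect01(p[i] + R::runif(-sc.p, sc.p));
      double lr = 0.0, lp_new[2];
      for (int g = 0; g < G; ++g) {
        lp_new[g] = dbeta_log(pt[g][i], theta_ct[g] * pp,
                              theta_ct[g] * (1.0 - pp), lg_tct[g]);
        lr += lp_new[g] - lp_pt[g][i];
      }
      if (std::log(R::unif_rand()) < lr) {
        p[i] = pp;
        for (int g = 0; g < G; ++g) lp_pt[g][i] = lp_new[g];
        ++acc_p;
      }
    }

    for (int g = 0; g < G; ++g) {
      const std::vector<int>& pj = pops_in[g];
      for (int i = 0; i < L; ++i) {
        // pool frequency
        ++try_pt;
        double cur = pt[g][i];
        double prop = reflect01(cur + R::runif(-sc.pt, sc.pt));
        double a_eff = inc[g][i] ? alpha[g][i] : 0.0;
        double lr = dbeta_log(prop, theta_ct[g] * p[i],
                              theta_ct[g] * (1.0 - p[i]), lg_tct[g]) -
                    lp_pt[g][i];
        double new_lp = lr + lp_pt[g][i];
        for (size_t k = 0; k < pj.size(); ++k) {
          int j = pj[k];
          cand_ll[j] = bb_ll(alt(i, j), tot(i, j), prop,
                             logistic(a_eff + beta[j]));
          lr += cand_ll[j] - ll_pop(i, j);
        }
        if (std::log(R::unif_rand()) < lr) {
          pt[g][i] = prop;
          lp_pt[g][i] = new_lp;
          for (int j : pj) ll_pop(i, j) = cand_ll[j];
          ++acc_pt;
        }

        // within-model alpha random walk
        if (inc[g][i]) {
          ++try_a;
          double ap = alpha[g][i] + R::norm_rand() * sc.alpha;
          double lr2 = dnorm_log(ap, 0.0, alpha_sd) -
                       dnorm_log(alpha[g][i], 0.0, alpha_sd);
          for (size_t k = 0; k < pj.size(); ++k) {
            int j = pj[k];
            cand_ll[j] = bb_ll(alt(i, j), tot(i, j), pt[g][i],
                               logistic(ap + beta[j]));
            lr2 += cand_ll[j] - ll_pop(i, j);
          }
          if (std::log(R::unif_rand()) < lr2) {
            alpha[g][i] = ap;
            for (int j : pj) ll_pop(i, j) = cand_ll[j];
            ++acc_a;
          }
        }

        // reversible jump: toggle inclusion of alpha_g at this locus.
        // Birth proposes alpha from its prior, so prior and proposal
        // densities cancel and the ratio reduces to the likelihood ratio
        // times the prior odds against selection.
        double lr3;
        if (!inc[g][i]) {
          double ap = R::norm_rand() * alpha_sd;
          lr3 = -log_prior_odds;
          for (size_t k = 0; k < pj.size(); ++k) {
            int j = pj[k];
            cand_ll[j] = bb_ll(alt(i, j), tot(i, j), pt[g][i],
                               logistic(ap + beta[j]));
            lr3 += cand_ll[j] - ll_pop(i, j);
          }
          if (std::log(R::unif_rand()) < lr3) {
            inc[g][i] = 1; alpha[g][i] = ap;
            for (int j : pj) ll_pop(i, j) = cand_ll[j];
          }
        } else {
          lr3 = log_prior_odds;
          for (size_t k = 0; k < pj.size(); ++k) {
            int j = pj[k];
            cand_ll[j] = bb_ll(alt(i, j), tot(i, j), pt[g][i],
                               logistic(beta[j]));
            lr3 += cand_ll[j] - ll_pop(i, j);
          }
          if (std::log(R::unif_rand()) < lr3) {
            inc[g][i] = 0; alpha[g][i] = 0.0;
            for (int j : pj) ll_pop(i, j) = cand_ll[j];
          }
        }
      }
    }

    // population effects beta
    for (int j = 0; j < J; ++j) {
      ++try_b;
      int g = group[j];
      double bp = beta[j] + R::norm_rand() * sc.beta;
      double lr = dnorm_log(bp, beta_mean, beta_sd) -
                  dnorm_log(beta[j], beta_mean, beta_sd);
      for (int i = 0; i < L; ++i) {
        double a_eff = inc[g][i] ? alpha[g][i] : 0.0;
        lr += bb_ll(alt(i, j), tot(i, j), pt[g][i],
                    logistic(a_eff + bp)) - ll_pop(i, j);
      }
      if (std::log(R::unif_rand()) < lr) {
        beta[j] = bp;
        for (int i = 0; i < L; ++i) {
          double a_eff = inc[g][i] ? alpha[g][i] : 0.0;
          ll_pop(i, j) = bb_ll(alt(i, j), tot(i, j), pt[g][i],
                               logistic(a_eff + beta[j]));
        }
        ++acc_b;
      }
    }

    // group divergence effects beta_ct
    for (int g = 0; g < G; ++g) {
      ++try_bc;
      double bp = beta_ct[g] + R::norm_rand() * sc.beta_ct;
      double f = logistic(bp);
      double th = (1.0 - f) / f;
      double lg_th = std::lgamma(th);
      double lr = dnorm_log(bp, beta_mean, beta_sd) -
                  dnorm_log(beta_ct[g], beta_mean, beta_sd);
      for (int i = 0; i < L; ++i)
        lr += dbeta_log(pt[g][i], th * p[i], th * (1.0 - p[i]), lg_th) -
              lp_pt[g][i];
      if (std::log(R::unif_rand()) < lr) {
        beta_ct[g] = bp;
        theta_ct[g] = th;
        lg_tct[g] = lg_th;
        for (int i = 0; i < L; ++i)
          lp_pt[g][i] = dbeta_log(pt[g][i], th * p[i], th * (1.0 - p[i]), lg_th);
        ++acc_bc;
      }
    }

    if (count_rj && post_acc) {
      for (int i = 0; i < L; ++i) {
        double pinc[2], amean_g[2];
        for (int g = 0; g < G; ++g) {
          const std::vector<int>& pj = pops_in[g];
          double ll0 = 0.0;
          for (int j : pj)
            ll0 += bb_ll(alt(i, j), tot(i, j), pt[g][i], logistic(beta[j]));
          double m_rel = 0.0, a_num = 0.0;
          for (int k = 0; k < K; ++k) {
            double llk = 0.0;
            for (int j : pj)
              llk += bb_ll(alt(i, j), tot(i, j), pt[g][i],
                           logistic(gh_nodes[k] + beta[j]));
            double r = gh_weights[k] * std::exp(clamp(llk - ll0, -700.0, 700.0));
            m_rel += r;
            a_num += r * gh_nodes[k];
          }
          pinc[g] = m_rel / (m_rel + prior_odds);
          amean_g[g] = m_rel > 0.0 ? a_num / m_rel : 0.0;
        }
        (*post_acc)[0][i] += (1.0 - pinc[0]) * (1.0 - pinc[1]);
        (*post_acc)[1][i] += pinc[0] * (1.0 - pinc[1]);
        (*post_acc)[2][i] += (1.0 - pinc[0]) * pinc[1];
        (*post_acc)[3][i] += pinc[0] * pinc[1];
        for (int g = 0; g < G; ++g) {
          (*alpha_acc)[g][i] += pinc[g] * amean_g[g];
          (*pinc_acc)[g][i] += pinc[g];
        }
      }
    }
  };

  // --- pilot runs: tune proposal scales into the 25-45% acceptance band ---
  auto tune = [](double& s, double acc, double lo, double hi) {
    if (acc < 0.25) s *= 0.7; else if (acc > 0.45) s *= 1.4;
    s = clamp(s, lo, hi);
  };
  for (int r = 0; r < pilot_runs; ++r) {
    acc_p = try_p = acc_pt = try_pt = acc_a = try_a = 0;
    acc_b = try_b = acc_bc = try_bc = 0;
    for (int it = 0; it < pilot_length; ++it)
      sweep(false, nullptr, nullptr, nullptr);
    tune(sc.p, try_p ? (double)acc_p / try_p : 0.35, 1e-3, 0.49);
    tune(sc.pt, try_pt ? (double)acc_pt / try_pt : 0.35, 1e-3, 0.49);
    if (try_a) tune(sc.alpha, (double)acc_a / try_a, 0.02, 5.0);
    tune(sc.beta, try_b ? (double)acc_b / try_b : 0.35, 0.01, 3.0);
    tune(sc.beta_ct, try_bc ? (double)acc_bc / try_bc : 0.35, 0.01, 3.0);
    Rcpp::checkUserInterrupt();
  }

  // --- burn-in ---
  for (int it = 0; it < burn_in; ++it) {
    sweep(false, nullptr, nullptr, nullptr);
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  // --- sampling ---
  std::vector<std::vector<double>> post_acc(4, std::vector<double>(L, 0.0));
  std::vector<std::vector<double>> alpha_acc(G, std::vector<double>(L, 0.0));
  std::vector<std::vector<double>> pinc_acc(G, std::vector<double>(L, 0.0));
  acc_p = try_p = acc_pt = try_pt = acc_a = try_a = 0;
  acc_b = try_b = acc_bc = try_bc = 0;
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thinning - 1; ++t)
      sweep(false, nullptr, nullptr, nullptr);
    sweep(true, &post_acc, &alpha_acc, &pinc_acc);
    if (s % 100 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix post(L, 4);
  NumericMatrix amean(L, G);
  for (int i = 0; i < L; ++i) {
    double tot_p = 0.0;
    for (int c = 0; c < 4; ++c) tot_p += post_acc[c][i];
    for (int c = 0; c < 4; ++c) post(i, c) = post_acc[c][i] / tot_p;
    for (int g = 0; g < G; ++g)
      amean(i, g) = pinc_acc[g][i] > 0.0 ? alpha_acc[g][i] / pinc_acc[g][i]
                                         : 0.0;
  }

  return List::create(
    _["post"] = post,            // columns: none, g1 only, g2 only, both
    _["alpha_mean"] = amean,     // posterior mean alpha | inclusion
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["beta_ct"] = NumericVector(beta_ct.begin(), beta_ct.end()),
    _["accept"] = NumericVector::create(
      _["p"] = try_p ? (double)acc_p / try_p : NA_REAL,
      _["pool"] = try_pt ? (double)acc_pt / try_pt : NA_REAL,
      _["alpha"] = try_a ? (double)acc_a / try_a : NA_REAL,
      _["beta"] = try_b ? (double)acc_b / try_b : NA_REAL,
      _["beta_ct"] = try_bc ? (double)acc_bc / try_bc : NA_REAL),
    _["scales"] = NumericVector::create(
      _["p"] = sc.p, _["pool"] = sc.pt, _["alpha"] = sc.alpha,
      _["beta"] = sc.beta, _["beta_ct"] = sc.beta_ct));
}

// Density-bin-matched null SUMSTAT draws for the gene set test: per draw,
// sample without replacement `need[b]` scores from each bin and sum them.
// [[Rcpp::export]]
NumericVector cpp_null_sumstat(List bin_scores, IntegerVector need,
                               int n_draws) {
  const int B = bin_scores.size();
  std::vector<std::vector<double>> sc(B);
  std::vector<std::vector<int>> idx(B);
  for (int b = 0; b < B; ++b) {
    NumericVector v = bin_scores[b];
    sc[b].assign(v.begin(), v.end());
    idx[b].resize(v.size());
    for (size_t k = 0; k < sc[b].size(); ++k) idx[b][k] = (int)k;
    if (need[b] > (int)sc[b].size())
      stop("density bin requires more genes than it contains");
  }
  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    double s = 0.0;
    for (int b = 0; b < B; ++b) {
      int m = need[b], n = (int)idx[b].size();
      for (int k = 0; k < m; ++k) {
        // partial Fisher-Yates; the array stays a permutation across draws
        int j = k + (int)(R::unif_rand() * (n - k));
        if (j >= n) j = n - 1;
        std::swap(idx[b][k], idx[b][j]);
        s += sc[b][idx[b][k]];
      }
    }
    out[d] = s;
    if ((d & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
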