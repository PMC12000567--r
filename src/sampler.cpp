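// Component-wise adaptive random-walk Metropolis sampler for the
// two-source ILR mixing model with taxon random intercepts/slopes, lake
// random intercepts and a multiplicative process-by-residual error factor.
//
// Parameter layout (fixed, length 2 + 2S + L + 4):
//   [0] beta0   [1] beta1
//   [2 .. 2+S-1]        b0 (taxon intercepts)
//   [2+S .. 2+2S-1]     b1 (taxon slopes)
//   [2+2S .. 2+2S+L-1]  u  (lake intercepts)
//   [2+2S+L]   sigma_sp0
//   [2+2S+L+1] sigma_sp1
//   [2+2S+L+2] sigma_lake
//   [2+2S+L+3] xi (multiplicative error)
// Inactive blocks (covariate or random effects disabled, xi fixed) stay at
// their initial values and are never proposed.
//
// Besides component-wise updates, three likelihood-invariant translation
// moves shift mass between the global intercept/slope and the matching
// random-effect block (beta0 vs u, beta0 vs b0, beta1 vs b1); they leave
// every linear predictor unchanged, so only the priors enter the
// acceptance ratio. These defeat the strong posterior correlation of the
// centered hierarchical parameterization.
//
// Per-observation log-likelihood terms are cached so each update touches
// only the observations its parameter enters.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double LN_SQRT_2PI = 0.918938533204672742;

struct Model {
  NumericVector y, x, tmean, amean;
  std::vector<double> tvar, avar, exvar;
  IntegerVector taxon, lake; // 0-based
  int n, S, L;
  bool use_cov, use_ranef;
  double beta_prior_sd, sd_upper, xi_upper;
  std::vector<std::vector<int> > by_taxon, by_lake;
  int i_s0, i_s1, i_sl, i_xi;
};

inline double ll_one(const Model& M, int i, const double* th) {
  const int S = M.S;
  const double phi = th[0] + th[2 + M.taxon[i]] + th[2 + 2 * S + M.lake[i]] +
    (th[1] + th[2 + S + M.taxon[i]]) * M.x[i];
  const double p = 1.0 / (1.0 + std::exp(-M_SQRT2 * phi));
  const double q = 1.0 - p;
  const double m = q * M.tmean[i] + p * M.amean[i];
  const double V = th[M.i_xi] * (q * q * M.tvar[i] + p * p * M.avar[i]) +
    M.exvar[i];
  if (!(V > 0.0)) return R_NegInf;
  const double r = M.y[i] - m;
  return -LN_SQRT_2PI - 0.5 * std::log(V) - r * r / (2.0 * V);
}

inline double dnorm0(double v, double sd) {
  if (!(sd > 0.0)) return R_NegInf;
  return -LN_SQRT_2PI - std::log(sd) - v * v / (2.0 * sd * sd);
}

// log prior contribution tied to parameter j (the only terms that change
// when component j moves)
double lp_component(const Model& M, int j, const double* th) {
  const int S = M.S, L = M.L;
  if (j <= 1) return dnorm0(th[j], M.beta_prior_sd);
  if (j < 2 + S) return dnorm0(th[j], th[M.i_s0]);
  if (j < 2 + 2 * S) return dnorm0(th[j], th[M.i_s1]);
  if (j < 2 + 2 * S + L) return dnorm0(th[j], th[M.i_sl]);
  if (j == M.i_s0) {
    if (th[j] <= 0.0 || th[j] > M.sd_upper) return R_NegInf;
    double s = 0.0;
    for (int k = 0; k < S; ++k) s += dnorm0(th[2 + k], th[j]);
    return s;
  }
  if (j == M.i_s1) {
    if (th[j] <= 0.0 || th[j] > M.sd_upper) return R_NegInf;
    double s = 0.0;
    for (int k = 0; k < S; ++k) s += dnorm0(th[2 + S + k], th[j]);
    return s;
  }
  if (j == M.i_sl) {
    if (th[j] <= 0.0 || th[j] > M.sd_upper) return R_NegInf;
    double s = 0.0;
    for (int k = 0; k < L; ++k) s += dnorm0(th[2 + 2 * S + k], th[j]);
    return s;
  }
  if (th[j] <= 0.0 || th[j] > M.xi_upper) return R_NegInf; // xi
  return 0.0;
}

double log_prior_full(const Model& M, const double* th) {
  double s = dnorm0(th[0], M.beta_prior_sd);
  if (M.use_cov) s += dnorm0(th[1], M.beta_prior_sd);
  if (M.use_ranef) {
    s += lp_component(M, M.i_s0, th);
    s += lp_component(M, M.i_sl, th);
    if (M.use_cov) s += lp_component(M, M.i_s1, th);
  }
  return s;
}

struct Adapt {
  std::vector<double> ls;
  std::vector<int> n_acc, n_try, acc_batch, try_batch;
  explicit Adapt(int k, double init_ls)
    : ls(k, init_ls), n_acc(k, 0), n_try(k, 0), acc_batch(k, 0), try_batch(k, 0) {}
  void hit(int j, bool acc) {
    ++n_try[j]; ++try_batch[j];
    if (acc) { ++n_acc[j]; ++acc_batch[j]; }
  }
  void tune(int batch) {
    const double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
    for (size_t j = 0; j < ls.size(); ++j) {
      if (try_batch[j] > 0) {
        const double rate = (double)acc_batch[j] / try_batch[j];
        ls[j] += (rate > 0.44) ? delta : -delta;
      }
      acc_batch[j] = 0; try_batch[j] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List run_chain_cpp(NumericVector y, NumericVector x,
                   IntegerVector taxon, IntegerVector lake,
                   NumericVector tmean, NumericVector tsd,
                   NumericVector amean, NumericVector asd,
                   NumericVector sdex,
                   int S, int L,
                   bool use_cov, bool use_ranef, bool xi_free,
                   double beta_prior_sd, double sd_upper, double xi_upper,
                   NumericVector init,
                   int n_iter, int n_burn, int thin,
                   bool keep_loglik) {
  Model M;
  M.y = y; M.x = x; M.taxon = taxon; M.lake = lake;
  M.tmean = tmean; M.amean = amean;
  M.n = y.size(); M.S = S; M.L = L;
  M.tvar.resize(M.n); M.avar.resize(M.n); M.exvar.resize(M.n);
  for (int i = 0; i < M.n; ++i) {
    M.tvar[i] = tsd[i] * tsd[i];
    M.avar[i] = asd[i] * asd[i];
    M.exvar[i] = sdex[i] * sdex[i];
  }
  M.use_cov = use_cov; M.use_ranef = use_ranef;
  M.beta_prior_sd = beta_prior_sd; M.sd_upper = sd_upper; M.xi_upper = xi_upper;
  M.by_taxon.assign(S, std::vector<int>());
  M.by_lake.assign(L, std::vector<int>());
  for (int i = 0; i < M.n; ++i) {
    M.by_taxon[taxon[i]].push_back(i);
    M.by_lake[lake[i]].push_back(i);
  }
  const int P = 2 + 2 * S + L + 4;
  M.i_s0 = 2 + 2 * S + L; M.i_s1 = M.i_s0 + 1; M.i_sl = M.i_s0 + 2;
  M.i_xi = M.i_s0 + 3;
  if (init.size() != P) stop("init has wrong length");
  std::vector<double> th(init.begin(), init.end());

  std::vector<int> active;
  active.push_back(0);
  if (use_cov) active.push_back(1);
  if (use_ranef) {
    for (int k = 0; k < S; ++k) active.push_back(2 + k);
    if (use_cov) for (int k = 0; k < S; ++k) active.push_back(2 + S + k);
    for (int k = 0; k < L; ++k) active.push_back(2 + 2 * S + k);
    active.push_back(M.i_s0);
    if (use_cov) active.push_back(M.i_s1);
    active.push_back(M.i_sl);
  }
  if (xi_free) active.push_back(M.i_xi);

  // per-observation log-likelihood cache and running total
  std::vector<double> cur_ll(M.n), new_ll(M.n);
  double total_ll = 0.0;
  for (int i = 0; i < M.n; ++i) { cur_ll[i] = ll_one(M, i, &th[0]); total_ll += cur_ll[i]; }

  Adapt comp((size_t)P, std::log(0.2));
  Adapt trans(3, std::log(0.2)); // translation moves: beta0/u, beta0/b0, beta1/b1

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, P);
  NumericVector lp_store(n_keep);
  NumericMatrix llmat(keep_loglik ? n_keep : 1, keep_loglik ? M.n : 1);
  int stored = 0, batch = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (size_t a = 0; a < active.size(); ++a) {
      const int j = active[a];
      const double old = th[j];
      const std::vector<int>* idx = 0;
      bool all_obs = false, no_lik = false;
      if (j == 0 || j == 1 || j == M.i_xi) all_obs = true;
      else if (j == M.i_s0 || j == M.i_s1 || j == M.i_sl) no_lik = true;
      else if (j < 2 + S) idx = &M.by_taxon[j - 2];
      else if (j < 2 + 2 * S) idx = &M.by_taxon[j - 2 - S];
      else idx = &M.by_lake[j - 2 - 2 * S];

      const double lp_old = lp_component(M, j, &th[0]);
      th[j] = old + std::exp(comp.ls[j]) * norm_rand();
      const double lp_new = lp_component(M, j, &th[0]);
      bool accept = false;
      double dll = 0.0;
      if (R_finite(lp_new)) {
        if (no_lik) {
          accept = std::log(unif_rand()) < (lp_new - lp_old);
        } else if (all_obs) {
          double s = 0.0;
          for (int i = 0; i < M.n; ++i) { new_ll[i] = ll_one(M, i, &th[0]); s += new_ll[i]; }
          dll = s - total_ll;
          accept = std::log(unif_rand()) < (lp_new - lp_old + dll);
          if (accept) { cur_ll.swap(new_ll); total_ll = s; }
        } else {
          double s_old = 0.0, s_new = 0.0;
          for (size_t k = 0; k < idx->size(); ++k) {
            const int i = (*idx)[k];
            s_old += cur_ll[i];
            new_ll[i] = ll_one(M, i, &th[0]);
            s_new += new_ll[i];
          }
          dll = s_new - s_old;
          accept = std::log(unif_rand()) < (lp_new - lp_old + dll);
          if (accept) {
            for (size_t k = 0; k < idx->size(); ++k) {
              const int i = (*idx)[k];
              cur_ll[i] = new_ll[i];
            }
            total_ll += dll;
          }
        }
      }
      if (!accept) th[j] = old;
      comp.hit(j, accept);
    }

    // translation moves: shift delta from a random-effect block into the
    // matching fixed effect; likelihood unchanged, priors only
    if (use_ranef) {
      { // beta0 vs u
        const double d = std::exp(trans.ls[0]) * norm_rand();
        double dlp = dnorm0(th[0] + d, M.beta_prior_sd) - dnorm0(th[0], M.beta_prior_sd);
        const double sl = th[M.i_sl];
        for (int l = 0; l < L; ++l) {
          const double v = th[2 + 2 * S + l];
          dlp += dnorm0(v - d, sl) - dnorm0(v, sl);
        }
        const bool acc = std::log(unif_rand()) < dlp;
        if (acc) {
          th[0] += d;
          for (int l = 0; l < L; ++l) th[2 + 2 * S + l] -= d;
        }
        trans.hit(0, acc);
      }
      { // beta0 vs b0
        const double d = std::exp(trans.ls[1]) * norm_rand();
        double dlp = dnorm0(th[0] + d, M.beta_prior_sd) - dnorm0(th[0], M.beta_prior_sd);
        const double s0 = th[M.i_s0];
        for (int k = 0; k < S; ++k) {
          const double v = th[2 + k];
          dlp += dnorm0(v - d, s0) - dnorm0(v, s0);
        }
        const bool acc = std::log(unif_rand()) < dlp;
        if (acc) {
          th[0] += d;
          for (int k = 0; k < S; ++k) th[2 + k] -= d;
        }
        trans.hit(1, acc);
      }
      if (use_cov) { // beta1 vs b1
        const double d = std::exp(trans.ls[2]) * norm_rand();
        double dlp = dnorm0(th[1] + d, M.beta_prior_sd) - dnorm0(th[1], M.beta_prior_sd);
        const double s1 = th[M.i_s1];
        for (int k = 0; k < S; ++k) {
          const double v = th[2 + S + k];
          dlp += dnorm0(v - d, s1) - dnorm0(v, s1);
        }
        const bool acc = std::log(unif_rand()) < dlp;
        if (acc) {
          th[1] += d;
          for (int k = 0; k < S; ++k) th[2 + S + k] -= d;
        }
        trans.hit(2, acc);
      }
    }

    // diminishing adaptation during burn-in, batches of 50 sweeps
    if (it <= n_burn && it % 50 == 0) {
      ++batch;
      comp.tune(batch);
      trans.tune(batch);
    }
    if (it > n_burn && (it - n_burn) % thin == 0 && stored < n_keep) {
      for (int jj = 0; jj < P; ++jj) draws(stored, jj) = th[jj];
      if (keep_loglik) for (int i = 0; i < M.n; ++i) llmat(stored, i) = cur_ll[i];
      lp_store[stored] = total_ll + log_prior_full(M, &th[0]);
      ++stored;
    }
  }

  NumericVector acc(P);
  for (int jj = 0; jj < P; ++jj)
    acc[jj] = comp.n_try[jj] > 0 ? (double)comp.n_acc[jj] / comp.n_try[jj] : NA_REAL;
  return List::create(_["draws"] = draws, _["log_posterior"] = lp_store,
                      _["loglik"] = llmat, _["accept"] = acc);
}
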