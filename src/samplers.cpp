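// Adaptive Metropolis-within-Gibbs samplers for the two hierarchical
// models: a binomial-logit GLMM with correlated per-dog (intercept, IgG
// slope) random effects, and a baseline-category multinomial-logit GLMM
// with independent per-dog, per-taxon random intercepts.
//
// Proposal scales adapt by Robbins-Monro during warmup only; fixed-effect
// blocks switch to a joint proposal whose covariance is estimated from the
// second quarter of warmup. All randomness comes from R's RNG so runs are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 35.0 ? x : std::log1p(std::exp(x));
}

// binomial log-likelihood kernel: y*eta - n*log(1+e^eta)
static inline double bin_ll(double y, double n, double eta) {
  return y * eta - n * softplus(eta);
}

// half-Student-t(3, 0, scale) log-density for sd > 0, plus log-sd Jacobian
static inline double half_t3_log(double sd, double scale, double log_sd) {
  double z = sd / scale;
  return -2.0 * std::log1p(z * z / 3.0) + log_sd;
}

struct Adapt {
  double log_s;
  double target;
  int t;
  Adapt(double init = 0.0, double tgt = 0.44) : log_s(init), target(tgt), t(0) {}
  double scale() const { return std::exp(log_s); }
  void update(double acc) {
    ++t;
    log_s += (acc - target) / std::pow(t + 1.0, 0.6);
    if (log_s < -12.0) log_s = -12.0;
    if (log_s > 6.0) log_s = 6.0;
  }
};

// Two-phase adaptation for a fixed-effect block: per-coordinate random walk
// in the first half of warmup (covariance learned from its second half),
// then joint multivariate-normal proposals with a globally adapted scale.
struct BlockAdapt {
  int P;
  std::vector<Adapt> coord;
  Adapt joint;
  arma::mat L;        // chol factor of learned covariance
  bool have_L;
  std::vector<arma::vec> history;
  BlockAdapt() {}
  void init(int p) {
    P = p;
    coord.assign(p, Adapt(std::log(0.1), 0.44));
    joint = Adapt(0.0, 0.234);
    have_L = false;
  }
  void learn_cov() {
    if ((int)history.size() < 10) { have_L = false; return; }
    arma::mat H(P, history.size());
    for (size_t i = 0; i < history.size(); ++i) H.col(i) = history[i];
    arma::mat S = arma::cov(H.t());
    S.diag() += 1e-8 + 1e-6 * arma::trace(S) / P;
    have_L = arma::chol(L, S, "lower");
    if (have_L) joint.log_s = std::log(2.38 / std::sqrt((double)P));
    history.clear();
  }
  // proposal covariance from a (Fisher) precision matrix: Sigma = Prec^-1
  void set_precision(const arma::mat& prec) {
    arma::mat S;
    if (arma::inv_sympd(S, prec)) {
      S = 0.5 * (S + S.t());
      S.diag() += 1e-12;
      have_L = arma::chol(L, S, "lower");
      if (have_L) joint.log_s = std::log(2.38 / std::sqrt((double)P));
    }
    if (!have_L) learn_cov();
    history.clear();
  }
};

// ---------------------------------------------------------------------------
// Flow-cytometry binomial model
// params: beta (P), u (D), v (D), log sigma_u, log sigma_v, atanh(rho)
// ---------------------------------------------------------------------------

static inline double bvn_log(double u, double v, double su, double sv,
                             double rho) {
  double zu = u / su, zv = v / sv, om = 1.0 - rho * rho;
  return -std::log(su) - std::log(sv) - 0.5 * std::log(om)
         - 0.5 * (zu * zu - 2.0 * rho * zu * zv + zv * zv) / om;
}

// [[Rcpp::export]]
NumericMatrix flow_mcmc_cpp(const arma::vec& y, const arma::vec& ntr,
                            const arma::mat& X, const arma::ivec& dog,
                            const arma::vec& ig, int n_dogs,
                            int warmup, int iter,
                            double prior_sd, double hyper_scale) {
  const int N = X.n_rows, P = X.n_cols, D = n_dogs;
  const int total = warmup + iter;
  const int w1 = warmup / 2;

  arma::vec beta(P, arma::fill::zeros);
  arma::vec u(D, arma::fill::zeros), v(D, arma::fill::zeros);
  double lsu = std::log(0.5), lsv = std::log(0.5), zr = 0.0;

  // crude initialisation: intercept at pooled empirical logit
  double ybar = arma::accu(y) / arma::accu(ntr);
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  beta(0) = std::log(ybar / (1.0 - ybar));

  std::vector<std::vector<int>> rows_of(D);
  for (int i = 0; i < N; ++i) rows_of[dog[i]].push_back(i);

  arma::vec eta = X * beta;
  for (int i = 0; i < N; ++i) eta[i] += u[dog[i]] + v[dog[i]] * ig[i];

  auto ll_rows = [&](const std::vector<int>& idx, const arma::vec& e) {
    double s = 0.0;
    for (int i : idx) s += bin_ll(y[i], ntr[i], e[i]);
    return s;
  };
  double ll_total = 0.0;
  for (int i = 0; i < N; ++i) ll_total += bin_ll(y[i], ntr[i], eta[i]);

  auto beta_prior = [&](const arma::vec& b) {
    if (prior_sd <= 0.0) return 0.0;
    return -0.5 * arma::dot(b, b) / (prior_sd * prior_sd);
  };

  BlockAdapt bad; bad.init(P);
  std::vector<Adapt> dog_ad(D, Adapt(std::log(0.2), 0.35));
  Adapt ad_lsu(std::log(0.3)), ad_lsv(std::log(0.3)), ad_zr(std::log(0.3));

  // Translation moves: a fixed-effect column that is constant within every
  // dog (x_ij = c_d, e.g. intercept or cohort indicators) is confounded
  // with the dog intercepts; a column of the form x_ij = ig_i * c_d (IgG
  // main effect and its dog-level interactions) is confounded with the dog
  // IgG slopes. Shifting beta_j by delta while subtracting delta * c_d from
  // u (or v) leaves the likelihood invariant, so the move is judged on the
  // random-effect prior alone and mixes the confounded direction rapidly.
  // type 0 = none, 1 = u-shift, 2 = v-shift
  std::vector<int> tr_type(P, 0);
  arma::mat tr_c(D, P, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    bool u_ok = true, v_ok = true;
    arma::vec cu(D, arma::fill::zeros), cv(D, arma::fill::zeros);
    arma::ivec seen_u(D, arma::fill::zeros), seen_v(D, arma::fill::zeros);
    for (int i = 0; i < N && (u_ok || v_ok); ++i) {
      int d = dog[i];
      if (u_ok) {
        if (!seen_u[d]) { cu[d] = X(i, p); seen_u[d] = 1; }
        else if (std::fabs(X(i, p) - cu[d]) > 1e-12) u_ok = false;
      }
      if (v_ok) {
        if (ig[i] == 0.0) { if (std::fabs(X(i, p)) > 1e-12) v_ok = false; }
        else if (!seen_v[d]) { cv[d] = X(i, p); seen_v[d] = 1; }
        else if (std::fabs(X(i, p) - cv[d]) > 1e-12) v_ok = false;
      }
    }
    if (u_ok && arma::accu(arma::abs(cu)) > 0) { tr_type[p] = 1; tr_c.col(p) = cu; }
    else if (v_ok && arma::accu(arma::abs(cv)) > 0) { tr_type[p] = 2; tr_c.col(p) = cv; }
  }
  std::vector<Adapt> tr_ad(P, Adapt(std::log(0.3), 0.44));

  NumericMatrix out(iter, P + 2 * D + 3);
  RNGScope rng;

  for (int t = 0; t < total; ++t) {
    bool adapting = t < warmup;
    double su = std::exp(lsu), sv = std::exp(lsv), rho = std::tanh(zr);

    // --- fixed effects: per-coordinate sweep every iteration ---
    for (int p = 0; p < P; ++p) {
      arma::vec b2 = beta;
      b2[p] += bad.coord[p].scale() * norm_rand();
      arma::vec de = X.col(p) * (b2[p] - beta[p]);
      double ll2 = 0.0;
      for (int i = 0; i < N; ++i) ll2 += bin_ll(y[i], ntr[i], eta[i] + de[i]);
      double lacc = ll2 + beta_prior(b2) - ll_total - beta_prior(beta);
      double a = std::min(1.0, std::exp(lacc));
      if (unif_rand() < a) { beta = b2; eta += de; ll_total = ll2; }
      if (adapting) bad.coord[p].update(a);
    }
    if (adapting && t >= w1 / 2 && t < w1) bad.history.push_back(beta);
    if (adapting && t == w1 - 1) {
      // Fisher information of beta at the current state (conditional on
      // the random effects): X' diag(n p (1-p)) X, plus prior precision
      arma::mat Hf(P, P, arma::fill::zeros);
      for (int i = 0; i < N; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        double w = ntr[i] * pi * (1.0 - pi);
        Hf += w * (X.row(i).t() * X.row(i));
      }
      if (prior_sd > 0.0) Hf.diag() += 1.0 / (prior_sd * prior_sd);
      else Hf.diag() += 1e-8;
      bad.set_precision(Hf);
    }
    // extra joint moves along the learned (Fisher) covariance
    if (bad.have_L && t >= w1) for (int rep = 0; rep < 3; ++rep) {
      arma::vec z(P);
      for (int p = 0; p < P; ++p) z[p] = norm_rand();
      arma::vec db = bad.joint.scale() * (bad.L * z);
      arma::vec de = X * db;
      double ll2 = 0.0;
      for (int i = 0; i < N; ++i) ll2 += bin_ll(y[i], ntr[i], eta[i] + de[i]);
      arma::vec b2 = beta + db;
      double lacc = ll2 + beta_prior(b2) - ll_total - beta_prior(beta);
      double a = std::min(1.0, std::exp(lacc));
      if (unif_rand() < a) { beta = b2; eta += de; ll_total = ll2; }
      if (adapting) bad.joint.update(a);
    }

    // --- translation moves along confounded directions (cheap: sweep 5x) ---
    for (int sweep = 0; sweep < 5; ++sweep)
    for (int p = 0; p < P; ++p) {
      if (!tr_type[p]) continue;
      double del = tr_ad[p].scale() * norm_rand();
      double lacc = 0.0;
      if (tr_type[p] == 1) {
        for (int d = 0; d < D; ++d) if (tr_c(d, p) != 0.0)
          lacc += bvn_log(u[d] - del * tr_c(d, p), v[d], su, sv, rho)
                - bvn_log(u[d], v[d], su, sv, rho);
      } else {
        for (int d = 0; d < D; ++d) if (tr_c(d, p) != 0.0)
          lacc += bvn_log(u[d], v[d] - del * tr_c(d, p), su, sv, rho)
                - bvn_log(u[d], v[d], su, sv, rho);
      }
      if (prior_sd > 0.0) {
        double b2 = beta[p] + del;
        lacc += -0.5 * (b2 * b2 - beta[p] * beta[p]) / (prior_sd * prior_sd);
      }
      double a = std::min(1.0, std::exp(lacc));
      if (unif_rand() < a) {
        beta[p] += del;
        if (tr_type[p] == 1)
          for (int d = 0; d < D; ++d) u[d] -= del * tr_c(d, p);
        else
          for (int d = 0; d < D; ++d) v[d] -= del * tr_c(d, p);
      }
      if (adapting) tr_ad[p].update(a);
    }

    // --- per-dog random effects (joint 2-d proposal) ---
    for (int d = 0; d < D; ++d) {
      double s = dog_ad[d].scale();
      double u2 = u[d] + s * norm_rand();
      double v2 = v[d] + s * norm_rand();
      const std::vector<int>& idx = rows_of[d];
      double ll_old = ll_rows(idx, eta);
      arma::vec e2 = eta;
      for (int i : idx) e2[i] += (u2 - u[d]) + (v2 - v[d]) * ig[i];
      double ll_new = ll_rows(idx, e2);
      double lacc = ll_new - ll_old
        + bvn_log(u2, v2, su, sv, rho) - bvn_log(u[d], v[d], su, sv, rho);
      double a = std::min(1.0, std::exp(lacc));
      if (unif_rand() < a) {
        for (int i : idx) eta[i] = e2[i];
        ll_total += ll_new - ll_old;
        u[d] = u2; v[d] = v2;
      }
      if (adapting) dog_ad[d].update(a);
    }

    // --- hyperparameters ---
    auto re_prior = [&](double s_u, double s_v, double r) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) s += bvn_log(u[d], v[d], s_u, s_v, r);
      return s;
    };
    double cur_re = re_prior(su, sv, rho);
    { // log sigma_u
      double l2 = lsu + ad_lsu.scale() * norm_rand();
      double a = 0.0;
      if (l2 > -10.0 && l2 < 5.0) {
        double s2 = std::exp(l2);
        double lacc = re_prior(s2, sv, rho) + half_t3_log(s2, hyper_scale, l2)
                    - cur_re - half_t3_log(su, hyper_scale, lsu);
        a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) { lsu = l2; su = s2; cur_re = re_prior(su, sv, rho); }
      }
      if (adapting) ad_lsu.update(a);
    }
    { // log sigma_v
      double l2 = lsv + ad_lsv.scale() * norm_rand();
      double a = 0.0;
      if (l2 > -10.0 && l2 < 5.0) {
        double s2 = std::exp(l2);
        double lacc = re_prior(su, s2, rho) + half_t3_log(s2, hyper_scale, l2)
                    - cur_re - half_t3_log(sv, hyper_scale, lsv);
        a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) { lsv = l2; sv = s2; cur_re = re_prior(su, sv, rho); }
      }
      if (adapting) ad_lsv.update(a);
    }
    { // atanh(rho); LKJ(1) prior is flat in rho, Jacobian log(1 - rho^2)
      double z2 = zr + ad_zr.scale() * norm_rand();
      double a = 0.0;
      if (std::fabs(z2) < 5.0) {
        double r2 = std::tanh(z2);
        double lacc = re_prior(su, sv, r2) + std::log1p(-r2 * r2)
                    - cur_re - std::log1p(-rho * rho);
        a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) { zr = z2; rho = r2; }
      }
      if (adapting) ad_zr.update(a);
    }

    if (t >= warmup) {
      int k = t - warmup;
      for (int p = 0; p < P; ++p) out(k, p) = beta[p];
      for (int d = 0; d < D; ++d) out(k, P + d) = u[d];
      for (int d = 0; d < D; ++d) out(k, P + D + d) = v[d];
      out(k, P + 2 * D) = std::exp(lsu);
      out(k, P + 2 * D + 1) = std::exp(lsv);
      out(k, P + 2 * D + 2) = std::tanh(zr);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Taxa baseline-category multinomial model
// params: beta (P x M, column-major), u (D x M), sigma (M)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix taxa_mcmc_cpp(const arma::mat& Y, const arma::mat& X,
                            const arma::ivec& dog, int n_dogs,
                            int warmup, int iter,
                            double prior_sd, double hyper_scale) {
  const int S = X.n_rows, P = X.n_cols, D = n_dogs;
  const int M = Y.n_cols - 1;  // last column is the "other" reference
  const int total = warmup + iter;
  const int w1 = warmup / 2;

  arma::vec Ntot = arma::sum(Y, 1);
  arma::mat beta(P, M, arma::fill::zeros);
  arma::mat u(D, M, arma::fill::zeros);
  arma::vec lsig(M, arma::fill::value(std::log(0.5)));

  // initialise intercepts at pooled empirical baseline-category logits
  arma::rowvec tot = arma::sum(Y, 0);
  double tot_other = std::max(tot[M], 1.0);
  for (int m = 0; m < M; ++m)
    beta(0, m) = std::log(std::max(tot[m], 0.5) / tot_other);

  std::vector<std::vector<int>> rows_of(D);
  for (int s = 0; s < S; ++s) rows_of[dog[s]].push_back(s);

  arma::mat eta = X * beta;
  for (int s = 0; s < S; ++s) eta.row(s) += u.row(dog[s]);

  // stable log(1 + sum_m exp(eta_sm)) and the per-sample log-likelihood
  auto row_ll = [&](int s, const arma::rowvec& e) {
    double mx = 0.0;
    for (int m = 0; m < M; ++m) if (e[m] > mx) mx = e[m];
    double acc = std::exp(-mx);
    for (int m = 0; m < M; ++m) acc += std::exp(e[m] - mx);
    double lden = mx + std::log(acc);
    double ll = -Ntot[s] * lden;
    for (int m = 0; m < M; ++m) ll += Y(s, m) * e[m];
    return ll;
  };
  arma::vec ll(S);
  for (int s = 0; s < S; ++s) ll[s] = row_ll(s, eta.row(s));

  double pvar = prior_sd * prior_sd;
  auto beta_prior = [&](const arma::vec& b) {
    return -0.5 * arma::dot(b, b) / pvar;
  };

  std::vector<BlockAdapt> bad(M);
  for (int m = 0; m < M; ++m) bad[m].init(P);
  std::vector<Adapt> u_ad(D * M, Adapt(std::log(0.2), 0.44));
  std::vector<Adapt> s_ad(M, Adapt(std::log(0.3), 0.44));

  // translation moves for columns constant within dog (intercept, cohort):
  // shift beta(p, m) and compensate u(., m); likelihood-invariant
  std::vector<int> tr_ok(P, 0);
  arma::mat tr_c(D, P, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    bool ok = true;
    arma::vec c(D, arma::fill::zeros);
    arma::ivec seen(D, arma::fill::zeros);
    for (int s = 0; s < S && ok; ++s) {
      int d = dog[s];
      if (!seen[d]) { c[d] = X(s, p); seen[d] = 1; }
      else if (std::fabs(X(s, p) - c[d]) > 1e-12) ok = false;
    }
    if (ok && arma::accu(arma::abs(c)) > 0) { tr_ok[p] = 1; tr_c.col(p) = c; }
  }
  std::vector<Adapt> tr_ad(P * M, Adapt(std::log(0.3), 0.44));

  NumericMatrix out(iter, P * M + D * M + M);
  RNGScope rng;

  for (int t = 0; t < total; ++t) {
    bool adapting = t < warmup;

    // --- fixed effects per taxon: coordinate sweep + joint AM move ---
    for (int m = 0; m < M; ++m) {
      arma::vec db(P);
      arma::rowvec e(M);
      auto try_move = [&](const arma::vec& dbv, Adapt& ad) {
        arma::vec de = X * dbv;
        double dll = 0.0;
        for (int s = 0; s < S; ++s) {
          e = eta.row(s); e[m] += de[s];
          dll += row_ll(s, e) - ll[s];
        }
        arma::vec b2 = beta.col(m) + dbv;
        double lacc = dll + beta_prior(b2) - beta_prior(beta.col(m));
        double a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) {
          beta.col(m) = b2;
          for (int s = 0; s < S; ++s) {
            eta(s, m) += de[s];
            ll[s] = row_ll(s, eta.row(s));
          }
        }
        if (adapting) ad.update(a);
      };
      for (int p = 0; p < P; ++p) {
        db.zeros();
        db[p] = bad[m].coord[p].scale() * norm_rand();
        try_move(db, bad[m].coord[p]);
      }
      if (adapting && t >= w1 / 2 && t < w1) bad[m].history.push_back(beta.col(m));
      if (adapting && t == w1 - 1) {
        // conditional Fisher information of beta_m: X' diag(N p (1-p)) X
        arma::mat Hf(P, P, arma::fill::zeros);
        for (int s = 0; s < S; ++s) {
          double mx = 0.0;
          for (int mm = 0; mm < M; ++mm) if (eta(s, mm) > mx) mx = eta(s, mm);
          double acc = std::exp(-mx);
          for (int mm = 0; mm < M; ++mm) acc += std::exp(eta(s, mm) - mx);
          double pm = std::exp(eta(s, m) - mx) / acc;
          double w = Ntot[s] * pm * (1.0 - pm);
          Hf += w * (X.row(s).t() * X.row(s));
        }
        Hf.diag() += 1.0 / pvar;
        bad[m].set_precision(Hf);
      }
      if (bad[m].have_L && t >= w1) for (int rep = 0; rep < 3; ++rep) {
        arma::vec z(P);
        for (int p = 0; p < P; ++p) z[p] = norm_rand();
        db = bad[m].joint.scale() * (bad[m].L * z);
        try_move(db, bad[m].joint);
      }
    }

    // --- translation moves along confounded directions (sweep 5x) ---
    for (int sweep = 0; sweep < 5; ++sweep)
    for (int m = 0; m < M; ++m) {
      double sg = std::exp(lsig[m]), sg2 = sg * sg;
      for (int p = 0; p < P; ++p) {
        if (!tr_ok[p]) continue;
        double del = tr_ad[p * M + m].scale() * norm_rand();
        double lacc = 0.0;
        for (int d = 0; d < D; ++d) if (tr_c(d, p) != 0.0) {
          double un = u(d, m) - del * tr_c(d, p);
          lacc += -0.5 * (un * un - u(d, m) * u(d, m)) / sg2;
        }
        double b2 = beta(p, m) + del;
        lacc += -0.5 * (b2 * b2 - beta(p, m) * beta(p, m)) / pvar;
        double a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) {
          beta(p, m) = b2;
          for (int d = 0; d < D; ++d) u(d, m) -= del * tr_c(d, p);
        }
        if (adapting) tr_ad[p * M + m].update(a);
      }
    }

    // --- per-dog, per-taxon random intercepts ---
    for (int d = 0; d < D; ++d) {
      const std::vector<int>& idx = rows_of[d];
      for (int m = 0; m < M; ++m) {
        double sg = std::exp(lsig[m]);
        double du = u_ad[d * M + m].scale() * norm_rand();
        double u2 = u(d, m) + du;
        double dll = 0.0;
        arma::rowvec e(M);
        for (int s : idx) {
          e = eta.row(s); e[m] += du;
          dll += row_ll(s, e) - ll[s];
        }
        double lacc = dll - 0.5 * (u2 * u2 - u(d, m) * u(d, m)) / (sg * sg);
        double a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) {
          u(d, m) = u2;
          for (int s : idx) {
            eta(s, m) += du;
            ll[s] = row_ll(s, eta.row(s));
          }
        }
        if (adapting) u_ad[d * M + m].update(a);
      }
    }

    // --- random-effect SDs ---
    for (int m = 0; m < M; ++m) {
      double l2 = lsig[m] + s_ad[m].scale() * norm_rand();
      double a = 0.0;
      if (l2 > -10.0 && l2 < 5.0) {
        double s_old = std::exp(lsig[m]), s_new = std::exp(l2);
        double ssq = arma::dot(u.col(m), u.col(m));
        double lacc =
          (-D * l2 - 0.5 * ssq / (s_new * s_new)
             + half_t3_log(s_new, hyper_scale, l2))
          - (-D * lsig[m] - 0.5 * ssq / (s_old * s_old)
             + half_t3_log(s_old, hyper_scale, lsig[m]));
        a = std::min(1.0, std::exp(lacc));
        if (unif_rand() < a) lsig[m] = l2;
      }
      if (adapting) s_ad[m].update(a);
    }

    if (t >= warmup) {
      int k = t - warmup, c = 0;
      for (int m = 0; m < M; ++m) for (int p = 0; p < P; ++p)
        out(k, c++) = beta(p, m);
      for (int m = 0; m < M; ++m) for (int d = 0; d < D; ++d)
        out(k, c++) = u(d, m);
      for (int m = 0; m < M; ++m) out(k, c++) = std::exp(lsig[m]);
    }
  }
  return out;
}
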