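// MCMC core for the Poisson spatio-temporal model with Leroux CAR spatial
// precision and AR(1) temporal evolution of the latent field.
//
//   Y[k,t] ~ Poisson(mu[k,t]),  log mu = x'beta + O + phi
//   phi_1 ~ N(0, tau2 Q(W,rhoS)^-1)
//   phi_t | phi_{t-1} ~ N(rhoT phi_{t-1}, tau2 Q(W,rhoS)^-1)
//   Q(W,rho) = rho (diag(W 1) - W) + (1 - rho) I      (Leroux)
//   beta ~ N(mu_beta, diag(sigma2_beta)); tau2 ~ IG(a,b); rho ~ U(0,1)
//
// Updates per sweep: componentwise adaptive random-walk Metropolis for beta,
// single-site Metropolis for phi (Gaussian full-conditional prior terms
// computed from the sparse neighbour structure), conjugate Gibbs for tau2,
// and logit-scale random-walk Metropolis for rhoS and rhoT. Adaptation of
// proposal scales happens during burn-in only. Uses R's RNG throughout so a
// fixed R seed gives bit-identical chains.

#include <Rcpp.h>
using namespace Rcpp;

// v' Q w with Q = rhoS (D - W) + (1 - rhoS) I, via neighbour lists
static double quad_Q(const NumericVector& v, const NumericVector& w,
                     const std::vector<std::vector<int>>& nbr,
                     const std::vector<double>& deg, double rhoS) {
  const int K = v.size();
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    double qkk = rhoS * deg[k] + (1.0 - rhoS);
    double cross = 0.0;
    for (int j : nbr[k]) cross += w[j];
    s += v[k] * (qkk * w[k] - rhoS * cross);
  }
  return s;
}

// full quadratic form phi' (M (x) Q) phi of the AR(1)-CAR prior
static double prior_quad(const NumericMatrix& phi,
                         const std::vector<std::vector<int>>& nbr,
                         const std::vector<double>& deg,
                         double rhoS, double rhoT) {
  const int K = phi.nrow(), N = phi.ncol();
  NumericVector e(K);
  double s = 0.0;
  for (int k = 0; k < K; ++k) e[k] = phi(k, 0);
  s += quad_Q(e, e, nbr, deg, rhoS);
  for (int t = 1; t < N; ++t) {
    for (int k = 0; k < K; ++k) e[k] = phi(k, t) - rhoT * phi(k, t - 1);
    s += quad_Q(e, e, nbr, deg, rhoS);
  }
  return s;
}

static double logdet_Q(const NumericVector& lap_eig, double rhoS) {
  double s = 0.0;
  for (double l : lap_eig) s += std::log(rhoS * l + 1.0 - rhoS);
  return s;
}

// [[Rcpp::export]]
List carar_chain(IntegerMatrix Y, NumericMatrix X, NumericMatrix offset,
                 List nbr_list, NumericVector lap_eig,
                 NumericVector beta0, NumericMatrix phi0,
                 double tau20, double rhoS0, double rhoT0,
                 NumericVector mu_beta, NumericVector sigma2_beta,
                 double a, double b,
                 int n_iter, int burn_in, int thin,
                 bool update_beta, bool update_phi, bool update_tau2,
                 bool update_rhoS, bool update_rhoT, bool center_phi,
                 bool keep_phi, bool use_lik, int intercept_col) {
  const int K = Y.nrow(), N = Y.ncol(), p = X.ncol();
  const int KN = K * N;

  std::vector<std::vector<int>> nbr(K);
  std::vector<double> deg(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector v = nbr_list[k];
    for (int j : v) nbr[k].push_back(j - 1);  // 1-based from R
    deg[k] = nbr[k].size();
  }

  NumericVector beta = clone(beta0);
  NumericMatrix phi = clone(phi0);
  double tau2 = tau20, rhoS = rhoS0, rhoT = rhoT0;

  // cached linear predictor and mean; X rows are k + K*t
  NumericMatrix eta(K, N), mu(K, N);
  for (int t = 0; t < N; ++t)
    for (int k = 0; k < K; ++k) {
      double lp = offset(k, t) + phi(k, t);
      for (int j = 0; j < p; ++j) lp += X(k + K * t, j) * beta[j];
      eta(k, t) = lp;
      mu(k, t) = std::exp(lp);
    }

  // proposal scales
  NumericVector sd_beta(p, 0.1);
  double sd_phi = 0.5, sd_rhoS = 0.5, sd_rhoT = 0.5, sd_shift = 0.1;
  std::vector<long> acc_beta(p, 0), try_beta(p, 0);
  long acc_phi = 0, try_phi = 0, acc_rhoS = 0, try_rhoS = 0,
       acc_rhoT = 0, try_rhoT = 0, acc_shift = 0, try_shift = 0;
  // windowed counters for adaptation
  std::vector<long> wacc_beta(p, 0), wtry_beta(p, 0);
  long wacc_phi = 0, wtry_phi = 0, wacc_rhoS = 0, wtry_rhoS = 0,
       wacc_rhoT = 0, wtry_rhoT = 0, wacc_shift = 0, wtry_shift = 0;
  // translation move beta0 -> beta0 + d, phi -> phi - d needs a constant
  // intercept column so the likelihood is exactly invariant
  bool do_shift = intercept_col >= 0 && update_beta && update_phi && use_lik
    && !center_phi;
  if (do_shift)
    for (int i = 0; i < KN; ++i)
      if (X(i, intercept_col) != 1.0) { do_shift = false; break; }

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix keep_beta(n_keep, p);
  NumericVector keep_tau2(n_keep), keep_rhoS(n_keep), keep_rhoT(n_keep);
  NumericMatrix keep_phi_mat(keep_phi ? n_keep : 0, keep_phi ? KN : 0);
  NumericMatrix phi_sum(K, N);

  RNGScope scope;
  int stored = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < burn_in;

    if (update_beta) {
      for (int j = 0; j < p; ++j) {
        double prop = beta[j] + sd_beta[j] * norm_rand();
        double delta = prop - beta[j];
        double dll = 0.0;
        if (use_lik)
          for (int t = 0; t < N; ++t)
            for (int k = 0; k < K; ++k) {
              double xv = X(k + K * t, j);
              if (xv == 0.0) continue;
              double de = delta * xv;
              dll += Y(k, t) * de - mu(k, t) * (std::exp(de) - 1.0);
            }
        dll += -0.5 * ((prop - mu_beta[j]) * (prop - mu_beta[j]) -
                       (beta[j] - mu_beta[j]) * (beta[j] - mu_beta[j])) /
               sigma2_beta[j];
        ++try_beta[j]; ++wtry_beta[j];
        if (std::log(unif_rand()) < dll) {
          ++acc_beta[j]; ++wacc_beta[j];
          beta[j] = prop;
          for (int t = 0; t < N; ++t)
            for (int k = 0; k < K; ++k) {
              double xv = X(k + K * t, j);
              if (xv == 0.0) continue;
              eta(k, t) += delta * xv;
              mu(k, t) = std::exp(eta(k, t));
            }
        }
      }
    }

    if (update_phi) {
      for (int t = 0; t < N; ++t) {
        double Mtt, rhoT2 = rhoT * rhoT;
        if (N == 1) Mtt = 1.0;
        else if (t == N - 1) Mtt = 1.0;
        else Mtt = 1.0 + rhoT2;
        for (int k = 0; k < K; ++k) {
          double qkk = rhoS * deg[k] + (1.0 - rhoS);
          double St = 0.0, Stm = 0.0, Stp = 0.0;
          for (int j : nbr[k]) {
            St += phi(j, t);
            if (t > 0) Stm += phi(j, t - 1);
            if (t < N - 1) Stp += phi(j, t + 1);
          }
          double blin = Mtt * rhoS * St;
          if (t > 0) blin += rhoT * qkk * phi(k, t - 1) - rhoT * rhoS * Stm;
          if (t < N - 1) blin += rhoT * qkk * phi(k, t + 1) - rhoT * rhoS * Stp;
          double prec = Mtt * qkk / tau2;
          double m = blin / (Mtt * qkk);  // = (blin/tau2) / prec
          double cur = phi(k, t);
          double prop = cur + sd_phi * norm_rand();
          double de = prop - cur;
          double dll =
            -0.5 * prec * ((prop - m) * (prop - m) - (cur - m) * (cur - m));
          if (use_lik) dll += Y(k, t) * de - mu(k, t) * (std::exp(de) - 1.0);
          ++try_phi; ++wtry_phi;
          if (std::log(unif_rand()) < dll) {
            ++acc_phi; ++wacc_phi;
            phi(k, t) = prop;
            eta(k, t) += de;
            mu(k, t) = std::exp(eta(k, t));
          }
        }
      }
      // joint translation beta0 + d, phi - d: likelihood invariant, so the
      // ratio involves only the priors; Q 1 = (1 - rhoS) 1 for any W since
      // (diag(W1) - W) 1 = 0, giving a closed-form prior quadratic change
      if (do_shift) {
        double d = sd_shift * norm_rand();
        double s1 = 0.0, SE = 0.0;
        for (int k = 0; k < K; ++k) s1 += phi(k, 0);
        for (int t = 1; t < N; ++t)
          for (int k = 0; k < K; ++k) SE += phi(k, t) - rhoT * phi(k, t - 1);
        double dquad = (1.0 - rhoS) *
          (-2.0 * d * (s1 + (1.0 - rhoT) * SE) +
           d * d * K * (1.0 + (N - 1) * (1.0 - rhoT) * (1.0 - rhoT)));
        double b0 = beta[intercept_col];
        double dll = -0.5 * dquad / tau2
          - 0.5 * ((b0 + d - mu_beta[intercept_col]) *
                     (b0 + d - mu_beta[intercept_col]) -
                   (b0 - mu_beta[intercept_col]) *
                     (b0 - mu_beta[intercept_col])) /
            sigma2_beta[intercept_col];
        ++try_shift; ++wtry_shift;
        if (std::log(unif_rand()) < dll) {
          ++acc_shift; ++wacc_shift;
          beta[intercept_col] += d;
          for (int t = 0; t < N; ++t)
            for (int k = 0; k < K; ++k) phi(k, t) -= d;
        }
      }

      if (center_phi) {
        for (int t = 0; t < N; ++t) {
          double mbar = 0.0;
          for (int k = 0; k < K; ++k) mbar += phi(k, t);
          mbar /= K;
          for (int k = 0; k < K; ++k) {
            phi(k, t) -= mbar;
            eta(k, t) -= mbar;
            mu(k, t) = std::exp(eta(k, t));
          }
        }
      }
    }

    if (update_tau2) {
      double quad = prior_quad(phi, nbr, deg, rhoS, rhoT);
      double shape = a + 0.5 * KN;
      double rate = b + 0.5 * quad;
      tau2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    if (update_rhoS) {
      double z = std::log(rhoS / (1.0 - rhoS));
      double zp = z + sd_rhoS * norm_rand();
      double prop = 1.0 / (1.0 + std::exp(-zp));
      double quad_cur = prior_quad(phi, nbr, deg, rhoS, rhoT);
      double quad_prop = prior_quad(phi, nbr, deg, prop, rhoT);
      double dll = 0.5 * N * (logdet_Q(lap_eig, prop) - logdet_Q(lap_eig, rhoS))
        - 0.5 * (quad_prop - quad_cur) / tau2
        + std::log(prop * (1.0 - prop)) - std::log(rhoS * (1.0 - rhoS));
      ++try_rhoS; ++wtry_rhoS;
      if (std::log(unif_rand()) < dll) { ++acc_rhoS; ++wacc_rhoS; rhoS = prop; }
    }

    if (update_rhoT) {
      double z = std::log(rhoT / (1.0 - rhoT));
      double zp = z + sd_rhoT * norm_rand();
      double prop = 1.0 / (1.0 + std::exp(-zp));
      double quad_cur = prior_quad(phi, nbr, deg, rhoS, rhoT);
      double quad_prop = prior_quad(phi, nbr, deg, rhoS, prop);
      double dll = -0.5 * (quad_prop - quad_cur) / tau2
        + std::log(prop * (1.0 - prop)) - std::log(rhoT * (1.0 - rhoT));
      ++try_rhoT; ++wtry_rhoT;
      if (std::log(unif_rand()) < dll) { ++acc_rhoT; ++wacc_rhoT; rhoT = prop; }
    }

    // adapt proposal scales during burn-in, every 100 iterations
    if (adapting && ((it + 1) % 100 == 0)) {
      for (int j = 0; j < p; ++j) {
        if (wtry_beta[j] >= 50) {
          double r = double(wacc_beta[j]) / wtry_beta[j];
          if (r > 0.5) sd_beta[j] *= 1.2; else if (r < 0.3) sd_beta[j] /= 1.2;
          wacc_beta[j] = wtry_beta[j] = 0;
        }
      }
      if (wtry_phi >= 50) {
        double r = double(wacc_phi) / wtry_phi;
        if (r > 0.5) sd_phi *= 1.2; else if (r < 0.3) sd_phi /= 1.2;
        wacc_phi = wtry_phi = 0;
      }
      if (wtry_rhoS >= 50) {
        double r = double(wacc_rhoS) / wtry_rhoS;
        if (r > 0.5) sd_rhoS *= 1.2; else if (r < 0.3) sd_rhoS /= 1.2;
        wacc_rhoS = wtry_rhoS = 0;
      }
      if (wtry_rhoT >= 50) {
        double r = double(wacc_rhoT) / wtry_rhoT;
        if (r > 0.5) sd_rhoT *= 1.2; else if (r < 0.3) sd_rhoT /= 1.2;
        wacc_rhoT = wtry_rhoT = 0;
      }
      if (wtry_shift >= 50) {
        double r = double(wacc_shift) / wtry_shift;
        if (r > 0.5) sd_shift *= 1.2; else if (r < 0.3) sd_shift /= 1.2;
        wacc_shift = wtry_shift = 0;
      }
    }

    if (it >= burn_in && ((it - burn_in + 1) % thin == 0) && stored < n_keep) {
      for (int j = 0; j < p; ++j) keep_beta(stored, j) = beta[j];
      keep_tau2[stored] = tau2;
      keep_rhoS[stored] = rhoS;
      keep_rhoT[stored] = rhoT;
      if (keep_phi)
        for (int t = 0; t < N; ++t)
          for (int k = 0; k < K; ++k)
            keep_phi_mat(stored, k + K * t) = phi(k, t);
      for (int t = 0; t < N; ++t)
        for (int k = 0; k < K; ++k) phi_sum(k, t) += phi(k, t);
      ++stored;
    }

    if ((it % 1000) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix phi_mean(K, N);
  if (stored > 0)
    for (int t = 0; t < N; ++t)
      for (int k = 0; k < K; ++k) phi_mean(k, t) = phi_sum(k, t) / stored;

  auto rate = [](long a, long t) { return t > 0 ? double(a) / t : NA_REAL; };
  double beta_acc = NA_REAL;
  {
    long at = 0, tt = 0;
    for (int j = 0; j < p; ++j) { at += acc_beta[j]; tt += try_beta[j]; }
    if (tt > 0) beta_acc = double(at) / tt;
  }

  return List::create(
    _["beta"] = keep_beta, _["tau2"] = keep_tau2,
    _["rho_s"] = keep_rhoS, _["rho_t"] = keep_rhoT,
    _["phi"] = keep_phi ? (SEXP)keep_phi_mat : R_NilValue,
    _["phi_mean"] = phi_mean,
    _["accept"] = List::create(
      _["beta"] = beta_acc, _["phi"] = rate(acc_phi, try_phi),
      _["rho_s"] = rate(acc_rhoS, try_rhoS),
      _["rho_t"] = rate(acc_rhoT, try_rhoT),
      _["shift"] = rate(acc_shift, try_shift)),
    _["proposal_sd"] = List::create(
      _["beta"] = sd_beta, _["phi"] = sd_phi,
      _["rho_s"] = sd_rhoS, _["rho_t"] = sd_rhoT),
    _["final"] = List::create(
      _["beta"] = beta, _["phi"] = phi, _["tau2"] = tau2,
      _["rho_s"] = rhoS, _["rho_t"] = rhoT));
}
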