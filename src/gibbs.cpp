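#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Blocked Gibbs sweep driver for the multinomial mixture with a truncated
// stick-breaking prior. Scan order within a sweep: psi | z, then V/beta | z,
// then z | beta, psi. Uses R's RNG so runs are reproducible via set.seed().
//
// When update_z is false the membership vector stays frozen at z_init (the
// conditional-refit mode); when update_beta is false beta stays at
// beta_fixed. Counts are consumed through a row-sparse representation since
// visitation matrices are mostly zeros.
//
// [[Rcpp::export]]
List gibbs_cpp(IntegerMatrix w, int K, double alpha, double eps,
               int n_iter, int burnin, int thin,
               IntegerVector z_init, bool update_z,
               bool update_beta, NumericVector beta_fixed) {
  const int J = w.nrow(), L = w.ncol();
  const int n_keep = (n_iter - burnin) / thin;

  // sparse rows of w
  std::vector<int> row_ptr(J + 1, 0);
  std::vector<int> cols;
  std::vector<double> vals;
  for (int j = 0; j < J; ++j) {
    for (int l = 0; l < L; ++l) {
      if (w(j, l) > 0) {
        cols.push_back(l);
        vals.push_back((double) w(j, l));
      }
    }
    row_ptr[j + 1] = (int) cols.size();
  }

  // log multinomial coefficients, constant across sweeps
  std::vector<double> log_coef(J);
  for (int j = 0; j < J; ++j) {
    double nj = 0.0, s = 0.0;
    for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p) {
      nj += vals[p];
      s += R::lgammafn(vals[p] + 1.0);
    }
    log_coef[j] = R::lgammafn(nj + 1.0) - s;
  }

  std::vector<int> z(J);
  for (int j = 0; j < J; ++j) {
    int zj = z_init[j];
    if (zj < 1 || zj > K) stop("initial membership out of range 1..K");
    z[j] = zj - 1;
  }

  std::vector<double> beta(K), V(K), log_beta(K);
  if (!update_beta) {
    if (beta_fixed.size() != K) stop("beta_fixed must have length K");
    for (int k = 0; k < K; ++k) { beta[k] = beta_fixed[k]; V[k] = NA_REAL; }
  }

  std::vector<double> psi(K * L), log_psi(K * L);
  std::vector<double> n_k(K), c_kl(K * L), lp(K);

  IntegerMatrix keep_z(n_keep, J);
  NumericMatrix keep_beta(n_keep, K), keep_V(n_keep, K);
  NumericVector keep_psi(n_keep * K * L);
  NumericVector loglik(n_iter);

  // log of the stick-breaking prior term of the collapsed membership
  // posterior: sum_{k<K} log B(1 + n_k, alpha + s_k), s_k = sum_{m>k} n_m
  auto stick_term = [&](const std::vector<double> &n) {
    double tail = 0.0, out = 0.0;
    for (int k = K - 1; k >= 1; --k) tail += n[k];
    for (int k = 0; k < K - 1; ++k) {
      out += R::lbeta(1.0 + n[k], alpha + tail);
      tail -= n[k + 1];
    }
    return out;
  };

  int stored = 0;
  for (int it = 0; it < n_iter; ++it) {
    std::fill(n_k.begin(), n_k.end(), 0.0);
    for (int j = 0; j < J; ++j) n_k[z[j]] += 1.0;

    // label-swap Metropolis moves on the collapsed membership posterior:
    // swapping the contents of two groups permutes the (label-invariant)
    // Dirichlet-multinomial factors, so only the stick prior term enters the
    // acceptance ratio. Freshly conjugate-drawing psi and beta given z below
    // keeps the joint chain exact; the moves let the chain hop between
    // label modes that single-site z updates traverse only rarely.
    if (update_z && K > 1) {
      double cur = stick_term(n_k);
      for (int rep = 0; rep < K; ++rep) {
        int a = (int) (unif_rand() * K);
        int b = (int) (unif_rand() * (K - 1));
        if (b >= a) ++b;
        if (a >= K || b >= K) continue;
        std::swap(n_k[a], n_k[b]);
        double prop = stick_term(n_k);
        if (std::log(unif_rand()) < prop - cur) {
          cur = prop;
          for (int j = 0; j < J; ++j) {
            if (z[j] == a) z[j] = b;
            else if (z[j] == b) z[j] = a;
          }
        } else {
          std::swap(n_k[a], n_k[b]);
        }
      }
    }

    // per-group location counts under current z
    std::fill(c_kl.begin(), c_kl.end(), 0.0);
    for (int j = 0; j < J; ++j) {
      int k = z[j];
      for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p)
        c_kl[k * L + cols[p]] += vals[p];
    }

    // psi | z : Dirichlet(eps + c_k.) per group via gamma draws
    for (int k = 0; k < K; ++k) {
      double tot = 0.0;
      for (int l = 0; l < L; ++l) {
        double g = R::rgamma(eps + c_kl[k * L + l], 1.0);
        psi[k * L + l] = g;
        tot += g;
      }
      if (tot <= 0.0) {  // all-underflow guard; fall back to uniform
        for (int l = 0; l < L; ++l) psi[k * L + l] = 1.0 / L;
        tot = 1.0;
        for (int l = 0; l < L; ++l) log_psi[k * L + l] = -std::log((double) L);
      } else {
        for (int l = 0; l < L; ++l) {
          psi[k * L + l] /= tot;
          log_psi[k * L + l] = std::log(psi[k * L + l]);
        }
      }
    }

    // V, beta | z : conjugate Beta updates of the sticks
    if (update_beta) {
      double tail = 0.0;
      for (int k = K - 1; k >= 0; --k) { V[k] = tail; tail += n_k[k]; }
      // V[k] now holds s_k = sum_{m>k} n_m
      double remain = 1.0;
      for (int k = 0; k < K - 1; ++k) {
        double v = R::rbeta(1.0 + n_k[k], alpha + V[k]);
        V[k] = v;
        beta[k] = v * remain;
        remain *= (1.0 - v);
      }
      V[K - 1] = 1.0;
      beta[K - 1] = remain;
    }
    for (int k = 0; k < K; ++k)
      log_beta[k] = beta[k] > 0.0 ? std::log(beta[k]) : R_NegInf;

    // z | beta, psi and the observed-data log-likelihood
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double s = log_beta[k];
        for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p)
          s += vals[p] * log_psi[k * L + cols[p]];
        lp[k] = s;
        if (s > m) m = s;
      }
      if (m == R_NegInf)
        stop("all group log-probabilities underflowed for individual %d", j + 1);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += std::exp(lp[k] - m);
      ll += log_coef[j] + m + std::log(tot);
      if (update_z) {
        double u = unif_rand() * tot, acc = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += std::exp(lp[k] - m);
          if (u <= acc) { pick = k; break; }
        }
        z[j] = pick;
      }
    }
    loglik[it] = ll;

    if (it + 1 > burnin && (it + 1 - burnin) % thin == 0 && stored < n_keep) {
      for (int j = 0; j < J; ++j) keep_z(stored, j) = z[j] + 1;
      for (int k = 0; k < K; ++k) {
        keep_beta(stored, k) = beta[k];
        keep_V(stored, k) = V[k];
        for (int l = 0; l < L; ++l)
          keep_psi[stored + n_keep * k + n_keep * K * l] = psi[k * L + l];
      }
      ++stored;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  keep_psi.attr("dim") = IntegerVector::create(n_keep, K, L);
  return List::create(_["z"] = keep_z, _["beta"] = keep_beta,
                      _["V"] = keep_V, _["psi"] = keep_psi,
                      _["loglik"] = loglik, _["n_keep"] = stored);
}
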