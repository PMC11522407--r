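// Metropolis-Hastings-within-Gibbs sampler for the spot-deconvolution model.
//
// Latent state per dataset (M mutations, K clones, S spots):
//   Pi  (S x K)  Beta(zeta_s/K, 1) feature-allocation probabilities
//   Z   (S x K)  Bernoulli(Pi) clone-presence indicators
//   G   (S x K)  Gamma(F'_k^Z F0^(1-Z), 1); H = G / rowSum(G)
//   Phi (M x K)  Gamma(r, p) expected per-cell coverage of variant i in clone k
//   N   (S)      Poisson(Lambda_s) cell counts, truncated to >= 1
// Likelihood:
//   D_is ~ Pois(N_s sum_k H_sk Phi_ik)
//   A_is ~ Binom(D_is, sum_k H_sk Phi_ik C_ik / sum_k H_sk Phi_ik)
//
// Incremental caches make one full sweep O(M*K*S_nz + S*K*M_nz) where
// *_nz counts entries with D > 0:
//   NG(i,s) = sum_k G_sk Phi_ik C_ik      (numerator, unnormalised by T_s)
//   DG(i,s) = sum_k G_sk Phi_ik           (denominator, unnormalised)
//   T(s)    = sum_k G_sk
//   SDG(s)  = sum_i DG(i,s) = sum_k G_sk * colSum(Phi)_k
// Binomial and Poisson terms share a log(DG) factor that cancels, so the
// per-site log-likelihood variable part reduces to
//   A log NG + (D - A) log(DG - NG) - N_s DG / T_s + D log(N_s / T_s).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double safe_log(double x) {
  return x > 0.0 ? std::log(x) : R_NegInf;
}

static inline double log_pnorm(double z) {
  return R::pnorm(z, 0.0, 1.0, 1, 1);
}

// zero-truncated normal draw (lower bound `lower`); mean >= 0 in all call
// sites, so rejection acceptance is >= 1/2 and the loop terminates fast
static double rtnorm(double mean, double sd, double lower) {
  for (;;) {
    double x = R::rnorm(mean, sd);
    if (x > lower) return x;
  }
}

// variable part of the site (i,s) data log-likelihood given unnormalised
// numerator ng and denominator dg
static inline double ll_site(int a, int d, double ng, double dg) {
  double out = 0.0;
  if (a > 0) out += a * safe_log(ng);
  int rem = d - a;
  if (rem > 0) out += rem * safe_log(dg - ng);
  return out;
}

// log proposal mass of integer m proposed from a rounded normal centred at
// c, truncated below 0.5 (so rounding always yields >= 1)
static double lq_int(int m, int c, double sigma) {
  double hi = R::pnorm((m + 0.5 - c) / sigma, 0.0, 1.0, 1, 0);
  double lo = R::pnorm((m - 0.5 - c) / sigma, 0.0, 1.0, 1, 0);
  double norm = R::pnorm((0.5 - c) / sigma, 0.0, 1.0, 0, 0);
  double mass = hi - lo;
  if (mass <= 0.0 || norm <= 0.0) return -1e300;
  return std::log(mass) - std::log(norm);
}

class Ctx {
public:
  int M, K, S;
  IntegerMatrix A, D;      // M x S
  NumericMatrix C;         // M x K
  NumericVector gshape1;   // K: Gamma shape for G when Z = 1 (floored F')
  double gshape0;          // Gamma shape for G when Z = 0 (F0)
  NumericVector zetaK;     // S: zeta_s / K
  double r, p;             // Gamma prior on Phi (shape, rate)
  NumericVector lambda;    // S

  NumericMatrix Pi, G, Phi;
  IntegerMatrix Z;
  IntegerVector N;

  NumericMatrix NG, DG;
  NumericVector T, SDG, phiColSum;
  NumericVector phi_scale;                  // per-site proposal scale (M)
  NumericVector sumD;                       // per spot
  std::vector< std::vector<int> > siteSpots; // spots with D(i,s) > 0, per site
  std::vector< std::vector<int> > spotSites; // sites with D(i,s) > 0, per spot

  Ctx(IntegerMatrix A_, IntegerMatrix D_, NumericMatrix C_,
      NumericVector gshape1_, double gshape0_, NumericVector zetaK_,
      double r_, double p_, NumericVector lambda_)
    : A(A_), D(D_), C(C_), gshape1(gshape1_), gshape0(gshape0_),
      zetaK(zetaK_), r(r_), p(p_), lambda(lambda_) {
    M = D.nrow();
    S = D.ncol();
    K = C.ncol();
    NG = NumericMatrix(M, S);
    DG = NumericMatrix(M, S);
    T = NumericVector(S);
    SDG = NumericVector(S);
    phiColSum = NumericVector(K);
    sumD = NumericVector(S);
    phi_scale = NumericVector(M, 1.0);
    siteSpots.resize(M);
    spotSites.resize(S);
    for (int s = 0; s < S; ++s) {
      double sd = 0.0;
      for (int i = 0; i < M; ++i) {
        if (D(i, s) > 0) {
          siteSpots[i].push_back(s);
          spotSites[s].push_back(i);
          sd += D(i, s);
        }
      }
      sumD[s] = sd;
    }
  }

  void refresh_caches() {
    for (int k = 0; k < K; ++k) {
      double cs = 0.0;
      for (int i = 0; i < M; ++i) cs += Phi(i, k);
      phiColSum[k] = cs;
    }
    for (int s = 0; s < S; ++s) {
      double t = 0.0, sdg = 0.0;
      for (int k = 0; k < K; ++k) {
        t += G(s, k);
        sdg += G(s, k) * phiColSum[k];
      }
      T[s] = t;
      SDG[s] = sdg;
      for (int i = 0; i < M; ++i) {
        double ng = 0.0, dg = 0.0;
        for (int k = 0; k < K; ++k) {
          double gp = G(s, k) * Phi(i, k);
          dg += gp;
          ng += gp * C(i, k);
        }
        NG(i, s) = ng;
        DG(i, s) = dg;
      }
    }
  }

  void init_state(IntegerVector n_init, NumericVector phi_init,
                  NumericMatrix g_init) {
    bool g_from_data = g_init.nrow() == S && g_init.ncol() == K;
    Pi = NumericMatrix(S, K);
    Z = IntegerMatrix(S, K);
    G = NumericMatrix(S, K);
    Phi = NumericMatrix(M, K);
    N = IntegerVector(S);
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < K; ++k) {
        Pi(s, k) = R::rbeta(zetaK[s], 1.0);
        Z(s, k) = 1;
        G(s, k) = g_from_data ? g_init(s, k) : R::rgamma(gshape1[k], 1.0);
        if (G(s, k) <= 0.0) G(s, k) = 1e-300;
      }
      N[s] = n_init[s] < 1 ? 1 : n_init[s];
    }
    bool from_data = phi_init.size() == M;
    for (int i = 0; i < M; ++i)
      for (int k = 0; k < K; ++k) {
        Phi(i, k) = from_data ? phi_init[i] : R::rgamma(r, 1.0 / p);
        if (Phi(i, k) <= 0.0) Phi(i, k) = 1e-300;
      }
    refresh_caches();
  }

  void sweep_pi() {
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K; ++k)
        Pi(s, k) = R::rbeta(zetaK[s] + Z(s, k), 2.0 - Z(s, k));
  }

  void sweep_z() {
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K; ++k) {
        double pi_ = Pi(s, k);
        int z;
        if (pi_ >= 1.0) z = 1;
        else if (pi_ <= 0.0) z = 0;
        else {
          double l1 = std::log(pi_) + R::dgamma(G(s, k), gshape1[k], 1.0, 1);
          double l0 = std::log1p(-pi_) + R::dgamma(G(s, k), gshape0, 1.0, 1);
          double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
          z = (R::unif_rand() < p1) ? 1 : 0;
        }
        Z(s, k) = z;
      }
  }

  int sweep_phi(double sigma, int &nprop) {
    std::vector<double> W(K);
    for (int k = 0; k < K; ++k) {
      double w = 0.0;
      for (int s = 0; s < S; ++s) w += N[s] * G(s, k) / T[s];
      W[k] = w;
    }
    int acc = 0;
    for (int i = 0; i < M; ++i) {
      double sd_i = sigma * phi_scale[i];
      for (int k = 0; k < K; ++k) {
        double xc = Phi(i, k);
        double xn = rtnorm(xc, sd_i, 0.0);
        double d = xn - xc;
        double lr = R::dgamma(xn, r, 1.0 / p, 1) - R::dgamma(xc, r, 1.0 / p, 1)
          - W[k] * d
          + log_pnorm(xc / sd_i) - log_pnorm(xn / sd_i);
        double cik = C(i, k);
        const std::vector<int> &ss = siteSpots[i];
        for (size_t u = 0; u < ss.size(); ++u) {
          int s = ss[u];
          double g = G(s, k);
          lr += ll_site(A(i, s), D(i, s), NG(i, s) + d * g * cik,
                        DG(i, s) + d * g)
              - ll_site(A(i, s), D(i, s), NG(i, s), DG(i, s));
        }
        ++nprop;
        if (std::log(R::unif_rand()) < lr) {
          ++acc;
          Phi(i, k) = xn;
          for (int s = 0; s < S; ++s) {
            double g = G(s, k);
            NG(i, s) += d * g * cik;
            DG(i, s) += d * g;
            SDG[s] += d * g;
          }
          phiColSum[k] += d;
        }
      }
    }
    return acc;
  }

  int sweep_g(double sigma, int &nprop) {
    int acc = 0;
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K; ++k) {
        double xc = G(s, k);
        double xn = rtnorm(xc, sigma, 0.0);
        double d = xn - xc;
        double shape = Z(s, k) == 1 ? gshape1[k] : gshape0;
        double Tn = T[s] + d;
        double SDGn = SDG[s] + d * phiColSum[k];
        double lr = R::dgamma(xn, shape, 1.0, 1) - R::dgamma(xc, shape, 1.0, 1)
          + log_pnorm(xc / sigma) - log_pnorm(xn / sigma)
          - (double)N[s] * (SDGn / Tn - SDG[s] / T[s]);
        if (sumD[s] > 0.0)
          lr += sumD[s] * (std::log(T[s]) - std::log(Tn));
        const std::vector<int> &si = spotSites[s];
        for (size_t u = 0; u < si.size(); ++u) {
          int i = si[u];
          double ph = Phi(i, k);
          lr += ll_site(A(i, s), D(i, s), NG(i, s) + d * ph * C(i, k),
                        DG(i, s) + d * ph)
              - ll_site(A(i, s), D(i, s), NG(i, s), DG(i, s));
        }
        ++nprop;
        if (std::log(R::unif_rand()) < lr) {
          ++acc;
          G(s, k) = xn;
          T[s] = Tn;
          SDG[s] = SDGn;
          for (int i = 0; i < M; ++i) {
            double ph = Phi(i, k);
            NG(i, s) += d * ph * C(i, k);
            DG(i, s) += d * ph;
          }
        }
      }
    return acc;
  }

  int sweep_n(double sigma, int &nprop) {
    int acc = 0;
    for (int s = 0; s < S; ++s) {
      int n0 = N[s];
      double t = rtnorm((double)n0, sigma, 0.5);
      int m = (int)std::lround(t);
      if (m < 1) m = 1;
      ++nprop;
      if (m == n0) { ++acc; continue; }
      double lr = R::dpois(m, lambda[s], 1) - R::dpois(n0, lambda[s], 1)
        - (double)(m - n0) * SDG[s] / T[s]
        + lq_int(n0, m, sigma) - lq_int(m, n0, sigma);
      if (sumD[s] > 0.0)
        lr += sumD[s] * std::log((double)m / (double)n0);
      if (std::log(R::unif_rand()) < lr) {
        ++acc;
        N[s] = m;
      }
    }
    return acc;
  }

  // full data log-likelihood (with constants), used as a convergence trace
  double data_loglik() {
    double ll = 0.0;
    for (int s = 0; s < S; ++s) {
      double invT = 1.0 / T[s];
      for (int i = 0; i < M; ++i) {
        double mu = N[s] * DG(i, s) * invT;
        double q = DG(i, s) > 0.0 ? NG(i, s) / DG(i, s) : 0.0;
        if (q < 0.0) q = 0.0;
        if (q > 1.0) q = 1.0;
        ll += R::dpois(D(i, s), mu, 1);
        ll += R::dbinom(A(i, s), D(i, s), q, 1);
      }
    }
    return ll;
  }
};

// [[Rcpp::export]]
List cpp_run_chain(IntegerMatrix A, IntegerMatrix D, NumericMatrix C,
                   NumericVector gshape1, double gshape0, NumericVector zetaK,
                   double r, double p, NumericVector lambda, bool fixed_n,
                   IntegerVector n_init, int n_iter, int burn_in, int thin,
                   int b_adapt, double r_opt, NumericVector sigma_init,
                   NumericVector phi_scale, NumericVector phi_init,
                   NumericMatrix g_init, bool store_traces) {
  Ctx ctx(A, D, C, gshape1, gshape0, zetaK, r, p, lambda);
  if (phi_scale.size() == ctx.M) ctx.phi_scale = phi_scale;
  ctx.init_state(n_init, phi_init, g_init);
  const int M = ctx.M, K = ctx.K, S = ctx.S;

  double s_phi = sigma_init[0], s_g = sigma_init[1], s_n = sigma_init[2];
  // tuning-window counters and post-burn-in counters, per block
  int wp_phi = 0, wa_phi = 0, wp_g = 0, wa_g = 0, wp_n = 0, wa_n = 0;
  double pp_phi = 0, pa_phi = 0, pp_g = 0, pa_g = 0, pp_n = 0, pa_n = 0;

  int kept_total = n_iter > burn_in ? (n_iter - burn_in - 1) / thin + 1 : 0;
  NumericMatrix Hsum(S, K), Phisum(M, K), Zsum(S, K);
  NumericVector Nsum(S);
  NumericVector ll_trace(kept_total);
  NumericMatrix trH, trPhi, trG, trPi;
  IntegerMatrix trN, trZ;
  if (store_traces) {
    trH = NumericMatrix(kept_total, S * K);
    trG = NumericMatrix(kept_total, S * K);
    trPi = NumericMatrix(kept_total, S * K);
    trPhi = NumericMatrix(kept_total, M * K);
    trN = IntegerMatrix(kept_total, S);
    trZ = IntegerMatrix(kept_total, S * K);
  }

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    ctx.sweep_pi();
    ctx.sweep_z();
    int np = 0, na = ctx.sweep_phi(s_phi, np);
    wa_phi += na; wp_phi += np;
    if (it >= burn_in) { pa_phi += na; pp_phi += np; }
    np = 0; na = ctx.sweep_g(s_g, np);
    wa_g += na; wp_g += np;
    if (it >= burn_in) { pa_g += na; pp_g += np; }
    if (!fixed_n) {
      np = 0; na = ctx.sweep_n(s_n, np);
      wa_n += na; wp_n += np;
      if (it >= burn_in) { pa_n += na; pp_n += np; }
    }

    // adapt proposal scales from block acceptance rates, burn-in only
    if (it < burn_in && b_adapt > 0 && (it + 1) % b_adapt == 0) {
      if (wp_phi > 0) s_phi *= 1.0 + ((double)wa_phi / wp_phi - r_opt);
      if (wp_g > 0) s_g *= 1.0 + ((double)wa_g / wp_g - r_opt);
      if (wp_n > 0) s_n *= 1.0 + ((double)wa_n / wp_n - r_opt);
      if (s_phi < 1e-4) s_phi = 1e-4; if (s_phi > 1e4) s_phi = 1e4;
      if (s_g < 1e-4) s_g = 1e-4; if (s_g > 1e4) s_g = 1e4;
      if (s_n < 0.25) s_n = 0.25; if (s_n > 1e4) s_n = 1e4;
      wp_phi = wa_phi = wp_g = wa_g = wp_n = wa_n = 0;
    }

    if ((it + 1) % 200 == 0) ctx.refresh_caches();

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int s = 0; s < S; ++s) {
        double invT = 1.0 / ctx.T[s];
        for (int k = 0; k < K; ++k) {
          Hsum(s, k) += ctx.G(s, k) * invT;
          Zsum(s, k) += ctx.Z(s, k);
        }
        Nsum[s] += ctx.N[s];
      }
      for (int i = 0; i < M; ++i)
        for (int k = 0; k < K; ++k) Phisum(i, k) += ctx.Phi(i, k);
      ll_trace[kept] = ctx.data_loglik();
      if (store_traces) {
        for (int s = 0; s < S; ++s) {
          double invT = 1.0 / ctx.T[s];
          for (int k = 0; k < K; ++k) {
            trH(kept, s + S * k) = ctx.G(s, k) * invT;
            trG(kept, s + S * k) = ctx.G(s, k);
            trPi(kept, s + S * k) = ctx.Pi(s, k);
            trZ(kept, s + S * k) = ctx.Z(s, k);
          }
          trN(kept, s) = ctx.N[s];
        }
        for (int i = 0; i < M; ++i)
          for (int k = 0; k < K; ++k) trPhi(kept, i + M * k) = ctx.Phi(i, k);
      }
      ++kept;
    }
  }

  double denom = kept > 0 ? (double)kept : 1.0;
  NumericMatrix Hmean(S, K), Phimean(M, K), Zmean(S, K);
  NumericVector Nmean(S);
  for (int s = 0; s < S; ++s) {
    for (int k = 0; k < K; ++k) {
      Hmean(s, k) = Hsum(s, k) / denom;
      Zmean(s, k) = Zsum(s, k) / denom;
    }
    Nmean[s] = Nsum[s] / denom;
  }
  for (int i = 0; i < M; ++i)
    for (int k = 0; k < K; ++k) Phimean(i, k) = Phisum(i, k) / denom;

  List out = List::create(
    Named("H_mean") = Hmean,
    Named("N_mean") = Nmean,
    Named("Phi_mean") = Phimean,
    Named("Z_mean") = Zmean,
    Named("kept") = kept,
    Named("accept_rates") = NumericVector::create(
      Named("phi") = pp_phi > 0 ? pa_phi / pp_phi : NA_REAL,
      Named("g") = pp_g > 0 ? pa_g / pp_g : NA_REAL,
      Named("n") = pp_n > 0 ? pa_n / pp_n : NA_REAL),
    Named("sigma_final") = NumericVector::create(
      Named("phi") = s_phi, Named("g") = s_g, Named("n") = s_n),
    Named("loglik_trace") = ll_trace);
  if (store_traces) {
    out["trace_H"] = trH;
    out["trace_G"] = trG;
    out["trace_Pi"] = trPi;
    out["trace_Phi"] = trPhi;
    out["trace_N"] = trN;
    out["trace_Z"] = trZ;
  }
  return out;
}

// ---- standalone single-sweep block updates (shared code path) --------------

// [[Rcpp::export]]
NumericMatrix cpp_gibbs_pi(IntegerMatrix Z, NumericVector zetaK) {
  int S = Z.nrow(), K = Z.ncol();
  NumericMatrix Pi(S, K);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < K; ++k)
      Pi(s, k) = R::rbeta(zetaK[s] + Z(s, k), 2.0 - Z(s, k));
  return Pi;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_z(NumericMatrix Pi, NumericMatrix G,
                          NumericVector gshape1, double gshape0) {
  int S = Pi.nrow(), K = Pi.ncol();
  IntegerMatrix Z(S, K);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < K; ++k) {
      double pi_ = Pi(s, k);
      int z;
      if (pi_ >= 1.0) z = 1;
      else if (pi_ <= 0.0) z = 0;
      else {
        double l1 = std::log(pi_) + R::dgamma(G(s, k), gshape1[k], 1.0, 1);
        double l0 = std::log1p(-pi_) + R::dgamma(G(s, k), gshape0, 1.0, 1);
        double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
        z = (R::unif_rand() < p1) ? 1 : 0;
      }
      Z(s, k) = z;
    }
  return Z;
}

static Ctx make_ctx(NumericMatrix Phi, NumericMatrix G, IntegerMatrix Z,
                    NumericMatrix C, IntegerMatrix A, IntegerMatrix D,
                    IntegerVector N, NumericVector gshape1, double gshape0,
                    double r, double p, NumericVector lambda) {
  int S = G.nrow();
  NumericVector zetaK(S, 1.0); // unused by MH sweeps
  Ctx ctx(A, D, C, gshape1, gshape0, zetaK, r, p, lambda);
  ctx.Phi = clone(Phi);
  ctx.G = clone(G);
  ctx.Z = clone(Z);
  ctx.N = clone(N);
  ctx.Pi = NumericMatrix(S, G.ncol());
  ctx.refresh_caches();
  return ctx;
}

// [[Rcpp::export]]
List cpp_mh_phi(NumericMatrix Phi, NumericMatrix G, NumericMatrix C,
                IntegerMatrix A, IntegerMatrix D, IntegerVector N,
                double r, double p, double sigma,
                Nullable<NumericVector> phi_scale = R_NilValue) {
  int S = G.nrow(), K = G.ncol();
  IntegerMatrix Z(S, K);
  NumericVector gshape1(K, 1.0), lambda(S, 1.0);
  Ctx ctx = make_ctx(Phi, G, Z, C, A, D, N, gshape1, 0.01, r, p, lambda);
  if (phi_scale.isNotNull()) {
    NumericVector ps(phi_scale);
    if (ps.size() == ctx.M) ctx.phi_scale = ps;
  }
  int np = 0;
  int na = ctx.sweep_phi(sigma, np);
  return List::create(Named("Phi") = ctx.Phi, Named("accepted") = na,
                      Named("proposed") = np);
}

// [[Rcpp::export]]
List cpp_mh_g(NumericMatrix G, IntegerMatrix Z, NumericMatrix Phi,
              NumericMatrix C, IntegerMatrix A, IntegerMatrix D,
              IntegerVector N, NumericVector gshape1, double gshape0,
              double sigma) {
  NumericVector lambda(G.nrow(), 1.0);
  Ctx ctx = make_ctx(Phi, G, Z, C, A, D, N, gshape1, gshape0, 1.0, 1.0, lambda);
  int np = 0;
  int na = ctx.sweep_g(sigma, np);
  int S = G.nrow(), K = G.ncol();
  NumericMatrix H(S, K);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < K; ++k) H(s, k) = ctx.G(s, k) / ctx.T[s];
  return List::create(Named("G") = ctx.G, Named("H") = H,
                      Named("accepted") = na, Named("proposed") = np);
}

// [[Rcpp::export]]
List cpp_mh_n(IntegerVector N, NumericMatrix G, NumericMatrix Phi,
              NumericMatrix C, IntegerMatrix A, IntegerMatrix D,
              NumericVector lambda, double sigma) {
  int S = G.nrow(), K = G.ncol();
  IntegerMatrix Z(S, K);
  NumericVector gshape1(K, 1.0);
  Ctx ctx = make_ctx(Phi, G, Z, C, A, D, N, gshape1, 0.01, 1.0, 1.0, lambda);
  int np = 0;
  int na = ctx.sweep_n(sigma, np);
  return List::create(Named("N") = ctx.N, Named("accepted") = na,
                      Named("proposed") = np);
}
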