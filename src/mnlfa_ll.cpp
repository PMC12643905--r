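#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal log-likelihood (and analytic gradient) of the moderated GRM.
//
// For person i with covariate row x_i:
//   lambda_ij = lambda0_j + Gamma[j,] . x_i
//   tau_ijc   = tau0[j,c] + B[j,] . x_i          (uniform shift of all thresholds)
//   eta_i ~ N(mu_i, s_i^2),  mu_i = Omega . x_i,  s_i^2 = exp(Kappa . x_i)
//   P(y >= c | eta) = logistic(lambda_ij * eta - tau_ijc)
// Category probabilities are adjacent differences of the cumulative curve.
//
// The marginal likelihood integrates the response-pattern probability over
// a standard-normal Gauss-Hermite rule (nodes u, weights w). With ten or
// more steep items the integrand f(eta) * N(eta; mu_i, s_i^2) is far
// narrower than the prior, so by default the rule is adapted per person:
// nodes are placed at nu_i + t_i * u with nu_i the posterior mode (damped
// Newton on the log-concave integrand) and t_i its curvature scale, and the
// integral is corrected by the density ratio. adaptive = false keeps the
// prior location-scale change of variable eta = mu_i + s_i * u.

static inline double logistic(double z) {
  if (z >= 0.0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// [[Rcpp::export(name = ".mnlfa_ll_cpp")]]
List mnlfa_ll_cpp(IntegerMatrix y, NumericMatrix X,
                  NumericMatrix tau0, NumericVector lambda0,
                  NumericMatrix B, NumericMatrix Gamma,
                  NumericVector Omega, NumericVector Kappa,
                  NumericVector nodes, NumericVector weights,
                  bool gradient, bool adaptive = true) {
  const int n = y.nrow(), J = y.ncol(), p = X.ncol();
  const int mm1 = tau0.ncol();           // m - 1 thresholds per item
  const int K = nodes.size();

  NumericMatrix g_tau(J, mm1), g_B(J, p), g_Gamma(J, p);
  NumericVector g_lambda(J), g_Omega(p), g_Kappa(p);
  double ll = 0.0;
  bool any_nonpos_lambda = false;

  // per-person scratch
  std::vector<double> bshift(J), lam(J);
  std::vector<double> ck(K), etak(K);
  std::vector<double> Aq(K * J), fLowP(K * J), fHighP(K * J);

  for (int i = 0; i < n; ++i) {
    double mu = 0.0, kap = 0.0;
    for (int q = 0; q < p; ++q) {
      mu  += Omega[q] * X(i, q);
      kap += Kappa[q] * X(i, q);
    }
    double s2 = std::exp(kap), s = std::exp(0.5 * kap);
    for (int j = 0; j < J; ++j) {
      double b = 0.0, g = 0.0;
      for (int q = 0; q < p; ++q) {
        b += B(j, q) * X(i, q);
        g += Gamma(j, q) * X(i, q);
      }
      bshift[j] = b;
      lam[j] = lambda0[j] + g;
      if (lam[j] <= 0.0) any_nonpos_lambda = true;
    }

    double nu = mu, tsc = s;  // adaptation centre and scale
    if (adaptive) {
      // damped Newton on g(eta) = sum_j log P_j + log prior; the graded
      // logistic pattern likelihood is log-concave, so this converges
      double d2 = -1.0 / s2;
      for (int it = 0; it < 12; ++it) {
        double d1 = -(nu - mu) / s2;
        d2 = -1.0 / s2;
        for (int j = 0; j < J; ++j) {
          int c = y(i, j);
          double Flow = 1.0, Fhigh = 0.0, flow = 0.0, fhigh = 0.0;
          double glow = 0.0, ghigh = 0.0;  // f * (1 - 2F) terms
          if (c >= 1) {
            Flow = logistic(lam[j] * nu - (tau0(j, c - 1) + bshift[j]));
            flow = Flow * (1.0 - Flow);
            glow = flow * (1.0 - 2.0 * Flow);
          }
          if (c <= mm1 - 1) {
            Fhigh = logistic(lam[j] * nu - (tau0(j, c) + bshift[j]));
            fhigh = Fhigh * (1.0 - Fhigh);
            ghigh = fhigh * (1.0 - 2.0 * Fhigh);
          }
          double P = Flow - Fhigh;
          if (P < 1e-30) P = 1e-30;
          double Pp = lam[j] * (flow - fhigh);
          double Ppp = lam[j] * lam[j] * (glow - ghigh);
          d1 += Pp / P;
          d2 += Ppp / P - (Pp / P) * (Pp / P);
        }
        if (d2 > -1e-10) d2 = -1.0 / s2;
        double step = d1 / d2;
        if (step > 1.5) step = 1.5; else if (step < -1.5) step = -1.5;
        nu -= step;
        if (std::fabs(step) < 1e-9) break;
      }
      tsc = 1.0 / std::sqrt(-d2);
    }

    double Li = 0.0;
    for (int k = 0; k < K; ++k) {
      double eta = nu + tsc * nodes[k];
      etak[k] = eta;
      double prod = 1.0;
      for (int j = 0; j < J; ++j) {
        int c = y(i, j);
        double Flow = 1.0, Fhigh = 0.0, flow = 0.0, fhigh = 0.0;
        if (c >= 1) {
          Flow = logistic(lam[j] * eta - (tau0(j, c - 1) + bshift[j]));
          flow = Flow * (1.0 - Flow);
        }
        if (c <= mm1 - 1) {
          Fhigh = logistic(lam[j] * eta - (tau0(j, c) + bshift[j]));
          fhigh = Fhigh * (1.0 - Fhigh);
        }
        double P = Flow - Fhigh;
        if (P < 1e-30) P = 1e-30;
        prod *= P;
        if (gradient) {
          double A = (flow - fhigh) / P;
          Aq[k * J + j] = A;
          fLowP[k * J + j] = flow / P;
          fHighP[k * J + j] = fhigh / P;
        }
      }
      double c_k;
      if (adaptive) {
        // density-ratio correction: N(eta; mu, s^2) / N(eta; nu, tsc^2)
        double d = (eta - mu) / s;
        c_k = weights[k] * (tsc / s) *
          std::exp(0.5 * nodes[k] * nodes[k] - 0.5 * d * d) * prod;
      } else {
        c_k = weights[k] * prod;
      }
      ck[k] = c_k;
      Li += c_k;
    }
    if (!R_finite(Li) || Li <= 0.0)
      stop("non-finite marginal likelihood contribution for person %d", i + 1);
    ll += std::log(Li);

    if (gradient) {
      for (int k = 0; k < K; ++k) {
        double W = ck[k] / Li;
        if (W == 0.0) continue;
        double eta = etak[k];
        double sumLamA = 0.0;
        for (int j = 0; j < J; ++j) {
          int c = y(i, j);
          double A = Aq[k * J + j];
          if (c >= 1)       g_tau(j, c - 1) += -W * fLowP[k * J + j];
          if (c <= mm1 - 1) g_tau(j, c)     +=  W * fHighP[k * J + j];
          g_lambda[j] += W * eta * A;
          sumLamA += lam[j] * A;
          for (int q = 0; q < p; ++q) {
            double xq = X(i, q);
            if (xq != 0.0) {
              g_B(j, q)     += -W * A * xq;
              g_Gamma(j, q) +=  W * eta * A * xq;
            }
          }
        }
        if (adaptive) {
          // nodes fixed: impact gradients flow through the explicit prior
          double d = (eta - mu) / s;
          for (int q = 0; q < p; ++q) {
            double xq = X(i, q);
            if (xq != 0.0) {
              g_Omega[q] += W * xq * d / s;
              g_Kappa[q] += W * xq * 0.5 * (d * d - 1.0);
            }
          }
        } else {
          // change-of-variable nodes eta = mu + s * u move with (mu, s)
          for (int q = 0; q < p; ++q) {
            double xq = X(i, q);
            if (xq != 0.0) {
              g_Omega[q] += W * sumLamA * xq;
              g_Kappa[q] += W * sumLamA * 0.5 * s * nodes[k] * xq;
            }
          }
        }
      }
    }
  }

  if (!gradient)
    return List::create(_["loglik"] = ll,
                        _["nonpos_lambda"] = any_nonpos_lambda);
  return List::create(_["loglik"] = ll,
                      _["g_tau"] = g_tau, _["g_lambda"] = g_lambda,
                      _["g_B"] = g_B, _["g_Gamma"] = g_Gamma,
                      _["g_Omega"] = g_Omega, _["g_Kappa"] = g_Kappa,
                      _["nonpos_lambda"] = any_nonpos_lambda);
}

// GRM response sampler used by the synthetic-data generator: one draw per
// person/item from the moderated category probabilities, given latent trait
// eta (already drawn in R) and uniform deviates u.
// [[Rcpp::export(name = ".grm_sample_cpp")]]
IntegerMatrix grm_sample_cpp(NumericVector eta, NumericMatrix X,
                             NumericMatrix tau0, NumericVector lambda0,
                             NumericMatrix B, NumericMatrix Gamma,
                             NumericMatrix u) {
  const int n = eta.size(), J = lambda0.size(), p = X.ncol();
  const int mm1 = tau0.ncol();
  IntegerMatrix y(n, J);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) {
      double b = 0.0, g = 0.0;
      for (int q = 0; q < p; ++q) {
        b += B(j, q) * X(i, q);
        g += Gamma(j, q) * X(i, q);
      }
      double lam = lambda0[j] + g;
      // inverse-CDF draw over categories 0..m-1
      double prev = 1.0;  // P(y >= c)
      int cat = mm1;      // default top category
      double ui = u(i, j);
      double acc = 0.0;
      for (int c = 0; c < mm1; ++c) {
        double cum = logistic(lam * eta[i] - (tau0(j, c) + b));
        acc += prev - cum;  // P(y == c)
        if (ui < acc) { cat = c; break; }
        prev = cum;
      }
      y(i, j) = cat;
    }
  }
  return y;
}
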