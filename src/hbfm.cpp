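#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Generalized inverse Gaussian sampler.
//
// Target density: f(x) ~ x^(p-1) exp(-(a*x + b/x)/2), x > 0, a > 0, b > 0.
// Strategy: reduce to the symmetric two-parameter form GIG(p, omega, omega)
// with omega = sqrt(a*b) via the scaling x = sqrt(b/a) * z, take t = log z
// shifted to the mode, and reject from a uniform/exponential envelope of the
// resulting log-concave density (Devroye, Statist. Comput. 2014). The
// envelope is tangent-based, so any anchor points t, s > 0 keep the sampler
// exact; the anchors below only tune the acceptance rate. Negative p uses
// the reciprocal identity 1/X ~ GIG(-p, b, a).
// ---------------------------------------------------------------------------

static inline double gig_psi(double x, double alpha, double lam) {
  return -alpha * (cosh(x) - 1.0) - lam * (exp(x) - x - 1.0);
}
static inline double gig_dpsi(double x, double alpha, double lam) {
  return -alpha * sinh(x) - lam * (exp(x) - 1.0);
}

// one draw from GIG(p, omega, omega), p >= 0, in the z parameterization
static double rgig_std(double lam, double omega) {
  double alpha = sqrt(omega * omega + lam * lam) - lam;

  // anchor t > 0
  double t, s, x;
  x = -gig_psi(1.0, alpha, lam);
  if (x >= 0.5 && x <= 2.0) t = 1.0;
  else if (x > 2.0) t = sqrt(2.0 / (alpha + lam));
  else t = log(4.0 / (alpha + 2.0 * lam));

  // anchor s > 0
  x = -gig_psi(-1.0, alpha, lam);
  if (x >= 0.5 && x <= 2.0) s = 1.0;
  else if (x > 2.0) s = sqrt(4.0 / (alpha * cosh(1.0) + lam));
  else {
    double s1 = (lam > 0.0) ? 1.0 / lam : R_PosInf;
    double s2 = log(1.0 + 1.0 / alpha + sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (s1 < s2) ? s1 : s2;
  }

  double eta = -gig_psi(t, alpha, lam);
  double zeta = -gig_dpsi(t, alpha, lam);
  double theta = -gig_psi(-s, alpha, lam);
  double xi = gig_dpsi(-s, alpha, lam);
  double pp = 1.0 / xi;
  double rr = 1.0 / zeta;
  double td = t - rr * eta;
  double sd = s - pp * theta;
  double q = td + sd;

  double u, v, w, xx, chi;
  for (;;) {
    u = unif_rand();
    v = unif_rand();
    w = unif_rand();
    if (u < q / (pp + q + rr)) {
      xx = -sd + q * v;
    } else if (u < (q + rr) / (pp + q + rr)) {
      xx = td - rr * log(v);
    } else {
      xx = -sd + pp * log(v);
    }
    if (xx > td) chi = exp(-eta - zeta * (xx - t));
    else if (xx < -sd) chi = exp(-theta + xi * (xx + s));
    else chi = 1.0;
    if (w * chi <= exp(gig_psi(xx, alpha, lam))) break;
  }
  // un-shift the mode of log z
  double t0 = asinh(lam / omega);
  return exp(xx + t0);
}

static double rgig1(double p, double a, double b) {
  if (!(a > 0.0) || !(b > 0.0) || !R_FINITE(a) || !R_FINITE(b))
    stop("rgig: parameters a, b must be positive and finite");
  if (p < 0.0) return 1.0 / rgig1(-p, b, a);
  double omega = sqrt(a * b);
  return sqrt(b / a) * rgig_std(p, omega);
}

// [[Rcpp::export]]
NumericVector cpp_rgig(int n, double p, double a, double b) {
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = rgig1(p, a, b);
  return out;
}

// ---------------------------------------------------------------------------
// Factor product C_gi = prod_f exp(-phi_f/2 |alpha_gf|) lambda_if^alpha_gf,
// so that mu_gi = beta_g * C_gi.  Accumulated in log space.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_factor_product(IntegerMatrix alpha, NumericMatrix lambda,
                                 NumericVector phi) {
  int G = alpha.nrow(), F = alpha.ncol(), N = lambda.nrow();
  NumericMatrix C(G, N);
  std::vector<double> loglam(N * F);
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < N; ++i)
      loglam[f * N + i] = log(lambda(i, f));
  for (int g = 0; g < G; ++g) {
    double base = 0.0;
    for (int f = 0; f < F; ++f)
      if (alpha(g, f) != 0) base -= 0.5 * phi[f];
    for (int i = 0; i < N; ++i) {
      double lc = base;
      for (int f = 0; f < F; ++f) {
        int a = alpha(g, f);
        if (a == 1) lc += loglam[f * N + i];
        else if (a == -1) lc -= loglam[f * N + i];
      }
      C(g, i) = exp(lc);
      if (!R_FINITE(C(g, i)) || C(g, i) <= 0.0)
        stop("numeric overflow in factor product at gene %d, cell %d",
             g + 1, i + 1);
    }
  }
  return C;
}

// Poisson log likelihood given beta and the factor product
static double loglik_from_C(const NumericMatrix &Y, const NumericVector &beta,
                            const NumericMatrix &C) {
  int G = Y.nrow(), N = Y.ncol();
  double ll = 0.0;
  for (int g = 0; g < G; ++g)
    for (int i = 0; i < N; ++i) {
      double mu = beta[g] * C(g, i);
      ll += Y(g, i) * log(mu) - mu - R::lgammafn(Y(g, i) + 1.0);
    }
  return ll;
}

// log conditional of phi_f given everything else (up to a constant):
//   -(N/2+1) log phi - Slog2/(2 phi) - (log phi - h1)^2/(2 h2)
//   - (phi/2) Sy - exp(-phi/2) K
// Slog2 = sum_i log(lambda_if)^2, Sy = sum_{g active} |alpha_gf| sum_i y_gi,
// K = sum_{alpha=1} beta_g S1_g + sum_{alpha=-1} beta_g Sm1_g.
static inline double phi_logcond(double phi, double Slog2, double Sy, double K,
                                 double h1, double h2, int N) {
  double lp = log(phi);
  return -(0.5 * N + 1.0) * lp - Slog2 / (2.0 * phi)
         - (lp - h1) * (lp - h1) / (2.0 * h2)
         - 0.5 * phi * Sy - exp(-0.5 * phi) * K;
}

// ---------------------------------------------------------------------------
// One sweep of the Metropolis-within-Gibbs sampler (or its stochastic-EM
// variant).  Blocks, in order: beta, theta, alpha, (h1, h2), phi, lambda.
// `blocks` is a length-6 logical mask enabling each block, so single-block
// transitions can be exercised in isolation.  In EM mode the beta, alpha and
// phi blocks optimize their conditionals instead of sampling; theta, h1, h2
// and lambda are always sampled.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sweep(NumericMatrix Y, NumericVector beta_in, IntegerMatrix alpha_in,
               NumericMatrix lambda_in, NumericVector phi_in,
               NumericVector theta_in, double h1, double h2,
               List prior, NumericVector sigma, double gig_b, bool em,
               LogicalVector blocks) {
  int G = Y.nrow(), N = Y.ncol(), F = phi_in.size();
  NumericVector beta = clone(beta_in);
  IntegerMatrix alpha = clone(alpha_in);
  NumericMatrix lambda = clone(lambda_in);
  NumericVector phi = clone(phi_in);
  NumericVector theta = clone(theta_in);

  double beta_a = prior["beta_a"], beta_b = prior["beta_b"];
  double h1_mean = prior["h1_mean"], h1_var = prior["h1_var"];
  double h2_a = prior["h2_a"], h2_b = prior["h2_b"];
  double th_a = prior["theta_a"], th_b = prior["theta_b"];

  // full recomputation of the factor product bounds incremental drift to a
  // single sweep
  NumericMatrix C = cpp_factor_product(alpha, lambda, phi);

  NumericVector ysum(G);          // per-gene total counts
  for (int g = 0; g < G; ++g) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += Y(g, i);
    ysum[g] = s;
  }

  // ---- step 1: beta ----
  if (blocks[0]) {
    for (int g = 0; g < G; ++g) {
      double rate = beta_b;
      for (int i = 0; i < N; ++i) rate += C(g, i);
      double shape = beta_a + ysum[g];
      if (!R_FINITE(rate)) stop("numeric overflow in beta rate at gene %d", g + 1);
      double val;
      if (em) {
        val = (shape > 1.0) ? (shape - 1.0) / rate : 1e-4;
        if (val < 1e-4) val = 1e-4;
      } else {
        val = R::rgamma(shape, 1.0 / rate);
        if (val <= 0.0) val = DBL_MIN * 1e10;  // guard against underflow to 0
      }
      beta[g] = val;
    }
  }

  // ---- step 2: theta ----
  if (blocks[1]) {
    for (int f = 0; f < F; ++f) {
      int act = 0;
      for (int g = 0; g < G; ++g) act += (alpha(g, f) != 0);
      theta[f] = R::rbeta(th_a + act, th_b + G - act);
    }
  }

  // ---- step 3: alpha ----
  if (blocks[2]) {
    // Ylog[g][f] = sum_i y_gi log(lambda_if)
    std::vector<double> loglam(N * F);
    for (int f = 0; f < F; ++f)
      for (int i = 0; i < N; ++i) loglam[f * N + i] = log(lambda(i, f));
    // row-major fixed sweep order over (g, f)
    for (int g = 0; g < G; ++g) {
      for (int f = 0; f < F; ++f) {
        int aold = alpha(g, f);
        double ephi2 = exp(0.5 * phi[f]);
        double S0 = 0.0, S1 = 0.0, Sm1 = 0.0, Ylog = 0.0;
        const double *ll = &loglam[f * N];
        for (int i = 0; i < N; ++i) {
          double lam = lambda(i, f);
          double psi = C(g, i);                    // product excluding f
          if (aold == 1) psi *= ephi2 / lam;
          else if (aold == -1) psi *= ephi2 * lam;
          S0 += psi;
          S1 += psi * lam;
          Sm1 += psi / lam;
          Ylog += Y(g, i) * ll[i];
        }
        // unnormalized log conditional probabilities, derived from the
        // joint Poisson likelihood times the Bernoulli(theta) prior; the
        // data-dependent terms (Ylog and the phi/2 * ysum piece) do not
        // cancel across the three values
        double lw0 = log(1.0 - theta[f]) - beta[g] * S0;
        double lw1 = log(0.5 * theta[f]) - 0.5 * phi[f] * ysum[g] + Ylog
                     - beta[g] * S1 / ephi2;
        double lwm = log(0.5 * theta[f]) - 0.5 * phi[f] * ysum[g] - Ylog
                     - beta[g] * Sm1 / ephi2;
        double m = std::max(lw0, std::max(lw1, lwm));
        if (!R_FINITE(m))
          stop("degenerate conditional for alpha at gene %d, factor %d",
               g + 1, f + 1);
        double w0 = exp(lw0 - m), w1 = exp(lw1 - m), wm = exp(lwm - m);
        int anew;
        if (em) {
          anew = (lw0 >= lw1 && lw0 >= lwm) ? 0 : (lw1 >= lwm ? 1 : -1);
        } else {
          double u = unif_rand() * (w0 + w1 + wm);
          anew = (u < w0) ? 0 : (u < w0 + w1 ? 1 : -1);
        }
        if (anew != aold) {
          alpha(g, f) = anew;
          // incremental rank-1 row update of the factor product
          for (int i = 0; i < N; ++i) {
            double lam = lambda(i, f);
            double fac = 1.0;
            if (aold == 1) fac *= ephi2 / lam;
            else if (aold == -1) fac *= ephi2 * lam;
            if (anew == 1) fac *= lam / ephi2;
            else if (anew == -1) fac /= (ephi2 * lam);
            C(g, i) *= fac;
          }
        }
      }
    }
  }

  // ---- steps 4 & 5: h1, h2 ----
  if (blocks[3]) {
    double slp = 0.0;
    for (int f = 0; f < F; ++f) slp += log(phi[f]);
    double prec = 1.0 / h1_var + F / h2;
    double mean = (h1_mean / h1_var + slp / h2) / prec;
    h1 = mean + norm_rand() / sqrt(prec);
    double ss = 0.0;
    for (int f = 0; f < F; ++f) {
      double d = log(phi[f]) - h1;
      ss += d * d;
    }
    h2 = 1.0 / R::rgamma(h2_a + 0.5 * F, 1.0 / (h2_b + 0.5 * ss));
  }

  // ---- step 6: phi ----
  // phi_acc codes: 0 = MH reject, 1 = MH accept (or EM optimum), 2 = prior
  // draw for an everywhere-inactive factor
  IntegerVector phi_acc(F);
  if (blocks[4]) {
    for (int f = 0; f < F; ++f) {
      int act = 0;
      for (int g = 0; g < G; ++g) act += (alpha(g, f) != 0);
      if (act == 0 && !em) {
        // factor inactive everywhere: draw from the Lognormal(h1,h2) prior.
        // Truncated to a physically meaningful range: under diffuse
        // hyperpriors h2 can drift large and an untruncated draw overflows
        // downstream exponentials.
        double z = h1 + norm_rand() * sqrt(h2);
        if (z > 6.9) z = 6.9;          // phi <= ~1e3
        if (z < -13.8) z = -13.8;      // phi >= ~1e-6
        phi[f] = exp(z);  // C unaffected: no active loadings
        phi_acc[f] = 2;
        continue;
      }
      double Slog2 = 0.0;
      for (int i = 0; i < N; ++i) {
        double l = log(lambda(i, f));
        Slog2 += l * l;
      }
      double Sy = 0.0, K = 0.0;
      double ephi2 = exp(0.5 * phi[f]);
      for (int g = 0; g < G; ++g) {
        int a = alpha(g, f);
        if (a == 0) continue;
        Sy += ysum[g];
        double s = 0.0;
        for (int i = 0; i < N; ++i) {
          double lam = lambda(i, f);
          double psi = C(g, i) * (a == 1 ? ephi2 / lam : ephi2 * lam);
          s += (a == 1) ? psi * lam : psi / lam;
        }
        K += beta[g] * s;
      }
      double phiold = phi[f];
      double phinew;
      bool accept;
      if (em) {
        // golden-section maximization of the log conditional on log phi
        const double gr = 0.5 * (sqrt(5.0) - 1.0);
        double lo = log(1e-6), hi = log(1e3);
        double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
        double f1 = phi_logcond(exp(x1), Slog2, Sy, K, h1, h2, N);
        double f2 = phi_logcond(exp(x2), Slog2, Sy, K, h1, h2, N);
        for (int it = 0; it < 100 && (hi - lo) > 1e-8; ++it) {
          if (f1 < f2) {
            lo = x1; x1 = x2; f1 = f2;
            x2 = lo + gr * (hi - lo);
            f2 = phi_logcond(exp(x2), Slog2, Sy, K, h1, h2, N);
          } else {
            hi = x2; x2 = x1; f2 = f1;
            x1 = hi - gr * (hi - lo);
            f1 = phi_logcond(exp(x1), Slog2, Sy, K, h1, h2, N);
          }
        }
        phinew = exp(0.5 * (lo + hi));
        accept = true;
      } else {
        // lognormal random walk: log phi_c ~ Normal(log phi, sigma^2);
        // the Jacobian of the lognormal proposal adds log(phi_c/phi).
        // Proposals outside [1e-12, 1e12] are rejected (MH on a truncated
        // support that contains all numerically representable posteriors).
        phinew = exp(log(phiold) + norm_rand() * sigma[f]);
        if (phinew < 1e-12 || phinew > 1e12) {
          accept = false;
        } else {
          double lr = phi_logcond(phinew, Slog2, Sy, K, h1, h2, N)
                    - phi_logcond(phiold, Slog2, Sy, K, h1, h2, N)
                    + log(phinew) - log(phiold);
          accept = (log(unif_rand()) < lr);
        }
      }
      if (accept && phinew != phiold) {
        phi[f] = phinew;
        phi_acc[f] = 1;
        // update C on the active rows: multiply by exp(-(phinew-phiold)/2)
        double fac = exp(-0.5 * (phinew - phiold));
        for (int g = 0; g < G; ++g)
          if (alpha(g, f) != 0)
            for (int i = 0; i < N; ++i) C(g, i) *= fac;
      }
    }
  }

  // ---- step 7: lambda ----
  int lam_acc = 0, lam_tot = 0;
  if (blocks[5]) {
    for (int f = 0; f < F; ++f) {
      double ph = phi[f];
      // active gene lists for this factor
      std::vector<int> gp, gm;
      for (int g = 0; g < G; ++g) {
        if (alpha(g, f) == 1) gp.push_back(g);
        else if (alpha(g, f) == -1) gm.push_back(g);
      }
      if (gp.empty() && gm.empty()) {
        // inactive factor: prior draws, truncated at exp(+-27.6) so an
        // inflated phi cannot underflow lambda to zero
        double sph = sqrt(ph);
        for (int i = 0; i < N; ++i) {
          double z = norm_rand() * sph;
          if (z > 27.6) z = 27.6;
          if (z < -27.6) z = -27.6;
          lambda(i, f) = exp(z);
        }
        continue;
      }
      for (int i = 0; i < N; ++i) {
        double lam = lambda(i, f);
        double kap = 0.0;
        for (size_t k = 0; k < gp.size(); ++k) kap += Y(gp[k], i);
        for (size_t k = 0; k < gm.size(); ++k) kap -= Y(gm[k], i);
        double P1 = 0.0, Pm = 0.0;
        for (size_t k = 0; k < gp.size(); ++k) P1 += beta[gp[k]] * C(gp[k], i);
        for (size_t k = 0; k < gm.size(); ++k) Pm += beta[gm[k]] * C(gm[k], i);
        // tau*lam/2 = sum of active-positive means, chi/(2 lam) = negative
        double tau = 2.0 * P1 / lam;
        double chi = 2.0 * Pm * lam;

        // draw a candidate from an independence proposal and form the
        // Metropolis-Hastings ratio on the log scale
        double cand, lq_old, lq_new;
        double lp_old, lp_new;
        bool ok = true;
        if (tau > 0.0 && chi > 0.0) {
          cand = rgig1(kap, gig_b * tau, gig_b * chi);
          lq_old = (kap - 1.0) * log(lam) - 0.5 * (gig_b * tau * lam + gig_b * chi / lam);
          lq_new = (kap - 1.0) * log(cand) - 0.5 * (gig_b * tau * cand + gig_b * chi / cand);
        } else if (tau > 0.0 && kap > 0.0) {
          cand = R::rgamma(kap, 2.0 / (gig_b * tau));
          lq_old = (kap - 1.0) * log(lam) - 0.5 * gig_b * tau * lam;
          lq_new = (kap - 1.0) * log(cand) - 0.5 * gig_b * tau * cand;
        } else if (chi > 0.0 && kap < 0.0) {
          cand = 1.0 / R::rgamma(-kap, 2.0 / (gig_b * chi));
          lq_old = (kap - 1.0) * log(lam) - 0.5 * gig_b * chi / lam;
          lq_new = (kap - 1.0) * log(cand) - 0.5 * gig_b * chi / cand;
        } else {
          // kappa == 0 with exactly one of tau, chi zero: the GIG proposal
          // degenerates, fall back to the Lognormal(0, phi_f) prior
          cand = exp(norm_rand() * sqrt(ph));
          double lc = log(cand), lo = log(lam);
          lq_old = -lo - lo * lo / (2.0 * ph);
          lq_new = -lc - lc * lc / (2.0 * ph);
          ok = R_FINITE(cand) && cand > 0.0;
        }
        if (!ok || !R_FINITE(cand) || cand <= 0.0)
          stop("invalid lambda proposal at cell %d, factor %d (kappa=%g, tau=%g, chi=%g)",
               i + 1, f + 1, kap, tau, chi);
        if (cand < 1e-12 || cand > 1e12) { ++lam_tot; continue; }  // reject
        double lc = log(cand), lo = log(lam);
        lp_new = (kap - 1.0) * lc - 0.5 * (tau * cand + chi / cand + lc * lc / ph);
        lp_old = (kap - 1.0) * lo - 0.5 * (tau * lam + chi / lam + lo * lo / ph);
        double lr = (lp_new - lq_new) - (lp_old - lq_old);
        ++lam_tot;
        if (log(unif_rand()) < lr) {
          ++lam_acc;
          lambda(i, f) = cand;
          double ratio = cand / lam;
          for (size_t k = 0; k < gp.size(); ++k) C(gp[k], i) *= ratio;
          for (size_t k = 0; k < gm.size(); ++k) C(gm[k], i) /= ratio;
        }
      }
    }
  }

  double ll = loglik_from_C(Y, beta, C);

  return List::create(_["beta"] = beta, _["alpha"] = alpha,
                      _["lambda"] = lambda, _["phi"] = phi,
                      _["theta"] = theta, _["h1"] = h1, _["h2"] = h2,
                      _["phi_accept"] = phi_acc,
                      _["lambda_accept"] = lam_acc,
                      _["lambda_total"] = lam_tot,
                      _["loglik"] = ll);
}
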