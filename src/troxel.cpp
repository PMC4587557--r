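#include <Rcpp.h>
using namespace Rcpp;

// Joint negative log-likelihood of a 3-exam Markov-normal outcome with
// logistic selection on the current (possibly unobserved) value:
//   y1 ~ N(m1, s1),  y_t | y_{t-1} ~ N(icpt_t + slope_t y_{t-1}, rsd_t)
//   P(missing at t | y_t) = expit(alpha_t + beta_t y_t)
// Observed cells contribute f(y_t | y_{t-1}) (1 - pi_t(y_t)); missing
// cells contribute int f(y | y_{t-1}) pi_t(y) dy by Gauss-Hermite
// quadrature, nested across consecutive missing exams. Each of the eight
// missingness patterns has its own closed integration order so no work is
// repeated across quadrature branches; the all-missing pattern is
// subject-independent and computed once.
//
// gx, gw are the standardized nodes sqrt(2)*x and weights w/sqrt(pi), so
// int N(y; mu, sd) g(y) dy ~= sum_k gw[k] g(mu + sd * gx[k]).

static inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double dnorm_(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// Parameter layout for the gradient version:
//   0..2  alpha_1..alpha_3      3..5  beta_1..beta_3
//   6 m1  7 s1  8 i2  9 b2  10 r2  11 i3  12 b3  13 r3
enum { A1, A2, A3, C1, C2, C3, M1, S1, I2, B2, R2, I3, B3, R3, NPAR };

// [[Rcpp::export(name = ".troxel_nll_grad_cpp")]]
List troxel_nll_grad_cpp(NumericMatrix y, IntegerMatrix m,
                         NumericVector alpha, NumericVector beta,
                         NumericVector mnp, NumericVector gx,
                         NumericVector gw) {
  const int n = y.nrow(), q = gx.size();
  const double m1 = mnp[0], s1 = mnp[1];
  const double i2 = mnp[2], b2 = mnp[3], r2 = mnp[4];
  const double i3 = mnp[5], b3 = mnp[6], r3 = mnp[7];
  const double a1 = alpha[0], a2 = alpha[1], a3 = alpha[2];
  const double c1 = beta[0], c2 = beta[1], c3 = beta[2];

  std::vector<double> v1(q), pw1(q), pc1(q);   // pc1 = 1 - pi1 at node
  for (int k = 0; k < q; ++k) {
    v1[k] = m1 + s1 * gx[k];
    double p = expit(a1 + c1 * v1[k]);
    pw1[k] = gw[k] * p;
    pc1[k] = 1.0 - p;
  }
  // J3 with derivative sums: out[0]=J3, then d/d{a3,c3,v,r3} pieces
  auto J3g = [&](double v, double* out) {
    double mu = i3 + b3 * v;
    double J = 0, da = 0, dc = 0, dr = 0;
    for (int l = 0; l < q; ++l) {
      double t = mu + r3 * gx[l];
      double p = expit(a3 + c3 * t);
      double gp = gw[l] * p, gpq = gp * (1.0 - p);
      J += gp;
      da += gpq;
      dc += gpq * t;
      dr += gpq * gx[l];
    }
    out[0] = J;                    // value
    out[1] = da;                   // d/da3
    out[2] = dc;                   // d/dc3
    out[3] = da * c3;              // d/dmu (for i3, b3, v chains)
    out[4] = dr * c3;              // d/dr3
  };

  double nll = 0.0;
  std::vector<double> g(NPAR, 0.0);       // gradient of the NLL
  double L8 = -1.0;
  std::vector<double> g8(NPAR, 0.0);      // d log L8 / d theta
  int n8 = 0;

  // accumulate one subject's (L, dL/dtheta) given as (L, L * dlogL) pieces
  std::vector<double> dL(NPAR);

  for (int i = 0; i < n; ++i) {
    const int mi1 = m(i, 0), mi2 = m(i, 1), mi3 = m(i, 2);
    const double y1 = y(i, 0), y2 = y(i, 1), y3 = y(i, 2);
    double L = 0.0;
    std::fill(dL.begin(), dL.end(), 0.0);
    double jout[5];

    if (mi1 == 1 && mi2 == 1 && mi3 == 1) {
      ++n8;
      continue;                    // handled once at the end
    }

    if (mi1 == 0) {
      const double z1 = (y1 - m1) / s1;
      const double p1 = expit(a1 + c1 * y1);
      const double f1 = dnorm_(y1, m1, s1) * (1.0 - p1);
      const double mu2 = i2 + b2 * y1;
      // log-derivatives of f1 (constant over quadrature branches)
      const double f1_m1 = z1 / s1, f1_s1 = (z1 * z1 - 1.0) / s1;
      const double f1_a1 = -p1, f1_c1 = -p1 * y1;
      if (mi2 == 0) {
        const double z2 = (y2 - mu2) / r2;
        const double p2 = expit(a2 + c2 * y2);
        const double f2 = dnorm_(y2, mu2, r2) * (1.0 - p2);
        double f3, lg[NPAR] = {0};
        if (mi3 == 0) {
          const double mu3 = i3 + b3 * y2, z3 = (y3 - mu3) / r3;
          const double p3 = expit(a3 + c3 * y3);
          f3 = dnorm_(y3, mu3, r3) * (1.0 - p3);
          lg[A3] = -p3; lg[C3] = -p3 * y3;
          lg[I3] = z3 / r3; lg[B3] = z3 * y2 / r3;
          lg[R3] = (z3 * z3 - 1.0) / r3;
        } else {
          J3g(y2, jout);
          f3 = jout[0];
          lg[A3] = jout[1] / f3; lg[C3] = jout[2] / f3;
          lg[I3] = jout[3] / f3; lg[B3] = jout[3] * y2 / f3;
          lg[R3] = jout[4] / f3;
        }
        L = f1 * f2 * f3;
        lg[M1] += f1_m1; lg[S1] += f1_s1; lg[A1] += f1_a1; lg[C1] += f1_c1;
        lg[A2] += -p2; lg[C2] += -p2 * y2;
        lg[I2] += z2 / r2; lg[B2] += z2 * y1 / r2;
        lg[R2] += (z2 * z2 - 1.0) / r2;
        for (int t = 0; t < NPAR; ++t) dL[t] = L * lg[t];
      } else {
        // exam 2 missing: integrate over v2 = mu2 + r2 * node
        double S = 0;
        double sg[NPAR] = {0};     // dS/dtheta
        if (mi3 == 0) {
          const double p3 = expit(a3 + c3 * y3);
          const double mu3c = i3, z3den = r3;
          for (int k = 0; k < q; ++k) {
            const double v2 = mu2 + r2 * gx[k];
            const double p2 = expit(a2 + c2 * v2);
            const double mu3 = mu3c + b3 * v2, z3 = (y3 - mu3) / z3den;
            const double w = gw[k] * p2 * dnorm_(y3, mu3, r3);
            const double A = 1.0 - p2;
            const double E = A * c2 + (z3 / r3) * b3;  // dlog w / dv2
            S += w;
            sg[A2] += w * A; sg[C2] += w * A * v2;
            sg[I2] += w * E; sg[B2] += w * E * y1; sg[R2] += w * E * gx[k];
            sg[I3] += w * z3 / r3; sg[B3] += w * z3 * v2 / r3;
            sg[R3] += w * (z3 * z3 - 1.0) / r3;
          }
          // global (1 - pi3(y3)) factor
          L = f1 * S * (1.0 - p3);
          for (int t = 0; t < NPAR; ++t) dL[t] = L * (S > 0 ? sg[t] / S : 0);
          dL[A3] += L * (-p3); dL[C3] += L * (-p3 * y3);
        } else {
          for (int k = 0; k < q; ++k) {
            const double v2 = mu2 + r2 * gx[k];
            const double p2 = expit(a2 + c2 * v2);
            J3g(v2, jout);
            const double w = gw[k] * p2 * jout[0];
            const double A = 1.0 - p2;
            const double E = A * c2 +
              (jout[0] > 0 ? jout[3] * b3 / jout[0] : 0);   // dJ3/dv2 chain
            S += w;
            sg[A2] += w * A; sg[C2] += w * A * v2;
            sg[I2] += w * E; sg[B2] += w * E * y1; sg[R2] += w * E * gx[k];
            if (jout[0] > 0) {
              sg[A3] += w * jout[1] / jout[0];
              sg[C3] += w * jout[2] / jout[0];
              sg[I3] += w * jout[3] / jout[0];
              sg[B3] += w * jout[3] * v2 / jout[0];
              sg[R3] += w * jout[4] / jout[0];
            }
          }
          L = f1 * S;
          for (int t = 0; t < NPAR; ++t) dL[t] = L * (S > 0 ? sg[t] / S : 0);
        }
        dL[M1] += L * f1_m1; dL[S1] += L * f1_s1;
        dL[A1] += L * f1_a1; dL[C1] += L * f1_c1;
      }
    } else if (mi2 == 0) {
      // exam 1 missing, exam 2 observed
      const double p2 = expit(a2 + c2 * y2);
      double S = 0;
      double sg[NPAR] = {0};
      for (int k = 0; k < q; ++k) {
        const double mu2 = i2 + b2 * v1[k], z2 = (y2 - mu2) / r2;
        const double w = pw1[k] * dnorm_(y2, mu2, r2);
        const double D = pc1[k] * c1 + (z2 / r2) * b2;  // dlog w / dv1
        S += w;
        sg[A1] += w * pc1[k]; sg[C1] += w * pc1[k] * v1[k];
        sg[M1] += w * D; sg[S1] += w * D * gx[k];
        sg[I2] += w * z2 / r2; sg[B2] += w * z2 * v1[k] / r2;
        sg[R2] += w * (z2 * z2 - 1.0) / r2;
      }
      double f3, lg3[NPAR] = {0};
      if (mi3 == 0) {
        const double mu3 = i3 + b3 * y2, z3 = (y3 - mu3) / r3;
        const double p3 = expit(a3 + c3 * y3);
        f3 = dnorm_(y3, mu3, r3) * (1.0 - p3);
        lg3[A3] = -p3; lg3[C3] = -p3 * y3;
        lg3[I3] = z3 / r3; lg3[B3] = z3 * y2 / r3;
        lg3[R3] = (z3 * z3 - 1.0) / r3;
      } else {
        J3g(y2, jout);
        f3 = jout[0];
        lg3[A3] = jout[1] / f3; lg3[C3] = jout[2] / f3;
        lg3[I3] = jout[3] / f3; lg3[B3] = jout[3] * y2 / f3;
        lg3[R3] = jout[4] / f3;
      }
      L = S * (1.0 - p2) * f3;
      for (int t = 0; t < NPAR; ++t) {
        dL[t] = L * ((S > 0 ? sg[t] / S : 0) + lg3[t]);
      }
      dL[A2] += L * (-p2); dL[C2] += L * (-p2 * y2);
    } else {
      // exams 1-2 missing, exam 3 observed
      const double p3 = expit(a3 + c3 * y3);
      double S = 0;
      double sg[NPAR] = {0};
      for (int k = 0; k < q; ++k) {
        const double mu2 = i2 + b2 * v1[k];
        for (int l = 0; l < q; ++l) {
          const double v2 = mu2 + r2 * gx[l];
          const double p2 = expit(a2 + c2 * v2);
          const double mu3 = i3 + b3 * v2, z3 = (y3 - mu3) / r3;
          const double w = pw1[k] * gw[l] * p2 * dnorm_(y3, mu3, r3);
          const double E = (1.0 - p2) * c2 + (z3 / r3) * b3;  // dlog/dv2
          const double D = pc1[k] * c1 + E * b2;              // dlog/dv1
          S += w;
          sg[A1] += w * pc1[k]; sg[C1] += w * pc1[k] * v1[k];
          sg[M1] += w * D; sg[S1] += w * D * gx[k];
          sg[A2] += w * (1.0 - p2); sg[C2] += w * (1.0 - p2) * v2;
          sg[I2] += w * E; sg[B2] += w * E * v1[k]; sg[R2] += w * E * gx[l];
          sg[I3] += w * z3 / r3; sg[B3] += w * z3 * v2 / r3;
          sg[R3] += w * (z3 * z3 - 1.0) / r3;
        }
      }
      L = S * (1.0 - p3);
      for (int t = 0; t < NPAR; ++t) dL[t] = L * (S > 0 ? sg[t] / S : 0);
      dL[A3] += L * (-p3); dL[C3] += L * (-p3 * y3);
    }

    if (std::isnan(L) || !R_finite(L)) {
      stop("non-finite likelihood contribution for subject %d", i + 1);
    }
    if (L < 1e-300) L = 1e-300;
    nll -= std::log(L);
    for (int t = 0; t < NPAR; ++t) g[t] -= dL[t] / L;
  }

  if (n8 > 0) {
    double S = 0;
    double sg[NPAR] = {0};
    double jout[5];
    for (int k = 0; k < q; ++k) {
      const double mu2 = i2 + b2 * v1[k];
      for (int l = 0; l < q; ++l) {
        const double v2 = mu2 + r2 * gx[l];
        const double p2 = expit(a2 + c2 * v2);
        J3g(v2, jout);
        const double w = pw1[k] * gw[l] * p2 * jout[0];
        const double jv = jout[0] > 0 ? jout[3] * b3 / jout[0] : 0;
        const double E = (1.0 - p2) * c2 + jv;
        const double D = pc1[k] * c1 + E * b2;
        S += w;
        sg[A1] += w * pc1[k]; sg[C1] += w * pc1[k] * v1[k];
        sg[M1] += w * D; sg[S1] += w * D * gx[k];
        sg[A2] += w * (1.0 - p2); sg[C2] += w * (1.0 - p2) * v2;
        sg[I2] += w * E; sg[B2] += w * E * v1[k]; sg[R2] += w * E * gx[l];
        if (jout[0] > 0) {
          sg[A3] += w * jout[1] / jout[0];
          sg[C3] += w * jout[2] / jout[0];
          sg[I3] += w * jout[3] / jout[0];
          sg[B3] += w * jout[3] * v2 / jout[0];
          sg[R3] += w * jout[4] / jout[0];
        }
      }
    }
    L8 = std::max(S, 1e-300);
    for (int t = 0; t < NPAR; ++t) g8[t] = (S > 0 ? sg[t] / S : 0);
    nll -= n8 * std::log(L8);
    for (int t = 0; t < NPAR; ++t) g[t] -= n8 * g8[t];
  }

  return List::create(Named("nll") = nll,
                      Named("grad") = NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export(name = ".troxel_nll_cpp")]]
double troxel_nll_cpp(NumericMatrix y, IntegerMatrix m,
                      NumericVector alpha, NumericVector beta,
                      NumericVector mnp, NumericVector gx, NumericVector gw) {
  const int n = y.nrow(), q = gx.size();
  const double m1 = mnp[0], s1 = mnp[1];
  const double i2 = mnp[2], b2 = mnp[3], r2 = mnp[4];
  const double i3 = mnp[5], b3 = mnp[6], r3 = mnp[7];
  const double a1 = alpha[0], a2 = alpha[1], a3 = alpha[2];
  const double c1 = beta[0], c2 = beta[1], c3 = beta[2];

  // exam-1 marginal nodes and their selection-weighted quadrature weights
  std::vector<double> v1(q), pw1(q);
  for (int k = 0; k < q; ++k) {
    v1[k] = m1 + s1 * gx[k];
    pw1[k] = gw[k] * expit(a1 + c1 * v1[k]);
  }
  // int f(y3 | v) pi3(y3) dy3 as a function of the conditioning value v
  auto J3 = [&](double v) {
    double mu = i3 + b3 * v, acc = 0.0;
    for (int l = 0; l < q; ++l) {
      acc += gw[l] * expit(a3 + c3 * (mu + r3 * gx[l]));
    }
    return acc;
  };

  double L8 = -1.0;   // all-missing contribution, lazily computed once
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    const int mi1 = m(i, 0), mi2 = m(i, 1), mi3 = m(i, 2);
    const double y1 = y(i, 0), y2 = y(i, 1), y3 = y(i, 2);
    double L;

    if (mi1 == 0) {
      const double f1 = dnorm_(y1, m1, s1) * (1.0 - expit(a1 + c1 * y1));
      const double mu2 = i2 + b2 * y1;
      if (mi2 == 0) {
        double f2 = dnorm_(y2, mu2, r2) * (1.0 - expit(a2 + c2 * y2));
        double f3 = (mi3 == 0)
          ? dnorm_(y3, i3 + b3 * y2, r3) * (1.0 - expit(a3 + c3 * y3))
          : J3(y2);
        L = f1 * f2 * f3;
      } else {
        double acc = 0.0;
        if (mi3 == 0) {
          const double s3f = 1.0 - expit(a3 + c3 * y3);
          for (int k = 0; k < q; ++k) {
            double v2 = mu2 + r2 * gx[k];
            acc += gw[k] * expit(a2 + c2 * v2) *
              dnorm_(y3, i3 + b3 * v2, r3) * s3f;
          }
        } else {
          for (int k = 0; k < q; ++k) {
            double v2 = mu2 + r2 * gx[k];
            acc += gw[k] * expit(a2 + c2 * v2) * J3(v2);
          }
        }
        L = f1 * acc;
      }
    } else if (mi2 == 0) {
      const double s2f = 1.0 - expit(a2 + c2 * y2);
      double acc = 0.0;
      for (int k = 0; k < q; ++k) {
        acc += pw1[k] * dnorm_(y2, i2 + b2 * v1[k], r2);
      }
      double f3 = (mi3 == 0)
        ? dnorm_(y3, i3 + b3 * y2, r3) * (1.0 - expit(a3 + c3 * y3))
        : J3(y2);
      L = acc * s2f * f3;
    } else if (mi3 == 0) {
      const double s3f = 1.0 - expit(a3 + c3 * y3);
      double acc = 0.0;
      for (int k = 0; k < q; ++k) {
        const double mu2 = i2 + b2 * v1[k];
        double inner = 0.0;
        for (int l = 0; l < q; ++l) {
          double v2 = mu2 + r2 * gx[l];
          inner += gw[l] * expit(a2 + c2 * v2) * dnorm_(y3, i3 + b3 * v2, r3);
        }
        acc += pw1[k] * inner;
      }
      L = acc * s3f;
    } else {
      if (L8 < 0.0) {
        double acc = 0.0;
        for (int k = 0; k < q; ++k) {
          const double mu2 = i2 + b2 * v1[k];
          double inner = 0.0;
          for (int l = 0; l < q; ++l) {
            double v2 = mu2 + r2 * gx[l];
            inner += gw[l] * expit(a2 + c2 * v2) * J3(v2);
          }
          acc += pw1[k] * inner;
        }
        L8 = acc;
      }
      L = L8;
    }

    if (std::isnan(L) || !R_finite(L)) {
      stop("non-finite likelihood contribution for subject %d", i + 1);
    }
    if (L < 1e-300) L = 1e-300;   // underflow guard, matches the R engine
    nll -= std::log(L);
  }
  return nll;
}
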