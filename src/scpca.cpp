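// Compiled core: multinomial exponential-family PCA (alternating damped
// Newton with QR re-orthonormalization) and logistic-regression Wald fits
// with a Firth-penalized fallback under separation.  The permutation layer
// refits both thousands of times per SNP set, hence compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Natural parameters are clipped before exponentiation so the likelihood
// stays finite under separation (zero-count categories).
static const double THETA_CLIP = 30.0;

static inline double clip_theta(double x) {
  if (x > THETA_CLIP) return THETA_CLIP;
  if (x < -THETA_CLIP) return -THETA_CLIP;
  return x;
}

// G: n x d integers in 0..K (0 is the reference category).
// U: n x l scores; V: (K*d) x l stacked loadings, category k occupying
// rows k*d .. (k+1)*d - 1; mu: length K*d stacked offsets.

static double loglik_all(const imat& G, const mat& U, const mat& V,
                         const vec& mu, int K) {
  const int n = G.n_rows, d = G.n_cols;
  double ll = 0.0;
  std::vector<double> th(K);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) {
      double denom = 1.0, tobs = 0.0;
      const int g = G(i, j);
      for (int k = 0; k < K; ++k) {
        double t = clip_theta(dot(U.row(i), V.row(k * d + j)) + mu(k * d + j));
        denom += std::exp(t);
        if (g == k + 1) tobs = t;
      }
      ll += tobs - std::log(denom);
    }
  }
  return ll;
}

static double loglik_row(const imat& G, int i, const rowvec& u, const mat& V,
                         const vec& mu, int K) {
  const int d = G.n_cols;
  double ll = 0.0;
  for (int j = 0; j < d; ++j) {
    double denom = 1.0, tobs = 0.0;
    const int g = G(i, j);
    for (int k = 0; k < K; ++k) {
      double t = clip_theta(dot(u, V.row(k * d + j)) + mu(k * d + j));
      denom += std::exp(t);
      if (g == k + 1) tobs = t;
    }
    ll += tobs - std::log(denom);
  }
  return ll;
}

// Column log-likelihood for SNP j with candidate per-category loading rows
// Vj (K x l) and offsets muj (K).
static double loglik_col(const imat& G, int j, const mat& U, const mat& Vj,
                         const vec& muj, int K) {
  const int n = G.n_rows;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double denom = 1.0, tobs = 0.0;
    const int g = G(i, j);
    for (int k = 0; k < K; ++k) {
      double t = clip_theta(dot(U.row(i), Vj.row(k)) + muj(k));
      denom += std::exp(t);
      if (g == k + 1) tobs = t;
    }
    ll += tobs - std::log(denom);
  }
  return ll;
}

// One damped Newton sweep over all score rows.  Each row is updated
// independently (the likelihood separates over rows given V, mu); the first
// halved step that does not decrease that row's likelihood is accepted.
static int step_scores(const imat& G, mat& U, const mat& V, const vec& mu,
                       int K, int damping, bool expand) {
  const int n = G.n_rows, d = G.n_cols, l = U.n_cols;
  int fallbacks = 0;
  mat A(K, l);
  vec p(K);
  for (int i = 0; i < n; ++i) {
    vec g(l, fill::zeros);
    mat info(l, l, fill::zeros);
    for (int j = 0; j < d; ++j) {
      double denom = 1.0;
      for (int k = 0; k < K; ++k) {
        A.row(k) = V.row(k * d + j);
        double t = clip_theta(dot(U.row(i), A.row(k)) + mu(k * d + j));
        p(k) = std::exp(t);
        denom += p(k);
      }
      p /= denom;
      const int gij = G(i, j);
      for (int k = 0; k < K; ++k) {
        double x = (gij == k + 1) ? 1.0 : 0.0;
        g += (x - p(k)) * A.row(k).t();
      }
      // multinomial covariance: diag(p) - p p^T, projected through loadings
      mat S = diagmat(p) - p * p.t();
      info += A.t() * S * A;
    }
    if (norm(g, 2) < 1e-12) continue;
    vec delta;
    bool ok = solve(delta, info, g, solve_opts::no_approx);
    if (!ok || !delta.is_finite()) {
      delta = g;  // gradient fallback (still subject to step-halving)
      ++fallbacks;
    }
    const double ll0 = loglik_row(G, i, U.row(i), V, mu, K);
    double t = 1.0;
    for (int h = 0; h <= damping; ++h) {
      rowvec cand = U.row(i) + t * delta.t();
      double llc = loglik_row(G, i, cand, V, mu, K);
      if (llc >= ll0 - 1e-12) {
        if (expand && h == 0) {
          // greedy step-doubling: traverses flat separation ridges in
          // O(log) sweeps instead of creeping; still monotone
          for (int e = 0; e < 12; ++e) {
            rowvec cand2 = U.row(i) + (t * 2.0) * delta.t();
            double ll2 = loglik_row(G, i, cand2, V, mu, K);
            if (ll2 <= llc) break;
            t *= 2.0; cand = cand2; llc = ll2;
          }
        }
        U.row(i) = cand;
        break;
      }
      t *= 0.5;
    }
  }
  return fallbacks;
}

// One damped Newton sweep over loadings: SNP j's K loading rows are updated
// jointly as one (K*l)-vector.
static int step_loadings(const imat& G, const mat& U, mat& V, const vec& mu,
                         int K, int damping, bool expand) {
  const int n = G.n_rows, d = G.n_cols, l = U.n_cols;
  int fallbacks = 0;
  for (int j = 0; j < d; ++j) {
    mat P(n, K);
    for (int i = 0; i < n; ++i) {
      double denom = 1.0;
      for (int k = 0; k < K; ++k) {
        double t = clip_theta(dot(U.row(i), V.row(k * d + j)) + mu(k * d + j));
        P(i, k) = std::exp(t);
        denom += P(i, k);
      }
      P.row(i) /= denom;
    }
    vec g(K * l, fill::zeros);
    mat info(K * l, K * l, fill::zeros);
    for (int k = 0; k < K; ++k) {
      vec xk(n);
      for (int i = 0; i < n; ++i) xk(i) = (G(i, j) == k + 1) ? 1.0 : 0.0;
      g.subvec(k * l, (k + 1) * l - 1) = U.t() * (xk - P.col(k));
      for (int k2 = 0; k2 < K; ++k2) {
        vec w = (k == k2) ? vec(P.col(k) % (1.0 - P.col(k)))
                          : vec(-P.col(k) % P.col(k2));
        info.submat(k * l, k2 * l, (k + 1) * l - 1, (k2 + 1) * l - 1) =
            U.t() * (U.each_col() % w);
      }
    }
    if (norm(g, 2) < 1e-12) continue;
    vec delta;
    bool ok = solve(delta, info, g, solve_opts::no_approx);
    if (!ok || !delta.is_finite()) {
      delta = g;
      ++fallbacks;
    }
    mat Vj(K, l);
    vec muj(K);
    for (int k = 0; k < K; ++k) {
      Vj.row(k) = V.row(k * d + j);
      muj(k) = mu(k * d + j);
    }
    const double ll0 = loglik_col(G, j, U, Vj, muj, K);
    double t = 1.0;
    for (int h = 0; h <= damping; ++h) {
      mat cand = Vj;
      for (int k = 0; k < K; ++k)
        cand.row(k) += t * delta.subvec(k * l, (k + 1) * l - 1).t();
      double llc = loglik_col(G, j, U, cand, muj, K);
      if (llc >= ll0 - 1e-12) {
        if (expand && h == 0) {
          for (int e = 0; e < 12; ++e) {
            mat cand2 = Vj;
            for (int k = 0; k < K; ++k)
              cand2.row(k) += (t * 2.0) * delta.subvec(k * l, (k + 1) * l - 1).t();
            double ll2 = loglik_col(G, j, U, cand2, muj, K);
            if (ll2 <= llc) break;
            t *= 2.0; cand = cand2; llc = ll2;
          }
        }
        for (int k = 0; k < K; ++k) V.row(k * d + j) = cand.row(k);
        break;
      }
      t *= 0.5;
    }
  }
  return fallbacks;
}

// One damped Newton sweep over offsets: SNP j's K offsets jointly.
static int step_offsets(const imat& G, const mat& U, const mat& V, vec& mu,
                        int K, int damping, bool expand) {
  const int n = G.n_rows, d = G.n_cols;
  int fallbacks = 0;
  for (int j = 0; j < d; ++j) {
    mat P(n, K);
    for (int i = 0; i < n; ++i) {
      double denom = 1.0;
      for (int k = 0; k < K; ++k) {
        double t = clip_theta(dot(U.row(i), V.row(k * d + j)) + mu(k * d + j));
        P(i, k) = std::exp(t);
        denom += P(i, k);
      }
      P.row(i) /= denom;
    }
    vec g(K, fill::zeros);
    mat info(K, K, fill::zeros);
    for (int k = 0; k < K; ++k) {
      double sx = 0.0;
      for (int i = 0; i < n; ++i) sx += (G(i, j) == k + 1) ? 1.0 : 0.0;
      g(k) = sx - accu(P.col(k));
      for (int k2 = 0; k2 < K; ++k2)
        info(k, k2) = (k == k2) ? accu(P.col(k) % (1.0 - P.col(k)))
                                : -accu(P.col(k) % P.col(k2));
    }
    if (norm(g, 2) < 1e-12) continue;
    vec delta;
    bool ok = solve(delta, info, g, solve_opts::no_approx);
    if (!ok || !delta.is_finite()) {
      delta = g / (double)n;
      ++fallbacks;
    }
    mat Vj(K, U.n_cols);
    vec muj(K);
    for (int k = 0; k < K; ++k) {
      Vj.row(k) = V.row(k * d + j);
      muj(k) = mu(k * d + j);
    }
    const double ll0 = loglik_col(G, j, U, Vj, muj, K);
    double t = 1.0;
    for (int h = 0; h <= damping; ++h) {
      vec cand = muj + t * delta;
      double llc = loglik_col(G, j, U, Vj, cand, K);
      if (llc >= ll0 - 1e-12) {
        if (expand && h == 0) {
          for (int e = 0; e < 12; ++e) {
            vec cand2 = muj + (t * 2.0) * delta;
            double ll2 = loglik_col(G, j, U, Vj, cand2, K);
            if (ll2 <= llc) break;
            t *= 2.0; cand = cand2; llc = ll2;
          }
        }
        for (int k = 0; k < K; ++k) mu(k * d + j) = cand(k);
        break;
      }
      t *= 0.5;
    }
  }
  return fallbacks;
}

// QR re-orthonormalization of the stacked loading matrix with back-rotation
// of the scores so every natural parameter is unchanged.  Returns the
// smallest |R_cc| (rank diagnostic).
static double orthonormalize_qr(mat& U, mat& V) {
  mat Q, R;
  qr_econ(Q, R, V);
  for (uword c = 0; c < R.n_cols; ++c) {
    if (R(c, c) < 0) {
      Q.col(c) *= -1.0;
      R.row(c) *= -1.0;
    }
  }
  U = U * R.t();
  V = Q;
  return abs(R.diag()).min();
}


// ---------------------------------------------------------------------------
// Specialized fast path for l = 1 and K <= 2 — the shape used by the
// supervised permutation layer, which performs thousands of refits.
// Identical algorithm (damped Newton with expansion, QR = normalization);
// raw loops, per-pass likelihood accounting, and a polynomial exp.

// exp(x) for clipped |x| <= 30 via 2^k * 2^f decomposition with a
// degree-6 polynomial for 2^f on [-0.5, 0.5]; relative error < 3e-11,
// ~4x faster than libm.  Used only inside the l = 1 solver, whose
// convergence tolerances are many orders coarser.
static inline double fexp(double x) {
  const double LOG2E = 1.4426950408889634;
  double y = x * LOG2E;
  double k = std::nearbyint(y);
  double f = y - k;                      // in [-0.5, 0.5]
  // minimax-ish coefficients for 2^f (Taylor of exp(f*ln2))
  const double c1 = 0.6931471805599453, c2 = 0.2402265069591007,
               c3 = 0.05550410866482158, c4 = 0.009618129107628477,
               c5 = 0.0013333558146428443, c6 = 0.00015403530393381608;
  double p = 1.0 + f * (c1 + f * (c2 + f * (c3 + f * (c4 + f * (c5 + f * c6)))));
  // scale by 2^k through the exponent bits
  int64_t ki = (int64_t)k;
  union { double d; int64_t i; } u;
  u.i = (int64_t)(1023 + ki) << 52;
  return p * u.d;
}

// log(x) for x >= 1 (denominators here are 1 + sum of exponentials):
// exponent/mantissa split plus an atanh series; relative error < 1e-10.
static inline double flog(double x) {
  union { double d; int64_t i; } u;
  u.d = x;
  int64_t k = ((u.i >> 52) & 0x7ff) - 1023;
  u.i = (u.i & 0x000fffffffffffffLL) | 0x3ff0000000000000LL;  // m in [1,2)
  double m = u.d;
  if (m > 1.4142135623730951) { m *= 0.5; k += 1; }
  double t = (m - 1.0) / (m + 1.0), t2 = t * t;
  double s = t * (2.0 + t2 * (0.6666666666666666 + t2 * (0.4 + t2 * (0.2857142857142857 + t2 * (0.2222222222222222 + t2 * 0.18181818181818182)))));
  return s + 0.6931471805599453 * (double)k;
}

struct ModelL1 {
  // pointers into caller-owned storage: V and mu are stacked by category
  double* U; double* V; double* mu;
  int n, d, K;
};

static double loglik_row_l1(const imat& G, const ModelL1& m, int i, double u) {
  double ll = 0.0;
  for (int j = 0; j < m.d; ++j) {
    double denom = 1.0, tobs = 0.0;
    const int g = G(i, j);
    for (int k = 0; k < m.K; ++k) {
      double t = clip_theta(u * m.V[k * m.d + j] + m.mu[k * m.d + j]);
      denom += fexp(t);
      if (g == k + 1) tobs = t;
    }
    ll += tobs - flog(denom);
  }
  return ll;
}

static double loglik_col_l1(const imat& G, const ModelL1& m, int j,
                            const double* vj, const double* muj) {
  double ll = 0.0;
  for (int i = 0; i < m.n; ++i) {
    double denom = 1.0, tobs = 0.0;
    const int g = G(i, j);
    for (int k = 0; k < m.K; ++k) {
      double t = clip_theta(m.U[i] * vj[k] + muj[k]);
      denom += fexp(t);
      if (g == k + 1) tobs = t;
    }
    ll += tobs - flog(denom);
  }
  return ll;
}

static double loglik_all_l1(const imat& G, const ModelL1& m) {
  double ll = 0.0;
  for (int i = 0; i < m.n; ++i) ll += loglik_row_l1(G, m, i, m.U[i]);
  return ll;
}

static int step_scores_l1(const imat& G, ModelL1& m, int damping,
                          bool expand) {
  int fallbacks = 0;
  for (int i = 0; i < m.n; ++i) {
    double g = 0.0, info = 0.0, ll0 = 0.0;
    const double u = m.U[i];
    for (int j = 0; j < m.d; ++j) {
      const int gij = G(i, j);
      double v0 = m.V[j], v1 = (m.K == 2) ? m.V[m.d + j] : 0.0;
      double t0 = clip_theta(u * v0 + m.mu[j]);
      double e0 = fexp(t0), denom = 1.0 + e0, t1 = 0.0, e1 = 0.0;
      if (m.K == 2) {
        t1 = clip_theta(u * v1 + m.mu[m.d + j]);
        e1 = fexp(t1);
        denom += e1;
      }
      double p0 = e0 / denom, p1 = e1 / denom;
      g += (((gij == 1) ? 1.0 : 0.0) - p0) * v0;
      info += p0 * (1.0 - p0) * v0 * v0;
      if (m.K == 2) {
        g += (((gij == 2) ? 1.0 : 0.0) - p1) * v1;
        info += p1 * (1.0 - p1) * v1 * v1 - 2.0 * p0 * p1 * v0 * v1;
      }
      ll0 += ((gij == 1) ? t0 : (gij == 2) ? t1 : 0.0) - flog(denom);
    }
    if (std::abs(g) < 1e-9) continue;  // stationary (possibly at clip)
    double delta;
    if (info > 1e-12) delta = g / info;
    else { delta = g; ++fallbacks; }
    // moves beyond the clip range are pointless and would only churn the
    // line search; cap the step so |theta| changes by at most ~2*clip
    double vmax = 0.0;
    for (int j = 0; j < m.K * m.d; ++j)
      vmax = std::max(vmax, std::abs(m.V[j]));
    double dmax = 2.0 * THETA_CLIP / std::max(vmax, 1e-8);
    if (std::abs(delta) > dmax) delta = (delta > 0 ? dmax : -dmax);
    double t = 1.0;
    for (int h = 0; h <= damping; ++h) {
      double cand = u + t * delta;
      double llc = loglik_row_l1(G, m, i, cand);
      if (llc >= ll0 - 1e-12) {
        if (expand && h == 0) {
          for (int e = 0; e < 12; ++e) {
            double cand2 = u + (t * 2.0) * delta;
            double ll2 = loglik_row_l1(G, m, i, cand2);
            if (ll2 <= llc) break;
            t *= 2.0; cand = cand2; llc = ll2;
          }
        }
        m.U[i] = cand;
        break;
      }
      t *= 0.5;
    }
  }
  return fallbacks;
}

// Shared 2x2 symmetric solve.
static inline bool solve2(double a, double b, double c, double g0, double g1,
                          double* d0, double* d1) {
  double det = a * c - b * b;
  if (std::abs(det) < 1e-14) return false;
  *d0 = (c * g0 - b * g1) / det;
  *d1 = (a * g1 - b * g0) / det;
  return true;
}

// Column sweep updating either SNP j's loading pair (what = 0) or offset
// pair (what = 1); accumulates the post-update column log-likelihoods so
// the caller gets the iteration likelihood for free.
static int step_cols_l1(const imat& G, ModelL1& m, int damping, bool expand,
                        int what, double* ll_out) {
  int fallbacks = 0;
  double ll_total = 0.0;
  for (int j = 0; j < m.d; ++j) {
    double g0 = 0, g1 = 0, a = 0, b = 0, c = 0, ll0 = 0.0;
    double v0 = m.V[j], v1 = (m.K == 2) ? m.V[m.d + j] : 0.0;
    double m0 = m.mu[j], m1 = (m.K == 2) ? m.mu[m.d + j] : 0.0;
    for (int i = 0; i < m.n; ++i) {
      const double u = m.U[i];
      const int gij = G(i, j);
      double t0 = clip_theta(u * v0 + m0);
      double e0 = fexp(t0), denom = 1.0 + e0, t1 = 0.0, e1 = 0.0;
      if (m.K == 2) {
        t1 = clip_theta(u * v1 + m1);
        e1 = fexp(t1);
        denom += e1;
      }
      double p0 = e0 / denom, p1 = e1 / denom;
      double w = (what == 0) ? u : 1.0;
      g0 += (((gij == 1) ? 1.0 : 0.0) - p0) * w;
      a += p0 * (1.0 - p0) * w * w;
      if (m.K == 2) {
        g1 += (((gij == 2) ? 1.0 : 0.0) - p1) * w;
        c += p1 * (1.0 - p1) * w * w;
        b += -p0 * p1 * w * w;
      }
      ll0 += ((gij == 1) ? t0 : (gij == 2) ? t1 : 0.0) - flog(denom);
    }
    // freeze any category with a vanishing gradient (e.g. a category
    // absent from the data): its curvature is equally tiny and a joint
    // Newton step would drift along the flat direction
    bool act0 = std::abs(g0) >= 1e-9;
    bool act1 = (m.K == 2) && std::abs(g1) >= 1e-9;
    if (!act0 && !act1) {
      ll_total += ll0;
      continue;
    }
    double d0 = 0.0, d1 = 0.0;
    bool ok;
    if (act0 && act1) ok = solve2(a, b, c, g0, g1, &d0, &d1);
    else if (act0) { ok = a > 1e-14; if (ok) d0 = g0 / a; }
    else { ok = c > 1e-14; if (ok) d1 = g1 / c; }
    if (!ok) {
      d0 = act0 ? ((what == 0) ? g0 : g0 / m.n) : 0.0;
      d1 = act1 ? ((what == 0) ? g1 : g1 / m.n) : 0.0;
      ++fallbacks;
    }
    double wmax = 1.0;
    if (what == 0) {
      wmax = 0.0;
      for (int i = 0; i < m.n; ++i) wmax = std::max(wmax, std::abs(m.U[i]));
    }
    double dmax = 2.0 * THETA_CLIP / std::max(wmax, 1e-8);
    double dn = std::max(std::abs(d0), std::abs(d1));
    if (dn > dmax) { d0 *= dmax / dn; d1 *= dmax / dn; }
    double base0 = (what == 0) ? v0 : m0, base1 = (what == 0) ? v1 : m1;
    double vj[2] = {v0, v1}, muj[2] = {m0, m1};
    double accepted = ll0;
    double t = 1.0;
    for (int h = 0; h <= damping; ++h) {
      double cand[2] = {base0 + t * d0, base1 + t * d1};
      double llc = (what == 0) ? loglik_col_l1(G, m, j, cand, muj)
                               : loglik_col_l1(G, m, j, vj, cand);
      if (llc >= ll0 - 1e-12) {
        if (expand && h == 0) {
          for (int e = 0; e < 12; ++e) {
            double cand2[2] = {base0 + 2.0 * t * d0, base1 + 2.0 * t * d1};
            double ll2 = (what == 0) ? loglik_col_l1(G, m, j, cand2, muj)
                                     : loglik_col_l1(G, m, j, vj, cand2);
            if (ll2 <= llc) break;
            t *= 2.0; cand[0] = cand2[0]; cand[1] = cand2[1]; llc = ll2;
          }
        }
        if (what == 0) {
          m.V[j] = cand[0];
          if (m.K == 2) m.V[m.d + j] = cand[1];
        } else {
          m.mu[j] = cand[0];
          if (m.K == 2) m.mu[m.d + j] = cand[1];
        }
        accepted = llc;
        break;
      }
      t *= 0.5;
    }
    ll_total += accepted;
  }
  *ll_out = ll_total;
  return fallbacks;
}

// Normalization step for l = 1 (QR of a single column): V <- V/||V||,
// U <- U*||V||; theta unchanged.
static double orthonormalize_l1(ModelL1& m) {
  double nv = 0.0;
  const int kd = m.K * m.d;
  for (int j = 0; j < kd; ++j) nv += m.V[j] * m.V[j];
  nv = std::sqrt(nv);
  if (nv < 1e-12) return nv;
  for (int j = 0; j < kd; ++j) m.V[j] /= nv;
  for (int i = 0; i < m.n; ++i) m.U[i] *= nv;
  return nv;
}

// ---------------------------------------------------------------------------
// Batched sweeps: compute every block's capped Newton delta, apply them
// all, and verify the total likelihood once; on a decrease, halve all
// steps together (up to `damping` times).  One gradient pass plus ~one
// likelihood pass per sweep — the screening-scale mode used by the
// permutation layer.  Monotone in the total likelihood by construction.

static double batched_deltas_scores(const imat& G, const ModelL1& m,
                                    std::vector<double>& delta) {
  double ll = 0.0;
  double vmax = 0.0;
  for (int j = 0; j < m.K * m.d; ++j)
    vmax = std::max(vmax, std::abs(m.V[j]));
  const double dmax = 2.0 * THETA_CLIP / std::max(vmax, 1e-8);
  for (int i = 0; i < m.n; ++i) {
    double g = 0.0, info = 0.0;
    const double u = m.U[i];
    for (int j = 0; j < m.d; ++j) {
      const int gij = G(i, j);
      double v0 = m.V[j], v1 = (m.K == 2) ? m.V[m.d + j] : 0.0;
      double t0 = clip_theta(u * v0 + m.mu[j]);
      double e0 = fexp(t0), denom = 1.0 + e0, e1 = 0.0, t1 = 0.0;
      if (m.K == 2) {
        t1 = clip_theta(u * v1 + m.mu[m.d + j]);
        e1 = fexp(t1);
        denom += e1;
      }
      double p0 = e0 / denom, p1 = e1 / denom;
      g += (((gij == 1) ? 1.0 : 0.0) - p0) * v0;
      info += p0 * (1.0 - p0) * v0 * v0;
      if (m.K == 2) {
        g += (((gij == 2) ? 1.0 : 0.0) - p1) * v1;
        info += p1 * (1.0 - p1) * v1 * v1 - 2.0 * p0 * p1 * v0 * v1;
      }
      ll += ((gij == 1) ? t0 : (gij == 2) ? t1 : 0.0) - flog(denom);
    }
    double dlt = (info > 1e-12) ? g / info : g;
    if (std::abs(dlt) > dmax) dlt = (dlt > 0 ? dmax : -dmax);
    delta[i] = dlt;
  }
  return ll;
}

static double batched_deltas_cols(const imat& G, const ModelL1& m, int what,
                                  std::vector<double>& d0s,
                                  std::vector<double>& d1s) {
  double ll = 0.0;
  double wmax = 1.0;
  if (what == 0) {
    wmax = 0.0;
    for (int i = 0; i < m.n; ++i) wmax = std::max(wmax, std::abs(m.U[i]));
  }
  const double dmax = 2.0 * THETA_CLIP / std::max(wmax, 1e-8);
  for (int j = 0; j < m.d; ++j) {
    double g0 = 0, g1 = 0, a = 0, b = 0, c = 0;
    double v0 = m.V[j], v1 = (m.K == 2) ? m.V[m.d + j] : 0.0;
    double m0 = m.mu[j], m1 = (m.K == 2) ? m.mu[m.d + j] : 0.0;
    for (int i = 0; i < m.n; ++i) {
      const double u = m.U[i];
      const int gij = G(i, j);
      double t0 = clip_theta(u * v0 + m0);
      double e0 = fexp(t0), denom = 1.0 + e0, e1 = 0.0, t1 = 0.0;
      if (m.K == 2) {
        t1 = clip_theta(u * v1 + m1);
        e1 = fexp(t1);
        denom += e1;
      }
      double p0 = e0 / denom, p1 = e1 / denom;
      double w = (what == 0) ? u : 1.0;
      g0 += (((gij == 1) ? 1.0 : 0.0) - p0) * w;
      a += p0 * (1.0 - p0) * w * w;
      if (m.K == 2) {
        g1 += (((gij == 2) ? 1.0 : 0.0) - p1) * w;
        c += p1 * (1.0 - p1) * w * w;
        b += -p0 * p1 * w * w;
      }
      ll += ((gij == 1) ? t0 : (gij == 2) ? t1 : 0.0) - flog(denom);
    }
    bool act0 = std::abs(g0) >= 1e-9;
    bool act1 = (m.K == 2) && std::abs(g1) >= 1e-9;
    double d0 = 0.0, d1 = 0.0;
    bool ok = true;
    if (act0 && act1) ok = solve2(a, b, c, g0, g1, &d0, &d1);
    else if (act0) { ok = a > 1e-14; if (ok) d0 = g0 / a; }
    else if (act1) { ok = c > 1e-14; if (ok) d1 = g1 / c; }
    if (!ok) {
      d0 = act0 ? g0 / m.n : 0.0;
      d1 = act1 ? g1 / m.n : 0.0;
    }
    double dn = std::max(std::abs(d0), std::abs(d1));
    if (dn > dmax) { d0 *= dmax / dn; d1 *= dmax / dn; }
    d0s[j] = d0;
    d1s[j] = d1;
  }
  return ll;
}

static Rcpp::List cpca_fit_l1_fast(const imat& G, int K, mat& U, mat& V,
                                   vec& mu, int max_iter, double tol,
                                   int damping) {
  ModelL1 m{U.memptr(), V.memptr(), mu.memptr(),
            (int)G.n_rows, (int)G.n_cols, K};
  const int kd = K * m.d;
  int iter = 0;
  bool converged = false;
  std::vector<double> trace;
  std::vector<double> du(m.n), d0(m.d), d1(m.d);
  std::vector<double> Usave(m.n), Psave(kd);

  // Fused optimistic iteration: each gradient pass also evaluates the
  // likelihood of the current state, which serves as the acceptance check
  // of the PREVIOUS sweep; on the rare decrease the previous sweep is
  // rolled back and redone with global step-halving.  Three passes per
  // iteration instead of six-plus, and the trace stays exactly monotone.

  auto redo_scores = [&](double ll_ref) {
    // slow path: restore and re-apply with halving until non-decreasing
    double t = 0.5;
    for (int h = 1; h <= damping; ++h) {
      for (int i = 0; i < m.n; ++i) m.U[i] = Usave[i] + t * du[i];
      if (loglik_all_l1(G, m) >= ll_ref - 1e-12) return;
      t *= 0.5;
    }
    for (int i = 0; i < m.n; ++i) m.U[i] = Usave[i];
  };
  auto redo_cols = [&](int what, double ll_ref) {
    double* par = (what == 0) ? m.V : m.mu;
    double t = 0.5;
    for (int h = 1; h <= damping; ++h) {
      for (int j = 0; j < m.d; ++j) {
        par[j] = Psave[j] + t * d0[j];
        if (K == 2) par[m.d + j] = Psave[m.d + j] + t * d1[j];
      }
      if (loglik_all_l1(G, m) >= ll_ref - 1e-12) return;
      t *= 0.5;
    }
    for (int j = 0; j < kd; ++j) par[j] = Psave[j];
  };

  // Pass 1 of the chain: scores gradients + ll of the initial state.
  double ll_state = batched_deltas_scores(G, m, du);
  trace.push_back(ll_state);
  double ll_iter_prev = ll_state;

  for (iter = 1; iter <= max_iter; ++iter) {
    // apply scores sweep (deltas already computed at current state)
    std::memcpy(Usave.data(), m.U, m.n * sizeof(double));
    for (int i = 0; i < m.n; ++i) m.U[i] += du[i];
    double ll_before_scores = ll_state;

    // loadings pass: gradients at post-scores state + its ll
    double ll1 = batched_deltas_cols(G, m, 0, d0, d1);
    if (ll1 < ll_before_scores - 1e-9) {
      redo_scores(ll_before_scores);
      ll1 = batched_deltas_cols(G, m, 0, d0, d1);
    }
    std::memcpy(Psave.data(), m.V, kd * sizeof(double));
    for (int j = 0; j < m.d; ++j) {
      m.V[j] += d0[j];
      if (K == 2) m.V[m.d + j] += d1[j];
    }

    // offsets pass: gradients at post-loadings state + its ll
    double ll2 = batched_deltas_cols(G, m, 1, d0, d1);
    if (ll2 < ll1 - 1e-9) {
      redo_cols(0, ll1);
      ll2 = batched_deltas_cols(G, m, 1, d0, d1);
    }
    std::memcpy(Psave.data(), m.mu, kd * sizeof(double));
    for (int j = 0; j < m.d; ++j) {
      m.mu[j] += d0[j];
      if (K == 2) m.mu[m.d + j] += d1[j];
    }

    // next scores pass doubles as the offsets acceptance check and the
    // end-of-iteration likelihood
    double ll3 = batched_deltas_scores(G, m, du);
    if (ll3 < ll2 - 1e-9) {
      redo_cols(1, ll2);
      ll3 = batched_deltas_scores(G, m, du);
    }
    ll_state = ll3;
    trace.push_back(ll_state);
    if (ll_state - ll_iter_prev <= tol * (std::abs(ll_iter_prev) + 1e-10)) {
      converged = true;
      break;
    }
    ll_iter_prev = ll_state;
  }
  if (orthonormalize_l1(m) < 1e-12)
    Rcpp::stop("stacked loading matrix is rank deficient; reduce latent_dim");
  return Rcpp::List::create(
      Rcpp::Named("U") = U, Rcpp::Named("V") = V, Rcpp::Named("mu") = mu,
      Rcpp::Named("loglik") = ll_state,
      Rcpp::Named("trace") = Rcpp::wrap(trace),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iterations") = std::min(iter, max_iter),
      Rcpp::Named("n_fallbacks") = 0);
}

static Rcpp::List cpca_fit_l1(const imat& G, int K, mat& U, mat& V, vec& mu,
                              int max_iter, double tol, int damping) {
  ModelL1 m{U.memptr(), V.memptr(), mu.memptr(),
            (int)G.n_rows, (int)G.n_cols, K};
  int fallbacks = 0, iter = 0;
  bool converged = false;
  std::vector<double> trace;
  double ll_prev = loglik_all_l1(G, m);
  trace.push_back(ll_prev);
  const int kd = K * m.d;
  std::vector<double> U_old(m.n), V_old(kd), mu_old(kd);
  std::vector<double> Ue(m.n), Ve(kd), me(kd);
  for (iter = 1; iter <= max_iter; ++iter) {
    std::memcpy(U_old.data(), m.U, m.n * sizeof(double));
    std::memcpy(V_old.data(), m.V, kd * sizeof(double));
    std::memcpy(mu_old.data(), m.mu, kd * sizeof(double));
    double ll_mid, ll;
    fallbacks += step_scores_l1(G, m, damping, true);
    if (orthonormalize_l1(m) < 1e-12)
      Rcpp::stop("stacked loading matrix is rank deficient; reduce latent_dim");
    fallbacks += step_cols_l1(G, m, damping, true, 0, &ll_mid);
    fallbacks += step_cols_l1(G, m, damping, true, 1, &ll);
    // joint extrapolation along the iteration displacement (heavy-ball /
    // SQUAREM-style): escapes the zigzag of alternating updates on
    // bilinear ridges; accepted only on improvement, so still monotone.
    for (double alpha = 1.0; alpha <= 16.0; alpha *= 2.0) {
      for (int i = 0; i < m.n; ++i)
        Ue[i] = m.U[i] + alpha * (m.U[i] - U_old[i]);
      for (int j = 0; j < kd; ++j) {
        Ve[j] = m.V[j] + alpha * (m.V[j] - V_old[j]);
        me[j] = m.mu[j] + alpha * (m.mu[j] - mu_old[j]);
      }
      ModelL1 mx{Ue.data(), Ve.data(), me.data(), m.n, m.d, K};
      double lle = loglik_all_l1(G, mx);
      if (lle > ll) {
        std::memcpy(m.U, Ue.data(), m.n * sizeof(double));
        std::memcpy(m.V, Ve.data(), kd * sizeof(double));
        std::memcpy(m.mu, me.data(), kd * sizeof(double));
        ll = lle;
      } else break;
    }
    trace.push_back(ll);
    if (ll - ll_prev <= tol * (std::abs(ll_prev) + 1e-10)) {
      converged = true;
      ll_prev = ll;
      break;
    }
    ll_prev = ll;
  }
  orthonormalize_l1(m);
  return Rcpp::List::create(
      Rcpp::Named("U") = U, Rcpp::Named("V") = V, Rcpp::Named("mu") = mu,
      Rcpp::Named("loglik") = ll_prev,
      Rcpp::Named("trace") = Rcpp::wrap(trace),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iterations") = std::min(iter, max_iter),
      Rcpp::Named("n_fallbacks") = fallbacks);
}

// [[Rcpp::export(name = ".cpp_cpca_loglik")]]
double cpp_cpca_loglik(Rcpp::IntegerMatrix Gr, int K, Rcpp::NumericMatrix Ur,
                       Rcpp::NumericMatrix Vr, Rcpp::NumericVector mur) {
  imat G = Rcpp::as<imat>(Gr);
  mat U = Rcpp::as<mat>(Ur), V = Rcpp::as<mat>(Vr);
  vec mu = Rcpp::as<vec>(mur);
  return loglik_all(G, U, V, mu, K);
}

// [[Rcpp::export(name = ".cpp_cpca_step")]]
Rcpp::List cpp_cpca_step(Rcpp::IntegerMatrix Gr, int K, Rcpp::NumericMatrix Ur,
                         Rcpp::NumericMatrix Vr, Rcpp::NumericVector mur,
                         std::string what, int damping) {
  imat G = Rcpp::as<imat>(Gr);
  mat U = Rcpp::as<mat>(Ur), V = Rcpp::as<mat>(Vr);
  vec mu = Rcpp::as<vec>(mur);
  int fb = 0;
  if (what == "scores")
    fb = step_scores(G, U, V, mu, K, damping, false);
  else if (what == "loadings")
    fb = step_loadings(G, U, V, mu, K, damping, false);
  else if (what == "offsets")
    fb = step_offsets(G, U, V, mu, K, damping, false);
  else
    Rcpp::stop("unknown step '%s'", what.c_str());
  return Rcpp::List::create(
      Rcpp::Named("U") = U, Rcpp::Named("V") = V, Rcpp::Named("mu") = mu,
      Rcpp::Named("loglik") = loglik_all(G, U, V, mu, K),
      Rcpp::Named("n_fallbacks") = fb);
}

// [[Rcpp::export(name = ".cpp_cpca_orthonormalize")]]
Rcpp::List cpp_cpca_orthonormalize(Rcpp::NumericMatrix Ur,
                                   Rcpp::NumericMatrix Vr) {
  mat U = Rcpp::as<mat>(Ur), V = Rcpp::as<mat>(Vr);
  double mindiag = orthonormalize_qr(U, V);
  return Rcpp::List::create(Rcpp::Named("U") = U, Rcpp::Named("V") = V,
                            Rcpp::Named("min_rdiag") = mindiag);
}

// [[Rcpp::export(name = ".cpp_cpca_fit")]]
Rcpp::List cpp_cpca_fit(Rcpp::IntegerMatrix Gr, int K, Rcpp::NumericMatrix U0,
                        Rcpp::NumericMatrix V0, Rcpp::NumericVector mu0,
                        int max_iter, double tol, int damping,
                        bool batched = false) {
  imat G = Rcpp::as<imat>(Gr);
  mat U = Rcpp::as<mat>(U0), V = Rcpp::as<mat>(V0);
  vec mu = Rcpp::as<vec>(mu0);

  if (batched && U.n_cols == 1 && K <= 2)
    return cpca_fit_l1_fast(G, K, U, V, mu, max_iter, tol, damping);
  if (U.n_cols == 1 && K <= 2)
    return cpca_fit_l1(G, K, U, V, mu, max_iter, tol, damping);

  int fallbacks = 0, iter = 0;
  bool converged = false;
  std::vector<double> trace;
  double ll_prev = loglik_all(G, U, V, mu, K);
  trace.push_back(ll_prev);

  mat U_old = U, V_old = V;
  vec mu_old = mu;
  for (iter = 1; iter <= max_iter; ++iter) {
    U_old = U; V_old = V; mu_old = mu;
    fallbacks += step_scores(G, U, V, mu, K, damping, true);
    double mindiag = orthonormalize_qr(U, V);
    if (mindiag < 1e-12)
      Rcpp::stop("stacked loading matrix is rank deficient; reduce latent_dim");
    fallbacks += step_loadings(G, U, V, mu, K, damping, true);
    fallbacks += step_offsets(G, U, V, mu, K, damping, true);
    double ll = loglik_all(G, U, V, mu, K);
    // joint extrapolation along the iteration direction (heavy-ball /
    // SQUAREM-style): alternating updates zigzag on bilinear ridges, and a
    // coordinated (U, V, mu) move along the last displacement escapes them;
    // candidates are only accepted if they improve, so the trace stays
    // monotone.
    for (double alpha = 1.0; alpha <= 16.0; alpha *= 2.0) {
      mat Ue = U + alpha * (U - U_old);
      mat Ve = V + alpha * (V - V_old);
      vec me = mu + alpha * (mu - mu_old);
      double lle = loglik_all(G, Ue, Ve, me, K);
      if (lle > ll) {
        U = Ue; V = Ve; mu = me;
        ll = lle;
      } else {
        break;
      }
    }
    trace.push_back(ll);
    if (ll - ll_prev <= tol * (std::abs(ll_prev) + 1e-10)) {
      converged = true;
      ll_prev = ll;
      break;
    }
    ll_prev = ll;
  }
  orthonormalize_qr(U, V);

  return Rcpp::List::create(
      Rcpp::Named("U") = U, Rcpp::Named("V") = V, Rcpp::Named("mu") = mu,
      Rcpp::Named("loglik") = ll_prev,
      Rcpp::Named("trace") = Rcpp::wrap(trace),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("n_iterations") = std::min(iter, max_iter),
      Rcpp::Named("n_fallbacks") = fallbacks);
}

// ---------------------------------------------------------------------------
// Logistic regression of a binary outcome on one predictor: Newton MLE with
// Wald statistic, refit with Firth's penalized score under separation.

struct LogisticFit {
  double b0, b1, se1, t;
  bool converged, firth;
};

static void logistic_eta_p(const vec& x, double b0, double b1, vec& eta,
                           vec& p, vec& w) {
  eta = b0 + b1 * x;
  eta = clamp(eta, -THETA_CLIP, THETA_CLIP);
  p = 1.0 / (1.0 + exp(-eta));
  w = p % (1.0 - p);
}

static bool info2_solve(const vec& x, const vec& w, const vec& rhs0,
                        mat& Iinv, vec& delta) {
  mat I(2, 2);
  I(0, 0) = accu(w);
  I(0, 1) = I(1, 0) = accu(w % x);
  I(1, 1) = accu(w % x % x);
  if (!inv(Iinv, I)) return false;
  delta = Iinv * rhs0;
  return delta.is_finite();
}

static LogisticFit logistic_firth(const vec& x, const vec& y) {
  LogisticFit f{0, 0, NA_REAL, NA_REAL, false, true};
  double b0 = 0, b1 = 0;
  vec eta, p, w;
  mat Iinv;
  for (int it = 0; it < 150; ++it) {
    logistic_eta_p(x, b0, b1, eta, p, w);
    mat I(2, 2);
    I(0, 0) = accu(w);
    I(0, 1) = I(1, 0) = accu(w % x);
    I(1, 1) = accu(w % x % x);
    if (!inv(Iinv, I)) break;
    // leverages of the weighted design
    vec h(x.n_elem);
    for (uword i = 0; i < x.n_elem; ++i) {
      vec xi = {1.0, x(i)};
      h(i) = w(i) * as_scalar(xi.t() * Iinv * xi);
    }
    vec resid = y - p + h % (0.5 - p);
    vec score = {accu(resid), accu(resid % x)};
    vec delta = Iinv * score;
    double nd = norm(delta, 2);
    if (nd > 5.0) delta *= 5.0 / nd;  // trust region
    b0 += delta(0);
    b1 += delta(1);
    if (std::max(std::abs(delta(0)), std::abs(delta(1))) < 1e-8) {
      f.converged = true;
      break;
    }
  }
  logistic_eta_p(x, b0, b1, eta, p, w);
  mat I(2, 2);
  I(0, 0) = accu(w);
  I(0, 1) = I(1, 0) = accu(w % x);
  I(1, 1) = accu(w % x % x);
  f.b0 = b0;
  f.b1 = b1;
  if (inv(Iinv, I) && Iinv(1, 1) > 0) {
    f.se1 = std::sqrt(Iinv(1, 1));
    f.t = b1 / f.se1;
  }
  return f;
}

static LogisticFit logistic_wald(const vec& x, const vec& y) {
  LogisticFit f{0, 0, NA_REAL, NA_REAL, false, false};
  double b0 = std::log((accu(y) + 0.5) / (y.n_elem - accu(y) + 0.5)), b1 = 0;
  vec eta, p, w;
  mat Iinv;
  for (int it = 0; it < 60; ++it) {
    logistic_eta_p(x, b0, b1, eta, p, w);
    vec score = {accu(y - p), accu((y - p) % x)};
    vec delta;
    if (!info2_solve(x, w, score, Iinv, delta)) break;
    double nd = norm(delta, 2);
    if (nd > 10.0) delta *= 10.0 / nd;
    b0 += delta(0);
    b1 += delta(1);
    if (std::max(std::abs(delta(0)), std::abs(delta(1))) < 1e-10) {
      f.converged = true;
      break;
    }
  }
  if (!f.converged || std::abs(b1) > 15.0 || std::abs(b0) > 15.0)
    return logistic_firth(x, y);
  logistic_eta_p(x, b0, b1, eta, p, w);
  vec dummy_rhs = {0, 0}, dd;
  if (!info2_solve(x, w, dummy_rhs, Iinv, dd) || Iinv(1, 1) <= 0)
    return logistic_firth(x, y);
  f.b0 = b0;
  f.b1 = b1;
  f.se1 = std::sqrt(Iinv(1, 1));
  f.t = b1 / f.se1;
  return f;
}

// [[Rcpp::export(name = ".cpp_logistic_wald")]]
Rcpp::List cpp_logistic_wald(Rcpp::NumericVector xr, Rcpp::NumericVector yr) {
  vec x = Rcpp::as<vec>(xr), y = Rcpp::as<vec>(yr);
  LogisticFit f = logistic_wald(x, y);
  return Rcpp::List::create(
      Rcpp::Named("beta0") = f.b0, Rcpp::Named("beta1") = f.b1,
      Rcpp::Named("se1") = f.se1, Rcpp::Named("t") = f.t,
      Rcpp::Named("converged") = f.converged, Rcpp::Named("firth") = f.firth);
}

// Per-SNP logistic screening on the numeric 0/1/2 coding.  Returns the Wald
// t per column (NA for constant columns; caller assigns p = 1 there).
// [[Rcpp::export(name = ".cpp_screen_logistic")]]
Rcpp::List cpp_screen_logistic(Rcpp::NumericMatrix Gr, Rcpp::NumericVector yr) {
  mat G = Rcpp::as<mat>(Gr);
  vec y = Rcpp::as<vec>(yr);
  const int d = G.n_cols;
  vec t(d), firth(d, fill::zeros);
  for (int j = 0; j < d; ++j) {
    vec x = G.col(j);
    if (x.max() - x.min() < 1e-12) {
      t(j) = NA_REAL;
      continue;
    }
    LogisticFit f = logistic_wald(x, y);
    t(j) = f.t;
    firth(j) = f.firth ? 1.0 : 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("t") = t, Rcpp::Named("firth") = firth);
}
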