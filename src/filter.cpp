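#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// scalar-first quaternion -> rotation matrix (sensor -> Earth)
static arma::mat33 quat_to_rot(const arma::vec4 &q) {
  double a = q(0), b = q(1), c = q(2), d = q(3);
  arma::mat33 R;
  R(0, 0) = a * a + b * b - c * c - d * d;
  R(1, 0) = 2 * (b * c + a * d);
  R(2, 0) = 2 * (b * d - a * c);
  R(0, 1) = 2 * (b * c - a * d);
  R(1, 1) = a * a - b * b + c * c - d * d;
  R(2, 1) = 2 * (c * d + a * b);
  R(0, 2) = 2 * (b * d + a * c);
  R(1, 2) = 2 * (c * d - a * b);
  R(2, 2) = a * a - b * b - c * c + d * d;
  return R;
}

static arma::vec4 quat_mult(const arma::vec4 &p, const arma::vec4 &q) {
  arma::vec4 r;
  r(0) = p(0) * q(0) - p(1) * q(1) - p(2) * q(2) - p(3) * q(3);
  r(1) = p(0) * q(1) + p(1) * q(0) + p(2) * q(3) - p(3) * q(2);
  r(2) = p(0) * q(2) - p(1) * q(3) + p(2) * q(0) + p(3) * q(1);
  r(3) = p(0) * q(3) + p(1) * q(2) - p(2) * q(1) + p(3) * q(0);
  return r;
}

// residual of the accel/mag alignment cost: acc (unit) should map to
// Earth-down (0,0,1); the horizontal component of mag should map to North.
static arma::vec residual(const arma::vec4 &q_raw, const arma::vec3 &ahat,
                          const arma::vec3 &mhat, bool use_mag) {
  arma::vec4 q = arma::normalise(q_raw);
  arma::mat33 R = quat_to_rot(q);
  arma::vec3 aE = R * ahat;
  arma::vec e(5, arma::fill::zeros);
  e(0) = aE(0);
  e(1) = aE(1);
  e(2) = aE(2) - 1.0;
  if (use_mag) {
    arma::vec3 mE = R * mhat;
    double hn = std::sqrt(mE(0) * mE(0) + mE(1) * mE(1));
    if (hn > 1e-12) {
      e(3) = mE(0) / hn - 1.0;
      e(4) = mE(1) / hn;
    }
  }
  return e;
}

// Gauss-Newton minimisation of the accel/mag cost over the 4 quaternion
// components (renormalised inside the residual), with step-halving on a
// cost increase. Returns the refined unit quaternion.
static arma::vec4 gn_refine(const arma::vec4 &q0, const arma::vec3 &acc,
                            const arma::vec3 &mag, int max_iter, double tol) {
  double an = arma::norm(acc), mn = arma::norm(mag);
  if (an < 1e-12 || mn < 1e-12) return arma::normalise(q0);
  arma::vec3 ahat = acc / an, mhat = mag / mn;
  bool use_mag = arma::norm(arma::cross(ahat, mhat)) > 1e-8;
  arma::vec4 q = arma::normalise(q0);
  arma::vec e = residual(q, ahat, mhat, use_mag);
  double cost = arma::dot(e, e);
  const double eps = 1e-6;
  for (int it = 0; it < max_iter; ++it) {
    if (cost < 1e-20) break;
    arma::mat J(5, 4);
    for (int k = 0; k < 4; ++k) {
      arma::vec4 qp = q, qm = q;
      qp(k) += eps;
      qm(k) -= eps;
      J.col(k) = (residual(qp, ahat, mhat, use_mag) -
                  residual(qm, ahat, mhat, use_mag)) / (2 * eps);
    }
    arma::mat44 A = J.t() * J;
    // the normalisation makes the radial direction gradient-free, so the
    // normal matrix is rank-deficient; damp proportionally to its scale
    A.diag() += 1e-9 * arma::trace(A) + 1e-12;
    arma::vec4 delta;
    bool ok = arma::solve(delta, A, -(J.t() * e), arma::solve_opts::fast);
    if (!ok) break;
    double step = 1.0;
    arma::vec4 q_new;
    double cost_new = cost;
    bool improved = false;
    for (int h = 0; h < 6; ++h) {
      q_new = arma::normalise(q + step * delta);
      arma::vec e_new = residual(q_new, ahat, mhat, use_mag);
      cost_new = arma::dot(e_new, e_new);
      if (cost_new <= cost) { improved = true; e = e_new; break; }
      step *= 0.5;
    }
    if (!improved) break;
    double dn = arma::norm(step * delta);
    q = q_new;
    cost = cost_new;
    if (dn < tol) break;
  }
  if (q(0) < 0) q = -q;
  return q;
}

// [[Rcpp::export]]
NumericVector gn_correct_cpp(NumericVector q_init, NumericVector acc,
                             NumericVector mag, int max_iter, double tol) {
  arma::vec4 q0(q_init.begin());
  arma::vec3 a(acc.begin()), m(mag.begin());
  arma::vec4 q = gn_refine(q0, a, m, max_iter, tol);
  return NumericVector(q.begin(), q.end());
}

// Complementary orientation filter: per sample, gyroscope quaternion
// integration (short term) fused by normalised weighted averaging with the
// Gauss-Newton accel/mag solution (long term, weight 1 - mu).
// acc/gyro/mag are N x 3; returns N x 4 scalar-first unit quaternions.
// [[Rcpp::export]]
NumericMatrix filter_core_cpp(NumericMatrix acc, NumericMatrix gyro,
                              NumericMatrix mag, double dt, double mu,
                              int max_iter, double tol, NumericVector q_init,
                              int prefix_n) {
  int n = acc.nrow();
  NumericMatrix out(n, 4);
  arma::vec4 q(q_init.begin());
  q = arma::normalise(q);
  for (int i = 0; i < n; ++i) {
    arma::vec4 q_gyro;
    // no step at the start, and none across the prefix boundary: the
    // steady-state prefix is held (fictitious) time, so no rotation elapses
    // between its last sample and the first real one
    if (i == 0 || i == prefix_n) {
      q_gyro = q;
    } else {
      // trapezoidal angular rate over the step, exact exponential-map update
      arma::vec3 w;
      w(0) = 0.5 * (gyro(i, 0) + gyro(i - 1, 0));
      w(1) = 0.5 * (gyro(i, 1) + gyro(i - 1, 1));
      w(2) = 0.5 * (gyro(i, 2) + gyro(i - 1, 2));
      double wn = arma::norm(w);
      arma::vec4 dq;
      if (wn < 1e-12) {
        dq = {1.0, 0.0, 0.0, 0.0};
      } else {
        double half = 0.5 * wn * dt;
        dq(0) = std::cos(half);
        dq(1) = std::sin(half) * w(0) / wn;
        dq(2) = std::sin(half) * w(1) / wn;
        dq(3) = std::sin(half) * w(2) / wn;
      }
      q_gyro = arma::normalise(quat_mult(q, dq));
    }
    arma::vec3 a, m;
    a(0) = acc(i, 0); a(1) = acc(i, 1); a(2) = acc(i, 2);
    m(0) = mag(i, 0); m(1) = mag(i, 1); m(2) = mag(i, 2);
    arma::vec4 q_gn = gn_refine(q_gyro, a, m, max_iter, tol);
    if (arma::dot(q_gn, q_gyro) < 0) q_gn = -q_gn;
    q = arma::normalise(mu * q_gyro + (1.0 - mu) * q_gn);
    if (q(0) < 0) q = -q;
    out(i, 0) = q(0); out(i, 1) = q(1); out(i, 2) = q(2); out(i, 3) = q(3);
  }
  return out;
}

// Greedy selection of the k largest local maxima of each column of a
// one-sided magnitude spectrum, enforcing a pairwise bin separation of at
// least minsep. Returns a (2k) x M matrix: rows 1..k the peak magnitudes,
// rows k+1..2k the 1-based bin indices (0 where fewer peaks qualify).
// [[Rcpp::export]]
NumericMatrix dft_peaks_cpp(NumericMatrix mag, int k, int minsep) {
  int nb = mag.nrow(), m = mag.ncol();
  NumericMatrix out(2 * k, m);
  std::vector<int> cand;
  cand.reserve(nb);
  std::vector<int> chosen;
  for (int j = 0; j < m; ++j) {
    cand.clear();
    for (int i = 0; i < nb; ++i) {
      bool left = (i == 0) || (mag(i, j) >= mag(i - 1, j));
      bool right = (i == nb - 1) || (mag(i, j) >= mag(i + 1, j));
      if (left && right) cand.push_back(i);
    }
    // sort candidates by magnitude descending, ties toward lower index
    std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
      if (mag(a, j) != mag(b, j)) return mag(a, j) > mag(b, j);
      return a < b;
    });
    chosen.clear();
    for (size_t c = 0; c < cand.size() && (int)chosen.size() < k; ++c) {
      int idx = cand[c];
      bool far_enough = true;
      for (size_t s = 0; s < chosen.size(); ++s) {
        if (std::abs(idx - chosen[s]) < minsep) { far_enough = false; break; }
      }
      if (far_enough) chosen.push_back(idx);
    }
    for (size_t s = 0; s < chosen.size(); ++s) {
      out(s, j) = mag(chosen[s], j);
      out(k + s, j) = chosen[s] + 1;
    }
  }
  return out;
}
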