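// Compiled inner loops for the egg-chamber rotation model.
//
// The base (axis-constrained) integrator stores crawling forces in each
// cell's tangent-frame components (b1 along t1, b2 along t2).  On a surface
// of revolution the meridional component exerts no torque about the long
// axis and the rigid-body velocity is purely azimuthal, so the torque sum
// and the Fat2 velocity term reduce to the azimuthal lever arm
// a2_i = (z x r_i) . t2_i.  Together with a sign-symmetric angular grid this
// makes the chirality mirror (beta -> -beta) an exact floating-point
// symmetry of the integrator.  The R-level step functions implement the
// unreduced vector algebra and are tested against this loop.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// inverse-CDF draw over M bins with weights w (all > 0); consumes u in [0,1)
static inline int draw_bin(const double* w, int M, double u, double* cs) {
  double acc = 0.0;
  for (int k = 0; k < M; ++k) { acc += w[k]; cs[k] = acc; }
  double target = u * acc;
  int k = 0;
  while (k < M - 1 && cs[k] < target) ++k;
  return k;
}

// [[Rcpp::export]]
List cpp_run_base(NumericMatrix positions, NumericMatrix normals,
                  NumericMatrix t1, NumericMatrix t2,
                  double Pi_e, double tau1, double tau2, double tau3,
                  double dt, int n_steps, int M, int resample_every,
                  double c_floor, int record_every, int snapshot_every,
                  bool mirror, double omega_max) {
  const int N = positions.nrow();

  // angular grid (sign-symmetric for even M, matching beta_centers())
  std::vector<double> centers(M), ck(M), sk(M);
  {
    double h = 2.0 * M_PI / M;
    if (M % 2 == 0) {
      int half = M / 2;
      for (int k = 0; k < half; ++k) {
        double a = (k + 0.5) * h;
        centers[half + k] = a;
        centers[half - 1 - k] = -a;
      }
    } else {
      for (int k = 0; k < M; ++k) centers[k] = -M_PI + (k + 0.5) * h;
    }
    for (int k = 0; k < M; ++k) { ck[k] = std::cos(centers[k]); sk[k] = std::sin(centers[k]); }
  }

  // azimuthal lever arm / speed factor a2_i = (z x r_i) . t2_i
  std::vector<double> a2(N);
  for (int i = 0; i < N; ++i)
    a2[i] = -positions(i, 1) * t2(i, 0) + positions(i, 0) * t2(i, 1);

  std::vector<double> fat2((size_t)N * M, 1.0 / (2.0 * M_PI));
  std::vector<double> b1(N, 0.0), b2(N, 0.0);
  std::vector<double> cosb(N, 0.0), sinb(N, 0.0), beta(N, 0.0);
  std::vector<double> cs(M), wrev(M);
  double omega3 = 0.0;

  std::vector<double> rec_t, rec_w;
  std::vector<double> snap_t;
  std::vector<std::vector<double> > snaps;

  // initial snapshot (isotropic)
  {
    std::vector<double> row(M, 1.0 / (2.0 * M_PI));
    snap_t.push_back(0.0);
    snaps.push_back(row);
  }

  GetRNGstate();
  for (int s = 0; s < n_steps; ++s) {
    if (s % resample_every == 0) {
      for (int i = 0; i < N; ++i) {
        double u = unif_rand();
        const double* ci = &fat2[(size_t)i * M];
        int k;
        if (mirror) {
          for (int j = 0; j < M; ++j) wrev[j] = ci[M - 1 - j];
          k = draw_bin(wrev.data(), M, u, cs.data());
          beta[i] = -centers[k];
          cosb[i] = ck[k];
          sinb[i] = -sk[k];
        } else {
          k = draw_bin(ci, M, u, cs.data());
          beta[i] = centers[k];
          cosb[i] = ck[k];
          sinb[i] = sk[k];
        }
      }
    }
    // force relaxation towards -eta in the co-rotating tangent frame
    double torque = 0.0;
    for (int i = 0; i < N; ++i) {
      b1[i] = b1[i] - dt * tau1 * (cosb[i] + b1[i]);
      b2[i] = b2[i] - dt * tau1 * (sinb[i] + b2[i]);
      torque += b2[i] * a2[i];
    }
    omega3 = torque / Pi_e;
    if (!std::isfinite(omega3) || std::fabs(omega3) > omega_max) {
      PutRNGstate();
      stop("integration diverged at t = %g (omega3 = %g)", (s + 1) * dt, omega3);
    }
    // mechanosensitive Fat2 update; v_i . m(beta_k) = omega3 * a2_i * sin(beta_k)
    for (int i = 0; i < N; ++i) {
      double va = omega3 * a2[i];
      double* ci = &fat2[(size_t)i * M];
      for (int k = 0; k < M; ++k) {
        double vm = va * sk[k];
        double c = ci[k];
        c = c - dt * tau2 * (tau3 * vm + c) * c;
        if (c < c_floor) c = c_floor;
        ci[k] = c;
      }
    }
    int s1 = s + 1;
    if (s1 % record_every == 0 || s1 == n_steps) {
      rec_t.push_back(s1 * dt);
      rec_w.push_back(omega3);
    }
    if (s1 % snapshot_every == 0 || s1 == n_steps) {
      std::vector<double> row(M, 0.0);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < M; ++k) row[k] += fat2[(size_t)i * M + k];
      for (int k = 0; k < M; ++k) row[k] /= N;
      snap_t.push_back(s1 * dt);
      snaps.push_back(row);
    }
  }
  PutRNGstate();
  double min_c = *std::min_element(fat2.begin(), fat2.end());

  NumericMatrix fat2_out(N, M), forces(N, 3), snap_out((int)snaps.size(), M);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < M; ++k) fat2_out(i, k) = fat2[(size_t)i * M + k];
    for (int d = 0; d < 3; ++d) forces(i, d) = b1[i] * t1(i, d) + b2[i] * t2(i, d);
  }
  for (size_t r = 0; r < snaps.size(); ++r)
    for (int k = 0; k < M; ++k) snap_out((int)r, k) = snaps[r][k];

  return List::create(
    _["times"] = wrap(rec_t), _["omega3"] = wrap(rec_w),
    _["snapshot_times"] = wrap(snap_t), _["snapshots"] = snap_out,
    _["fat2"] = fat2_out, _["forces"] = forces, _["beta"] = wrap(beta),
    _["min_c"] = min_c, _["max_abs_bn"] = 0.0);
}

// --- full 3-D rotation (free sphere / pre-stalk interface) ----------------

static inline void quat_mul(const double* p, const double* q, double* out) {
  out[0] = p[0]*q[0] - p[1]*q[1] - p[2]*q[2] - p[3]*q[3];
  out[1] = p[0]*q[1] + p[1]*q[0] + p[2]*q[3] - p[3]*q[2];
  out[2] = p[0]*q[2] - p[1]*q[3] + p[2]*q[0] + p[3]*q[1];
  out[3] = p[0]*q[3] + p[1]*q[2] - p[2]*q[1] + p[3]*q[0];
}

static inline void quat_to_R(const double* q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2*(y*y + z*z); R[0][1] = 2*(x*y - w*z); R[0][2] = 2*(x*z + w*y);
  R[1][0] = 2*(x*y + w*z); R[1][1] = 1 - 2*(x*x + z*z); R[1][2] = 2*(y*z - w*x);
  R[2][0] = 2*(x*z - w*y); R[2][1] = 2*(y*z + w*x); R[2][2] = 1 - 2*(x*x + y*y);
}

// solve 3x3 symmetric positive-definite system A x = b (Gaussian elimination
// with partial pivoting; A is well conditioned: Pi*I plus a PSD drag term)
static inline void solve3(double A[3][3], const double* b, double* x) {
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
    M[i][3] = b[i];
  }
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (piv != col)
      for (int j = col; j < 4; ++j) std::swap(M[col][j], M[piv][j]);
    for (int r = col + 1; r < 3; ++r) {
      double f = M[r][col] / M[col][col];
      for (int j = col; j < 4; ++j) M[r][j] -= f * M[col][j];
    }
  }
  for (int i = 2; i >= 0; --i) {
    double acc = M[i][3];
    for (int j = i + 1; j < 3; ++j) acc -= M[i][j] * x[j];
    x[i] = acc / M[i][i];
  }
}

// [[Rcpp::export]]
List cpp_run_sphere(NumericMatrix positions, NumericMatrix normals,
                    NumericMatrix t1, NumericMatrix t2,
                    double Pi_iso, double tau1, double tau2, double tau3,
                    double dt, int n_steps, int M, int resample_every,
                    double c_floor, int record_every,
                    double ks, double mus, double theta_s,
                    double omega_max) {
  const int N = positions.nrow();
  const double e3[3] = {0.0, 0.0, 1.0};
  const double cos_ts = std::cos(theta_s);
  const bool constrained = (ks > 0.0 || mus > 0.0);

  std::vector<double> centers(M), ck(M), sk(M);
  {
    double h = 2.0 * M_PI / M;
    if (M % 2 == 0) {
      int half = M / 2;
      for (int k = 0; k < half; ++k) {
        double a = (k + 0.5) * h;
        centers[half + k] = a;
        centers[half - 1 - k] = -a;
      }
    } else {
      for (int k = 0; k < M; ++k) centers[k] = -M_PI + (k + 0.5) * h;
    }
    for (int k = 0; k < M; ++k) { ck[k] = std::cos(centers[k]); sk[k] = std::sin(centers[k]); }
  }

  std::vector<double> fat2((size_t)N * M, 1.0 / (2.0 * M_PI));
  std::vector<double> b1(N, 0.0), b2(N, 0.0), cosb(N, 0.0), sinb(N, 0.0), beta(N, 0.0);
  std::vector<double> cs(M);
  double q[4] = {1.0, 0.0, 0.0, 0.0};

  std::vector<double> rec_t, rec_w3, rec_wx, rec_wy, rec_wz;
  std::vector<double> rec_d3x, rec_d3y, rec_d3z;

  GetRNGstate();
  for (int s = 0; s < n_steps; ++s) {
    if (s % resample_every == 0) {
      for (int i = 0; i < N; ++i) {
        double u = unif_rand();
        const double* ci = &fat2[(size_t)i * M];
        int k = draw_bin(ci, M, u, cs.data());
        beta[i] = centers[k];
        cosb[i] = std::cos(beta[i]);
        sinb[i] = std::sin(beta[i]);
      }
    }
    double R[3][3];
    quat_to_R(q, R);

    // forces and body-frame active torque tau_b = sum_i r_i x b_i
    double tb[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < N; ++i) {
      b1[i] = b1[i] - dt * tau1 * (cosb[i] + b1[i]);
      b2[i] = b2[i] - dt * tau1 * (sinb[i] + b2[i]);
      double bx = b1[i] * t1(i, 0) + b2[i] * t2(i, 0);
      double by = b1[i] * t1(i, 1) + b2[i] * t2(i, 1);
      double bz = b1[i] * t1(i, 2) + b2[i] * t2(i, 2);
      double rx = positions(i, 0), ry = positions(i, 1), rz = positions(i, 2);
      tb[0] += ry * bz - rz * by;
      tb[1] += rz * bx - rx * bz;
      tb[2] += rx * by - ry * bx;
    }
    // lab-frame torque
    double T[3];
    for (int d = 0; d < 3; ++d)
      T[d] = R[d][0] * tb[0] + R[d][1] * tb[1] + R[d][2] * tb[2];

    double d3[3] = {R[0][2], R[1][2], R[2][2]};
    double omega[3];
    if (constrained) {
      // elastic restoring torque ks * (d3 x e3)
      T[0] += ks * (d3[1] * e3[2] - d3[2] * e3[1]);
      T[1] += ks * (d3[2] * e3[0] - d3[0] * e3[2]);
      T[2] += ks * (d3[0] * e3[1] - d3[1] * e3[0]);
      // drag operator: Pi*I + mus * sum_cap (I - r' r'^T), r' = R r_j unit
      double A[3][3] = {{Pi_iso, 0, 0}, {0, Pi_iso, 0}, {0, 0, Pi_iso}};
      if (mus > 0.0) {
        for (int i = 0; i < N; ++i) {
          double rx = positions(i, 0), ry = positions(i, 1), rz = positions(i, 2);
          double px = R[0][0]*rx + R[0][1]*ry + R[0][2]*rz;
          double py = R[1][0]*rx + R[1][1]*ry + R[1][2]*rz;
          double pz = R[2][0]*rx + R[2][1]*ry + R[2][2]*rz;
          if (px*e3[0] + py*e3[1] + pz*e3[2] >= cos_ts) {
            A[0][0] += mus * (1.0 - px*px); A[0][1] += mus * (-px*py); A[0][2] += mus * (-px*pz);
            A[1][0] += mus * (-py*px); A[1][1] += mus * (1.0 - py*py); A[1][2] += mus * (-py*pz);
            A[2][0] += mus * (-pz*px); A[2][1] += mus * (-pz*py); A[2][2] += mus * (1.0 - pz*pz);
          }
        }
      }
      solve3(A, T, omega);
    } else {
      for (int d = 0; d < 3; ++d) omega[d] = T[d] / Pi_iso;
    }
    double wn = std::sqrt(omega[0]*omega[0] + omega[1]*omega[1] + omega[2]*omega[2]);
    if (!std::isfinite(wn) || wn > omega_max) {
      PutRNGstate();
      stop("integration diverged at t = %g (|omega| = %g)", (s + 1) * dt, wn);
    }

    // advance orientation: q <- exp(omega*dt/2) (x) q, renormalized
    if (wn > 0.0) {
      double half_angle = 0.5 * wn * dt;
      double sa = std::sin(half_angle) / wn;
      double dq[4] = {std::cos(half_angle), sa * omega[0], sa * omega[1], sa * omega[2]};
      double qn[4];
      quat_mul(dq, q, qn);
      double nrm = std::sqrt(qn[0]*qn[0] + qn[1]*qn[1] + qn[2]*qn[2] + qn[3]*qn[3]);
      for (int d = 0; d < 4; ++d) q[d] = qn[d] / nrm;
    }

    // Fat2 update with body-frame velocity v_i = (R^T omega) x r_i
    double wb[3];
    for (int d = 0; d < 3; ++d)
      wb[d] = R[0][d]*omega[0] + R[1][d]*omega[1] + R[2][d]*omega[2];
    for (int i = 0; i < N; ++i) {
      double rx = positions(i, 0), ry = positions(i, 1), rz = positions(i, 2);
      double vx = wb[1]*rz - wb[2]*ry;
      double vy = wb[2]*rx - wb[0]*rz;
      double vz = wb[0]*ry - wb[1]*rx;
      double vm1 = vx*t1(i,0) + vy*t1(i,1) + vz*t1(i,2);
      double vm2 = vx*t2(i,0) + vy*t2(i,1) + vz*t2(i,2);
      double* ci = &fat2[(size_t)i * M];
      for (int k = 0; k < M; ++k) {
        double vm = vm1 * ck[k] + vm2 * sk[k];
        double c = ci[k];
        c = c - dt * tau2 * (tau3 * vm + c) * c;
        if (c < c_floor) c = c_floor;
        ci[k] = c;
      }
    }

    int s1 = s + 1;
    if (s1 % record_every == 0 || s1 == n_steps) {
      double Rn[3][3];
      quat_to_R(q, Rn);
      double d3n[3] = {Rn[0][2], Rn[1][2], Rn[2][2]};
      rec_t.push_back(s1 * dt);
      rec_wx.push_back(omega[0]); rec_wy.push_back(omega[1]); rec_wz.push_back(omega[2]);
      rec_w3.push_back(omega[0]*d3n[0] + omega[1]*d3n[1] + omega[2]*d3n[2]);
      rec_d3x.push_back(d3n[0]); rec_d3y.push_back(d3n[1]); rec_d3z.push_back(d3n[2]);
    }
  }
  PutRNGstate();
  double min_c = *std::min_element(fat2.begin(), fat2.end());

  int K = (int)rec_t.size();
  NumericMatrix omega_out(K, 3), d3_out(K, 3), fat2_out(N, M), forces(N, 3);
  for (int r = 0; r < K; ++r) {
    omega_out(r, 0) = rec_wx[r]; omega_out(r, 1) = rec_wy[r]; omega_out(r, 2) = rec_wz[r];
    d3_out(r, 0) = rec_d3x[r]; d3_out(r, 1) = rec_d3y[r]; d3_out(r, 2) = rec_d3z[r];
  }
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < M; ++k) fat2_out(i, k) = fat2[(size_t)i * M + k];
    for (int d = 0; d < 3; ++d) forces(i, d) = b1[i] * t1(i, d) + b2[i] * t2(i, d);
  }
  NumericVector qout(4);
  for (int d = 0; d < 4; ++d) qout[d] = q[d];

  return List::create(
    _["times"] = wrap(rec_t), _["omega"] = omega_out,
    _["omega3"] = wrap(rec_w3), _["d3"] = d3_out,
    _["quat"] = qout, _["fat2"] = fat2_out, _["forces"] = forces,
    _["beta"] = wrap(beta), _["min_c"] = min_c);
}
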