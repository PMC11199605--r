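// Time steppers for the vegetation models.
//
// Both models share the same mixed boundary conventions: the x direction is
// either pinned to bare ground (Dirichlet, b = 0 on the first and last grid
// column and on ghost nodes beyond them) or periodic; the y direction is
// always periodic.  Explicit RK4 is used throughout, matching the scheme the
// models are normally integrated with.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cx_mat;

static const double DIVERGENCE_CAP = 1e3;
static const double EXPONENT_CAP = 50.0;

// rhs of the reduced fourth-order PDE:
//   -eta b + kappa b^2 - b^3/2 + d lap(b) - b (alpha bx + gamma bxx + bxxxx)
static void rhs_reduced_core(const mat& b, mat& out,
                             double eta, double kappa, double d,
                             double alpha, double gamma_,
                             double dx, double dy, bool dirichlet_x) {
  const int nx = b.n_rows, ny = b.n_cols;
  const double idx = 1.0 / dx, idx2 = idx * idx, idx4 = idx2 * idx2;
  const double idy2 = 1.0 / (dy * dy);
  out.zeros(nx, ny);
  const int i0 = dirichlet_x ? 1 : 0, i1 = dirichlet_x ? nx - 2 : nx - 1;
  // neighbour index tables; -1 marks a zero ghost node (Dirichlet walls)
  std::vector<int> ip1(nx), im1(nx), ip2(nx), im2(nx);
  for (int i = 0; i < nx; ++i) {
    if (dirichlet_x) {
      ip1[i] = i + 1 <= nx - 1 ? i + 1 : -1;
      im1[i] = i - 1 >= 0      ? i - 1 : -1;
      ip2[i] = i + 2 <= nx - 1 ? i + 2 : -1;
      im2[i] = i - 2 >= 0      ? i - 2 : -1;
    } else {
      ip1[i] = (i + 1) % nx;      im1[i] = (i + nx - 1) % nx;
      ip2[i] = (i + 2) % nx;      im2[i] = (i + nx - 2) % nx;
    }
  }
  for (int j = 0; j < ny; ++j) {
    const int jp = (j + 1) % ny, jm = (j + ny - 1) % ny;
    const double* col  = b.colptr(j);
    const double* colN = b.colptr(jp);
    const double* colS = b.colptr(jm);
    double* o = out.colptr(j);
    for (int i = i0; i <= i1; ++i) {
      const double C = col[i];
      const double E  = ip1[i] >= 0 ? col[ip1[i]] : 0.0;
      const double W  = im1[i] >= 0 ? col[im1[i]] : 0.0;
      const double EE = ip2[i] >= 0 ? col[ip2[i]] : 0.0;
      const double WW = im2[i] >= 0 ? col[im2[i]] : 0.0;
      const double bx    = 0.5 * (E - W) * idx;
      const double bxx   = (E - 2.0 * C + W) * idx2;
      const double bxxxx = (EE - 4.0 * E + 6.0 * C - 4.0 * W + WW) * idx4;
      const double lap   = bxx + (colN[i] - 2.0 * C + colS[i]) * idy2;
      o[i] = -eta * C + kappa * C * C - 0.5 * C * C * C + d * lap
        - C * (alpha * bx + gamma_ * bxx + bxxxx);
    }
  }
}

// [[Rcpp::export]]
arma::mat rhs_reduced_cpp(const arma::mat& b, double eta, double kappa,
                          double d, double alpha, double gamma_,
                          double dx, double dy, bool dirichlet_x) {
  if (!b.is_finite()) stop("non-finite values in input field");
  mat out;
  rhs_reduced_core(b, out, eta, kappa, d, alpha, gamma_, dx, dy, dirichlet_x);
  return out;
}

// [[Rcpp::export]]
List simulate_reduced_cpp(const arma::mat& b0, double eta, double kappa,
                          double d, double alpha, double gamma_,
                          double dx, double dy, double dt, int n_steps,
                          int snap_stride, int rec_stride, bool dirichlet_x) {
  if (!b0.is_finite()) stop("non-finite values in initial condition");
  const int nx = b0.n_rows, ny = b0.n_cols;
  mat b = b0, k1, k2, k3, k4, tmp;
  std::vector<mat> snaps;
  std::vector<int> snap_steps;
  const int nrec = rec_stride > 0 ? n_steps / rec_stride + 1 : 0;
  mat mid_col(ny, std::max(nrec, 1)), mid_row(nx, std::max(nrec, 1));
  std::vector<int> rec_steps;
  const int imid = nx / 2, jmid = ny / 2;
  int irec = 0;
  auto record = [&](int step) {
    if (rec_stride > 0 && step % rec_stride == 0 && irec < nrec) {
      mid_col.col(irec) = b.row(imid).t();
      mid_row.col(irec) = b.col(jmid);
      rec_steps.push_back(step);
      ++irec;
    }
  };
  auto snap = [&](int step) {
    snaps.push_back(b);
    snap_steps.push_back(step);
  };
  snap(0);
  record(0);
  for (int s = 1; s <= n_steps; ++s) {
    rhs_reduced_core(b, k1, eta, kappa, d, alpha, gamma_, dx, dy, dirichlet_x);
    tmp = b + 0.5 * dt * k1;
    rhs_reduced_core(tmp, k2, eta, kappa, d, alpha, gamma_, dx, dy, dirichlet_x);
    tmp = b + 0.5 * dt * k2;
    rhs_reduced_core(tmp, k3, eta, kappa, d, alpha, gamma_, dx, dy, dirichlet_x);
    tmp = b + dt * k3;
    rhs_reduced_core(tmp, k4, eta, kappa, d, alpha, gamma_, dx, dy, dirichlet_x);
    b += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (s % 100 == 0 || s == n_steps) {
      if (!b.is_finite() || arma::abs(b).max() > DIVERGENCE_CAP)
        stop("simulation diverged at step %d", s);
    }
    record(s);
    if (snap_stride > 0 && s % snap_stride == 0 && s != n_steps) snap(s);
  }
  snap(n_steps);
  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snap_list[i] = snaps[i];
  List out = List::create(
    _["snapshots"]  = snap_list,
    _["snap_steps"] = wrap(snap_steps),
    _["rec_steps"]  = wrap(rec_steps));
  if (nrec > 0) {
    out["mid_col"] = mid_col.cols(0, irec - 1);
    out["mid_row"] = mid_row.cols(0, irec - 1);
  }
  return out;
}

// Workspace for the nonlocal model: the padded array, its transform and the
// two feedback convolutions are reused across RK4 stages.
struct NonlocalWork {
  cx_mat pad, F, G;
  mat convf, convc;
};

// kernel-weighted integral of b: zero extension beyond the x boundaries is
// realised by zero-padding to pad_nx rows before the periodic FFT product.
static void conv_pair(const mat& b, const cx_mat& Kf, const cx_mat& Kc,
                      double dxdy, NonlocalWork& w) {
  const int nx = b.n_rows, ny = b.n_cols;
  const int pad_nx = Kf.n_rows;
  w.pad.zeros(pad_nx, ny);
  w.pad.submat(0, 0, nx - 1, ny - 1) =
    arma::conv_to<cx_mat>::from(b);
  w.F = arma::fft2(w.pad);
  w.G = arma::ifft2(w.F % Kf);
  w.convf = arma::real(w.G.submat(0, 0, nx - 1, ny - 1)) * dxdy;
  w.G = arma::ifft2(w.F % Kc);
  w.convc = arma::real(w.G.submat(0, 0, nx - 1, ny - 1)) * dxdy;
}

// [[Rcpp::export]]
arma::mat conv_fft_cpp(const arma::mat& b, const arma::cx_mat& Khat,
                       double dxdy) {
  NonlocalWork w;
  conv_pair(b, Khat, Khat, dxdy, w);
  return w.convf;
}

// rhs of the nonlocal model: b(1-b) Mf - mu b Mc + D lap(b) with
// M_i = exp(chi_i * conv_i).
static void rhs_nonlocal_core(const mat& b, mat& out,
                              const cx_mat& Kf, const cx_mat& Kc,
                              double chi_f, double chi_c, double mu, double D,
                              double dx, double dy, bool dirichlet_x,
                              NonlocalWork& w) {
  const int nx = b.n_rows, ny = b.n_cols;
  conv_pair(b, Kf, Kc, dx * dy, w);
  const double ef = chi_f == 0.0 ? 0.0 : arma::abs(chi_f * w.convf).max();
  const double ec = chi_c == 0.0 ? 0.0 : arma::abs(chi_c * w.convc).max();
  if (ef > EXPONENT_CAP || ec > EXPONENT_CAP)
    stop("feedback exponent magnitude exceeds %g: parameters out of the "
         "intended regime", EXPONENT_CAP);
  const double idx2 = 1.0 / (dx * dx), idy2 = 1.0 / (dy * dy);
  out.zeros(nx, ny);
  const int i0 = dirichlet_x ? 1 : 0, i1 = dirichlet_x ? nx - 2 : nx - 1;
  for (int j = 0; j < ny; ++j) {
    const int jp = (j + 1) % ny, jm = (j + ny - 1) % ny;
    for (int i = i0; i <= i1; ++i) {
      const double C = b(i, j);
      double E, W;
      if (dirichlet_x) {
        E = (i + 1 <= nx - 1) ? b(i + 1, j) : 0.0;
        W = (i - 1 >= 0)      ? b(i - 1, j) : 0.0;
      } else {
        E = b((i + 1) % nx, j);
        W = b((i + nx - 1) % nx, j);
      }
      const double lap = (E - 2.0 * C + W) * idx2
        + (b(i, jp) - 2.0 * C + b(i, jm)) * idy2;
      const double Mf = std::exp(chi_f * w.convf(i, j));
      const double Mc = std::exp(chi_c * w.convc(i, j));
      out(i, j) = C * (1.0 - C) * Mf - mu * C * Mc + D * lap;
    }
  }
}

// [[Rcpp::export]]
arma::mat rhs_nonlocal_cpp(const arma::mat& b, const arma::cx_mat& Kf,
                           const arma::cx_mat& Kc, double chi_f, double chi_c,
                           double mu, double D, double dx, double dy,
                           bool dirichlet_x) {
  if (!b.is_finite()) stop("non-finite values in input field");
  mat out;
  NonlocalWork w;
  rhs_nonlocal_core(b, out, Kf, Kc, chi_f, chi_c, mu, D, dx, dy,
                    dirichlet_x, w);
  return out;
}

// [[Rcpp::export]]
List simulate_nonlocal_cpp(const arma::mat& b0, const arma::cx_mat& Kf,
                           const arma::cx_mat& Kc, double chi_f, double chi_c,
                           double mu, double D, double dx, double dy,
                           double dt, int n_steps, int snap_stride,
                           int rec_stride, bool dirichlet_x) {
  if (!b0.is_finite()) stop("non-finite values in initial condition");
  const int nx = b0.n_rows, ny = b0.n_cols;
  mat b = b0, k1, k2, k3, k4, tmp;
  NonlocalWork w;
  std::vector<mat> snaps;
  std::vector<int> snap_steps;
  const int nrec = rec_stride > 0 ? n_steps / rec_stride + 1 : 0;
  mat mid_col(ny, std::max(nrec, 1)), mid_row(nx, std::max(nrec, 1));
  std::vector<int> rec_steps;
  const int imid = nx / 2, jmid = ny / 2;
  int irec = 0;
  auto record = [&](int step) {
    if (rec_stride > 0 && step % rec_stride == 0 && irec < nrec) {
      mid_col.col(irec) = b.row(imid).t();
      mid_row.col(irec) = b.col(jmid);
      rec_steps.push_back(step);
      ++irec;
    }
  };
  snaps.push_back(b); snap_steps.push_back(0);
  record(0);
  for (int s = 1; s <= n_steps; ++s) {
    rhs_nonlocal_core(b, k1, Kf, Kc, chi_f, chi_c, mu, D, dx, dy, dirichlet_x, w);
    tmp = b + 0.5 * dt * k1;
    rhs_nonlocal_core(tmp, k2, Kf, Kc, chi_f, chi_c, mu, D, dx, dy, dirichlet_x, w);
    tmp = b + 0.5 * dt * k2;
    rhs_nonlocal_core(tmp, k3, Kf, Kc, chi_f, chi_c, mu, D, dx, dy, dirichlet_x, w);
    tmp = b + dt * k3;
    rhs_nonlocal_core(tmp, k4, Kf, Kc, chi_f, chi_c, mu, D, dx, dy, dirichlet_x, w);
    b += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (s % 50 == 0 || s == n_steps) {
      if (!b.is_finite() || arma::abs(b).max() > DIVERGENCE_CAP)
        stop("simulation diverged at step %d", s);
    }
    record(s);
    if (snap_stride > 0 && s % snap_stride == 0 && s != n_steps) {
      snaps.push_back(b); snap_steps.push_back(s);
    }
  }
  snaps.push_back(b); snap_steps.push_back(n_steps);
  List snap_list(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snap_list[i] = snaps[i];
  List out = List::create(
    _["snapshots"]  = snap_list,
    _["snap_steps"] = wrap(snap_steps),
    _["rec_steps"]  = wrap(rec_steps));
  if (nrec > 0) {
    out["mid_col"] = mid_col.cols(0, irec - 1);
    out["mid_row"] = mid_row.cols(0, irec - 1);
  }
  return out;
}
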