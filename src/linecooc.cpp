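#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double half_away(double x) {
  return (x >= 0) ? std::floor(x + 0.5) : -std::floor(-x + 0.5);
}

// Tridiagonal solve with partial pivoting (LAPACK zgtsv algorithm).
// dl, d, du of lengths n-1, n, n-1; rhs b of length n; solves in place.
static bool tridiag_solve(std::vector<arma::cx_double>& dl,
                          std::vector<arma::cx_double>& d,
                          std::vector<arma::cx_double>& du,
                          std::vector<arma::cx_double>& b,
                          std::vector<arma::cx_double>& du2) {
  const int n = (int)d.size();
  std::fill(du2.begin(), du2.end(), arma::cx_double(0.0, 0.0));
  for (int i = 0; i < n - 1; ++i) {
    if (std::norm(d[i]) >= std::norm(dl[i])) {
      if (std::norm(d[i]) == 0.0) return false;
      const arma::cx_double m = dl[i] / d[i];
      d[i + 1] -= m * du[i];
      b[i + 1] -= m * b[i];
      dl[i] = 0.0;  // no du2 fill needed
    } else {
      const arma::cx_double m = d[i] / dl[i];
      d[i] = dl[i];
      const arma::cx_double tmp = d[i + 1];
      d[i + 1] = du[i] - m * tmp;
      du2[i] = (i < n - 2) ? du[i + 1] : arma::cx_double(0.0, 0.0);
      if (i < n - 2) du[i + 1] = -m * du2[i];
      du[i] = tmp;
      const arma::cx_double bt = b[i];
      b[i] = b[i + 1];
      b[i + 1] = bt - m * b[i];
      dl[i] = 1.0;  // marker: row swap happened (du2 used)
    }
  }
  if (std::norm(d[n - 1]) == 0.0) return false;
  b[n - 1] /= d[n - 1];
  if (n > 1)
    b[n - 2] = (b[n - 2] - du[n - 2] * b[n - 1]) / d[n - 2];
  for (int i = n - 3; i >= 0; --i)
    b[i] = (b[i] - du[i] * b[i + 1] - du2[i] * b[i + 2]) / d[i];
  return true;
}

// Resolvent of the direction process: spatial Fourier transform plus a
// theta-Fourier (harmonic) expansion.  For spatial frequency w = (wx, wy)
// the generator becomes tridiagonal over harmonics e^{ik theta}:
//   (alpha + D33 k^2) c_k + (i/2)(conj(W) c_{k-1} + W c_{k+1}) = alpha/(2 pi)
// with W = wx + i wy; angular diffusion is exact in this basis.  Each
// output value is the exact integral of the truncated series over a
// one-pixel theta bin of width pi/n_theta, matching histogram estimates.
// Returns the complex cube [wx, wy, theta-bin] in DFT frequency ordering;
// the conjugate-symmetric half plane is filled by symmetry.
// [[Rcpp::export]]
arma::cx_cube resolvent_fourier_cpp(double alpha, double D33, int L,
                                    int n_theta, int K = 96,
                                    double freq_scale = 1.0) {
  const int Nt = 2 * n_theta;
  const int n = 2 * K + 1;
  const double dth = M_PI / n_theta;

  // bin-integration evaluation matrix: bin j gets sum_k c_k E(j, k)
  arma::cx_mat E(Nt, n);
  for (int j = 0; j < Nt; ++j) {
    const double thj = -M_PI + j * dth;
    for (int q = 0; q < n; ++q) {
      const int k = q - K;
      const double smear =
          (k == 0) ? 1.0 : std::sin(k * dth / 2.0) / (k * dth / 2.0);
      E(j, q) = arma::cx_double(std::cos(k * thj), std::sin(k * thj)) *
                (dth * smear);
    }
  }

  arma::vec freq(L);
  for (int i = 0; i < L; ++i)
    freq[i] = freq_scale * 2.0 * M_PI * ((i <= (L - 1) / 2) ? i : i - L) / L;

  std::vector<arma::cx_double> dl(n - 1), dg(n), du(n - 1), b(n), du2(n);
  arma::cx_cube out(L, L, Nt);
  const int BATCH = 512;
  arma::cx_mat C(n, BATCH);
  std::vector<std::pair<int, int> > where(BATCH);
  int nb = 0;
  auto flush = [&]() {
    if (!nb) return;
    arma::cx_mat vals = E * C.cols(0, nb - 1);   // Nt x nb
    for (int q = 0; q < nb; ++q)
      for (int t = 0; t < Nt; ++t)
        out(where[q].first, where[q].second, t) = vals(t, q);
    nb = 0;
  };
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      const int ip = (L - i) % L, jp = (L - j) % L;
      if (jp < j || (jp == j && ip < i)) continue;  // filled afterwards
      // coupling constants: lower = i conj(W)/2, upper = i W / 2
      const arma::cx_double W(freq[i], freq[j]);
      const arma::cx_double cu = arma::cx_double(0, 0.5) * W;
      const arma::cx_double cl = arma::cx_double(0, 0.5) * std::conj(W);
      for (int q = 0; q < n; ++q) {
        const double k = q - K;
        dg[q] = arma::cx_double(alpha + D33 * k * k, 0.0);
        b[q] = arma::cx_double(alpha / (2.0 * M_PI), 0.0);
        if (q < n - 1) { dl[q] = cl; du[q] = cu; }
      }
      if (!tridiag_solve(dl, dg, du, b, du2))
        stop("singular linear system in resolvent solve");
      for (int q = 0; q < n; ++q) C(q, nb) = b[q];
      where[nb++] = std::make_pair(i, j);
      if (nb == BATCH) flush();
    }
  }
  flush();
  for (int j = 0; j < L; ++j) {     // conjugate-symmetric half plane
    for (int i = 0; i < L; ++i) {
      const int ip = (L - i) % L, jp = (L - j) % L;
      if (jp < j || (jp == j && ip < i))
        for (int t = 0; t < Nt; ++t) out(i, j, t) = std::conj(out(ip, jp, t));
    }
  }
  return out;
}

// Monte Carlo sampler of the direction process resolvent: endpoints of
// Euler paths with Exp(alpha) lifetimes, binned on the
// (2d+1) x (2d+1) x 2 n_theta grid.  Uses the R RNG (seed with set.seed).
// [[Rcpp::export]]
List mc_resolvent_cpp(double alpha, double sigma, double n_paths, double dt,
                      int d, int n_theta) {
  const int Nt = 2 * n_theta, S = 2 * d + 1;
  const double dth = M_PI / n_theta;
  NumericVector out(S * S * Nt);
  double inside = 0.0;
  const double sdt = std::sqrt(dt) * sigma;
  const long np = (long)n_paths;
  for (long p = 0; p < np; ++p) {
    const double T = R::rexp(1.0 / alpha);
    double x = 0.0, y = 0.0, th = 0.0;
    const long n = (long)std::floor(T / dt);
    for (long s = 0; s < n; ++s) {
      x += dt * std::cos(th);
      y += dt * std::sin(th);
      th += sdt * norm_rand();
    }
    const double rem = T - n * dt;
    x += rem * std::cos(th);
    y += rem * std::sin(th);
    th += std::sqrt(rem) * sigma * norm_rand();
    const double rx = half_away(x), ry = half_away(y);
    if (std::abs(rx) <= d && std::abs(ry) <= d) {
      double thw = th + M_PI;
      thw -= 2.0 * M_PI * std::floor(thw / (2.0 * M_PI));
      const int ti = ((int)half_away(thw / dth)) % Nt;
      const int ix = (int)rx + d, iy = (int)ry + d;
      out[ix + S * iy + S * S * ti] += 1.0;
      inside += 1.0;
    }
  }
  return List::create(_["counts"] = out, _["inside"] = inside);
}

// Full trajectories of the direction process, decimated to pixel entries:
// each path is returned as a matrix (x, y, theta) holding the integer
// pixel first entered and the heading at entry time.
// [[Rcpp::export]]
List sample_paths_cpp(double alpha, double sigma, int n_paths, double dt) {
  const double sdt = std::sqrt(dt) * sigma;
  List paths(n_paths);
  std::vector<double> xs, ys, ths;
  for (int p = 0; p < n_paths; ++p) {
    const double T = R::rexp(1.0 / alpha);
    double x = 0.0, y = 0.0, th = 0.0;
    const long n = (long)std::floor(T / dt);
    xs.clear(); ys.clear(); ths.clear();
    double cx = half_away(x), cy = half_away(y);
    xs.push_back(cx); ys.push_back(cy); ths.push_back(th);
    for (long s = 0; s < n; ++s) {
      x += dt * std::cos(th);
      y += dt * std::sin(th);
      const double rx = half_away(x), ry = half_away(y);
      if (rx != cx || ry != cy) {
        cx = rx; cy = ry;
        xs.push_back(cx); ys.push_back(cy); ths.push_back(th);
      }
      th += sdt * norm_rand();
    }
    NumericMatrix m(xs.size(), 3);
    for (size_t i = 0; i < xs.size(); ++i) {
      m(i, 0) = xs[i]; m(i, 1) = ys[i]; m(i, 2) = ths[i];
    }
    paths[p] = m;
  }
  return paths;
}

// Shift-twist co-occurrence accumulation over a list of interest-point
// sets (pairs are never formed across sets).  Each set is an n x 3 matrix
// (x, y, k) with k the 1-based orientation bin, or an n x 4 matrix whose
// fourth column carries continuous orientations in radians (then the
// rotation uses the exact angle and the orientation difference is binned
// once).  Ordered pairs within Chebyshev distance d contribute weight 1/2
// at the -theta_p-rotated offset and 1/2 at its antipode; rotated offsets
// rounding outside the (2d+1)^2 grid are dropped (weight reported).
// [[Rcpp::export]]
List cooc_accumulate_cpp(List pointsets, int d, int n_theta) {
  const int S = 2 * d + 1;
  const double dth = M_PI / n_theta;
  NumericVector out(S * S * n_theta);
  double dropped = 0.0, total = 0.0;
  for (int s = 0; s < pointsets.size(); ++s) {
    NumericMatrix P = pointsets[s];
    const int n = P.nrow();
    const bool cont = P.ncol() >= 4;
    std::vector<double> ct(n), st(n), th(n);
    for (int i = 0; i < n; ++i) {
      th[i] = cont ? P(i, 3)
                   : -M_PI_2 + (P(i, 2) - 1.0) * dth;
      ct[i] = std::cos(th[i]); st[i] = std::sin(th[i]);
    }
    for (int i = 0; i < n; ++i) {
      const double xi = P(i, 0), yi = P(i, 1);
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        const double dx = P(j, 0) - xi, dy = P(j, 1) - yi;
        if (std::abs(dx) > d || std::abs(dy) > d) continue;
        total += 1.0;
        const double rx = ct[i] * dx + st[i] * dy;
        const double ry = -st[i] * dx + ct[i] * dy;
        const int irx = (int)half_away(rx), iry = (int)half_away(ry);
        int dk;
        if (cont) {
          double dd = th[j] - th[i];
          dd -= M_PI * std::floor(dd / M_PI);     // [0, pi)
          dk = ((int)half_away(dd / dth)) % n_theta;
        } else {
          dk = (((int)P(j, 2) - (int)P(i, 2)) % n_theta + n_theta) %
               n_theta;
        }
        if (std::abs(irx) <= d && std::abs(iry) <= d) {
          out[(irx + d) + S * (iry + d) + S * S * dk] += 0.5;
          out[(-irx + d) + S * (-iry + d) + S * S * dk] += 0.5;
        } else dropped += 1.0;
      }
    }
  }
  return List::create(_["counts"] = out, _["dropped"] = dropped,
                      _["pairs"] = total);
}
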