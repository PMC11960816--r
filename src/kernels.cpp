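#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Local-contrast saliency of a normalized contact map.
// b[i,j] = 1 - exp(-(1/(2k)^2) * sum_{|p-i|<=k, |q-j|<=k} |z[i,j]-z[p,q]| /
//          (1 + sqrt((i-p)^2 + (j-q)^2)))
// The window is truncated at the borders while the (2k)^2 denominator is
// kept, so edge cells are slightly attenuated; values are clamped to [0,1].
// Symmetric inputs are computed on the upper triangle and mirrored.
// [[Rcpp::export]]
NumericMatrix saliency_cpp(const NumericMatrix& z, int k, bool symmetric) {
  const int n = z.nrow(), m = z.ncol();
  if (k < 1) stop("k must be >= 1");
  if (k >= n || k >= m) stop("window exceeds matrix");
  const int w = 2 * k + 1;
  // wt[(dq+k)*w + (dp+k)]: contiguous in dp for the inner loop
  std::vector<double> wt((size_t)w * w);
  for (int dq = -k; dq <= k; ++dq)
    for (int dp = -k; dp <= k; ++dp)
      wt[(size_t)(dq + k) * w + (dp + k)] =
          1.0 / (1.0 + std::sqrt((double)(dp * dp + dq * dq)));
  NumericMatrix b(n, m);
  const double* zp = &z(0, 0);
  double* bp = &b(0, 0);
  const double denom = 4.0 * k * k;
  for (int j = 0; j < m; ++j) {
    const int q0 = std::max(0, j - k), q1 = std::min(m - 1, j + k);
    const int i0 = symmetric ? j : 0;
    for (int i = i0; i < n; ++i) {
      const int p0 = std::max(0, i - k), p1 = std::min(n - 1, i + k);
      const double zij = zp[(size_t)j * n + i];
      double s = 0.0;
      for (int q = q0; q <= q1; ++q) {
        const double* zcol = zp + (size_t)q * n;
        const double* wrow = wt.data() + (ptrdiff_t)(q - j + k) * w + (k - i);
        for (int p = p0; p <= p1; ++p) {
          s += std::fabs(zij - zcol[p]) * wrow[p];
        }
      }
      double val = 1.0 - std::exp(-s / denom);
      if (val < 0.0) val = 0.0;
      if (val > 1.0) val = 1.0;
      bp[(size_t)j * n + i] = val;
      if (symmetric && i != j) bp[(size_t)i * n + j] = val;
    }
  }
  return b;
}

static double tv_energy_ptr(const double* f, const double* u, int n, int m,
                            double lambda) {
  double data = 0.0, tv = 0.0;
  for (int j = 0; j < m; ++j) {
    const double* uc = u + (size_t)j * n;
    const double* un = (j + 1 < m) ? uc + n : uc; // replicate boundary
    const double* fc = f + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double r = fc[i] - uc[i];
      data += r * r;
      const double dx = (i + 1 < n) ? uc[i + 1] - uc[i] : 0.0;
      const double dy = un[i] - uc[i];
      tv += std::sqrt(dx * dx + dy * dy);
    }
  }
  return data + lambda * tv;
}

// Isotropic 2D total-variation denoising by Chambolle's dual projection.
// Minimizes sum (f - u)^2 + lambda * sum |grad u| (forward differences,
// replicate boundary). The ROF weight is theta = lambda / 2 and the primal
// iterate is u = f - theta * div p. Returns the iterate with the lowest
// objective seen, the energy trace of those accepted states (non-increasing
// by construction) and the iteration count.
// [[Rcpp::export]]
List tv_denoise_cpp(const NumericMatrix& fmat, double lambda, int max_iter,
                    double tol) {
  const int n = fmat.nrow(), m = fmat.ncol();
  const size_t sz = (size_t)n * m;
  NumericMatrix u(n, m);
  const double* f = &fmat(0, 0);
  double* up = &u(0, 0);
  if (lambda <= 0.0) {
    std::copy(f, f + sz, up);
    return List::create(
        _["u"] = u,
        _["energy"] = NumericVector::create(tv_energy_ptr(f, up, n, m, 0.0)),
        _["iterations"] = 0, _["converged"] = true);
  }
  const double theta = lambda / 2.0;
  const double tau = 0.248;
  std::vector<double> px(sz, 0.0), py(sz, 0.0), g(sz, 0.0), ucur(sz, 0.0),
      ubest(sz, 0.0);
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  std::copy(f, f + sz, ubest.begin()); // p = 0 start: u = f
  double ebest = tv_energy_ptr(f, ubest.data(), n, m, lambda);
  trace.push_back(ebest);
  bool converged = false;
  int it;
  double eprev = ebest;
  for (it = 1; it <= max_iter; ++it) {
    // g = div p - f / theta
    for (int j = 0; j < m; ++j) {
      const size_t c = (size_t)j * n;
      const double* pxc = px.data() + c;
      const double* pyc = py.data() + c;
      double* gc = g.data() + c;
      const double* fc = f + c;
      for (int i = 0; i < n; ++i) {
        double d = 0.0;
        if (i < n - 1) d += pxc[i];
        if (i > 0) d -= pxc[i - 1];
        if (j < m - 1) d += pyc[i];
        if (j > 0) d -= pyc[i - n];
        gc[i] = d - fc[i] / theta;
      }
    }
    // p <- (p + tau * grad g) / (1 + tau * |grad g|)
    for (int j = 0; j < m; ++j) {
      const size_t c = (size_t)j * n;
      const double* gc = g.data() + c;
      const double* gn = (j + 1 < m) ? gc + n : gc;
      double* pxc = px.data() + c;
      double* pyc = py.data() + c;
      for (int i = 0; i < n; ++i) {
        const double gx = (i + 1 < n) ? gc[i + 1] - gc[i] : 0.0;
        const double gy = gn[i] - gc[i];
        const double mag = std::sqrt(gx * gx + gy * gy);
        const double den = 1.0 + tau * mag;
        pxc[i] = (pxc[i] + tau * gx) / den;
        pyc[i] = (pyc[i] + tau * gy) / den;
      }
    }
    // primal iterate for the updated dual: u = f - theta * div p
    for (int j = 0; j < m; ++j) {
      const size_t c = (size_t)j * n;
      const double* pxc = px.data() + c;
      const double* pyc = py.data() + c;
      double* uc = ucur.data() + c;
      const double* fc = f + c;
      for (int i = 0; i < n; ++i) {
        double d = 0.0;
        if (i < n - 1) d += pxc[i];
        if (i > 0) d -= pxc[i - 1];
        if (j < m - 1) d += pyc[i];
        if (j > 0) d -= pyc[i - n];
        uc[i] = fc[i] - theta * d;
      }
    }
    const double e = tv_energy_ptr(f, ucur.data(), n, m, lambda);
    if (e < ebest) {
      ebest = e;
      std::copy(ucur.begin(), ucur.end(), ubest.begin());
    }
    trace.push_back(ebest); // accepted (best-so-far) state
    const double rel = std::fabs(eprev - e) / std::max(std::fabs(eprev), 1e-12);
    eprev = e;
    if (rel < tol) {
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;
  std::copy(ubest.begin(), ubest.end(), up);
  return List::create(
      _["u"] = u,
      _["energy"] = NumericVector(trace.begin(), trace.end()),
      _["iterations"] = it, _["converged"] = converged);
}
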