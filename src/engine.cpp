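// Compiled core: staircase ray tracing, full-view MART emulation, refine passes.
// Pixel coordinates are 0-based (row, col); linear indices are column-major
// (r + c*H), matching R matrix storage.

#include <Rcpp.h>
#include <cmath>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct Tracer {
  double dr, dc;   // direction (sin, cos) of the view angle, rows downward
  double slope;    // minor-axis increment per dominant-axis step
  bool coldom;     // true: step along columns, false: along rows

  explicit Tracer(double angle_deg) {
    double rad = angle_deg * M_PI / 180.0;
    dr = std::sin(rad);
    dc = std::cos(rad);
    coldom = std::fabs(dc) >= std::fabs(dr);
    slope = coldom ? dr / dc : dc / dr;
  }
};

// Midpoint staircase through anchor (ar, ac): one pixel per dominant-axis
// step, minor coordinate = floor(x + 0.5). Writes linear indices; returns
// the pixel count. idx must hold at least max(H, W) entries.
int trace_line(const Tracer& t, double ar, double ac, int H, int W, int* idx) {
  int n = 0;
  if (t.coldom) {
    for (int c = 0; c < W; ++c) {
      int r = (int)std::floor(ar + (c - ac) * t.slope + 0.5);
      if (r >= 0 && r < H) idx[n++] = r + c * H;
    }
  } else {
    for (int r = 0; r < H; ++r) {
      int c = (int)std::floor(ac + (r - ar) * t.slope + 0.5);
      if (c >= 0 && c < W) idx[n++] = r + c * H;
    }
  }
  return n;
}

// One MART update against target S; returns the pre-update relative residual.
// S == 0 zeroes the ray (zero-raysum conservation); a zero current raysum
// with S > 0 is skipped (division guard).
double update_ray(double* A, const int* idx, int n, double S, double eps,
                  long* skipped) {
  double si = 0.0;
  for (int j = 0; j < n; ++j) si += A[idx[j]];
  double res = std::fabs(si - S) / std::max(S, eps);
  if (S == 0.0) {
    for (int j = 0; j < n; ++j) A[idx[j]] = 0.0;
  } else if (si > 0.0) {
    double f = S / si;
    for (int j = 0; j < n; ++j) A[idx[j]] *= f;
  } else {
    ++*skipped;
  }
  return res;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(double ar, double ac, double angle, int H, int W) {
  Tracer t(angle);
  std::vector<int> idx((size_t)std::max(H, W));
  int n = trace_line(t, ar, ac, H, W, idx.data());
  IntegerMatrix out(n, 2);
  for (int j = 0; j < n; ++j) {
    out(j, 0) = idx[j] % H;  // row
    out(j, 1) = idx[j] / H;  // col
  }
  return out;
}

// Full-view MART emulation: place a star of n_views equally spaced views at
// every pixel (row-major), registering each geometrically new ray once
// (identity: view angle + quantised perpendicular line offset), measure its
// raysum from the hidden image and apply one MART update; then refine to
// convergence.
// [[Rcpp::export]]
List cpp_full_view(NumericMatrix hidden, int n_views, double tol,
                   int max_passes, double eps) {
  int H = hidden.nrow(), W = hidden.ncol();
  std::vector<Tracer> tr;
  tr.reserve(n_views);
  for (int k = 0; k < n_views; ++k) tr.emplace_back(k * 180.0 / n_views);

  struct Rec {
    int view, ar, ac;
  };
  std::vector<Rec> rays;
  {
    std::vector<std::unordered_set<long long> > seen(n_views);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        for (int k = 0; k < n_views; ++k) {
          double off = r * tr[k].dc - c * tr[k].dr;
          long long key = (long long)std::llround(off * 1e9);
          if (seen[k].insert(key).second) {
            Rec rec;
            rec.view = k;
            rec.ar = r;
            rec.ac = c;
            rays.push_back(rec);
          }
        }
  }
  size_t nr = rays.size();

  NumericMatrix est(H, W);
  std::fill(est.begin(), est.end(), 1.0);
  double* A = est.begin();
  const double* U = hidden.begin();

  std::vector<int> buf((size_t)std::max(H, W));
  std::vector<double> S(nr);
  std::vector<int> len(nr);
  long skipped = 0;
  size_t total_px = 0;

  // ray-by-ray processing pass (measure + first update, insertion order)
  for (size_t i = 0; i < nr; ++i) {
    const Rec& rc = rays[i];
    int n = trace_line(tr[rc.view], rc.ar, rc.ac, H, W, buf.data());
    len[i] = n;
    total_px += (size_t)n;
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += U[buf[j]];
    S[i] = s;
    update_ray(A, buf.data(), n, s, eps, &skipped);
  }

  // Cache every ray's pixel indices for the refine passes when that fits
  // comfortably in memory; otherwise re-trace each pass.
  const size_t cache_cap = 400000000;  // 400M int32 entries (~1.6 GB)
  bool cached = total_px <= cache_cap;
  std::vector<int> px;
  std::vector<size_t> start;
  if (cached) {
    px.resize(total_px);
    start.resize(nr + 1);
    size_t pos = 0;
    for (size_t i = 0; i < nr; ++i) {
      start[i] = pos;
      const Rec& rc = rays[i];
      int n = trace_line(tr[rc.view], rc.ar, rc.ac, H, W, &px[pos]);
      pos += (size_t)n;
    }
    start[nr] = pos;
  }

  std::vector<double> hist;
  bool converged = false;
  int pass = 0;
  while (pass < max_passes) {
    ++pass;
    double maxres = 0.0;
    for (size_t i = 0; i < nr; ++i) {
      double res;
      if (cached) {
        res = update_ray(A, &px[start[i]], len[i], S[i], eps, &skipped);
      } else {
        const Rec& rc = rays[i];
        int n = trace_line(tr[rc.view], rc.ar, rc.ac, H, W, buf.data());
        res = update_ray(A, buf.data(), n, S[i], eps, &skipped);
      }
      if (res > maxres) maxres = res;
    }
    hist.push_back(maxres);
    if (maxres < tol) {
      converged = true;
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["estimate"] = est, _["n_unique"] = (double)nr,
                      _["residuals"] = hist, _["passes"] = pass,
                      _["converged"] = converged,
                      _["skipped"] = (double)skipped);
}

// Refine passes over an explicit registry: rays as a list of 1-based linear
// index vectors with stored target raysums S. Runs until the per-pass maximum
// relative residual drops below tol or max_passes is reached.
// [[Rcpp::export]]
List cpp_refine(NumericMatrix estimate, List rays, NumericVector S, double tol,
                int max_passes, double eps) {
  NumericMatrix est = clone(estimate);
  double* A = est.begin();
  int nr = rays.size();
  std::vector<std::vector<int> > idx((size_t)nr);
  for (int i = 0; i < nr; ++i) {
    IntegerVector v = rays[i];
    idx[i].resize(v.size());
    for (int j = 0; j < v.size(); ++j) idx[i][j] = v[j] - 1;
  }
  long skipped = 0;
  std::vector<double> hist;
  bool converged = false;
  int pass = 0;
  while (pass < max_passes) {
    ++pass;
    double maxres = 0.0;
    for (int i = 0; i < nr; ++i) {
      double res = update_ray(A, idx[i].data(), (int)idx[i].size(), S[i], eps,
                              &skipped);
      if (res > maxres) maxres = res;
    }
    hist.push_back(maxres);
    if (maxres < tol) {
      converged = true;
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["estimate"] = est, _["residuals"] = hist,
                      _["passes"] = pass, _["converged"] = converged,
                      _["skipped"] = (double)skipped);
}
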