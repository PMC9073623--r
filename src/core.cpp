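#include <Rcpp.h>
using namespace Rcpp;

static const double EARTH_R = 6371008.8; // mean Earth radius, m
static const double DEG = M_PI / 180.0;

// haversine great-circle distance in meters
static inline double hav_m(double lat1, double lon1, double lat2, double lon2) {
  double dlat = (lat2 - lat1) * DEG / 2.0;
  double dlon = (lon2 - lon1) * DEG / 2.0;
  double a = std::sin(dlat) * std::sin(dlat) +
             std::cos(lat1 * DEG) * std::cos(lat2 * DEG) *
             std::sin(dlon) * std::sin(dlon);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// [[Rcpp::export]]
NumericVector hav_dist_cpp(NumericVector lat1, NumericVector lon1,
                           NumericVector lat2, NumericVector lon2) {
  R_xlen_t n = lat1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hav_m(lat1[i], lon1[i], lat2[i], lon2[i]);
  return out;
}

// Discrete Frechet distance between point sequences A (n x 2) and B (m x 2).
// metric: 0 = haversine on (lat, lon) columns in degrees -> meters;
//         1 = Euclidean on planar columns (any unit).
// DP over the coupling table:
//   c(i,j) = max(d(a_i, b_j), min(c(i-1,j), c(i-1,j-1), c(i,j-1)))
// [[Rcpp::export]]
double dfd_cpp(NumericMatrix A, NumericMatrix B, int metric) {
  int n = A.nrow(), m = B.nrow();
  if (n < 1 || m < 1) stop("empty trajectory");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d;
      if (metric == 0) {
        d = hav_m(A(i, 0), A(i, 1), B(j, 0), B(j, 1));
      } else {
        double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
        d = std::sqrt(dx * dx + dy * dy);
      }
      double c;
      if (i == 0 && j == 0) {
        c = d;
      } else if (i == 0) {
        c = std::max(d, cur[j - 1]);
      } else if (j == 0) {
        c = std::max(d, prev[0]);
      } else {
        double mn = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
        c = std::max(d, mn);
      }
      cur[j] = c;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Sequential spike scan. A fix is removed when its haversine distance from the
// last *retained* fix exceeds vmax * dt (dt = time difference to that retained
// fix); the scan then continues from the last retained fix.
// Returns logical keep vector.
// [[Rcpp::export]]
LogicalVector spike_scan_cpp(NumericVector lat, NumericVector lon,
                             NumericVector t, double vmax_ms) {
  R_xlen_t n = lat.size();
  LogicalVector keep(n, true);
  if (n < 2) return keep;
  R_xlen_t last = 0;
  for (R_xlen_t i = 1; i < n; ++i) {
    double dt = t[i] - t[last];
    double d = hav_m(lat[last], lon[last], lat[i], lon[i]);
    if (dt > 0 && d > vmax_ms * dt) {
      keep[i] = false;
    } else {
      last = i;
    }
  }
  return keep;
}

// Buffer membership: point p is inside the buffer of a polyline iff it lies in
// the union of per-segment rectangles (oriented, width 2r) and per-vertex
// discs (radius r). Polyline rows with NaN separate disjoint parts. All
// coordinates are planar (projected meters).
// [[Rcpp::export]]
LogicalVector pts_in_buffer_cpp(NumericVector px, NumericVector py,
                                NumericVector lx, NumericVector ly,
                                double r) {
  R_xlen_t np = px.size(), nl = lx.size();
  LogicalVector out(np, false);
  double r2 = r * r;
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = px[i], y = py[i];
    bool inside = false;
    for (R_xlen_t j = 0; j < nl && !inside; ++j) {
      if (ISNAN(lx[j])) continue;
      // vertex disc
      double dx = x - lx[j], dy = y - ly[j];
      if (dx * dx + dy * dy <= r2) { inside = true; break; }
      // segment rectangle to next vertex
      if (j + 1 < nl && !ISNAN(lx[j + 1])) {
        double sx = lx[j + 1] - lx[j], sy = ly[j + 1] - ly[j];
        double len2 = sx * sx + sy * sy;
        if (len2 > 0) {
          double tpar = (dx * sx + dy * sy) / len2;
          if (tpar >= 0.0 && tpar <= 1.0) {
            double perp = dx * sy - dy * sx; // cross product = perp dist * len
            if (perp * perp <= r2 * len2) inside = true;
          }
        }
      }
    }
    out[i] = inside;
  }
  return out;
}
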