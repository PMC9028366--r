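#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance between rows i and j of an N x P state matrix.
static inline double row_dist2(const NumericMatrix &x, const int i, const int j) {
  double s = 0.0;
  const int p = x.ncol(), n = x.nrow();
  for (int c = 0; c < p; ++c) {
    const double d = x[i + n * c] - x[j + n * c];
    s += d * d;
  }
  return s;
}

// Streaming per-diagonal RQA pass. Walks every diagonal of the (implicit)
// recurrence plot outside the Theiler band (offsets |k| < theiler are
// excluded; theiler = 1 excludes only the main diagonal, theiler = 0
// nothing), counting recurrent cells and maximal runs of recurrent cells,
// without materialising the N x N matrix. Off-diagonal counts are doubled
// for the symmetric lower triangle.
// Returns: recurrent cell count, total off-band cell count, and the
// diagonal-line length histogram (index = length, entries below lmin zeroed).
// [[Rcpp::export]]
List rqa_stream(const NumericMatrix states, const double eps, const int theiler,
                const int lmin, const bool want_hist) {
  const int n = states.nrow();
  if (n < 1) stop("empty state matrix");
  const double eps2 = eps * eps;
  std::vector<double> hist(n + 1, 0.0);
  double rec = 0.0, cells = 0.0;
  if (theiler == 0) {  // main diagonal: every state recurs with itself
    cells += n;
    rec += n;
    if (want_hist && n >= lmin) hist[n] += 1.0;
  }
  const int k0 = theiler > 0 ? theiler : 1;
  for (int k = k0; k < n; ++k) {
    int run = 0;
    const int len = n - k;
    cells += 2.0 * len;
    for (int i = 0; i < len; ++i) {
      const bool r = row_dist2(states, i, i + k) <= eps2;
      if (r) {
        rec += 2.0;
        ++run;
      } else {
        if (want_hist && run >= lmin) hist[run] += 2.0;
        run = 0;
      }
    }
    if (want_hist && run >= lmin) hist[run] += 2.0;
  }
  return List::create(_["recurrent"] = rec, _["cells"] = cells,
                      _["hist"] = NumericVector(hist.begin(), hist.end()));
}

// Full binary recurrence matrix (small N; inspection, plotting, tests).
// [[Rcpp::export]]
IntegerMatrix recurrence_matrix_full(const NumericMatrix states, const double eps) {
  const int n = states.nrow();
  const double eps2 = eps * eps;
  IntegerMatrix r(n, n);
  for (int i = 0; i < n; ++i) {
    r(i, i) = 1;
    for (int j = i + 1; j < n; ++j) {
      const int v = row_dist2(states, i, j) <= eps2 ? 1 : 0;
      r(i, j) = v;
      r(j, i) = v;
    }
  }
  return r;
}

// Maximum pairwise distance between states (upper bound for radius search).
// [[Rcpp::export]]
double max_pair_dist(const NumericMatrix states) {
  const int n = states.nrow();
  double m = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double d = row_dist2(states, i, j);
      if (d > m) m = d;
    }
  return std::sqrt(m);
}

// False-nearest-neighbour fractions (Kennel criteria) for a D-channel series
// embedded jointly at dimensions 1..maxdim with delay tau. For each embedded
// point the nearest neighbour (Theiler-excluded) is found by brute force at
// dimension m; the neighbour is false when the distance added by the m+1
// coordinates exceeds rtol times the dimension-m distance, or when the
// expanded distance exceeds atol times the attractor size.
// [[Rcpp::export]]
NumericVector fnn_fractions(const NumericMatrix x, const int tau, const int maxdim,
                            const double rtol, const double atol, const int theiler) {
  const int n = x.nrow(), d = x.ncol();
  // attractor size: sd of all samples around the global mean
  double mu = 0.0;
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < n; ++i) mu += x(i, c);
  mu /= (double)(n * d);
  double ra = 0.0;
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < n; ++i) {
      const double dv = x(i, c) - mu;
      ra += dv * dv;
    }
  ra = std::sqrt(ra / (double)(n * d - 1));

  NumericVector frac(maxdim, NA_REAL);
  for (int m = 1; m <= maxdim; ++m) {
    const int np = n - m * tau;  // points that also exist at dimension m+1
    if (np < 2) break;
    long nfalse = 0, ntot = 0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < np; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double s = 0.0;
        for (int lag = 0; lag < m; ++lag)
          for (int c = 0; c < d; ++c) {
            const double dv = x(i + lag * tau, c) - x(j + lag * tau, c);
            s += dv * dv;
            if (s >= best) goto next_j;
          }
        if (s < best) { best = s; bj = j; }
        next_j:;
      }
      if (bj < 0) continue;
      double extra2 = 0.0;
      for (int c = 0; c < d; ++c) {
        const double dv = x(i + m * tau, c) - x(bj + m * tau, c);
        extra2 += dv * dv;
      }
      const double rm = std::sqrt(best), rext = std::sqrt(extra2);
      bool is_false;
      // (near-)duplicate states: the distance ratio is numerical noise, so
      // judge only by whether the extra coordinates actually separate them
      const double tiny = 1e-8 * ra;
      if (rm <= tiny) {
        is_false = rext > tiny;
      } else {
        is_false = (rext / rm > rtol) ||
                   (std::sqrt(best + extra2) / ra > atol);
      }
      ++ntot;
      if (is_false) ++nfalse;
    }
    frac[m - 1] = ntot > 0 ? (double)nfalse / (double)ntot : NA_REAL;
  }
  return frac;
}
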