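#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Linear SVM (L2-regularized hinge loss) for the voxel-coordinate
// classifier, specialized to its training structure: every chunk
// (subject) labels the SAME V coordinate points, so a fold's stacked
// training set collapses exactly into per-point label counts.  A point v
// labeled positive by p_v chunks and negative by m_v chunks contributes
//
//   C * [ p_v * max(0, 1 - w.x_v) + m_v * max(0, 1 + w.x_v) ]
//
// to the primal.  In the dual, the pair of weighted instances at the
// same x_v reduces to one net variable delta_v = alpha+ - alpha- in
// [-C m_v, C p_v] with a concave piecewise-linear term whose breakpoint
// is delta* = C (p_v - m_v); coordinate updates remain closed-form.
// This eliminates the degenerate direction (alpha+ and alpha- growing
// together) that makes generic dual coordinate descent crawl on
// duplicated points, so convergence is fast and exact.
//
// The bias is an augmented constant feature (row of ones in Xt).

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s;
}

// Coordinate ascent on the reduced dual.  Xt is d x V feature-major;
// delta is warm-start in/out; w out.
static void svm_pair_solve(const double *Xt, const double *Cp,
                           const double *Cm, int V, int d,
                           int max_epochs, double tol, uint64_t rng_seed,
                           double *delta, double *w) {
  std::vector<double> qii(V);
  for (int j = 0; j < d; ++j) w[j] = 0.0;
  for (int v = 0; v < V; ++v) {
    const double *xv = Xt + (size_t)v * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xv[j] * xv[j];
    qii[v] = s;
    // clamp the warm start into the current box and rebuild w
    if (delta[v] > Cp[v]) delta[v] = Cp[v];
    if (delta[v] < -Cm[v]) delta[v] = -Cm[v];
    if (delta[v] != 0.0)
      for (int j = 0; j < d; ++j) w[j] += delta[v] * xv[j];
  }
  std::vector<int> order(V);
  for (int v = 0; v < V; ++v) order[v] = v;
  uint64_t state = rng_seed * 2685821657736338717ULL + 1ULL;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = V - 1; i > 0; --i) {
      int j = (int)(xorshift64(state) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_step = 0.0;
    for (int k = 0; k < V; ++k) {
      int v = order[k];
      double q = qii[v];
      if (q <= 0.0) continue;
      const double *xv = Xt + (size_t)v * d;
      double u = 0.0;
      for (int j = 0; j < d; ++j) u += w[j] * xv[j];
      double r = u - delta[v] * q;          // x_v . w_without_v
      double bp = Cp[v] - Cm[v];            // breakpoint of the PL term
      double d1 = (1.0 - r) / q;            // optimum on the left piece
      double opt;
      if (d1 < bp) {
        opt = d1 < -Cm[v] ? -Cm[v] : d1;
      } else {
        double d2 = (-1.0 - r) / q;         // optimum on the right piece
        if (d2 > bp) opt = d2 > Cp[v] ? Cp[v] : d2;
        else opt = bp;
      }
      double step = opt - delta[v];
      if (step != 0.0) {
        double astep = step < 0.0 ? -step : step;
        if (astep > max_step) max_step = astep;
        delta[v] = opt;
        for (int j = 0; j < d; ++j) w[j] += step * xv[j];
      }
    }
    if (max_step < tol) break;
  }
}

// [[Rcpp::export(name = ".svm_pair_dcd_cpp")]]
NumericVector svm_pair_dcd_cpp(NumericMatrix Xt, NumericVector pos,
                               NumericVector neg, double cost,
                               int max_epochs = 1000, double tol = 1e-8,
                               int seed = 12345) {
  const int d = Xt.nrow(), V = Xt.ncol();
  if (pos.size() != V || neg.size() != V)
    stop("pos/neg must have one entry per point");
  std::vector<double> Cp(V), Cm(V), delta(V, 0.0);
  for (int v = 0; v < V; ++v) {
    Cp[v] = cost * pos[v];
    Cm[v] = cost * neg[v];
  }
  NumericVector w(d);
  svm_pair_solve(&Xt(0, 0), Cp.data(), Cm.data(), V, d, max_epochs, tol,
                 (uint64_t)seed, delta.data(), &w[0]);
  return w;
}

// [[Rcpp::export(name = ".loso_perm_null_cpp")]]
NumericVector loso_perm_null_cpp(NumericMatrix Xt, IntegerMatrix labels,
                                 int n_iter, double cost, int seed,
                                 int max_epochs = 1000, double tol = 1e-8) {
  const int d = Xt.nrow(), V = Xt.ncol(), n = labels.ncol();
  if (labels.nrow() != V) stop("labels must be V x n");
  const double *X = &Xt(0, 0);

  std::vector<int> perm(V * n), pos_tot(V);
  std::vector<double> w(d), delta(V), Cp(V), Cm(V);
  uint64_t state = (uint64_t)seed * 6364136223846793005ULL +
    1442695040888963407ULL;
  NumericVector out(n_iter);

  for (int it = 0; it < n_iter; ++it) {
    // permute each chunk's labels, preserving its label counts
    for (int s = 0; s < n; ++s) {
      int *col = &perm[(size_t)s * V];
      for (int v = 0; v < V; ++v) col[v] = labels(v, s);
      for (int v = V - 1; v > 0; --v) {
        int j = (int)(xorshift64(state) % (uint64_t)(v + 1));
        std::swap(col[v], col[j]);
      }
    }
    for (int v = 0; v < V; ++v) {
      int t = 0;
      for (int s = 0; s < n; ++s) t += perm[(size_t)s * V + v];
      pos_tot[v] = t;
    }
    double acc_sum = 0.0;
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int s = 0; s < n; ++s) {
      for (int v = 0; v < V; ++v) {
        int p = pos_tot[v] - perm[(size_t)s * V + v];
        Cp[v] = cost * p;
        Cm[v] = cost * ((n - 1) - p);
      }
      svm_pair_solve(X, Cp.data(), Cm.data(), V, d, max_epochs, tol,
                     12345ULL, delta.data(), w.data());
      int correct = 0;
      for (int v = 0; v < V; ++v) {
        const double *xv = X + (size_t)v * d;
        double sc = 0.0;
        for (int j = 0; j < d; ++j) sc += w[j] * xv[j];
        int pred = sc >= 0.0 ? 1 : 0;
        if (pred == labels(v, s)) ++correct;
      }
      acc_sum += (double)correct / V;
    }
    out[it] = acc_sum / n;
  }
  return out;
}
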