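#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centers/weights layout: flat arrays indexed j + m*(c + 2*f) for membership
// function j (0..m-1), class c (0,1), feature f (0..F-1). Centers are kept
// sorted within each (f, c) block; triangular supports are derived from the
// midpoints toward the neighbouring centers, so the whole model state is
// (centers, weights).

static inline double tri_membership(const double* c, int m, int j, double x) {
  // supports by the midpoint-to-neighbor rule: each triangle reaches the
  // midpoints toward its neighbouring centers (edge MFs extend by the
  // adjacent half-gap), so left <= center <= right for any center layout
  double left, right;
  if (j == 0) {
    left = c[0] - (c[1] - c[0]) / 2.0;
  } else {
    left = (c[j - 1] + c[j]) / 2.0;
  }
  if (j == m - 1) {
    right = c[m - 1] + (c[m - 1] - c[m - 2]) / 2.0;
  } else {
    right = (c[j] + c[j + 1]) / 2.0;
  }
  double cj = c[j];
  if (x == cj) return 1.0;
  if (x <= left || x >= right) return 0.0;
  if (x < cj) {
    double w = cj - left;
    return w > 0.0 ? (x - left) / w : 0.0;
  }
  double w = right - cj;
  return w > 0.0 ? (right - x) / w : 0.0;
}

// bounded sum of weighted fuzzy memberships for one (feature, class) block
static inline double bswfm_block(const double* c, const double* w, int m, double x) {
  double s = 0.0;
  for (int j = 0; j < m; ++j) {
    if (w[j] > 0.0) s += w[j] * tri_membership(c, m, j, x);
  }
  return s > 1.0 ? 1.0 : s;
}

// class scores: sum of BSWFM values over the selected features
static inline void scores_for(const std::vector<double>& cen,
                              const std::vector<double>& wei, int m,
                              const NumericMatrix& X, int i,
                              const IntegerVector& sel, double* out) {
  out[0] = 0.0;
  out[1] = 0.0;
  for (int s = 0; s < sel.size(); ++s) {
    int f = sel[s];
    double x = X(i, f);
    for (int c = 0; c < 2; ++c) {
      const double* cb = &cen[(size_t)m * (c + 2 * f)];
      const double* wb = &wei[(size_t)m * (c + 2 * f)];
      out[c] += bswfm_block(cb, wb, m, x);
    }
  }
}

static double accuracy_of(const std::vector<double>& cen,
                          const std::vector<double>& wei, int m,
                          const NumericMatrix& X, const IntegerVector& y,
                          const IntegerVector& sel) {
  int n = X.nrow(), correct = 0;
  double sc[2];
  for (int i = 0; i < n; ++i) {
    scores_for(cen, wei, m, X, i, sel, sc);
    int pred = sc[1] > sc[0] ? 1 : 0;  // tie -> class 0
    if (pred == y[i]) ++correct;
  }
  return (double)correct / n;
}

// winner = membership-maximal MF of the block; all-zero membership falls back
// to the nearest center so out-of-support values still recruit an MF
static inline int winner_mf(const double* c, int m, double x) {
  int best = 0;
  double bestmu = tri_membership(c, m, 0, x);
  for (int j = 1; j < m; ++j) {
    double mu = tri_membership(c, m, j, x);
    if (mu > bestmu) {
      bestmu = mu;
      best = j;
    }
  }
  if (bestmu == 0.0) {
    best = 0;
    double bd = std::abs(x - c[0]);
    for (int j = 1; j < m; ++j) {
      double d = std::abs(x - c[j]);
      if (d < bd) {
        bd = d;
        best = j;
      }
    }
  }
  return best;
}

// re-sort one (f,c) block by center, carrying weights along
static inline void resort_block(double* c, double* w, int m) {
  for (int j = 1; j < m; ++j) {
    double cj = c[j], wj = w[j];
    int k = j - 1;
    while (k >= 0 && c[k] > cj) {
      c[k + 1] = c[k];
      w[k + 1] = w[k];
      --k;
    }
    c[k + 1] = cj;
    w[k + 1] = wj;
  }
}

// [[Rcpp::export]]
List newfm_train_cpp(NumericVector centers0, NumericVector weights0, int m,
                     NumericMatrix X, IntegerVector y, double alpha,
                     double delta, int max_epochs, int patience,
                     IntegerVector sel) {
  int n = X.nrow(), F = X.ncol();
  std::vector<double> cen(centers0.begin(), centers0.end());
  std::vector<double> wei(weights0.begin(), weights0.end());
  double best_acc = accuracy_of(cen, wei, m, X, y, sel);
  std::vector<double> acc_hist;
  int stale = 0, epochs_run = 0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = 0; i < n; ++i) {
      int yc = y[i], oc = 1 - yc;
      for (int f = 0; f < F; ++f) {
        double x = X(i, f);
        double* ct = &cen[(size_t)m * (yc + 2 * f)];
        double* wt = &wei[(size_t)m * (yc + 2 * f)];
        int j = winner_mf(ct, m, x);
        ct[j] += alpha * (x - ct[j]);
        wt[j] += delta * (1.0 - wt[j]);
        resort_block(ct, wt, m);
        double* co = &cen[(size_t)m * (oc + 2 * f)];
        double* wo = &wei[(size_t)m * (oc + 2 * f)];
        int k = winner_mf(co, m, x);
        wo[k] -= delta * wo[k];
      }
    }
    ++epochs_run;
    double acc = accuracy_of(cen, wei, m, X, y, sel);
    acc_hist.push_back(acc);
    if (acc > best_acc) {
      best_acc = acc;
      stale = 0;
    } else {
      ++stale;
    }
    if (stale >= patience) break;
  }

  double final_acc = accuracy_of(cen, wei, m, X, y, sel);
  return List::create(
      _["centers"] = NumericVector(cen.begin(), cen.end()),
      _["weights"] = NumericVector(wei.begin(), wei.end()),
      _["epochs_run"] = epochs_run, _["train_accuracy"] = final_acc,
      _["accuracy_history"] = NumericVector(acc_hist.begin(), acc_hist.end()));
}

// [[Rcpp::export]]
NumericMatrix newfm_scores_cpp(NumericVector centers, NumericVector weights,
                               int m, NumericMatrix X, IntegerVector sel) {
  int n = X.nrow();
  std::vector<double> cen(centers.begin(), centers.end());
  std::vector<double> wei(weights.begin(), weights.end());
  NumericMatrix out(n, 2);
  double sc[2];
  for (int i = 0; i < n; ++i) {
    scores_for(cen, wei, m, X, i, sel, sc);
    out(i, 0) = sc[0];
    out(i, 1) = sc[1];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector newfm_bswfm_cpp(NumericVector centers, NumericVector weights,
                              int m, int feature, int cls, NumericVector xs) {
  const double* cb = &centers[(size_t)m * (cls + 2 * feature)];
  const double* wb = &weights[(size_t)m * (cls + 2 * feature)];
  NumericVector out(xs.size());
  for (int i = 0; i < xs.size(); ++i) out[i] = bswfm_block(cb, wb, m, xs[i]);
  return out;
}
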