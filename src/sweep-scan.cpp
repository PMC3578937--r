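// Scan kernels for the composite-likelihood-ratio sweep statistic and the
// linkage-disequilibrium omega statistic. Both are grid scans whose inner
// loops are too hot for interpreted code at calibration replicate counts.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// CLR scan. The sweep-model log-probabilities logq are tabulated over a
// log-spaced grid of the compound parameter s = alpha * distance:
// column j corresponds to s_j = s_min * exp(j * dlog); s below s_min uses
// column 0 and s above s_max falls back to the neutral log-probabilities
// (the sweep model converges to the background as escape becomes certain).
// Point sites carry an observed class each; the invariant (class-0) bulk is
// pre-binned by position with integer counts.
// [[Rcpp::export]]
List sv_clr_scan_cpp(NumericVector point_pos, IntegerVector point_class,
                     NumericVector bin_pos, NumericVector bin_count,
                     NumericVector grid, NumericVector alphas,
                     NumericMatrix logq, double s_min, double s_max,
                     NumericVector logp) {
  int npt = point_pos.size(), nbin = bin_pos.size();
  int G = grid.size(), A = alphas.size(), B = logq.ncol();
  double dlog = std::log(s_max / s_min) / (B - 1);
  // neutral composite log-likelihood (constant over x)
  double ll0 = 0.0;
  for (int i = 0; i < npt; ++i) ll0 += logp[point_class[i]];
  for (int i = 0; i < nbin; ++i) ll0 += bin_count[i] * logp[0];

  NumericVector value(G), best_alpha(G);
  const double* lq = logq.begin();
  int nrow = logq.nrow();
  for (int g = 0; g < G; ++g) {
    double x = grid[g];
    double best = 0.0, ba = 0.0;
    for (int ai = 0; ai < A; ++ai) {
      double alpha = alphas[ai];
      double ll = 0.0;
      for (int i = 0; i < npt; ++i) {
        double sval = alpha * std::fabs(point_pos[i] - x);
        int cls = point_class[i];
        if (sval >= s_max) {
          ll += logp[cls];
        } else {
          int j = (sval <= s_min) ? 0 : (int)(std::log(sval / s_min) / dlog + 0.5);
          if (j >= B) j = B - 1;
          ll += lq[j * nrow + cls];
        }
      }
      for (int i = 0; i < nbin; ++i) {
        double sval = alpha * std::fabs(bin_pos[i] - x);
        if (sval >= s_max) {
          ll += bin_count[i] * logp[0];
        } else {
          int j = (sval <= s_min) ? 0 : (int)(std::log(sval / s_min) / dlog + 0.5);
          if (j >= B) j = B - 1;
          ll += bin_count[i] * lq[j * nrow];
        }
      }
      double stat = 2.0 * (ll - ll0);
      if (stat > best) {
        best = stat;
        ba = alpha;
      }
    }
    value[g] = best;
    best_alpha[g] = ba;
  }
  return List::create(_["value"] = value, _["alpha"] = best_alpha,
                      _["ll_neutral"] = ll0);
}

// Composite log-likelihood under the sweep model at a single (x, alpha);
// used for the post-grid refinement of alpha at the argmax position.
// [[Rcpp::export]]
double sv_clr_loglik_cpp(double x, double alpha, NumericVector point_pos,
                         IntegerVector point_class, NumericVector bin_pos,
                         NumericVector bin_count, NumericMatrix logq,
                         double s_min, double s_max, NumericVector logp) {
  int B = logq.ncol(), nrow = logq.nrow();
  double dlog = std::log(s_max / s_min) / (B - 1);
  const double* lq = logq.begin();
  double ll = 0.0;
  for (int i = 0; i < point_pos.size(); ++i) {
    double sval = alpha * std::fabs(point_pos[i] - x);
    int cls = point_class[i];
    if (sval >= s_max) {
      ll += logp[cls];
    } else {
      int j = (sval <= s_min) ? 0 : (int)(std::log(sval / s_min) / dlog + 0.5);
      if (j >= B) j = B - 1;
      ll += lq[j * nrow + cls];
    }
  }
  for (int i = 0; i < bin_pos.size(); ++i) {
    double sval = alpha * std::fabs(bin_pos[i] - x);
    if (sval >= s_max) {
      ll += bin_count[i] * logp[0];
    } else {
      int j = (sval <= s_min) ? 0 : (int)(std::log(sval / s_min) / dlog + 0.5);
      if (j >= B) j = B - 1;
      ll += bin_count[i] * lq[j * nrow];
    }
  }
  return ll;
}

// Omega scan over grid centers: the candidate sweep position splits the two
// site blocks, and the outer borders of the left and right flanking regions
// vary independently over a ladder of half-widths (rows of `halves`: left
// half-width, right half-width, already filtered to the admissible total
// window sizes and ordered smallest-total first so ties prefer the smaller
// window). r2 must be a full symmetric matrix with zero diagonal and
// undefined pairs set to 0. Denominators are the combinatorial pair counts.
// A zero between-block sum with a positive within-block sum yields the +Inf
// sentinel.
// [[Rcpp::export]]
List sv_omega_scan_cpp(NumericVector pos, NumericMatrix r2,
                       NumericVector centers, NumericMatrix halves) {
  int S = pos.size();
  int G = centers.size(), W = halves.nrow();
  // 2D prefix sums: P[(i) * (S+1) + j] = sum r2 over rows < i, cols < j
  std::vector<double> P((size_t)(S + 1) * (S + 1), 0.0);
  for (int i = 0; i < S; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < S; ++j) {
      rowsum += r2(i, j);
      P[(size_t)(i + 1) * (S + 1) + (j + 1)] =
          P[(size_t)i * (S + 1) + (j + 1)] + rowsum;
    }
  }
  auto rect = [&](int a, int b, int c, int d) {  // rows [a,b], cols [c,d], inclusive
    return P[(size_t)(b + 1) * (S + 1) + (d + 1)] -
           P[(size_t)a * (S + 1) + (d + 1)] -
           P[(size_t)(b + 1) * (S + 1) + c] + P[(size_t)a * (S + 1) + c];
  };

  NumericVector value(G), best_w(G), best_split(G), n_sites(G);
  for (int g = 0; g < G; ++g) {
    double c = centers[g];
    double best = NA_REAL, bw = NA_REAL, bl = NA_REAL, bs = NA_REAL;
    // sites at or left of the center go to the left block
    int mid = (int)(std::upper_bound(pos.begin(), pos.end(), c) - pos.begin());
    for (int wi = 0; wi < W; ++wi) {
      double wl = halves(wi, 0), wr = halves(wi, 1);
      int i0 = (int)(std::lower_bound(pos.begin(), pos.end(), c - wl) -
                     pos.begin());
      int i1 = (int)(std::upper_bound(pos.begin(), pos.end(), c + wr) -
                     pos.begin()) - 1;
      int sl = mid - i0, sr = i1 - mid + 1;
      if (sl < 2 || sr < 2) continue;
      int s = sl + sr;
      int aEnd = mid - 1;  // last index of the left block
      double Wl = rect(i0, aEnd, i0, aEnd) / 2.0;
      double Wr = rect(mid, i1, mid, i1) / 2.0;
      double Bt = rect(i0, aEnd, mid, i1);
      double npairs_w = sl * (sl - 1) / 2.0 + sr * (sr - 1) / 2.0;
      double npairs_b = (double)sl * sr;
      double num = (Wl + Wr) / npairs_w;
      double den = Bt / npairs_b;
      double om;
      if (den > 0) {
        om = num / den;
      } else if (num > 0) {
        om = R_PosInf;
      } else {
        continue;  // 0/0: undefined, not admissible
      }
      if (!ISNA(best) ? (om > best) : true) {
        best = om;
        bw = wl + wr;
        bl = pos[aEnd];
        bs = s;
      }
    }
    value[g] = best;
    best_w[g] = bw;
    best_split[g] = bl;
    n_sites[g] = bs;
  }
  return List::create(_["value"] = value, _["window"] = best_w,
                      _["split_after"] = best_split, _["n_sites"] = n_sites);
}
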