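#include <Rcpp.h>
using namespace Rcpp;

// Exact Debye sum over precomputed pair distances.
// dists / wpair: one entry per unordered bead pair (i<j); fsq_sum = sum f_i^2.
// I(q) = fsq_sum + 2 * sum_pairs w_ij * sin(q d) / (q d).
// [[Rcpp::export]]
NumericVector cpp_debye_pairs(NumericVector dists, NumericVector wpair,
                              double fsq_sum, NumericVector q) {
  const R_xlen_t np = dists.size(), nq = q.size();
  NumericVector out(nq);
  for (R_xlen_t k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = 0.0;
    for (R_xlen_t p = 0; p < np; ++p) {
      const double x = qk * dists[p];
      acc += (x < 1e-9) ? wpair[p] : wpair[p] * std::sin(x) / x;
    }
    out[k] = fsq_sum + 2.0 * acc;
  }
  return out;
}

// Histogram-binned Debye sum over per-bin centroid distances, with a
// second-order correction using the within-bin distance variance:
// E[sinc(q d)] ~ sinc(q dbar) + q^2 var/2 * sinc''(q dbar).
// [[Rcpp::export]]
NumericVector cpp_debye_hist(NumericVector centers, NumericVector wts,
                             double fsq_sum, NumericVector q,
                             Nullable<NumericVector> var_ = R_NilValue) {
  const R_xlen_t nb = centers.size(), nq = q.size();
  NumericVector var = var_.isNotNull() ? NumericVector(var_)
                                       : NumericVector(nb);
  NumericVector out(nq);
  for (R_xlen_t k = 0; k < nq; ++k) {
    const double qk = q[k];
    double acc = 0.0;
    for (R_xlen_t b = 0; b < nb; ++b) {
      const double x = qk * centers[b];
      if (x < 1e-9) { acc += wts[b]; continue; }
      const double s = std::sin(x), c = std::cos(x);
      const double sinc = s / x;
      const double sinc2 = -s / x - 2.0 * c / (x * x) + 2.0 * s / (x * x * x);
      acc += wts[b] * (sinc + 0.5 * qk * qk * var[b] * sinc2);
    }
    out[k] = fsq_sum + 2.0 * acc;
  }
  return out;
}

// All unordered pair distances and form-factor products for <= 5000 beads.
// [[Rcpp::export]]
List cpp_pair_table(NumericMatrix pos, NumericVector f) {
  const R_xlen_t n = pos.nrow();
  const R_xlen_t np = n * (n - 1) / 2;
  NumericVector d(np), w(np);
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j, ++k) {
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      d[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
      w[k] = f[i] * f[j];
    }
  }
  return List::create(_["dist"] = d, _["w"] = w);
}

// Weighted pair-distance histogram with fixed bin width (for the binned
// Debye path on large bead sets). Bin b covers [b*bw, (b+1)*bw); returns
// the summed f_i*f_j per bin ("w") and the weighted mean distance per bin
// ("d", the bin centroid), which keeps the binned Debye sum accurate to
// second order in the bin width.
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix pos, NumericVector f, double bw,
                   int nbins) {
  NumericVector wts(nbins), wd(nbins), wd2(nbins);
  const R_xlen_t n = pos.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)(d / bw);
      if (b >= nbins) b = nbins - 1;
      const double w = f[i] * f[j];
      wts[b] += w;
      wd[b] += w * d;
      wd2[b] += w * d * d;
    }
  }
  NumericVector var(nbins);
  for (int b = 0; b < nbins; ++b) {
    if (wts[b] > 0) {
      wd[b] /= wts[b];
      var[b] = wd2[b] / wts[b] - wd[b] * wd[b];
      if (var[b] < 0) var[b] = 0;
    } else {
      wd[b] = (b + 0.5) * bw;
    }
  }
  return List::create(_["w"] = wts, _["d"] = wd, _["var"] = var);
}

// Minimum pairwise distance between two coordinate sets (clash screening).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      const double dx = A(i, 0) - B(j, 0);
      const double dy = A(i, 1) - B(j, 1);
      const double dz = A(i, 2) - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
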