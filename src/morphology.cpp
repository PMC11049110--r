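#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Non-flat grayscale erosion/dilation with an arbitrary structuring element.
// The element is passed as a matrix of heights with NA outside its support;
// its centre is the middle pixel ((nrow-1)/2, (ncol-1)/2). Samples falling
// outside the image are ignored (equivalent to padding with +Inf for erosion
// and -Inf for dilation), which keeps the opening anti-extensive up to the
// image border.

struct SEOffsets {
  std::vector<int> di, dj;
  std::vector<double> h;
};

static SEOffsets se_offsets(const NumericMatrix &se) {
  SEOffsets o;
  const int ci = (se.nrow() - 1) / 2, cj = (se.ncol() - 1) / 2;
  for (int j = 0; j < se.ncol(); ++j)
    for (int i = 0; i < se.nrow(); ++i)
      if (!NumericMatrix::is_na(se(i, j))) {
        o.di.push_back(i - ci);
        o.dj.push_back(j - cj);
        o.h.push_back(se(i, j));
      }
  return o;
}

// [[Rcpp::export(name = ".nf_erode")]]
NumericMatrix nf_erode(NumericMatrix img, NumericMatrix se) {
  const int nr = img.nrow(), nc = img.ncol();
  SEOffsets o = se_offsets(se);
  const int m = (int)o.h.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_PosInf;
      for (int t = 0; t < m; ++t) {
        int ii = i + o.di[t], jj = j + o.dj[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double c = img(ii, jj) - o.h[t];
        if (c < v) v = c;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nf_dilate")]]
NumericMatrix nf_dilate(NumericMatrix img, NumericMatrix se) {
  const int nr = img.nrow(), nc = img.ncol();
  SEOffsets o = se_offsets(se);
  const int m = (int)o.h.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_NegInf;
      for (int t = 0; t < m; ++t) {
        int ii = i - o.di[t], jj = j - o.dj[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double c = img(ii, jj) + o.h[t];
        if (c > v) v = c;
      }
      out(i, j) = v;
    }
  }
  return out;
}
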