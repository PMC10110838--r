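#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Adaptive pooling over precomputed bins for a batch of cubic feature maps.
// X: (B * l3) x C matrix; sample s (0-based) occupies rows [s*l3, (s+1)*l3),
// spatially flattened with z fastest. bins: list of 1-based spatial index
// vectors (one per output bin, concatenated over pyramid levels; bins may
// overlap or repeat voxels when a level is finer than the input).
// Output desc: B x (C * nbins) with column (c * nbins + j) holding channel c,
// bin j; argmax holds the 1-based winning row of X (max pooling only).
// [[Rcpp::export]]
List spp_pool_forward_cpp(NumericMatrix X, int B, int l3, List bins,
                          bool mean_pool) {
  const int C = X.ncol();
  const int nb = bins.size();
  NumericMatrix desc(B, C * nb);
  IntegerMatrix argmax(mean_pool ? 1 : B, mean_pool ? 1 : C * nb);
  std::vector< std::vector<int> > bv(nb);
  for (int j = 0; j < nb; ++j) {
    IntegerVector v = bins[j];
    bv[j].assign(v.begin(), v.end());
  }
  for (int s = 0; s < B; ++s) {
    const int off = s * l3;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < nb; ++j) {
        const std::vector<int> &m = bv[j];
        if (mean_pool) {
          double acc = 0.0;
          for (size_t q = 0; q < m.size(); ++q) acc += X(off + m[q] - 1, c);
          desc(s, c * nb + j) = acc / (double)m.size();
        } else {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (size_t q = 0; q < m.size(); ++q) {
            double v = X(off + m[q] - 1, c);
            if (v > best) { best = v; bi = off + m[q]; }
          }
          desc(s, c * nb + j) = best;
          argmax(s, c * nb + j) = bi;
        }
      }
    }
  }
  return List::create(_["desc"] = desc, _["argmax"] = argmax);
}

// Gradient of max pooling: route each output gradient to its argmax row.
// [[Rcpp::export]]
NumericMatrix spp_pool_backward_max_cpp(NumericMatrix dDesc,
                                        IntegerMatrix argmax,
                                        int nrowX, int C) {
  const int B = dDesc.nrow();
  const int nb = dDesc.ncol() / C;
  NumericMatrix dX(nrowX, C);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < nb; ++j)
        dX(argmax(s, c * nb + j) - 1, c) += dDesc(s, c * nb + j);
  return dX;
}

// Gradient of mean pooling: spread each output gradient over its bin.
// [[Rcpp::export]]
NumericMatrix spp_pool_backward_mean_cpp(NumericMatrix dDesc, int B, int l3,
                                         List bins, int C) {
  const int nb = bins.size();
  NumericMatrix dX(B * l3, C);
  std::vector< std::vector<int> > bv(nb);
  for (int j = 0; j < nb; ++j) {
    IntegerVector v = bins[j];
    bv[j].assign(v.begin(), v.end());
  }
  for (int s = 0; s < B; ++s) {
    const int off = s * l3;
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < nb; ++j) {
        const std::vector<int> &m = bv[j];
        const double g = dDesc(s, c * nb + j) / (double)m.size();
        for (size_t q = 0; q < m.size(); ++q) dX(off + m[q] - 1, c) += g;
      }
  }
  return dX;
}

// Batched gather for the convolution-as-matmul path, without materializing
// the (B * l3) x k3 index matrix. X: (B * l3) x C stacked feature maps
// (sample-blocked, z fastest); base: l3 x k3 per-position neighbor indices
// (1-based within a sample, 0 = zero padding). Returns G: (B * l3) x
// (k3 * C) with neighbor fastest within each channel block, matching
// W rows ordered input-channel-major with offsets z fastest.
// [[Rcpp::export]]
NumericMatrix conv_gather_batched_cpp(NumericMatrix X, IntegerMatrix base,
                                      int B, int l3) {
  const int k3 = base.ncol();
  const int C = X.ncol();
  NumericMatrix G(B * l3, k3 * C);
  for (int c = 0; c < C; ++c) {
    const double *xc = &X(0, c);
    for (int n = 0; n < k3; ++n) {
      double *gcol = &G(0, c * k3 + n);
      const int *bcol = &base(0, n);
      for (int b = 0; b < B; ++b) {
        const int off = b * l3;
        for (int p = 0; p < l3; ++p) {
          const int t = bcol[p];
          gcol[off + p] = t == 0 ? 0.0 : xc[off + t - 1];
        }
      }
    }
  }
  return G;
}

// Scatter-add transpose of conv_gather_batched_cpp: accumulates the
// gradient dG (B * l3) x (k3 * C) back onto the input rows, skipping
// padding targets.
// [[Rcpp::export]]
NumericMatrix conv_scatter_batched_cpp(NumericMatrix dG, IntegerMatrix base,
                                       int B, int l3) {
  const int k3 = base.ncol();
  const int C = dG.ncol() / k3;
  NumericMatrix dX(B * l3, C);
  for (int c = 0; c < C; ++c) {
    double *xc = &dX(0, c);
    for (int n = 0; n < k3; ++n) {
      const double *gcol = &dG(0, c * k3 + n);
      const int *bcol = &base(0, n);
      for (int b = 0; b < B; ++b) {
        const int off = b * l3;
        for (int p = 0; p < l3; ++p) {
          const int t = bcol[p];
          if (t != 0) xc[off + t - 1] += gcol[off + p];
        }
      }
    }
  }
  return dX;
}

// Fused convolution forward: Z = gather(X) %*% W + bias without
// materializing the gathered matrix. Per position the (k3 * C)-vector of
// neighborhood values is collected once into a small buffer and dotted
// with each output-channel column of W (rows input-channel-major,
// neighbor fastest, matching conv_gather_batched_cpp).
// [[Rcpp::export]]
NumericMatrix conv_forward_cpp(NumericMatrix X, IntegerMatrix base,
                               NumericMatrix W, NumericVector bias,
                               int B, int l3) {
  const int k3 = base.ncol();
  const int C = X.ncol();
  const int Co = W.ncol();
  const int len = k3 * C;
  NumericMatrix Z(B * l3, Co);
  std::vector<const int*> bcol(k3);
  for (int n = 0; n < k3; ++n) bcol[n] = &base(0, n);
  std::vector<const double*> xcol(C), wcol(Co);
  std::vector<double*> zcol(Co);
  for (int c = 0; c < C; ++c) xcol[c] = &X(0, c);
  for (int co = 0; co < Co; ++co) { wcol[co] = &W(0, co); zcol[co] = &Z(0, co); }
  std::vector<double> buf(len);
  for (int b = 0; b < B; ++b) {
    const int off = b * l3;
    for (int p = 0; p < l3; ++p) {
      int m = 0;
      for (int c = 0; c < C; ++c) {
        const double *xc = xcol[c] + off;
        for (int n = 0; n < k3; ++n) {
          const int t = bcol[n][p];
          buf[m++] = t == 0 ? 0.0 : xc[t - 1];
        }
      }
      const int row = off + p;
      for (int co = 0; co < Co; ++co) {
        const double *w = wcol[co];
        double acc = bias[co];
        for (int i = 0; i < len; ++i) acc += buf[i] * w[i];
        zcol[co][row] = acc;
      }
    }
  }
  return Z;
}

// Fused convolution backward: given the stage input H, upstream gradient
// dA (B * l3) x Co, and weights W, returns the weight gradient
// gW = gather(H)^T dA and the input gradient dX = scatter(dA W^T) in one
// pass, without materializing the gathered matrix. Zero rows of dA
// (from ReLU/dropout) are skipped.
// [[Rcpp::export]]
List conv_backward_cpp(NumericMatrix H, IntegerMatrix base, NumericMatrix W,
                       NumericMatrix dA, int B, int l3) {
  const int k3 = base.ncol();
  const int C = H.ncol();
  const int Co = W.ncol();
  const int len = k3 * C;
  NumericMatrix gW(len, Co), dX(B * l3, C);
  std::vector<const int*> bcol(k3);
  for (int n = 0; n < k3; ++n) bcol[n] = &base(0, n);
  std::vector<double> buf(len), dg(len);
  for (int b = 0; b < B; ++b) {
    const int off = b * l3;
    for (int p = 0; p < l3; ++p) {
      const int row = off + p;
      int m = 0;
      for (int c = 0; c < C; ++c) {
        const double *xc = &H(0, c) + off;
        for (int n = 0; n < k3; ++n) {
          const int t = bcol[n][p];
          buf[m++] = t == 0 ? 0.0 : xc[t - 1];
        }
      }
      std::fill(dg.begin(), dg.end(), 0.0);
      for (int co = 0; co < Co; ++co) {
        const double d = dA(row, co);
        if (d == 0.0) continue;
        double *gw = &gW(0, co);
        const double *w = &W(0, co);
        for (int i = 0; i < len; ++i) {
          gw[i] += d * buf[i];
          dg[i] += d * w[i];
        }
      }
      m = 0;
      for (int c = 0; c < C; ++c) {
        double *xc = &dX(0, c) + off;
        for (int n = 0; n < k3; ++n, ++m) {
          const int t = bcol[n][p];
          if (t != 0) xc[t - 1] += dg[m];
        }
      }
    }
  }
  return List::create(Named("gW") = gW, Named("dX") = dX);
}
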