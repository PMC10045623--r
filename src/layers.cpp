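// Compiled gather/scatter for the 1-D convolutional layers (feature
// mode). The arithmetic itself is left to BLAS on the R side; these
// kernels only rearrange memory (im2col / col2im) and run the max-pool
// scans. Arrays follow R's column-major layout: activations are
// (n, L, C); the im2col matrix is (n*outL) x (k*C) with the batch index
// fastest within a row block and the kernel offset fastest within a
// column block, matching the (k*C, filters) weight layout.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col1d(NumericVector Xp, IntegerVector dims,
                           int k, int s, int outL) {
  const int n = dims[0], Lp = dims[1], C = dims[2];
  NumericMatrix M(n * outL, k * C);
  const double* x = &Xp[0];
  double* m = &M(0, 0);
  const R_xlen_t rows = static_cast<R_xlen_t>(n) * outL;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double* mcol = m + (static_cast<R_xlen_t>(c) * k + j) * rows;
      for (int t = 0; t < outL; ++t) {
        const double* xcol = x + static_cast<R_xlen_t>(t * s + j) * n +
                             static_cast<R_xlen_t>(c) * n * Lp;
        std::copy(xcol, xcol + n, mcol + static_cast<R_xlen_t>(t) * n);
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_col2im1d(NumericMatrix dM, IntegerVector dims,
                           int k, int s, int outL) {
  const int n = dims[0], Lp = dims[1], C = dims[2];
  NumericVector dXp(static_cast<R_xlen_t>(n) * Lp * C);
  const R_xlen_t rows = static_cast<R_xlen_t>(n) * outL;
  const double* m = &dM(0, 0);
  double* x = &dXp[0];
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double* mcol = m + (static_cast<R_xlen_t>(c) * k + j) * rows;
      for (int t = 0; t < outL; ++t) {
        double* xcol = x + static_cast<R_xlen_t>(t * s + j) * n +
                       static_cast<R_xlen_t>(c) * n * Lp;
        const double* src = mcol + static_cast<R_xlen_t>(t) * n;
        for (int i = 0; i < n; ++i) xcol[i] += src[i];
      }
    }
  }
  dXp.attr("dim") = IntegerVector::create(n, Lp, C);
  return dXp;
}

// [[Rcpp::export]]
List cpp_pool1d_fwd(NumericVector Xp, IntegerVector dims,
                    int k, int s, int outL) {
  const int n = dims[0], Lp = dims[1], C = dims[2];
  NumericVector out(static_cast<R_xlen_t>(n) * outL * C);
  IntegerVector arg(static_cast<R_xlen_t>(n) * outL * C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < outL; ++t) {
      const int st = t * s;
      double* ocol = &out[static_cast<R_xlen_t>(t) * n +
                          static_cast<R_xlen_t>(c) * n * outL];
      int* acol = &arg[static_cast<R_xlen_t>(t) * n +
                       static_cast<R_xlen_t>(c) * n * outL];
      for (int i = 0; i < n; ++i) {
        double best = R_NegInf;
        int bidx = st + 1;
        for (int j = 0; j < k; ++j) {
          const double v = Xp[static_cast<R_xlen_t>(st + j) * n +
                              static_cast<R_xlen_t>(c) * n * Lp + i];
          if (v > best) { best = v; bidx = st + j + 1; }  // 1-based position
        }
        ocol[i] = best;
        acol[i] = bidx;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, outL, C);
  arg.attr("dim") = IntegerVector::create(n, outL, C);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_pool1d_bwd(IntegerVector arg, NumericVector dOut,
                             IntegerVector dims, int padL) {
  const int n = dims[0], outL = dims[1], C = dims[2];
  NumericVector dXp(static_cast<R_xlen_t>(n) * padL * C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < outL; ++t) {
      const R_xlen_t off = static_cast<R_xlen_t>(t) * n +
                           static_cast<R_xlen_t>(c) * n * outL;
      for (int i = 0; i < n; ++i) {
        const int pos = arg[off + i];  // 1-based padded position
        dXp[static_cast<R_xlen_t>(pos - 1) * n +
            static_cast<R_xlen_t>(c) * n * padL + i] += dOut[off + i];
      }
    }
  }
  dXp.attr("dim") = IntegerVector::create(n, padL, C);
  return dXp;
}
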