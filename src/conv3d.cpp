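// 3D convolution kernels for the registration network.
// Tensors are R arrays in (x, y, z, channel) order, column-major, so x is the
// fastest index. Convolutions are 3x3x3, stride 1, zero "same" padding, and are
// evaluated as chunked im2col + GEMM so peak memory stays bounded on large
// grids.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Fill `col` (rows x 27*Cin) with the im2col patch matrix for output voxels
// with z index in [z0, z1).
void im2col_chunk(const double* x, int d1, int d2, int d3, int cin,
                  int z0, int z1, arma::mat& col) {
  const int plane = d1 * d2;
  const int vol = plane * d3;
  col.zeros();
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)vol * c;
    for (int kz = 0; kz < 3; ++kz) {
      for (int ky = 0; ky < 3; ++ky) {
        for (int kx = 0; kx < 3; ++kx) {
          const int cc = kx + 3 * ky + 9 * kz + 27 * c;
          double* colptr = col.colptr(cc);
          for (int z = z0; z < z1; ++z) {
            const int zi = z + kz - 1;
            if (zi < 0 || zi >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yi = y + ky - 1;
              if (yi < 0 || yi >= d2) continue;
              const double* src = xc + (size_t)plane * zi + (size_t)d1 * yi;
              double* dst = colptr + (size_t)plane * (z - z0) + (size_t)d1 * y;
              const int xlo = std::max(0, 1 - kx);
              const int xhi = std::min(d1, d1 + 1 - kx);
              for (int i = xlo; i < xhi; ++i) dst[i] = src[i + kx - 1];
            }
          }
        }
      }
    }
  }
}

int chunk_slices(int d1, int d2, int cin) {
  // target <= ~2^24 doubles (128 MB) for the patch matrix
  double per_slice = (double)d1 * d2 * 27.0 * cin;
  int zc = (int)std::floor(16777216.0 / per_slice);
  return std::max(1, zc);
}

} // namespace

// When `keep_col` is true and the full patch matrix fits one chunk, it is
// returned alongside the output so the backward pass can reuse it.
// [[Rcpp::export(name = ".conv3d_fwd")]]
SEXP conv3d_fwd(NumericVector x, IntegerVector dims,
                NumericMatrix W, NumericVector b, bool keep_col = false) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = W.ncol();
  if (W.nrow() != 27 * cin) stop("weight matrix has wrong row count");
  const int plane = d1 * d2;
  NumericVector out((size_t)plane * d3 * cout);
  const int zc = chunk_slices(d1, d2, cin);
  arma::mat Wm(W.begin(), W.nrow(), cout, false, true);
  const bool single = zc >= d3;
  if (keep_col && single) {
    NumericMatrix colR((size_t)plane * d3, 27 * cin);
    arma::mat col(colR.begin(), colR.nrow(), colR.ncol(), false, true);
    im2col_chunk(x.begin(), d1, d2, d3, cin, 0, d3, col);
    arma::mat o = col * Wm;
    for (int c = 0; c < cout; ++c) {
      double* dst = out.begin() + (size_t)plane * d3 * c;
      const double* src = o.colptr(c);
      const double bc = b[c];
      for (size_t r = 0; r < (size_t)plane * d3; ++r) dst[r] = src[r] + bc;
    }
    out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
    return List::create(_["out"] = out, _["col"] = colR);
  }
  arma::mat col((size_t)plane * std::min(zc, d3), 27 * cin);
  for (int z0 = 0; z0 < d3; z0 += zc) {
    const int z1 = std::min(d3, z0 + zc);
    const int rows = plane * (z1 - z0);
    if ((int)col.n_rows != rows) col.set_size(rows, 27 * cin);
    im2col_chunk(x.begin(), d1, d2, d3, cin, z0, z1, col);
    arma::mat o = col * Wm;
    for (int c = 0; c < cout; ++c) {
      double* dst = out.begin() + (size_t)plane * d3 * c + (size_t)plane * z0;
      const double* src = o.colptr(c);
      const double bc = b[c];
      for (int r = 0; r < rows; ++r) dst[r] = src[r] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  if (keep_col) return List::create(_["out"] = out, _["col"] = R_NilValue);
  return out;
}

// Backward pass reusing a cached full patch matrix from the forward pass.
// [[Rcpp::export(name = ".conv3d_bwd_col")]]
List conv3d_bwd_col(NumericMatrix colR, IntegerVector dims, NumericMatrix W,
                    NumericVector dout) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = W.ncol();
  const int plane = d1 * d2;
  const size_t vol = (size_t)plane * d3;
  arma::mat Wm(W.begin(), W.nrow(), cout, false, true);
  arma::mat col(colR.begin(), colR.nrow(), colR.ncol(), false, true);
  arma::mat dchunk(dout.begin(), vol, cout, false, true);
  arma::mat dW = col.t() * dchunk;
  arma::vec db = arma::sum(dchunk, 0).t();
  arma::mat dcol = dchunk * Wm.t();
  NumericVector dx(vol * cin);
  for (int c = 0; c < cin; ++c) {
    double* dxc = dx.begin() + vol * c;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          const int cc = kx + 3 * ky + 9 * kz + 27 * c;
          const double* colptr = dcol.colptr(cc);
          for (int z = 0; z < d3; ++z) {
            const int zi = z + kz - 1;
            if (zi < 0 || zi >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yi = y + ky - 1;
              if (yi < 0 || yi >= d2) continue;
              double* dst = dxc + (size_t)plane * zi + (size_t)d1 * yi;
              const double* src = colptr + (size_t)plane * z + (size_t)d1 * y;
              const int xlo = std::max(0, 1 - kx);
              const int xhi = std::min(d1, d1 + 1 - kx);
              for (int i = xlo; i < xhi; ++i) dst[i + kx - 1] += src[i];
            }
          }
        }
  }
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                NumericVector dout) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = W.ncol();
  const int plane = d1 * d2;
  const int vol = plane * d3;
  arma::mat Wm(W.begin(), W.nrow(), cout, false, true);
  arma::mat dW(27 * cin, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((size_t)vol * cin);
  const int zc = chunk_slices(d1, d2, cin);
  arma::mat col;
  for (int z0 = 0; z0 < d3; z0 += zc) {
    const int z1 = std::min(d3, z0 + zc);
    const int rows = plane * (z1 - z0);
    col.set_size(rows, 27 * cin);
    im2col_chunk(x.begin(), d1, d2, d3, cin, z0, z1, col);
    arma::mat dchunk(rows, cout);
    for (int c = 0; c < cout; ++c) {
      const double* src = dout.begin() + (size_t)vol * c + (size_t)plane * z0;
      std::copy(src, src + rows, dchunk.colptr(c));
    }
    dW += col.t() * dchunk;
    db += arma::sum(dchunk, 0).t();
    arma::mat dcol = dchunk * Wm.t();  // rows x 27*cin
    // col2im: scatter-add the patch gradients back onto dx
    for (int c = 0; c < cin; ++c) {
      double* dxc = dx.begin() + (size_t)vol * c;
      for (int kz = 0; kz < 3; ++kz) {
        for (int ky = 0; ky < 3; ++ky) {
          for (int kx = 0; kx < 3; ++kx) {
            const int cc = kx + 3 * ky + 9 * kz + 27 * c;
            const double* colptr = dcol.colptr(cc);
            for (int z = z0; z < z1; ++z) {
              const int zi = z + kz - 1;
              if (zi < 0 || zi >= d3) continue;
              for (int y = 0; y < d2; ++y) {
                const int yi = y + ky - 1;
                if (yi < 0 || yi >= d2) continue;
                double* dst = dxc + (size_t)plane * zi + (size_t)d1 * yi;
                const double* src = colptr + (size_t)plane * (z - z0) + (size_t)d1 * y;
                const int xlo = std::max(0, 1 - kx);
                const int xhi = std::min(d1, d1 + 1 - kx);
                for (int i = xlo; i < xhi; ++i) dst[i + kx - 1] += src[i];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = wrap(db));
}
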