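// Pooling and trilinear resizing for (x, y, z, channel) tensors.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ch = dims[3];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const size_t ovol = (size_t)o1 * o2 * o3;
  NumericVector out(ovol * ch);
  IntegerVector arg(ovol * ch);
  const size_t plane = (size_t)d1 * d2, vol = plane * d3;
  for (int c = 0; c < ch; ++c) {
    const double* xc = x.begin() + vol * c;
    double* oc = out.begin() + ovol * c;
    int* ac = arg.begin() + ovol * c;
    size_t oi = 0;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int i = 0; i < o1; ++i, ++oi) {
          double best = -1e300; size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int di = 0; di < 2; ++di) {
                size_t ii = (size_t)(2 * i + di) + (size_t)d1 * (2 * y + dy) +
                            plane * (2 * z + dz);
                if (xc[ii] > best) { best = xc[ii]; besti = ii; }
              }
          oc[oi] = best; ac[oi] = (int)besti;
        }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3, ch);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dout, IntegerVector arg,
                           IntegerVector in_dims) {
  const int d1 = in_dims[0], d2 = in_dims[1], d3 = in_dims[2], ch = in_dims[3];
  const size_t vol = (size_t)d1 * d2 * d3;
  NumericVector dx(vol * ch);
  const size_t ovol = (size_t)dout.size() / ch;
  for (int c = 0; c < ch; ++c) {
    const double* dc = dout.begin() + ovol * c;
    const int* ac = arg.begin() + ovol * c;
    double* xc = dx.begin() + vol * c;
    for (size_t i = 0; i < ovol; ++i) xc[ac[i]] += dc[i];
  }
  dx.attr("dim") = in_dims;
  return dx;
}

// [[Rcpp::export(name = ".avgpool2")]]
NumericVector avgpool2(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ch = dims[3];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const size_t ovol = (size_t)o1 * o2 * o3;
  NumericVector out(ovol * ch);
  const size_t plane = (size_t)d1 * d2, vol = plane * d3;
  for (int c = 0; c < ch; ++c) {
    const double* xc = x.begin() + vol * c;
    double* oc = out.begin() + ovol * c;
    size_t oi = 0;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int i = 0; i < o1; ++i, ++oi) {
          double s = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int di = 0; di < 2; ++di)
                s += xc[(size_t)(2 * i + di) + (size_t)d1 * (2 * y + dy) +
                        plane * (2 * z + dz)];
          oc[oi] = s / 8.0;
        }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3, ch);
  return out;
}

namespace {
// align-corners mapping: out index i -> in coordinate i*(Din-1)/(Dout-1)
inline void lin_coeff(int dout, int din, int i, int& i0, int& i1, double& w1) {
  if (dout == 1 || din == 1) { i0 = 0; i1 = 0; w1 = 0.0; return; }
  double p = (double)i * (din - 1) / (dout - 1);
  i0 = (int)std::floor(p);
  if (i0 >= din - 1) i0 = din - 2;
  i1 = i0 + 1;
  w1 = p - i0;
}
} // namespace

// [[Rcpp::export(name = ".resize_trilinear_fwd")]]
NumericVector resize_trilinear_fwd(NumericVector x, IntegerVector dims,
                                   IntegerVector out_dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], ch = dims[3];
  const int o1 = out_dims[0], o2 = out_dims[1], o3 = out_dims[2];
  const size_t plane = (size_t)d1 * d2, vol = plane * d3;
  const size_t ovol = (size_t)o1 * o2 * o3;
  NumericVector out(ovol * ch);
  std::vector<int> x0(o1), x1(o1), y0(o2), y1(o2), z0(o3), z1(o3);
  std::vector<double> wx(o1), wy(o2), wz(o3);
  for (int i = 0; i < o1; ++i) lin_coeff(o1, d1, i, x0[i], x1[i], wx[i]);
  for (int i = 0; i < o2; ++i) lin_coeff(o2, d2, i, y0[i], y1[i], wy[i]);
  for (int i = 0; i < o3; ++i) lin_coeff(o3, d3, i, z0[i], z1[i], wz[i]);
  for (int c = 0; c < ch; ++c) {
    const double* xc = x.begin() + vol * c;
    double* oc = out.begin() + ovol * c;
    size_t oi = 0;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int i = 0; i < o1; ++i, ++oi) {
          double v = 0;
          const double wzs[2] = {1.0 - wz[z], wz[z]};
          const double wys[2] = {1.0 - wy[y], wy[y]};
          const double wxs[2] = {1.0 - wx[i], wx[i]};
          const int zz[2] = {z0[z], z1[z]}, yy[2] = {y0[y], y1[y]},
                    xx[2] = {x0[i], x1[i]};
          for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b)
              for (int d = 0; d < 2; ++d)
                v += wzs[a] * wys[b] * wxs[d] *
                     xc[(size_t)xx[d] + (size_t)d1 * yy[b] + plane * zz[a]];
          oc[oi] = v;
        }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3, ch);
  return out;
}

// exact transpose of resize_trilinear_fwd
// [[Rcpp::export(name = ".resize_trilinear_bwd")]]
NumericVector resize_trilinear_bwd(NumericVector dout, IntegerVector out_dims,
                                   IntegerVector in_dims) {
  const int d1 = in_dims[0], d2 = in_dims[1], d3 = in_dims[2], ch = in_dims[3];
  const int o1 = out_dims[0], o2 = out_dims[1], o3 = out_dims[2];
  const size_t plane = (size_t)d1 * d2, vol = plane * d3;
  const size_t ovol = (size_t)o1 * o2 * o3;
  NumericVector dx(vol * ch);
  std::vector<int> x0(o1), x1(o1), y0(o2), y1(o2), z0(o3), z1(o3);
  std::vector<double> wx(o1), wy(o2), wz(o3);
  for (int i = 0; i < o1; ++i) lin_coeff(o1, d1, i, x0[i], x1[i], wx[i]);
  for (int i = 0; i < o2; ++i) lin_coeff(o2, d2, i, y0[i], y1[i], wy[i]);
  for (int i = 0; i < o3; ++i) lin_coeff(o3, d3, i, z0[i], z1[i], wz[i]);
  for (int c = 0; c < ch; ++c) {
    double* xc = dx.begin() + vol * c;
    const double* oc = dout.begin() + ovol * c;
    size_t oi = 0;
    for (int z = 0; z < o3; ++z)
      for (int y = 0; y < o2; ++y)
        for (int i = 0; i < o1; ++i, ++oi) {
          const double g = oc[oi];
          if (g == 0.0) continue;
          const double wzs[2] = {1.0 - wz[z], wz[z]};
          const double wys[2] = {1.0 - wy[y], wy[y]};
          const double wxs[2] = {1.0 - wx[i], wx[i]};
          const int zz[2] = {z0[z], z1[z]}, yy[2] = {y0[y], y1[y]},
                    xx[2] = {x0[i], x1[i]};
          for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b)
              for (int d = 0; d < 2; ++d)
                xc[(size_t)xx[d] + (size_t)d1 * yy[b] + plane * zz[a]] +=
                    g * wzs[a] * wys[b] * wxs[d];
        }
  }
  dx.attr("dim") = in_dims;
  return dx;
}
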