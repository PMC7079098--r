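// Fused spatial batch-normalization + ReLU (batch of one: statistics are
// taken over the voxels of each channel).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_relu_fwd")]]
List bn_relu_fwd(NumericVector x, IntegerVector dims, NumericVector gamma,
                 NumericVector beta, NumericVector ema_mean,
                 NumericVector ema_var, bool training, double eps) {
  const int ch = dims[3];
  const size_t v = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector out(v * ch), xhat(v * ch), invstd(ch);
  NumericVector bmean(training ? ch : 0), bvar(training ? ch : 0);
  LogicalVector mask(v * ch);
  for (int c = 0; c < ch; ++c) {
    const double* xc = x.begin() + v * c;
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (size_t i = 0; i < v; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      mu = s / v;
      var = s2 / v - mu * mu;
      bmean[c] = mu; bvar[c] = var;
    } else {
      mu = ema_mean[c]; var = ema_var[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* oc = out.begin() + v * c;
    double* hc = xhat.begin() + v * c;
    int* mc = LOGICAL(mask) + v * c;
    for (size_t i = 0; i < v; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      const double y = g * h + b;
      mc[i] = y > 0;
      oc[i] = y > 0 ? y : 0.0;
    }
  }
  out.attr("dim") = dims;
  return List::create(_["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["mask"] = mask, _["batch_mean"] = bmean,
                      _["batch_var"] = bvar);
}

// [[Rcpp::export(name = ".bn_relu_bwd")]]
List bn_relu_bwd(NumericVector dout, IntegerVector dims, NumericVector xhat,
                 NumericVector invstd, NumericVector gamma,
                 LogicalVector mask) {
  const int ch = dims[3];
  const size_t v = (size_t)dims[0] * dims[1] * dims[2];
  NumericVector dx(v * ch), dgamma(ch), dbeta(ch);
  for (int c = 0; c < ch; ++c) {
    const double* dc = dout.begin() + v * c;
    const double* hc = xhat.begin() + v * c;
    const int* mc = LOGICAL(mask) + v * c;
    double s1 = 0, s2 = 0, sg = 0;
    for (size_t i = 0; i < v; ++i) {
      const double dy = mc[i] ? dc[i] : 0.0;
      s1 += dy;
      s2 += dy * hc[i];
    }
    sg = s2;
    const double m1 = s1 / v, m2 = s2 / v;
    const double coef = gamma[c] * invstd[c];
    double* xc = dx.begin() + v * c;
    for (size_t i = 0; i < v; ++i) {
      const double dy = mc[i] ? dc[i] : 0.0;
      xc[i] = coef * (dy - m1 - hc[i] * m2);
    }
    dgamma[c] = sg;
    dbeta[c] = s1;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
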