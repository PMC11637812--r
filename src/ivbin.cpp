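#include <Rcpp.h>
using namespace Rcpp;

// Fused genotype + allele-dose sampler.  Column k draws n Binomial(2, q_k)
// genotypes by inverting the three-point cdf on one uniform per subject
// (exactly the draws runif(n) would produce, in the same stream order) and
// accumulates the allele dose sum_k alpha_k Z_ik on the fly, so the n x K
// integer matrix never has to be coerced to double for a matrix product.
// [[Rcpp::export(name = ".draw_genotypes_dose")]]
List draw_genotypes_dose(int n, NumericVector q, NumericVector alpha) {
  int K = q.size();
  IntegerMatrix Z(n, K);
  NumericVector dose(n);
  for (int k = 0; k < K; ++k) {
    double p0 = (1.0 - q[k]) * (1.0 - q[k]);
    double p01 = p0 + 2.0 * q[k] * (1.0 - q[k]);
    double ak = alpha[k];
    int *zcol = &Z(0, k);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      int z = (u > p0) + (u > p01);
      zcol[i] = z;
      dose[i] += ak * z;
    }
  }
  return List::create(_["Z"] = Z, _["dose"] = dose);
}

// One IRLS accumulation pass for per-SNP log-link regressions, vectorised
// across SNPs.  For SNP k with centred genotypes z (column k of Zc), centred
// covariate x (optional) and current coefficients (a_k, b_k, c_k):
//   eta = a_k + b_k z + c_k x, mu = exp(eta)
//   weight w = mu/(1-mu) (binomial log link) or mu (Poisson log link)
//   working response u* = eta + (y - mu)/mu
// accumulates the weighted sums needed for the normal equations plus a flag
// for SNPs whose linear predictor hits the risk cap (binomial only).
// Returns a K x 10 matrix: S_w, S_wz, S_wzz, S_wx, S_wxx, S_wzx,
// r_a, r_b, r_x, atcap.
// [[Rcpp::export(name = ".snp_irls_sums")]]
NumericMatrix snp_irls_sums(NumericVector y, NumericMatrix Zc,
                            Nullable<NumericVector> x_,
                            NumericVector a, NumericVector b,
                            NumericVector cx, bool poisson) {
  int n = Zc.nrow(), K = Zc.ncol();
  bool has_x = x_.isNotNull();
  NumericVector x;
  if (has_x) x = x_.get();
  NumericMatrix out(K, 10);
  const double cap = poisson ? 30.0 : -1e-10;
  for (int k = 0; k < K; ++k) {
    double Sw = 0, Swz = 0, Swzz = 0, Swx = 0, Swxx = 0, Swzx = 0;
    double ra = 0, rb = 0, rx = 0;
    double atcap = 0;
    double ak = a[k], bk = b[k], ck = cx[k];
    const double *z = &Zc(0, k);
    for (int i = 0; i < n; ++i) {
      double eta = ak + bk * z[i];
      if (has_x) eta += ck * x[i];
      if (eta >= -1e-10) atcap = 1;
      if (eta > cap) eta = cap;
      double mu = std::exp(eta);
      double w = poisson ? mu : mu / (1.0 - mu);
      double wu = w * eta + (y[i] - mu) * (w / mu);
      Sw += w;
      double wz = w * z[i];
      Swz += wz;
      Swzz += wz * z[i];
      ra += wu;
      rb += wu * z[i];
      if (has_x) {
        double wx = w * x[i];
        Swx += wx;
        Swxx += wx * x[i];
        Swzx += wz * x[i];
        rx += wu * x[i];
      }
    }
    out(k, 0) = Sw;  out(k, 1) = Swz;  out(k, 2) = Swzz;
    out(k, 3) = Swx; out(k, 4) = Swxx; out(k, 5) = Swzx;
    out(k, 6) = ra;  out(k, 7) = rb;   out(k, 8) = rx;
    out(k, 9) = atcap;
  }
  return out;
}
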