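#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs sweep over the latent cluster-of-origin variables z[i,l] of the
// haploid-band admixture model. For each individual i and locus l the
// responsibility of cluster k is Q(i,k) * (x ? P(k,l) : 1-P(k,l)); z is
// sampled from it and the sufficient statistics are accumulated:
//   zcount(i,k)  - loci assigned to cluster k in individual i
//   ones(k,l)    - band-present observations assigned to (k,l)
//   tots(k,l)    - all observations assigned to (k,l)
// The returned loglik is the observed-data log likelihood with z summed out,
// sum_il log(sum_k Q(i,k) lik(k,i,l)).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List admixture_z_sweep(const IntegerMatrix& X, const NumericMatrix& Q,
                       const NumericMatrix& P) {
  const int N = X.nrow(), L = X.ncol(), K = Q.ncol();
  NumericMatrix zcount(N, K), ones(K, L), tots(K, L);
  double loglik = 0.0;        // marginal: sum log sum_k Q lik
  double loglik_z = 0.0;      // complete-data: sum log lik at the sampled z
  std::vector<double> r(K);
  for (int i = 0; i < N; ++i) {
    // row likelihoods accumulated as products with explicit exponent
    // rescaling: one log per individual instead of one per cell
    double prod = 1.0, prod_z = 1.0;
    int ex = 0, ex_z = 0;
    for (int l = 0; l < L; ++l) {
      const int x = X(i, l);
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        const double p = P(k, l);
        const double lik = x ? p : (1.0 - p);
        r[k] = Q(i, k) * lik;
        tot += r[k];
      }
      if (tot < 1e-300) tot = 1e-300;
      prod *= tot;
      if (prod < 1e-280) { prod *= 1e280; ex -= 280; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += r[k];
        if (u <= acc) { pick = k; break; }
      }
      zcount(i, pick) += 1.0;
      tots(pick, l) += 1.0;
      if (x) ones(pick, l) += 1.0;
      const double pe = P(pick, l);
      double lik_z = x ? pe : (1.0 - pe);
      if (lik_z < 1e-300) lik_z = 1e-300;
      prod_z *= lik_z;
      if (prod_z < 1e-280) { prod_z *= 1e280; ex_z -= 280; }
    }
    loglik += std::log(prod) + ex * M_LN10;
    loglik_z += std::log(prod_z) + ex_z * M_LN10;
  }
  return List::create(_["zcount"] = zcount, _["ones"] = ones,
                      _["tots"] = tots, _["loglik"] = loglik,
                      _["loglik_z"] = loglik_z);
}
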