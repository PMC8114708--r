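#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward for the haploid Li-Stephens copying model.
//
// Hidden state at site l: which of the K reference haplotypes the target is
// copying. Transition between adjacent sites with switch probability rho_l:
//   P(j -> k) = (1 - rho_l) * I(j == k) + rho_l / K
// Emission at a typed site: 1 - eps on allele match, eps on mismatch;
// untyped sites (obs == NA) emit uniformly. Initial state uniform.
//
// ref: L x K 0/1 matrix (NA allele treated as uninformative).
// obs: length-L 0/1 vector with NA at untyped sites.
// rho: length L-1 switch probabilities.
// Returns the posterior P(allele = 1) per site and optionally the full
// state posterior matrix. State vectors are kept contiguous per site.

// [[Rcpp::export(name = ".ls_forward_backward")]]
List ls_forward_backward_cpp(IntegerMatrix ref, IntegerVector obs,
                             NumericVector rho, double eps,
                             bool return_states) {
  const int L = ref.nrow(), K = ref.ncol();
  if (K < 1) stop("at least one reference haplotype is required");
  if (obs.size() != L) stop("obs length must match reference sites");
  if (L > 1 && rho.size() != L - 1) stop("need one switch probability per interval");

  // emission table, site-major: emis[l*K + k]
  std::vector<double> emis((size_t)L * K, 1.0);
  const int* refp = INTEGER(ref); // column-major: ref[l + k*L]
  for (int l = 0; l < L; ++l) {
    const int o = obs[l];
    if (o == NA_INTEGER) continue;
    double* e = &emis[(size_t)l * K];
    for (int k = 0; k < K; ++k) {
      const int a = refp[l + (size_t)k * L];
      if (a != NA_INTEGER) e[k] = (a == o) ? (1.0 - eps) : eps;
    }
  }

  std::vector<double> alpha((size_t)L * K);
  std::vector<double> scale(L);

  // forward
  {
    double s = 0.0;
    const double* e = &emis[0];
    double* a = &alpha[0];
    for (int k = 0; k < K; ++k) { a[k] = e[k] / K; s += a[k]; }
    if (s <= 0) stop("zero forward likelihood at site 1");
    scale[0] = s;
    for (int k = 0; k < K; ++k) a[k] /= s;
  }
  for (int l = 1; l < L; ++l) {
    const double r = rho[l - 1];
    const double stay = 1.0 - r, jump = r / K;
    const double* e = &emis[(size_t)l * K];
    const double* ap = &alpha[(size_t)(l - 1) * K];
    double* a = &alpha[(size_t)l * K];
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double v = (stay * ap[k] + jump) * e[k]; // sum(ap) == 1
      a[k] = v;
      s += v;
    }
    if (s <= 0) stop("zero forward likelihood");
    scale[l] = s;
    for (int k = 0; k < K; ++k) a[k] /= s;
  }

  // backward, combined into the posterior in place
  std::vector<double> beta(K, 1.0), v(K);
  std::vector<double>& post = alpha; // alpha rows become posterior rows
  for (int l = L - 2; l >= 0; --l) {
    const double r = rho[l];
    const double stay = 1.0 - r, jumpK = r / K;
    const double* e = &emis[(size_t)(l + 1) * K];
    double vsum = 0.0;
    for (int k = 0; k < K; ++k) { v[k] = e[k] * beta[k]; vsum += v[k]; }
    const double c = scale[l + 1];
    double s = 0.0;
    double* p = &post[(size_t)l * K];
    for (int k = 0; k < K; ++k) {
      beta[k] = (stay * v[k] + jumpK * vsum) / c;
      const double pk = p[k] * beta[k];
      p[k] = pk;
      s += pk;
    }
    for (int k = 0; k < K; ++k) p[k] /= s; // renormalise rounding error
  }

  NumericVector allele_post(L);
  for (int l = 0; l < L; ++l) {
    const double* p = &post[(size_t)l * K];
    double num = 0.0, mass = 0.0;
    for (int k = 0; k < K; ++k) {
      const int a = refp[l + (size_t)k * L];
      if (a == NA_INTEGER) continue;
      mass += p[k];
      if (a == 1) num += p[k];
    }
    allele_post[l] = (mass > 0) ? num / mass : NA_REAL;
  }

  if (return_states) {
    NumericMatrix states(L, K);
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k) states(l, k) = post[(size_t)l * K + k];
    return List::create(_["allele"] = allele_post, _["states"] = states);
  }
  return List::create(_["allele"] = allele_post);
}
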