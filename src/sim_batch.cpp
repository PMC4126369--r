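#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Small fast PCG32 generator, seeded from R's RNG at each call so that
// results remain a deterministic function of set.seed().  The simulation
// burns ~100 variates per family and tens of millions of families per
// evaluation run; calling R's generator for each variate would dominate
// the run time.
namespace {

struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() {  // in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace

// Batch gene-dropping simulation of one pedigree structure.
//
// Founder alleles at each causal locus are iid Bernoulli(RAF) draws under
// Hardy-Weinberg equilibrium; each transmitted allele is drawn uniformly
// from the parent's two.  Distinct founder-allele slot labels are tracked
// so realized IBD sharing can be computed exactly, and so that a null
// marker in linkage equilibrium with the locus-2 causal variant can later
// be assigned independent founder allele types on the same locus-2
// segregation pattern.
//
// Phenotypes follow the two-step scheme: Y1 ~ Bernoulli(P[(1,0)|X] +
// P[(1,1)|X]) from the polytomous model, then, given one multivariate
// normal polygenic vector U ~ N(0, sigma^2 Phi) per family,
// Y2_i ~ Bernoulli(logit^-1(gamma(X_i, Y1_i) + U_i +
//                           alpha * sum_{h != i} (Y1_h - nu) phi_ih)).
//
// Families are optionally filtered by the ascertainment rule "at least
// one first-cousin pair with Y2 = 1"; only kept families are returned.
//
// fa, mo: 0-based parent indices in topological order, -1 for founders.
// beta: 3 x 4 coefficient matrix (rows: categories (1,0),(0,1),(1,1);
//       columns: intercept, X1, X2, X1X2); shift added to intercepts.
// Lchol: lower Cholesky factor of sigma^2 * Phi (all zero if sigma^2=0).
// phiAlpha: alpha * Phi with zero diagonal.
// cpairs: 0-based index pairs with kinship 1/16 (first cousins).
// [[Rcpp::export]]
List sim_batch_cpp(int B, IntegerVector fa, IntegerVector mo,
                   double raf1, double raf2, NumericMatrix beta,
                   double shift, NumericMatrix Lchol,
                   NumericMatrix phiAlpha, double nu,
                   IntegerMatrix cpairs, bool ascertain,
                   int max_keep) {
  const int n = fa.size();
  std::vector<int> founders, nonf;
  for (int i = 0; i < n; ++i) {
    if (fa[i] < 0) founders.push_back(i); else nonf.push_back(i);
  }
  const int F = (int)founders.size();

  // seed the fast generator from R's RNG stream
  uint64_t s1 = (uint64_t)std::floor(R::unif_rand() * 4294967296.0);
  uint64_t s2 = (uint64_t)std::floor(R::unif_rand() * 4294967296.0);
  uint64_t s3 = (uint64_t)std::floor(R::unif_rand() * 4294967296.0);
  Pcg32 rng((s1 << 32) | s2, s3);

  std::vector<int> la1(n), lb1(n), la2(n), lb2(n);  // slot labels
  std::vector<int> t1(2 * F), t2(2 * F);            // founder types
  std::vector<double> x1(n), x2(n), e1(n), e2(n), e3(n), u(n);
  std::vector<int> y1(n), y2(n);

  std::vector<int> keepY1, keepY2, keepLa1, keepLb1, keepLa2, keepLb2;
  std::vector<int> keepT1, keepT2;
  int kept = 0, draws = 0;

  for (int b = 0; b < B && kept < max_keep; ++b) {
    ++draws;
    // founder slots and types
    for (int f = 0; f < F; ++f) {
      int i = founders[f];
      la1[i] = 2 * f; lb1[i] = 2 * f + 1;
      la2[i] = 2 * f; lb2[i] = 2 * f + 1;
      t1[2 * f]     = (rng.unif() < raf1) ? 1 : 0;
      t1[2 * f + 1] = (rng.unif() < raf1) ? 1 : 0;
      t2[2 * f]     = (rng.unif() < raf2) ? 1 : 0;
      t2[2 * f + 1] = (rng.unif() < raf2) ? 1 : 0;
    }
    // independent Mendelian transmissions at the two unlinked loci
    for (size_t q = 0; q < nonf.size(); ++q) {
      int i = nonf[q];
      la1[i] = (rng.unif() < 0.5) ? la1[fa[i]] : lb1[fa[i]];
      lb1[i] = (rng.unif() < 0.5) ? la1[mo[i]] : lb1[mo[i]];
      la2[i] = (rng.unif() < 0.5) ? la2[fa[i]] : lb2[fa[i]];
      lb2[i] = (rng.unif() < 0.5) ? la2[mo[i]] : lb2[mo[i]];
    }
    for (int i = 0; i < n; ++i) {
      x1[i] = 0.5 * (t1[la1[i]] + t1[lb1[i]]);
      x2[i] = 0.5 * (t2[la2[i]] + t2[lb2[i]]);
    }
    // step 1: endophenotype from the polytomous marginal
    for (int i = 0; i < n; ++i) {
      double p12 = x1[i] * x2[i];
      e1[i] = std::exp(beta(0, 0) + shift + beta(0, 1) * x1[i] +
                       beta(0, 2) * x2[i] + beta(0, 3) * p12);
      e2[i] = std::exp(beta(1, 0) + shift + beta(1, 1) * x1[i] +
                       beta(1, 2) * x2[i] + beta(1, 3) * p12);
      e3[i] = std::exp(beta(2, 0) + shift + beta(2, 1) * x1[i] +
                       beta(2, 2) * x2[i] + beta(2, 3) * p12);
      double den = 1.0 + e1[i] + e2[i] + e3[i];
      double pY1 = (e1[i] + e3[i]) / den;
      y1[i] = (rng.unif() < pY1) ? 1 : 0;
    }
    // step 2: disease given endophenotype vector, polygenic U, kin term
    for (int i = 0; i < n; ++i) u[i] = rng.norm();
    for (int i = 0; i < n; ++i) {  // U = L z, L lower triangular
      double s = 0.0;
      for (int j = 0; j <= i; ++j) s += Lchol(i, j) * u[j];
      e1[i] = s;  // e1 is free after step 1; reused to hold U
    }
    for (int i = 0; i < n; ++i) {
      double kin = 0.0;
      for (int h = 0; h < n; ++h) kin += phiAlpha(i, h) * (y1[h] - nu);
      double p12 = x1[i] * x2[i];
      double g;
      if (y1[i] == 1) {
        g = (beta(2, 0) - beta(0, 0)) + (beta(2, 1) - beta(0, 1)) * x1[i] +
            (beta(2, 2) - beta(0, 2)) * x2[i] +
            (beta(2, 3) - beta(0, 3)) * p12;
      } else {
        g = beta(1, 0) + shift + beta(1, 1) * x1[i] + beta(1, 2) * x2[i] +
            beta(1, 3) * p12;
      }
      double lin = g + e1[i] + kin;
      double pY2 = 1.0 / (1.0 + std::exp(-lin));
      y2[i] = (rng.unif() < pY2) ? 1 : 0;
    }
    if (ascertain) {
      bool keep = false;
      for (int p = 0; p < cpairs.nrow(); ++p) {
        if (y2[cpairs(p, 0)] == 1 && y2[cpairs(p, 1)] == 1) {
          keep = true; break;
        }
      }
      if (!keep) continue;
    }
    for (int i = 0; i < n; ++i) {
      keepY1.push_back(y1[i]); keepY2.push_back(y2[i]);
      keepLa1.push_back(la1[i]); keepLb1.push_back(lb1[i]);
      keepLa2.push_back(la2[i]); keepLb2.push_back(lb2[i]);
    }
    for (int s = 0; s < 2 * F; ++s) {
      keepT1.push_back(t1[s]); keepT2.push_back(t2[s]);
    }
    ++kept;
  }
  auto mat = [&](std::vector<int>& v, int nr) {
    IntegerMatrix m(nr, kept);
    std::copy(v.begin(), v.end(), m.begin());
    return m;
  };
  return List::create(
    _["Y1"] = mat(keepY1, n), _["Y2"] = mat(keepY2, n),
    _["la1"] = mat(keepLa1, n), _["lb1"] = mat(keepLb1, n),
    _["la2"] = mat(keepLa2, n), _["lb2"] = mat(keepLb2, n),
    _["t1"] = mat(keepT1, 2 * F), _["t2"] = mat(keepT2, 2 * F),
    _["kept"] = kept, _["draws"] = draws);
}
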