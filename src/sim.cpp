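#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One meiosis under the Haldane (no-interference) model: crossovers are
// Poisson along each chromosome, positions uniform; the starting parental
// haplotype is chosen at random per chromosome. Writes the gamete into row
// `orow` of `Out`. Uses R's RNG (caller holds the RNGScope).
static void meiosis(const IntegerMatrix &H, int h1, int h2,
                    const NumericVector &posM, const IntegerVector &chromStart,
                    const IntegerVector &chromEnd, IntegerMatrix &Out,
                    int orow) {
  int nChr = chromStart.size();
  for (int c = 0; c < nChr; ++c) {
    int s = chromStart[c], e = chromEnd[c];
    double len = posM[e] - posM[s];
    int cur = (unif_rand() < 0.5) ? h1 : h2;
    int k = (len > 0) ? (int)R::rpois(len) : 0;
    if (k == 0) {
      for (int i = s; i <= e; ++i) Out(orow, i) = H(cur, i);
    } else {
      std::vector<double> x(k);
      for (int j = 0; j < k; ++j) x[j] = posM[s] + unif_rand() * len;
      std::sort(x.begin(), x.end());
      int xi = 0;
      for (int i = s; i <= e; ++i) {
        while (xi < k && x[xi] < posM[i]) {
          cur = (cur == h1) ? h2 : h1;
          ++xi;
        }
        Out(orow, i) = H(cur, i);
      }
    }
  }
}

// Drop founder-haplotype labels down a pedigree with recombination.
// sire/dam are 0-based indices into the (topologically ordered) pedigree,
// -1 for founders. Returns a (2n x L) matrix of founder-haplotype ids:
// founder i carries constant labels 2i and 2i+1.
// [[Rcpp::export]]
IntegerMatrix cpp_gene_drop(IntegerVector sire, IntegerVector dam,
                            NumericVector posM, IntegerVector chromStart,
                            IntegerVector chromEnd) {
  int n = sire.size();
  int L = posM.size();
  IntegerMatrix H(2 * n, L);
  for (int i = 0; i < n; ++i) {
    if (sire[i] < 0 || dam[i] < 0) {
      if (!(sire[i] < 0 && dam[i] < 0))
        stop("gene dropping needs both parents known or none");
      for (int j = 0; j < L; ++j) {
        H(2 * i, j) = 2 * i;
        H(2 * i + 1, j) = 2 * i + 1;
      }
    } else {
      if (sire[i] >= i || dam[i] >= i)
        stop("pedigree not topologically ordered");
      meiosis(H, 2 * sire[i], 2 * sire[i] + 1, posM, chromStart, chromEnd, H,
              2 * i);
      meiosis(H, 2 * dam[i], 2 * dam[i] + 1, posM, chromStart, chromEnd, H,
              2 * i + 1);
    }
  }
  return H;
}

// Discrete-generation Wright-Fisher population of N diploids with
// recombination. H0 is the (2N x L) matrix of 0/1 founder haplotypes;
// each generation every offspring draws two distinct parents uniformly
// and receives one recombinant gamete from each. Returns the final
// generation's haplotypes.
// [[Rcpp::export]]
IntegerMatrix cpp_wright_fisher(IntegerMatrix H0, int nGen,
                                NumericVector posM, IntegerVector chromStart,
                                IntegerVector chromEnd) {
  int N = H0.nrow() / 2;
  if (N < 2) stop("need at least two diploids");
  int L = posM.size();
  IntegerMatrix A = clone(H0);
  IntegerMatrix B(2 * N, L);
  for (int g = 0; g < nGen; ++g) {
    for (int i = 0; i < N; ++i) {
      int p1 = (int)(unif_rand() * N);
      if (p1 == N) --p1;
      int p2 = p1;
      while (p2 == p1) {
        p2 = (int)(unif_rand() * N);
        if (p2 == N) --p2;
      }
      meiosis(A, 2 * p1, 2 * p1 + 1, posM, chromStart, chromEnd, B, 2 * i);
      meiosis(A, 2 * p2, 2 * p2 + 1, posM, chromStart, chromEnd, B,
              2 * i + 1);
    }
    std::swap(A, B);
  }
  return A;
}
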