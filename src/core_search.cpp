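// Subset search engine for core-collection construction.
//
// Objective over a subset S of accessions:
//   obj(S) = wMr * meanPairwiseMR(S) + wSh * pooledShannonNorm(S)
// where meanPairwiseMR comes from a precomputed modified-Rogers matrix and
// pooledShannonNorm pools all alleles of all loci called in S:
//   f_a = (allele frequency at its locus) / Leff,  sum f_a = 1
//   SH = -sum f_a ln f_a = mean_l I_l + ln Leff,   normalized by ln(2 Leff).
// Greedy fill from a protected seed set, then steepest-ascent single-swap
// hill climbing (seeds never leave). Ties resolve to the first candidate in
// index order, so the search is deterministic for a given start.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SearchState {
  const IntegerMatrix& geno;   // L x N dosages, NA for missing
  const NumericMatrix& D;      // N x N modified Rogers
  int L, N;
  std::vector<double> logTab;  // ln(i), ln(0) := 0 (only hit with weight 0)
  std::vector<int> altc, cc;   // per-locus alt-allele and called counts in S
  std::vector<double> contrib; // per-locus Shannon index I_l in S
  std::vector<char> inS;
  std::vector<double> rowSum;  // sum over j in S of D(i, j)
  double sumD = 0.0, shSum = 0.0;
  int Leff = 0, sz = 0;

  SearchState(const IntegerMatrix& g, const NumericMatrix& d)
      : geno(g), D(d), L(g.nrow()), N(g.ncol()),
        logTab(std::max(2 * g.ncol(), g.nrow()) + 3, 0.0),
        altc(g.nrow(), 0), cc(g.nrow(), 0),
        contrib(g.nrow(), 0.0), inS(g.ncol(), 0), rowSum(g.ncol(), 0.0) {
    for (int i = 1; i < (int)logTab.size(); ++i) logTab[i] = std::log((double)i);
  }

  // Shannon index of one locus with alt count a on c called genotypes
  inline double locusI(int a, int c) const {
    if (c <= 0) return 0.0;
    const int tot = 2 * c, b = tot - a;
    return logTab[tot] - (a * logTab[a] + b * logTab[b]) / (double)tot;
  }

  inline double shNorm(double s, int leff) const {
    if (leff == 0) return 0.0;
    return (s / leff + logTab[leff]) / (logTab[leff] + logTab[2]);
  }

  double wMr = 0.7, wSh = 0.3;
  inline double objOf(double sd, double s, int leff, int size) const {
    double mr = size >= 2 ? sd / (size * (size - 1) / 2.0) : 0.0;
    return wMr * mr + wSh * shNorm(s, leff);
  }
  inline double obj() const { return objOf(sumD, shSum, Leff, sz); }

  void add(int j) {
    sumD += rowSum[j];
    for (int i = 0; i < N; ++i) rowSum[i] += D(i, j);
    for (int l = 0; l < L; ++l) {
      int x = geno(l, j);
      if (x == NA_INTEGER) continue;
      if (cc[l] > 0) shSum -= contrib[l]; else ++Leff;
      altc[l] += x; cc[l] += 1;
      contrib[l] = locusI(altc[l], cc[l]);
      shSum += contrib[l];
    }
    inS[j] = 1; ++sz;
  }

  void remove(int u) {
    sumD -= rowSum[u];
    for (int i = 0; i < N; ++i) rowSum[i] -= D(i, u);
    for (int l = 0; l < L; ++l) {
      int x = geno(l, u);
      if (x == NA_INTEGER) continue;
      shSum -= contrib[l];
      altc[l] -= x; cc[l] -= 1;
      if (cc[l] > 0) { contrib[l] = locusI(altc[l], cc[l]); shSum += contrib[l]; }
      else { contrib[l] = 0.0; --Leff; }
    }
    inS[u] = 0; --sz;
  }

  // objective if v were added (no commit)
  double tryAdd(int v) const {
    double sd = sumD + rowSum[v], s = shSum;
    int leff = Leff;
    for (int l = 0; l < L; ++l) {
      int x = geno(l, v);
      if (x == NA_INTEGER) continue;
      if (cc[l] > 0) s -= contrib[l]; else ++leff;
      s += locusI(altc[l] + x, cc[l] + 1);
    }
    return objOf(sd, s, leff, sz + 1);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_core_search")]]
List cpp_core_search(IntegerMatrix geno, NumericMatrix D,
                     IntegerVector seed0, IntegerVector init0,
                     int size, double wMr, double wSh, int maxIter) {
  SearchState st(geno, D);
  st.wMr = wMr; st.wSh = wSh;
  const int N = st.N, L = st.L;
  std::vector<char> isSeed(N, 0);
  for (int k = 0; k < seed0.size(); ++k) isSeed[seed0[k]] = 1;
  for (int k = 0; k < init0.size(); ++k) st.add(init0[k]);

  // greedy fill by best objective gain
  while (st.sz < size) {
    int best = -1; double bestObj = -1e300;
    for (int v = 0; v < N; ++v) {
      if (st.inS[v]) continue;
      double o = st.tryAdd(v);
      if (o > bestObj + 1e-15) { bestObj = o; best = v; }
    }
    st.add(best);
  }

  std::vector<double> trace;
  double cur = st.obj();
  trace.push_back(cur);

  // steepest-ascent single swap; seeds are protected
  std::vector<double> contrib2(L);
  std::vector<int> altc2(L), cc2(L);
  for (int iter = 0; iter < maxIter; ++iter) {
    int bu = -1, bv = -1; double bestObj = cur;
    for (int u = 0; u < N; ++u) {
      if (!st.inS[u] || isSeed[u]) continue;
      // state minus u
      double sh2 = st.shSum; int leff2 = st.Leff;
      std::copy(st.altc.begin(), st.altc.end(), altc2.begin());
      std::copy(st.cc.begin(), st.cc.end(), cc2.begin());
      std::copy(st.contrib.begin(), st.contrib.end(), contrib2.begin());
      for (int l = 0; l < L; ++l) {
        int x = geno(l, u);
        if (x == NA_INTEGER) continue;
        sh2 -= contrib2[l];
        altc2[l] -= x; cc2[l] -= 1;
        if (cc2[l] > 0) { contrib2[l] = st.locusI(altc2[l], cc2[l]); sh2 += contrib2[l]; }
        else { contrib2[l] = 0.0; --leff2; }
      }
      const double sumD2 = st.sumD - st.rowSum[u];
      for (int v = 0; v < N; ++v) {
        if (st.inS[v]) continue;
        double sd = sumD2 + st.rowSum[v] - D(u, v);
        double s = sh2; int leff = leff2;
        for (int l = 0; l < L; ++l) {
          int x = geno(l, v);
          if (x == NA_INTEGER) continue;
          if (cc2[l] > 0) s -= contrib2[l]; else ++leff;
          s += st.locusI(altc2[l] + x, cc2[l] + 1);
        }
        double o = st.objOf(sd, s, leff, st.sz);
        if (o > bestObj + 1e-12) { bestObj = o; bu = u; bv = v; }
      }
    }
    if (bu < 0) break;
    st.remove(bu);
    st.add(bv);
    cur = st.obj();
    trace.push_back(cur);
  }

  IntegerVector sel;
  for (int i = 0; i < N; ++i) if (st.inS[i]) sel.push_back(i);
  return List::create(_["selected"] = sel, _["objective"] = cur,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
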