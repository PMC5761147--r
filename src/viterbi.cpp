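#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman-like, single-hit) Viterbi over a profile HMM.
//
// States: M_1..M_L, I_1..I_{L-1} (inserts between match nodes) and
// D_2..D_L (delete chain; D_1 is unreachable because local entry goes to
// match states only). Entry cost is log2(1/L) into any match state, exit
// from any match state is free, and unmatched flanking residues cancel
// against the null model (net contribution 0).
//
// codes: residue indices 0..19, or -1 for ambiguity codes (background
// emission, log-odds 0). lodds: L x 20 match-state log2-odds. ltM
// (L-1 x 3: MM MI MD), ltI (L-1 x 2: IM II), ltD (L-1 x 2: DM DD) hold
// log2 transition probabilities out of source node j (row j-1, 0-based).
//
// A large finite sentinel stands in for -Inf: IEEE infinity propagation
// in the inner loop costs an order of magnitude in throughput.
static const double NEG = -1e300;

// [[Rcpp::export]]
List viterbi_dp(IntegerVector codes, NumericMatrix lodds,
                NumericMatrix ltM, NumericMatrix ltI, NumericMatrix ltD) {
  const int n = codes.size();
  const int L = lodds.nrow();
  if (n < 1) stop("empty sequence");
  if (L < 1) stop("empty profile");
  const double entry = -std::log2((double)L);

  // transpose emissions to residue-major rows; copy transitions to flat
  // arrays (raw buffers keep the inner loop tight)
  std::vector<double> eM((size_t)20 * L);
  for (int a = 0; a < 20; ++a)
    for (int j = 0; j < L; ++j) eM[(size_t)a * L + j] = lodds(j, a);
  std::vector<double> tMM(L), tMI(L), tMD(L), tIM(L), tII(L), tDM(L), tDD(L);
  for (int j = 0; j + 1 < L; ++j) {
    tMM[j] = ltM(j, 0); tMI[j] = ltM(j, 1); tMD[j] = ltM(j, 2);
    tIM[j] = ltI(j, 0); tII[j] = ltI(j, 1);
    tDM[j] = ltD(j, 0); tDD[j] = ltD(j, 1);
  }

  std::vector<double> VMp(L + 1, NEG), VIp(L + 1, NEG), VDp(L + 1, NEG),
      VM(L + 1, NEG), VI(L + 1, NEG), VD(L + 1, NEG);
  // traceback pointers: 0 = local entry, 1 = from M, 2 = from I, 3 = from D
  std::vector<unsigned char> PM((size_t)(n + 1) * (L + 1), 0),
      PI((size_t)(n + 1) * (L + 1), 0), PD((size_t)(n + 1) * (L + 1), 0);
  auto idx = [&](int i, int j) { return (size_t)i * (L + 1) + j; };

  double best = NEG;
  int best_i = 1, best_j = 1;

  for (int i = 1; i <= n; ++i) {
    const int a = codes[i - 1];
    const double* e = (a >= 0) ? &eM[(size_t)a * L] : nullptr;
    const size_t row = (size_t)i * (L + 1);
    VM[0] = VI[0] = VD[0] = NEG;
    for (int j = 1; j <= L; ++j) {
      // delete: from M or D of the same row at node j-1 (consumes nothing)
      if (j >= 2) {
        double fM = VM[j - 1] + tMD[j - 2];
        double fD = VD[j - 1] + tDD[j - 2];
        if (fM >= fD) { VD[j] = fM; PD[row + j] = 1; }
        else          { VD[j] = fD; PD[row + j] = 3; }
      } else VD[j] = NEG;
      // match: emit residue i at node j; predecessors at (i-1, j-1)
      double v = entry;
      unsigned char ptr = 0;
      if (j >= 2) {
        double fM = VMp[j - 1] + tMM[j - 2];
        double fI = VIp[j - 1] + tIM[j - 2];
        double fD = VDp[j - 1] + tDM[j - 2];
        if (fM > v) { v = fM; ptr = 1; }
        if (fI > v) { v = fI; ptr = 2; }
        if (fD > v) { v = fD; ptr = 3; }
      }
      double m = (e ? e[j - 1] : 0.0) + v;
      VM[j] = m;
      PM[row + j] = ptr;
      if (m > best) { best = m; best_i = i; best_j = j; }
      // insert: background emission (log-odds 0); predecessors at (i-1, j)
      if (j < L) {
        double fM = VMp[j] + tMI[j - 1];
        double fI = VIp[j] + tII[j - 1];
        if (fM >= fI) { VI[j] = fM; PI[row + j] = 1; }
        else          { VI[j] = fI; PI[row + j] = 2; }
      } else VI[j] = NEG;
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
  }

  // traceback from the best match cell to the local entry
  std::string path;
  int i = best_i, j = best_j;
  int qstart = best_i, mstart = best_j;
  char state = 'M';
  while (true) {
    path.push_back(state);
    if (state == 'M') {
      unsigned char p = PM[idx(i, j)];
      qstart = i; mstart = j;
      if (p == 0) break;
      state = (p == 1) ? 'M' : (p == 2) ? 'I' : 'D';
      --i; --j;          // all M-predecessors live at (i-1, j-1)
    } else if (state == 'I') {
      state = (PI[idx(i, j)] == 1) ? 'M' : 'I';
      --i;
    } else {             // D consumes no residue
      state = (PD[idx(i, j)] == 1) ? 'M' : 'D';
      --j;
    }
  }
  std::reverse(path.begin(), path.end());

  return List::create(_["score"] = best, _["path"] = path,
                      _["qstart"] = qstart, _["qend"] = best_i,
                      _["mstart"] = mstart, _["mend"] = best_j);
}
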