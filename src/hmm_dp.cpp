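// Viterbi and Forward dynamic programming for the package's profile HMM.
//
// State graph (log2-odds space against an iid background null): a flanking
// N state with self-loop (emitting background, odds 0 per residue), local
// entry B -> M_k, per-node match/insert/delete core transitions, local exit
// M_k -> E (plus D_M -> E), and a flanking C state mirroring N. All
// parameter vectors arrive as log2 probabilities; match emissions as log2
// odds. Sequence symbols are 0-based alphabet indices; -1 marks an unknown
// residue (emission odds 0).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double l2se(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// [[Rcpp::export]]
List cpp_hmm_viterbi(NumericMatrix me, NumericVector lEntry, NumericVector lExit,
                     NumericVector lMM, NumericVector lMI, NumericVector lMD,
                     NumericVector lIM, NumericVector lII,
                     NumericVector lDM, NumericVector lDD,
                     IntegerVector seq, double lpLoop, double lpMove) {
  const int M = me.nrow();
  const int L = seq.size();
  // DP matrices, (M+1) x (L+1), index [k*(L+1)+i]
  std::vector<double> VM((M + 1) * (L + 1), NEG_INF);
  std::vector<double> VI((M + 1) * (L + 1), NEG_INF);
  std::vector<double> VD((M + 1) * (L + 1), NEG_INF);
  std::vector<signed char> tbM((M + 1) * (L + 1), -1);
  std::vector<signed char> tbI((M + 1) * (L + 1), -1);
  std::vector<signed char> tbD((M + 1) * (L + 1), -1);
  std::vector<double> VE(L + 1, NEG_INF);
  std::vector<int> tbE(L + 1, 0);  // k of best M_k -> E; 0 => from D_M

#define IDX(k, i) ((k) * (L + 1) + (i))

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    const double vb = (double)(i - 1) * lpLoop + lpMove;  // B after i-1 residues
    for (int k = 1; k <= M; ++k) {
      const double em = (a >= 0) ? me(k - 1, a) : 0.0;
      // match
      double best = vb + lEntry[k - 1];
      signed char who = 0;
      if (k > 1) {
        double v = VM[IDX(k - 1, i - 1)] + lMM[k - 2];
        if (v > best) { best = v; who = 1; }
        v = VI[IDX(k - 1, i - 1)] + lIM[k - 2];
        if (v > best) { best = v; who = 2; }
        v = VD[IDX(k - 1, i - 1)] + lDM[k - 2];
        if (v > best) { best = v; who = 3; }
      }
      VM[IDX(k, i)] = best + em;
      tbM[IDX(k, i)] = who;
      // insert (k = 1..M-1)
      if (k < M) {
        double vm = VM[IDX(k, i - 1)] + lMI[k - 1];
        double vi = VI[IDX(k, i - 1)] + lII[k - 1];
        if (vm >= vi) { VI[IDX(k, i)] = vm; tbI[IDX(k, i)] = 0; }
        else          { VI[IDX(k, i)] = vi; tbI[IDX(k, i)] = 1; }
      }
      // delete
      if (k > 1) {
        double vm = VM[IDX(k - 1, i)] + lMD[k - 2];
        double vd = VD[IDX(k - 1, i)] + lDD[k - 2];
        if (vm >= vd) { VD[IDX(k, i)] = vm; tbD[IDX(k, i)] = 0; }
        else          { VD[IDX(k, i)] = vd; tbD[IDX(k, i)] = 1; }
      }
    }
    // E at position i
    double beste = NEG_INF;
    int whoe = 0;
    for (int k = 1; k <= M; ++k) {
      double v = VM[IDX(k, i)] + lExit[k - 1];
      if (v > beste) { beste = v; whoe = k; }
    }
    if (VD[IDX(M, i)] > beste) { beste = VD[IDX(M, i)]; whoe = 0; }
    VE[i] = beste;
    tbE[i] = whoe;
  }

  // choose end position (ties toward smaller end => smaller start coordinate bias)
  double best = NEG_INF;
  int iEnd = 0;
  for (int i = 1; i <= L; ++i) {
    double v = VE[i] + (double)(L - i) * lpLoop + lpMove;
    if (v > best) { best = v; iEnd = i; }
  }

  IntegerVector matchpos(M, 0);
  int envStart = 0, envEnd = 0;
  if (iEnd > 0 && best > NEG_INF) {
    int i = iEnd;
    int k = tbE[i];
    int stateType;  // 0 = M, 2 = D
    if (k == 0) { k = M; stateType = 2; } else { stateType = 0; }
    envEnd = 0;
    bool done = false;
    while (!done) {
      if (stateType == 0) {  // in M_k at position i
        matchpos[k - 1] = i;
        if (envEnd == 0) envEnd = i;
        envStart = i;
        signed char who = tbM[IDX(k, i)];
        if (who == 0) { done = true; }
        else if (who == 1) { --k; --i; stateType = 0; }
        else if (who == 2) { --k; --i; stateType = 1; }
        else { --k; --i; stateType = 2; }
      } else if (stateType == 1) {  // in I_k at position i
        signed char who = tbI[IDX(k, i)];
        if (who == 0) { --i; stateType = 0; }
        else { --i; stateType = 1; }
      } else {  // in D_k at position i
        signed char who = tbD[IDX(k, i)];
        if (who == 0) { --k; stateType = 0; }
        else { --k; stateType = 2; }
      }
    }
  }
  return List::create(_["bits"] = best, _["env_start"] = envStart,
                      _["env_end"] = envEnd, _["matchpos"] = matchpos);
#undef IDX
}

// [[Rcpp::export]]
double cpp_hmm_forward(NumericMatrix me, NumericVector lEntry, NumericVector lExit,
                       NumericVector lMM, NumericVector lMI, NumericVector lMD,
                       NumericVector lIM, NumericVector lII,
                       NumericVector lDM, NumericVector lDD,
                       IntegerVector seq, double lpLoop, double lpMove) {
  const int M = me.nrow();
  const int L = seq.size();
  std::vector<double> FM((M + 1) * (L + 1), NEG_INF);
  std::vector<double> FI((M + 1) * (L + 1), NEG_INF);
  std::vector<double> FD((M + 1) * (L + 1), NEG_INF);
  std::vector<double> FE(L + 1, NEG_INF);

#define IDX(k, i) ((k) * (L + 1) + (i))

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    const double fb = (double)(i - 1) * lpLoop + lpMove;
    for (int k = 1; k <= M; ++k) {
      const double em = (a >= 0) ? me(k - 1, a) : 0.0;
      double s = fb + lEntry[k - 1];
      if (k > 1) {
        s = l2se(s, FM[IDX(k - 1, i - 1)] + lMM[k - 2]);
        s = l2se(s, FI[IDX(k - 1, i - 1)] + lIM[k - 2]);
        s = l2se(s, FD[IDX(k - 1, i - 1)] + lDM[k - 2]);
      }
      FM[IDX(k, i)] = s + em;
      if (k < M)
        FI[IDX(k, i)] = l2se(FM[IDX(k, i - 1)] + lMI[k - 1],
                             FI[IDX(k, i - 1)] + lII[k - 1]);
      if (k > 1)
        FD[IDX(k, i)] = l2se(FM[IDX(k - 1, i)] + lMD[k - 2],
                             FD[IDX(k - 1, i)] + lDD[k - 2]);
    }
    double s = NEG_INF;
    for (int k = 1; k <= M; ++k) s = l2se(s, FM[IDX(k, i)] + lExit[k - 1]);
    s = l2se(s, FD[IDX(M, i)]);
    FE[i] = s;
  }
  double total = NEG_INF;
  for (int i = 1; i <= L; ++i)
    total = l2se(total, FE[i] + (double)(L - i) * lpLoop + lpMove);
  return total;
#undef IDX
}
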