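#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log2-space sum of two odds
static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}

// Viterbi DP over the local profile grammar. All transition vectors are
// 1-based by source state position, passed as in the R model object:
// lmm/lmi/lmd from M_k (k=1..M-1, exit mass folded in), lim/lii from I_k,
// ldm/ldd from D_k. Emission matrix E is match log-odds (M x L); iem the
// insert log-odds per sequence position; lexit[k] the log exit prob.
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(NumericMatrix E, NumericVector iem, double lentry,
                  NumericVector lexit, NumericVector lmm, NumericVector lmi,
                  NumericVector lmd, NumericVector lim, NumericVector lii,
                  NumericVector ldm, NumericVector ldd, bool traceback) {
  const int M = E.nrow(), L = E.ncol();
  const int MI = M > 1 ? M - 1 : 1;
  IntegerMatrix PM(traceback ? M : 1, traceback ? L : 1);
  IntegerMatrix PI(traceback ? MI : 1, traceback ? L : 1);
  IntegerMatrix PD(traceback ? M : 1, traceback ? L : 1);
  std::vector<double> VM_prev(M, R_NegInf), VD_prev(M, R_NegInf),
      VI_prev(MI, R_NegInf), VM(M), VD(M), VI(MI);
  double best = R_NegInf;
  int bi = -1, bk = -1, bstate = 0;  // 0 = end from M, 1 = end from D_M
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < M; ++k) {
      double b1 = lentry;
      int p = 1;
      if (k > 0) {
        double a2 = VM_prev[k - 1] + lmm[k - 1];
        double a3 = VI_prev[k - 1] + lim[k - 1];
        double a4 = VD_prev[k - 1] + ldm[k - 1];
        if (a2 > b1) { b1 = a2; p = 2; }
        if (a3 > b1) { b1 = a3; p = 3; }
        if (a4 > b1) { b1 = a4; p = 4; }
      }
      VM[k] = E(k, i) + b1;
      if (traceback) PM(k, i) = p;
    }
    VD[0] = R_NegInf;
    for (int j = 1; j < M; ++j) {  // VD[j] is state D_{j+1}
      double fromM = VM[j - 1] + lmd[j - 1];
      double fromD = (j >= 2) ? VD[j - 1] + ldd[j - 1] : R_NegInf;
      if (fromM >= fromD) {
        VD[j] = fromM;
        if (traceback) PD(j, i) = 1;
      } else {
        VD[j] = fromD;
        if (traceback) PD(j, i) = 2;
      }
    }
    for (int k = 0; k + 1 < M; ++k) {
      double b1 = VM_prev[k] + lmi[k], b2 = VI_prev[k] + lii[k];
      if (b2 > b1) {
        VI[k] = iem[i] + b2;
        if (traceback) PI(k, i) = 2;
      } else {
        VI[k] = iem[i] + b1;
        if (traceback) PI(k, i) = 1;
      }
    }
    for (int k = 0; k < M; ++k) {
      double e = VM[k] + lexit[k];
      if (e > best) { best = e; bi = i; bk = k; bstate = 0; }
    }
    if (M > 1 && VD[M - 1] > best) {
      best = VD[M - 1]; bi = i; bk = M - 1; bstate = 1;
    }
    VM_prev = VM; VI_prev = VI; VD_prev = VD;
  }
  return List::create(_["bit_score"] = best, _["best_i"] = bi + 1,
                      _["best_k"] = bk + 1, _["best_state"] = bstate,
                      _["PM"] = PM, _["PI"] = PI, _["PD"] = PD);
}

// Forward DP: identical grammar, log-sum-exp instead of max.
// [[Rcpp::export(name = ".forward_core")]]
double forward_core(NumericMatrix E, NumericVector iem, double lentry,
                    NumericVector lexit, NumericVector lmm,
                    NumericVector lmi, NumericVector lmd, NumericVector lim,
                    NumericVector lii, NumericVector ldm,
                    NumericVector ldd) {
  const int M = E.nrow(), L = E.ncol();
  const int MI = M > 1 ? M - 1 : 1;
  std::vector<double> FM_prev(M, R_NegInf), FD_prev(M, R_NegInf),
      FI_prev(MI, R_NegInf), FM(M), FD(M), FI(MI);
  double total = R_NegInf;
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < M; ++k) {
      double s = lentry;
      if (k > 0) {
        s = lse2(s, FM_prev[k - 1] + lmm[k - 1]);
        s = lse2(s, FI_prev[k - 1] + lim[k - 1]);
        s = lse2(s, FD_prev[k - 1] + ldm[k - 1]);
      }
      FM[k] = E(k, i) + s;
    }
    FD[0] = R_NegInf;
    for (int j = 1; j < M; ++j) {
      double s = FM[j - 1] + lmd[j - 1];
      if (j >= 2) s = lse2(s, FD[j - 1] + ldd[j - 1]);
      FD[j] = s;
    }
    for (int k = 0; k + 1 < M; ++k) {
      FI[k] = iem[i] + lse2(FM_prev[k] + lmi[k], FI_prev[k] + lii[k]);
    }
    for (int k = 0; k < M; ++k) total = lse2(total, FM[k] + lexit[k]);
    if (M > 1) total = lse2(total, FD[M - 1]);
    FM_prev = FM; FI_prev = FI; FD_prev = FD;
  }
  return total;
}
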