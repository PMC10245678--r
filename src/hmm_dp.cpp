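// Forward / Viterbi dynamic programming for local profile-HMM alignment.
//
// Model: a local (Smith-Waterman style) alignment of the profile against
// the target. A path enters any match node i at any target position with
// entry probability 1/L, runs through the core M/I/D states using the
// node transitions, and exits freely (probability 1) from any match state.
// Flanking target residues are emitted by the background and cancel in the
// odds ratio, so the DP works entirely in log-odds space. Scores are
// returned in bits (log2 odds).

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double emit(const NumericMatrix& lod, int node, int sym) {
  return sym < 0 ? 0.0 : lod(node, sym);
}

// transition columns: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD

// [[Rcpp::export]]
double c_forward(NumericMatrix mlod, NumericMatrix ilod, NumericMatrix ltr,
                 IntegerVector seq) {
  const int L = mlod.nrow(), n = seq.size();
  const double lentry = -std::log((double)L);
  std::vector<double> FM(L, NEG_INF), FI(L, NEG_INF), FD(L, NEG_INF);
  std::vector<double> nM(L), nI(L), nD(L);
  double total = NEG_INF;
  for (int j = 0; j < n; ++j) {
    const int s = seq[j];
    for (int i = 0; i < L; ++i) {
      double acc = lentry;  // fresh local start
      if (i > 0) {
        acc = lse2(acc, FM[i - 1] + ltr(i - 1, 0));
        acc = lse2(acc, FI[i - 1] + ltr(i - 1, 3));
        acc = lse2(acc, FD[i - 1] + ltr(i - 1, 5));
      }
      nM[i] = emit(mlod, i, s) + acc;
      // delete: same target column, from new M/D at node i-1
      nD[i] = (i > 0)
        ? lse2(nM[i - 1] + ltr(i - 1, 2), nD[i - 1] + ltr(i - 1, 6))
        : NEG_INF;
      // insert at node i: previous column, same node
      nI[i] = emit(ilod, i, s) +
        lse2(FM[i] + ltr(i, 1), FI[i] + ltr(i, 4));
      total = lse2(total, nM[i]);  // free exit from any match
    }
    FM.swap(nM); FI.swap(nI); FD.swap(nD);
  }
  return total / M_LN2;
}

// [[Rcpp::export]]
NumericVector c_forward_batch(NumericMatrix mlod, NumericMatrix ilod,
                              NumericMatrix ltr, List seqs) {
  const int N = seqs.size();
  NumericVector out(N);
  for (int k = 0; k < N; ++k)
    out[k] = c_forward(mlod, ilod, ltr, as<IntegerVector>(seqs[k]));
  return out;
}

// [[Rcpp::export]]
List c_viterbi(NumericMatrix mlod, NumericMatrix ilod, NumericMatrix ltr,
               IntegerVector seq) {
  const int L = mlod.nrow(), n = seq.size();
  const double lentry = -std::log((double)L);
  // state codes: 0 M, 1 I, 2 D; backpointer: 0 from M, 1 from I,
  // 2 from D, 3 fresh entry
  std::vector<double> VM(L * n, NEG_INF), VI(L * n, NEG_INF),
                      VD(L * n, NEG_INF);
  std::vector<signed char> BM(L * n, 3), BI(L * n, 0), BD(L * n, 0);
  auto at = [L](int i, int j) { return j * L + i; };
  for (int j = 0; j < n; ++j) {
    const int s = seq[j];
    for (int i = 0; i < L; ++i) {
      double best = lentry; signed char bp = 3;
      if (i > 0 && j > 0) {
        // tie-break preference: M > D > I (strict > keeps earlier choice)
        double v = VM[at(i - 1, j - 1)] + ltr(i - 1, 0);
        if (v > best) { best = v; bp = 0; }
        v = VD[at(i - 1, j - 1)] + ltr(i - 1, 5);
        if (v > best) { best = v; bp = 2; }
        v = VI[at(i - 1, j - 1)] + ltr(i - 1, 3);
        if (v > best) { best = v; bp = 1; }
      }
      VM[at(i, j)] = emit(mlod, i, s) + best;
      BM[at(i, j)] = bp;
      if (i > 0) {
        double vm = VM[at(i - 1, j)] + ltr(i - 1, 2);
        double vd = VD[at(i - 1, j)] + ltr(i - 1, 6);
        if (vm >= vd) { VD[at(i, j)] = vm; BD[at(i, j)] = 0; }
        else          { VD[at(i, j)] = vd; BD[at(i, j)] = 2; }
      }
      if (j > 0) {
        double vm = VM[at(i, j - 1)] + ltr(i, 1);
        double vi = VI[at(i, j - 1)] + ltr(i, 4);
        double e = emit(ilod, i, s);
        if (vm >= vi) { VI[at(i, j)] = e + vm; BI[at(i, j)] = 0; }
        else          { VI[at(i, j)] = e + vi; BI[at(i, j)] = 1; }
      }
    }
  }
  // best exit over all match cells
  double best = NEG_INF; int bi = -1, bj = -1;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < L; ++i)
      if (VM[at(i, j)] > best) { best = VM[at(i, j)]; bi = i; bj = j; }
  if (bi < 0) return List::create(_["bits"] = NEG_INF / M_LN2,
                                  _["path"] = IntegerMatrix(0, 3));
  // traceback
  std::vector<int> nodes, poss, states;
  int i = bi, j = bj, st = 0;  // start at a match state
  while (true) {
    nodes.push_back(i + 1);
    poss.push_back(st == 2 ? NA_INTEGER : j + 1);
    states.push_back(st + 1);
    signed char bp;
    if (st == 0) bp = BM[at(i, j)];
    else if (st == 1) bp = BI[at(i, j)];
    else bp = BD[at(i, j)];
    if (st == 0) {
      if (bp == 3) break;
      --i; --j; st = bp;
    } else if (st == 1) {
      --j; st = bp;
    } else {
      --i; st = bp;
    }
  }
  const int m = nodes.size();
  IntegerMatrix path(m, 3);
  for (int k = 0; k < m; ++k) {
    path(k, 0) = nodes[m - 1 - k];
    path(k, 1) = poss[m - 1 - k];
    path(k, 2) = states[m - 1 - k];
  }
  colnames(path) = CharacterVector::create("node", "pos", "state");
  return List::create(_["bits"] = best / M_LN2, _["path"] = path);
}
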