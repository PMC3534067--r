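#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Stacking-weighted secondary-structure DP.
// Allowed pairs: A-U(T), G-C, G-U(T); hairpin loops >= 3 unpaired bases.
// A pair whose inner neighbour (i+1, j-1) is also a pair scores its stack
// weight (GC 3, AU 2, GU 1); an unstacked pair scores 1. The reported energy
// is the negated optimum, so more negative = more stable.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

static const int NEG = -1000000;
static const int MINLOOP = 3;  // unpaired bases enclosed by a pair

// [[Rcpp::export]]
List fold_dp_cpp(std::string seq) {
  int n = (int) seq.size();
  std::vector<int> W((size_t) n * n, 0), Q((size_t) n * n, 0),
      P((size_t) n * n, NEG);
  // W[i][j]: best score on [i,j]; P: best given (i,j) paired together;
  // Q: best given (i,j) not paired together.
  auto id = [n](int i, int j) { return (size_t) i * n + j; };

  for (int span = MINLOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pc = pair_weight(seq[i], seq[j]);
      if (pc > 0) {
        int best = NEG;
        if (j - 1 - (i + 1) > MINLOOP &&
            pair_weight(seq[i + 1], seq[j - 1]) > 0 &&
            P[id(i + 1, j - 1)] > NEG / 2)
          best = std::max(best, pc + P[id(i + 1, j - 1)]);
        int q_in = (j - 1 > i + 1) ? Q[id(i + 1, j - 1)] : 0;
        best = std::max(best, 1 + q_in);
        P[id(i, j)] = best;
      }
      int best = W[id(i, j - 1)];  // j unpaired
      for (int k = i + 1; k + MINLOOP + 1 <= j; ++k) {
        if (pair_weight(seq[k], seq[j]) > 0 && P[id(k, j)] > NEG / 2) {
          int left = (k - 1 >= i) ? W[id(i, k - 1)] : 0;
          best = std::max(best, left + P[id(k, j)]);
        }
      }
      Q[id(i, j)] = best;
      W[id(i, j)] = std::max(best, P[id(i, j)]);
    }
  }

  // Traceback, deterministic: prefer the outermost pair (P over Q), prefer
  // stacking, and prefer the 5'-most split point.
  IntegerVector pairs(n, 0);
  std::vector<std::array<int, 3>> stack;  // {i, j, mode}: 0 = W, 1 = Q, 2 = P
  if (n > MINLOOP + 1) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto it = stack.back();
    stack.pop_back();
    int i = it[0], j = it[1], mode = it[2];
    if (j - i <= MINLOOP) continue;
    if (mode == 0) {
      if (P[id(i, j)] > NEG / 2 && P[id(i, j)] >= Q[id(i, j)])
        stack.push_back({i, j, 2});
      else
        stack.push_back({i, j, 1});
    } else if (mode == 2) {
      pairs[i] = j + 1;  // 1-based partners
      pairs[j] = i + 1;
      int pc = pair_weight(seq[i], seq[j]);
      bool stacked = false;
      if (j - 1 - (i + 1) > MINLOOP &&
          pair_weight(seq[i + 1], seq[j - 1]) > 0 &&
          P[id(i + 1, j - 1)] > NEG / 2 &&
          pc + P[id(i + 1, j - 1)] == P[id(i, j)]) {
        stack.push_back({i + 1, j - 1, 2});
        stacked = true;
      }
      if (!stacked && j - 1 > i + 1) stack.push_back({i + 1, j - 1, 1});
    } else {
      int target = Q[id(i, j)];
      bool done = false;
      for (int k = i + 1; k + MINLOOP + 1 <= j && !done; ++k) {
        if (pair_weight(seq[k], seq[j]) > 0 && P[id(k, j)] > NEG / 2) {
          int left = (k - 1 >= i) ? W[id(i, k - 1)] : 0;
          if (left + P[id(k, j)] == target) {
            stack.push_back({k, j, 2});
            if (k - 1 > i) stack.push_back({i, k - 1, 0});
            done = true;
          }
        }
      }
      if (!done) stack.push_back({i, j - 1, 0});
    }
  }

  int score = (n > MINLOOP + 1) ? W[id(0, n - 1)] : 0;
  return List::create(_["score"] = score, _["pairs"] = pairs);
}

// Hamming mismatch counts of a pattern at every start position of a subject
// (used by the genome-scan oracle and the trigger/TE matchers for speed).
// [[Rcpp::export]]
IntegerVector mismatch_profile_cpp(std::string subject, std::string pattern) {
  int n = (int) subject.size(), m = (int) pattern.size();
  if (m > n) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int k = 0; k < m; ++k) mm += subject[i + k] != pattern[k];
    out[i] = mm;
  }
  return out;
}
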