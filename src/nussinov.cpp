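#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum base-pair-count folding (Nussinov DP) over the DNA-encoded
// alphabet; allowed pairs are Watson-Crick plus the G:U wobble
// (internally G:T). Loop constraint: a pair (i,j) requires j - i - 1 >=
// min_loop unpaired-or-nested bases between them. Traceback is
// deterministic: at interval [i,j] the leftmost base i is paired with the
// smallest admissible j', else left unpaired.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false; // N never pairs
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq, int min_loop) {
  int n = seq.size();
  // M[i][j], 0-based, j >= i
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1 + (k > i ? M[i][k - 1] : 0) +
                    (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // deterministic traceback: pair leftmost i with smallest valid j'
  std::vector<int> partner(n, -1);
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    int target = M[i][j];
    if (target == 0) continue;
    bool paired = false;
    for (int jp = i + min_loop + 1; jp <= j; ++jp) {
      if (!can_pair(seq[i], seq[jp])) continue;
      int inner = (i + 1 <= jp - 1) ? M[i + 1][jp - 1] : 0;
      int right = (jp + 1 <= j) ? M[jp + 1][j] : 0;
      if (1 + inner + right == target) {
        partner[i] = jp;
        partner[jp] = i;
        stack.push_back(std::make_pair(i + 1, jp - 1));
        stack.push_back(std::make_pair(jp + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  std::string db(n, '.');
  int npairs = 0;
  Rcpp::IntegerVector pi, pj;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      db[i] = '(';
      db[partner[i]] = ')';
      pi.push_back(i);
      pj.push_back(partner[i]);
      ++npairs;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("dotbracket") = db,
    Rcpp::Named("pair_i") = pi,
    Rcpp::Named("pair_j") = pj,
    Rcpp::Named("n_pairs") = npairs,
    Rcpp::Named("max_pairs") = n > 0 ? M[0][n - 1] : 0);
}
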