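#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Per-pair energies (kcal/mol) of the simple folding model:
// GC/CG -3, AU/UA -2, GU/UG -1; anything else cannot pair.
// Integer energies keep all DP comparisons exact.
static inline int pair_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1;
  return 1; // sentinel: not pairable
}

// Minimum-energy non-crossing pairing with hairpin loops >= 3 nt.
// E(i,j) = min( E(i+1,j),
//               min_k { e(i,k) + E(i+1,k-1) + E(k+1,j) : k >= i+4 } )
// Traceback prefers pairing the 5'-most position, then the LARGEST
// admissible partner (outermost helix first), which yields a canonical
// optimal structure deterministically and favors extended stems over
// equally-scoring fragmented pairings.
// [[Rcpp::export]]
List fold_dp(std::string seq) {
  const int n = (int)seq.size();
  const int MINLOOP = 3;
  if (n == 0) stop("empty sequence");
  std::vector<int> E((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return E[(size_t)i * n + j]; };

  for (int span = MINLOOP + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int best = at(i + 1, j); // i unpaired (i+1 <= j always here)
      for (int k = i + MINLOOP + 1; k <= j; ++k) {
        int e = pair_e(seq[i], seq[k]);
        if (e > 0) continue;
        int inner = (k - 1 >= i + 1) ? at(i + 1, k - 1) : 0;
        int outer = (k + 1 <= j) ? at(k + 1, j) : 0;
        int cand = e + inner + outer;
        if (cand < best) best = cand;
      }
      at(i, j) = best;
    }
  }

  IntegerVector partner(n, 0); // 1-based partner, 0 = unpaired
  std::vector<std::pair<int,int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    while (i < j && j - i >= MINLOOP + 1) {
      int target = at(i, j);
      bool paired = false;
      for (int k = j; k >= i + MINLOOP + 1; --k) {
        int e = pair_e(seq[i], seq[k]);
        if (e > 0) continue;
        int inner = (k - 1 >= i + 1) ? at(i + 1, k - 1) : 0;
        int outer = (k + 1 <= j) ? at(k + 1, j) : 0;
        if (e + inner + outer == target) {
          partner[i] = k + 1;
          partner[k] = i + 1;
          if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
          i = i + 1; j = k - 1; // descend into the enclosed region
          paired = true;
          break;
        }
      }
      if (!paired) i = i + 1; // i stays unpaired at the optimum
    }
  }

  int energy = (n >= MINLOOP + 2) ? at(0, n - 1) : 0;
  return List::create(_["energy"] = (double)energy, _["partner"] = partner);
}
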