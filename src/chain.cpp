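#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symbols are coded 1=U, 2=H, 3=I, 4=D throughout.
//
// One step of the four-move chain. RNG draw order is fixed: move type, then
// the index (or index pair) for that move, then one uniform consumed as the
// Bernoulli. When m == 1 and the move type is 1 or 4 the index range
// randInt(1, m-1) is empty; the step is an automatic no-op and consumes no
// further draws.

static inline bool is_ud(int s) { return s == 1 || s == 4; }

static bool valid_path(const std::vector<int>& x) {
  int h = 0;
  for (size_t k = 0; k < x.size(); ++k) {
    if (x[k] == 1) ++h;
    else if (x[k] == 4) { if (--h < 0) return false; }
  }
  return h == 0;
}

struct MoveProbs {
  double ud_hh, hh_ud, i_h, h_i;
};

static MoveProbs move_probs(double alpha, double beta) {
  MoveProbs p;
  p.ud_hh = 0.5 / (1.0 + std::exp(alpha));         // e^-a / (2(1+e^-a))
  p.hh_ud = 0.5 / (1.0 + std::exp(-alpha));        // 1 / (2(1+e^-a))
  p.i_h   = 0.5 / (1.0 + std::exp(alpha - beta));  // e^-a / (2(e^-a+e^-b))
  p.h_i   = 0.5 / (1.0 + std::exp(beta - alpha));  // e^-b / (2(e^-a+e^-b))
  return p;
}

static inline int rand_index(int n) {   // uniform on 0..n-1
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// Returns the move type drawn (1..4); *changed reports whether the state
// moved.
static int do_step(std::vector<int>& x, int m, const MoveProbs& p,
                   bool* changed) {
  *changed = false;
  int l = 1 + rand_index(4);
  if (l == 1) {
    if (m >= 2) {
      int i = rand_index(m - 1);
      double b = unif_rand();
      if (x[i] == 1 && x[i + 1] == 4) {
        if (b < p.ud_hh) { x[i] = 2; x[i + 1] = 2; *changed = true; }
      } else if (x[i] == 2 && x[i + 1] == 2) {
        if (b < p.hh_ud) { x[i] = 1; x[i + 1] = 4; *changed = true; }
      }
    }
  } else if (l == 2) {
    int i = rand_index(m);
    double b = unif_rand();
    if (x[i] == 3) {
      if (b < p.i_h) { x[i] = 2; *changed = true; }
    } else if (x[i] == 2) {
      if (b < p.h_i) { x[i] = 3; *changed = true; }
    }
  } else if (l == 3) {
    int i = rand_index(m);
    int j = rand_index(m);
    double b = unif_rand();
    if (is_ud(x[i]) && is_ud(x[j]) && b < 0.5) {
      if (i != j && x[i] != x[j]) {
        std::swap(x[i], x[j]);
        if (!valid_path(x)) std::swap(x[i], x[j]);  // revert invalid swap
        else *changed = true;
      }
      // i == j or equal symbols: identity move, stays on the diagonal
    }
  } else {
    if (m >= 2) {
      int i = rand_index(m - 1);
      double b = unif_rand();
      bool a_ud = is_ud(x[i]), b_ud = is_ud(x[i + 1]);
      if ((a_ud != b_ud) && b < 0.5) {  // one of {U,D} next to one of {H,I}
        std::swap(x[i], x[i + 1]);      // colour-crossing swap stays valid
        *changed = true;
      }
    }
  }
  return l;
}

// Run the chain for `steps` steps from x0, keeping every `thin`-th state
// after `burn_in`. Returns the kept states (rows), per-move-type attempt and
// acceptance tallies, and the final state.
// [[Rcpp::export]]
List cpp_run_chain(IntegerVector x0, double alpha, double beta,
                   double steps, double burn_in, double thin) {
  int m = x0.size();
  std::vector<int> x(x0.begin(), x0.end());
  MoveProbs p = move_probs(alpha, beta);
  long long S = (long long)steps, B = (long long)burn_in, T = (long long)thin;
  long long n_keep = (S - B) / T;
  IntegerMatrix kept(n_keep > 0 ? (int)n_keep : 0, m);
  IntegerVector attempts(4), accepted(4);
  long long k = 0;
  bool changed;
  for (long long t = 1; t <= S; ++t) {
    int l = do_step(x, m, p, &changed);
    attempts[l - 1]++;
    if (changed) accepted[l - 1]++;
    if (t > B && (t - B) % T == 0 && k < n_keep) {
      for (int c = 0; c < m; ++c) kept((int)k, c) = x[c];
      ++k;
    }
  }
  return List::create(_["kept"] = kept,
                      _["attempts"] = attempts,
                      _["accepted"] = accepted,
                      _["final"] = IntegerVector(x.begin(), x.end()));
}

// `trials` independent single steps from x0; row t is the state after one
// step. Used to compare empirical one-step frequencies with the exact
// transition matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_single_steps(IntegerVector x0, double alpha, double beta,
                               int trials) {
  int m = x0.size();
  MoveProbs p = move_probs(alpha, beta);
  IntegerMatrix out(trials, m);
  std::vector<int> x(m);
  bool changed;
  for (int t = 0; t < trials; ++t) {
    std::copy(x0.begin(), x0.end(), x.begin());
    do_step(x, m, p, &changed);
    for (int c = 0; c < m; ++c) out(t, c) = x[c];
  }
  return out;
}

// Long validity fuzz: run `steps` steps, checking the path invariant after
// every step without storing states. Returns the number of invalid states
// observed (always 0 if the moves are implemented correctly).
// [[Rcpp::export]]
double cpp_fuzz_chain(IntegerVector x0, double alpha, double beta,
                      double steps) {
  int m = x0.size();
  std::vector<int> x(x0.begin(), x0.end());
  MoveProbs p = move_probs(alpha, beta);
  long long S = (long long)steps;
  long long bad = 0;
  bool changed;
  for (long long t = 0; t < S; ++t) {
    do_step(x, m, p, &changed);
    if (changed && !valid_path(x)) ++bad;
  }
  return (double)bad;
}
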