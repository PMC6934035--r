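#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Weighted pool-adjacent-violators for a nondecreasing fit.
// Blocks store weighted sums so the SSE can be recovered without
// expanding the fit: SSE = sum(w v^2) - sum_blocks (sum(wv))^2 / sum(w).

namespace {

struct PavaWork {
  std::vector<double> W, S;  // block weight, block weighted sum
  std::vector<int> len;
};

// Returns SSE; if fitted != nullptr also expands the block means.
double pava_core(const double* v, const double* w, int n, PavaWork& wk,
                 std::vector<double>* fitted) {
  wk.W.resize(n); wk.S.resize(n); wk.len.resize(n);
  int nb = 0;
  double sumwv2 = 0.0;
  for (int i = 0; i < n; ++i) {
    sumwv2 += w[i] * v[i] * v[i];
    wk.W[nb] = w[i]; wk.S[nb] = w[i] * v[i]; wk.len[nb] = 1; ++nb;
    while (nb > 1 &&
           wk.S[nb - 2] * wk.W[nb - 1] > wk.S[nb - 1] * wk.W[nb - 2]) {
      // previous block mean exceeds current: pool
      wk.W[nb - 2] += wk.W[nb - 1];
      wk.S[nb - 2] += wk.S[nb - 1];
      wk.len[nb - 2] += wk.len[nb - 1];
      --nb;
    }
  }
  double fitsq = 0.0;
  for (int b = 0; b < nb; ++b) fitsq += wk.S[b] * wk.S[b] / wk.W[b];
  if (fitted) {
    fitted->resize(n);
    int pos = 0;
    for (int b = 0; b < nb; ++b) {
      double mu = wk.S[b] / wk.W[b];
      for (int k = 0; k < wk.len[b]; ++k) (*fitted)[pos++] = mu;
    }
  }
  double sse = sumwv2 - fitsq;
  return sse > 0.0 ? sse : 0.0;
}

// Joint lack of fit of both variables under one order of the units.
double order_sse(const std::vector<double>& x, const std::vector<double>& y,
                 const std::vector<double>& wx, const std::vector<double>& wy,
                 const std::vector<int>& ord, PavaWork& wk,
                 std::vector<double>& bx, std::vector<double>& by,
                 std::vector<double>& bwx, std::vector<double>& bwy) {
  int n = (int)ord.size();
  for (int i = 0; i < n; ++i) {
    bx[i] = x[ord[i]]; bwx[i] = wx[ord[i]];
    by[i] = y[ord[i]]; bwy[i] = wy[ord[i]];
  }
  return pava_core(bx.data(), bwx.data(), n, wk, nullptr) +
         pava_core(by.data(), bwy.data(), n, wk, nullptr);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List pava_cpp(Rcpp::NumericVector values, Rcpp::NumericVector weights) {
  int n = values.size();
  PavaWork wk;
  std::vector<double> fitted;
  double sse = pava_core(values.begin(), weights.begin(), n, wk, &fitted);
  return Rcpp::List::create(Rcpp::Named("fitted") = Rcpp::wrap(fitted),
                            Rcpp::Named("sse") = sse);
}

// Exhaustive minimisation of the coupled lack of fit over all unit orders.
// Permutations are visited in lexicographic order and ties keep the first
// optimum, so the reported order is the lexicographically smallest.
// [[Rcpp::export]]
Rcpp::List cmr_exact_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
                         Rcpp::NumericVector wx, Rcpp::NumericVector wy) {
  int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<double> vwx(wx.begin(), wx.end()), vwy(wy.begin(), wy.end());
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  PavaWork wk;
  std::vector<double> bx(n), by(n), bwx(n), bwy(n);
  std::vector<int> best = perm;
  double best_sse = R_PosInf;
  do {
    double s = order_sse(vx, vy, vwx, vwy, perm, wk, bx, by, bwx, bwy);
    if (s < best_sse - 0.0) {  // strict: first optimum wins ties
      best_sse = s;
      best = perm;
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  Rcpp::IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = best[i] + 1;
  return Rcpp::List::create(Rcpp::Named("order") = ord,
                            Rcpp::Named("sse") = best_sse);
}

namespace {

// First-improvement local search: cheap sweeps of adjacent transpositions
// until none improves, then a scan of single-element insertions; an
// accepted insertion returns control to the swap sweeps. Terminates when
// neither move type improves (or the fit reaches 0, a global optimum).
double local_search(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& wx,
                    const std::vector<double>& wy, std::vector<int>& ord,
                    PavaWork& wk, std::vector<double>& bx,
                    std::vector<double>& by, std::vector<double>& bwx,
                    std::vector<double>& bwy, int* iters) {
  int n = (int)ord.size();
  double cur = order_sse(x, y, wx, wy, ord, wk, bx, by, bwx, bwy);
  std::vector<int> cand(n);
  bool outer = true;
  while (outer && cur > 1e-15) {
    outer = false;
    bool sw = true;
    while (sw && cur > 1e-15) {
      sw = false;
      for (int i = 0; i + 1 < n; ++i) {
        std::swap(ord[i], ord[i + 1]);
        double s = order_sse(x, y, wx, wy, ord, wk, bx, by, bwx, bwy);
        if (s < cur - 1e-12) {
          cur = s;
          sw = true;
        } else {
          std::swap(ord[i], ord[i + 1]);
        }
      }
      ++(*iters);
    }
    for (int i = 0; i < n && !outer && cur > 1e-15; ++i) {
      for (int j = 0; j < n; ++j) {
        if (j == i || j == i - 1) continue;
        // move element i to position j (positions in the reduced sequence)
        int pos = 0;
        for (int k = 0; k < n; ++k) {
          if (k == i) continue;
          if (pos == j) cand[pos++] = ord[i];
          cand[pos++] = ord[k];
        }
        if (pos < n) cand[pos++] = ord[i];
        double s = order_sse(x, y, wx, wy, cand, wk, bx, by, bwx, bwy);
        if (s < cur - 1e-12) {
          ord = cand;
          cur = s;
          outer = true;
          break;
        }
      }
    }
  }
  return cur;
}

}  // namespace

// Multi-start local search. `starts` holds deterministic start orders
// (1-based, one per row); `n_random` extra starts are drawn with R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::List cmr_heuristic_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y,
                             Rcpp::NumericVector wx, Rcpp::NumericVector wy,
                             Rcpp::IntegerMatrix starts, int n_random) {
  int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  std::vector<double> vwx(wx.begin(), wx.end()), vwy(wy.begin(), wy.end());
  PavaWork wk;
  std::vector<double> bx(n), by(n), bwx(n), bwy(n);
  std::vector<int> ord(n), best_ord(n);
  double best_sse = R_PosInf;
  int iters = 0, n_starts = 0;
  Rcpp::RNGScope rng;

  auto run_start = [&](std::vector<int>& o) {
    double s = local_search(vx, vy, vwx, vwy, o, wk, bx, by, bwx, bwy, &iters);
    ++n_starts;
    if (s < best_sse) { best_sse = s; best_ord = o; }
  };

  for (int r = 0; r < starts.nrow(); ++r) {
    for (int i = 0; i < n; ++i) ord[i] = starts(r, i) - 1;
    run_start(ord);
    if (best_sse <= 1e-15) break;
  }
  for (int r = 0; r < n_random && best_sse > 1e-15; ++r) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates with R uniforms
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    run_start(ord);
  }
  Rcpp::IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_ord[i] + 1;
  return Rcpp::List::create(
      Rcpp::Named("order") = out, Rcpp::Named("sse") = best_sse,
      Rcpp::Named("n_starts") = n_starts, Rcpp::Named("iterations") = iters);
}
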