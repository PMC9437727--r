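#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy secondary structure by Zuker-style dynamic programming
// under a nearest-neighbour model: stacking energies for Watson-Crick and G:U
// pairs, length-dependent hairpin/bulge/internal-loop initiations with
// Jacobson-Stockmayer extrapolation, internal-loop asymmetry, and an affine
// multiloop term. No dangles, no coaxial stacking, no pseudoknots.
//
// All energies are handled as integer decacalories (kcal/mol * 100) so that
// the traceback and any independent re-scoring of the returned structure are
// exact, with no floating-point equality hazards.

static const int INF_E = 1000000000;
static const int MIN_HAIRPIN = 3;

// base encoding: A=0, C=1, G=2, U=3
// pair types (0 = non-pair): 1=CG 2=GC 3=GU 4=UG 5=AU 6=UA
static const int REV_PT[7] = {0, 2, 1, 4, 3, 6, 5};

static int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

struct EnergyModel {
  int stack[7][7];        // [pt(i,j)][pt(l,k)], 1-based pair types
  std::vector<int> hairpin; // index = loop size, sizes 0..30 (0..2 unused)
  std::vector<int> bulge;   // index = loop size, 1..30
  std::vector<int> internal_; // index = total size, 2..30
  int asym_per_nt;
  int asym_max;
  int ml_init;
  int ml_branch;
  int ml_unpaired;
  double lxc;             // extrapolation coefficient, decacal
  int maxloop;

  int hairpin_e(int size) const {
    if (size < MIN_HAIRPIN) return INF_E;
    if (size <= 30) return hairpin[size];
    return hairpin[30] + (int)std::floor(lxc * std::log((double)size / 30.0) + 0.5);
  }
  int bulge_e(int size) const {
    if (size < 1) return INF_E;
    if (size <= 30) return bulge[size];
    return bulge[30] + (int)std::floor(lxc * std::log((double)size / 30.0) + 0.5);
  }
  int internal_e(int n1, int n2) const {
    int size = n1 + n2;
    int init;
    if (size <= 30) init = internal_[size];
    else init = internal_[30] + (int)std::floor(lxc * std::log((double)size / 30.0) + 0.5);
    int asym = asym_per_nt * std::abs(n1 - n2);
    if (asym > asym_max) asym = asym_max;
    return init + asym;
  }
  // two-loop (stack / bulge / internal) energy for outer pair (i,j),
  // inner pair (k,l); pt_out = pt(i,j), pt_in_rev = pt(l,k)
  int loop_e(int n1, int n2, int pt_out, int pt_in_rev) const {
    if (n1 == 0 && n2 == 0) return stack[pt_out][pt_in_rev];
    if (n1 == 0 || n2 == 0) return bulge_e(n1 + n2);
    return internal_e(n1, n2);
  }
};

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> x(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': x[i] = 0; break;
      case 'C': x[i] = 1; break;
      case 'G': x[i] = 2; break;
      case 'U': x[i] = 3; break;
      default: stop("fold: sequence must contain only A/C/G/U after conversion");
    }
  }
  return x;
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq,
                  IntegerMatrix stack_dcal,
                  IntegerVector hairpin_dcal,
                  IntegerVector bulge_dcal,
                  IntegerVector internal_dcal,
                  int asym_per_nt_dcal,
                  int asym_max_dcal,
                  int ml_init_dcal,
                  int ml_branch_dcal,
                  int ml_unpaired_dcal,
                  double lxc_dcal,
                  int maxloop) {
  const int n = (int)seq.size();
  std::vector<int> x = encode_seq(seq);

  EnergyModel em;
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      em.stack[a][b] = stack_dcal(a - 1, b - 1);
  em.hairpin.assign(31, INF_E);
  em.bulge.assign(31, INF_E);
  em.internal_.assign(31, INF_E);
  for (int s = 0; s <= 30 && s < hairpin_dcal.size(); ++s) em.hairpin[s] = hairpin_dcal[s];
  for (int s = 0; s <= 30 && s < bulge_dcal.size(); ++s) em.bulge[s] = bulge_dcal[s];
  for (int s = 0; s <= 30 && s < internal_dcal.size(); ++s) em.internal_[s] = internal_dcal[s];
  em.asym_per_nt = asym_per_nt_dcal;
  em.asym_max = asym_max_dcal;
  em.ml_init = ml_init_dcal;
  em.ml_branch = ml_branch_dcal;
  em.ml_unpaired = ml_unpaired_dcal;
  em.lxc = lxc_dcal;
  em.maxloop = maxloop;

  // pair type table
  std::vector<std::vector<int>> pt(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pt[i][j] = pair_type(x[i], x[j]);

  auto idx = [n](int i, int j) { return (size_t)i * n + j; };
  std::vector<int> V((size_t)n * n, INF_E);
  std::vector<int> WM((size_t)n * n, INF_E);
  std::vector<int> WM1((size_t)n * n, INF_E);
  std::vector<int> WM2((size_t)n * n, INF_E);

  auto addE = [](int a, int b) -> int {
    if (a >= INF_E || b >= INF_E) return INF_E;
    return a + b;
  };

  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;

      // ---- V(i,j): i pairs j ----
      if (pt[i][j] > 0) {
        int best = em.hairpin_e(j - i - 1);
        // interior loops / stacks / bulges
        int kmax = std::min(i + 1 + em.maxloop, j - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          const int n1 = k - i - 1;
          int lmin = k + MIN_HAIRPIN + 1;
          int lmin2 = j - 1 - (em.maxloop - n1);
          if (lmin2 > lmin) lmin = lmin2;
          for (int l = j - 1; l >= lmin; --l) {
            if (V[idx(k, l)] >= INF_E) continue;
            const int n2 = j - l - 1;
            int e = addE(em.loop_e(n1, n2, pt[i][j], REV_PT[pt[k][l]]),
                         V[idx(k, l)]);
            if (e < best) best = e;
          }
        }
        // multiloop closed by (i,j)
        if (WM2[idx(i + 1, j - 1)] < INF_E) {
          int e = em.ml_init + em.ml_branch + WM2[idx(i + 1, j - 1)];
          if (e < best) best = e;
        }
        V[idx(i, j)] = best;
      }

      // ---- WM1(i,j): one branch whose helix starts at i ----
      {
        int best = INF_E;
        if (j - 1 > i && WM1[idx(i, j - 1)] < INF_E)
          best = WM1[idx(i, j - 1)] + em.ml_unpaired;
        if (V[idx(i, j)] < INF_E) {
          int e = V[idx(i, j)] + em.ml_branch;
          if (e < best) best = e;
        }
        WM1[idx(i, j)] = best;
      }

      // ---- WM(i,j): >= 1 branch ----
      {
        int best = WM1[idx(i, j)];
        if (i + 1 < j && WM[idx(i + 1, j)] < INF_E) {
          int e = WM[idx(i + 1, j)] + em.ml_unpaired;
          if (e < best) best = e;
        }
        for (int k = i + 1; k < j; ++k) {
          if (WM[idx(i, k - 1)] >= INF_E || WM1[idx(k, j)] >= INF_E) continue;
          int e = WM[idx(i, k - 1)] + WM1[idx(k, j)];
          if (e < best) best = e;
        }
        WM[idx(i, j)] = best;
      }

      // ---- WM2(i,j): >= 2 branches ----
      {
        int best = INF_E;
        for (int k = i + 1; k < j; ++k) {
          if (WM[idx(i, k - 1)] >= INF_E || WM1[idx(k, j)] >= INF_E) continue;
          int e = WM[idx(i, k - 1)] + WM1[idx(k, j)];
          if (e < best) best = e;
        }
        WM2[idx(i, j)] = best;
      }
    }
  }

  // ---- exterior loop ----
  std::vector<int> W(n + 1, 0);
  for (int j = 1; j <= n; ++j) {
    int best = W[j - 1];
    for (int i = 1; i <= j - MIN_HAIRPIN - 1; ++i) {
      int v = V[idx(i - 1, j - 1)];
      if (v >= INF_E) continue;
      int e = W[i - 1] + v;
      if (e < best) best = e;
    }
    W[j] = best;
  }
  const int mfe_dcal = W[n];

  // ---- traceback (deterministic: cases probed in fixed order,
  //      pairs preferred at the leftmost opening position) ----
  std::string db(n, '.');
  struct Seg { int i, j, type; }; // type: 0=V, 1=WM, 2=WM2, 3=WM1
  std::vector<Seg> stackv;

  {
    int j = n;
    while (j > 0) {
      if (W[j] == W[j - 1]) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j - MIN_HAIRPIN - 1 && !found; ++i) {
        int v = V[idx(i - 1, j - 1)];
        if (v < INF_E && W[i - 1] + v == W[j]) {
          stackv.push_back({i - 1, j - 1, 0});
          j = i - 1;
          found = true;
        }
      }
      if (!found) stop("fold: traceback failure in exterior loop");
    }
  }

  while (!stackv.empty()) {
    Seg s = stackv.back();
    stackv.pop_back();
    int i = s.i, j = s.j;

    if (s.type == 0) { // V
      db[i] = '(';
      db[j] = ')';
      const int target = V[idx(i, j)];
      if (target == em.hairpin_e(j - i - 1)) continue;
      bool found = false;
      int kmax = std::min(i + 1 + em.maxloop, j - 2);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        const int n1 = k - i - 1;
        int lmin = k + MIN_HAIRPIN + 1;
        int lmin2 = j - 1 - (em.maxloop - n1);
        if (lmin2 > lmin) lmin = lmin2;
        for (int l = j - 1; l >= lmin && !found; --l) {
          if (V[idx(k, l)] >= INF_E) continue;
          const int n2 = j - l - 1;
          if (addE(em.loop_e(n1, n2, pt[i][j], REV_PT[pt[k][l]]), V[idx(k, l)]) == target) {
            stackv.push_back({k, l, 0});
            found = true;
          }
        }
      }
      if (found) continue;
      if (WM2[idx(i + 1, j - 1)] < INF_E &&
          em.ml_init + em.ml_branch + WM2[idx(i + 1, j - 1)] == target) {
        stackv.push_back({i + 1, j - 1, 2});
        continue;
      }
      stop("fold: traceback failure in paired state");
    }

    if (s.type == 3) { // WM1 = min over l of V(i,l) + ml_branch + unpaired tail
      const int target = WM1[idx(i, j)];
      bool found = false;
      for (int l = j; l > i && !found; --l) {
        if (V[idx(i, l)] < INF_E &&
            V[idx(i, l)] + em.ml_branch + em.ml_unpaired * (j - l) == target) {
          stackv.push_back({i, l, 0});
          found = true;
        }
      }
      if (!found) stop("fold: traceback failure in WM1");
      continue;
    }

    if (s.type == 1) { // WM
      const int target = WM[idx(i, j)];
      if (WM1[idx(i, j)] == target) {
        stackv.push_back({i, j, 3});
        continue;
      }
      if (i + 1 < j && WM[idx(i + 1, j)] < INF_E &&
          WM[idx(i + 1, j)] + em.ml_unpaired == target) {
        stackv.push_back({i + 1, j, 1});
        continue;
      }
      bool found = false;
      for (int k = i + 1; k < j && !found; ++k) {
        if (WM[idx(i, k - 1)] >= INF_E || WM1[idx(k, j)] >= INF_E) continue;
        if (WM[idx(i, k - 1)] + WM1[idx(k, j)] == target) {
          stackv.push_back({i, k - 1, 1});
          stackv.push_back({k, j, 3});
          found = true;
        }
      }
      if (!found) stop("fold: traceback failure in WM");
      continue;
    }

    if (s.type == 2) { // WM2
      const int target = WM2[idx(i, j)];
      bool found = false;
      for (int k = i + 1; k < j && !found; ++k) {
        if (WM[idx(i, k - 1)] >= INF_E || WM1[idx(k, j)] >= INF_E) continue;
        if (WM[idx(i, k - 1)] + WM1[idx(k, j)] == target) {
          stackv.push_back({i, k - 1, 1});
          stackv.push_back({k, j, 3});
          found = true;
        }
      }
      if (!found) stop("fold: traceback failure in WM2");
      continue;
    }
  }

  return List::create(_["structure"] = db,
                      _["mfe_dcal"] = mfe_dcal);
}
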