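#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Contact-map alignment engine.
//
// A mapping is a strictly increasing partial correspondence between residues
// of map A (observed, binary contacts) and map B (predicted, probabilistic).
// Its score is
//   sum over aligned residue pairs (k,l), k<l, whose endpoints form a contact
//   in BOTH maps of  p_B * s(sep_A, sep_B),   s = 1 / (1 + |sep_A - sep_B|/tol)
// plus affine gap costs for the gaps between consecutive aligned positions
// (unaligned overhangs are free: local alignment).

struct MapPair {
  int la, lb;
  std::vector<char> cA;             // la*la, observed contact indicator
  std::vector<double> pB;           // lb*lb, predicted probability, -1 = absent
  std::vector<std::vector<int>> nbA;
  std::vector<std::vector<std::pair<int,double>>> nbB;
  double go, ge, septol;

  bool contA(int i, int j) const { return cA[i * la + j] != 0; }
  double probB(int i, int j) const { return pB[i * lb + j]; }
};

static inline double wfun(int sa, int sb, double p, double septol) {
  return p / (1.0 + std::abs(sa - sb) / septol);
}
static inline double gapcost(int g, double go, double ge) {
  return g > 0 ? go + (g - 1) * ge : 0.0;
}

static MapPair build_problem(int la, int lb, const IntegerMatrix& obs,
                             const NumericMatrix& pred,
                             double go, double ge, double septol) {
  MapPair mp;
  mp.la = la; mp.lb = lb; mp.go = go; mp.ge = ge; mp.septol = septol;
  mp.cA.assign((size_t)la * la, 0);
  mp.pB.assign((size_t)lb * lb, -1.0);
  mp.nbA.assign(la, {});
  mp.nbB.assign(lb, {});
  for (int r = 0; r < obs.nrow(); ++r) {
    int i = obs(r, 0) - 1, j = obs(r, 1) - 1;
    mp.cA[i * la + j] = mp.cA[j * la + i] = 1;
    mp.nbA[i].push_back(j);
    mp.nbA[j].push_back(i);
  }
  for (int r = 0; r < pred.nrow(); ++r) {
    int i = (int)pred(r, 0) - 1, j = (int)pred(r, 1) - 1;
    double p = pred(r, 2);
    mp.pB[i * lb + j] = mp.pB[j * lb + i] = p;
    mp.nbB[i].push_back({j, p});
    mp.nbB[j].push_back({i, p});
  }
  return mp;
}

// exact objective for a mapping (0-based index vectors, strictly increasing)
static double exact_score(const MapPair& mp, const std::vector<int>& ma,
                          const std::vector<int>& mb) {
  double s = 0.0;
  int n = (int)ma.size();
  for (int k = 0; k < n; ++k) {
    for (int l = k + 1; l < n; ++l) {
      if (mp.contA(ma[k], ma[l])) {
        double p = mp.probB(mb[k], mb[l]);
        if (p >= 0.0)
          s += wfun(ma[l] - ma[k], mb[l] - mb[k], p, mp.septol);
      }
    }
    if (k > 0) {
      s += gapcost(ma[k] - ma[k - 1] - 1, mp.go, mp.ge);
      s += gapcost(mb[k] - mb[k - 1] - 1, mp.go, mp.ge);
    }
  }
  return s;
}

// Gotoh affine-gap DP over a residue-pair score matrix M (la x lb,
// column-major as in R). local = Smith-Waterman style (free overhangs),
// otherwise global. Ties prefer match over gaps, then smaller indices.
// Returns matched pairs (0-based) and the DP score.
static double affine_dp(const std::vector<double>& M, int la, int lb,
                        double go, double ge, bool local,
                        std::vector<int>& out_a, std::vector<int>& out_b) {
  const double NEG = -1e100;
  int W = lb + 1;
  std::vector<double> H((la + 1) * W, 0.0), E((la + 1) * W, NEG),
      F((la + 1) * W, NEG);
  std::vector<char> tbH((la + 1) * W, 0), tbE((la + 1) * W, 0),
      tbF((la + 1) * W, 0);
  // tbH: 0 stop/boundary, 1 diag, 2 from E, 3 from F
  if (!local) {
    for (int j = 1; j <= lb; ++j) {
      E[j] = gapcost(j, go, ge);
      H[j] = E[j];
      tbH[j] = 2; tbE[j] = (char)(j > 1 ? 1 : 0); // extend chain
    }
    for (int i = 1; i <= la; ++i) {
      F[i * W] = gapcost(i, go, ge);
      H[i * W] = F[i * W];
      tbH[i * W] = 3; tbF[i * W] = (char)(i > 1 ? 1 : 0);
    }
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int id = i * W + j;
      // E: gap in A (consume B)
      double eo = H[id - 1] + go, ee = E[id - 1] + ge;
      if (eo >= ee) { E[id] = eo; tbE[id] = 0; } else { E[id] = ee; tbE[id] = 1; }
      // F: gap in B (consume A)
      double fo = H[id - W] + go, fe = F[id - W] + ge;
      if (fo >= fe) { F[id] = fo; tbF[id] = 0; } else { F[id] = fe; tbF[id] = 1; }
      double diag = H[id - W - 1] + M[(i - 1) + (size_t)(j - 1) * la];
      double best = diag; char tb = 1;
      if (E[id] > best) { best = E[id]; tb = 2; }
      if (F[id] > best) { best = F[id]; tb = 3; }
      if (local && best <= 0.0) { best = 0.0; tb = 0; }
      H[id] = best; tbH[id] = tb;
    }
  }
  int bi, bj;
  double score;
  if (local) {
    score = 0.0; bi = 0; bj = 0;
    for (int i = 1; i <= la; ++i)
      for (int j = 1; j <= lb; ++j)
        if (H[i * W + j] > score) { score = H[i * W + j]; bi = i; bj = j; }
  } else {
    bi = la; bj = lb;
    score = H[bi * W + bj];
  }
  // traceback
  out_a.clear(); out_b.clear();
  int i = bi, j = bj; char state = 'H';
  while (i > 0 || j > 0) {
    int id = i * W + j;
    if (state == 'H') {
      char tb = tbH[id];
      if (tb == 0) break;
      if (tb == 1) {
        if (i == 0 || j == 0) break;
        out_a.push_back(i - 1); out_b.push_back(j - 1);
        --i; --j;
      } else if (tb == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      if (tbE[id] == 0) state = 'H';
      --j;
      if (j < 0) break;
    } else {
      if (tbF[id] == 0) state = 'H';
      --i;
      if (i < 0) break;
    }
    if (!local && i == 0 && j == 0) break;
    if (local && state == 'H' && tbH[i * W + j] == 0) break;
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
  return score;
}

// Refined residue-pair seed scores from the contact neighbourhoods of a
// current mapping (double dynamic programming step). Halved so the DP total
// approximates the exact objective (each matched contact has two endpoints).
static void refine_matrix(const MapPair& mp, const std::vector<int>& ma,
                          const std::vector<int>& mb, std::vector<double>& M) {
  std::fill(M.begin(), M.end(), 0.0);
  int n = (int)ma.size();
  for (int k = 0; k < n; ++k) {
    int a0 = ma[k], b0 = mb[k];
    for (int a : mp.nbA[a0]) {
      for (auto& bp : mp.nbB[b0]) {
        int b = bp.first;
        if ((a < a0) == (b < b0)) // preserve chain direction
          M[a + (size_t)b * mp.la] +=
              0.5 * wfun(std::abs(a - a0), std::abs(b - b0), bp.second, mp.septol);
      }
    }
  }
}

// one seeded run of iterative DP refinement; updates best-so-far
static void run_seed(const MapPair& mp, std::vector<double>& M, int iters,
                     double& best, std::vector<int>& best_a,
                     std::vector<int>& best_b) {
  std::vector<int> ma, mb, pa, pb;
  for (int it = 0; it <= iters; ++it) {
    affine_dp(M, mp.la, mp.lb, mp.go, mp.ge, true, ma, mb);
    double sc = exact_score(mp, ma, mb);
    if (sc > best) { best = sc; best_a = ma; best_b = mb; }
    if (ma == pa && mb == pb) break;
    pa = ma; pb = mb;
    if (it < iters) refine_matrix(mp, ma, mb, M);
  }
}

// greedy polish: drop single aligned pairs while the exact score improves
static void polish_drop(const MapPair& mp, double& best, std::vector<int>& ma,
                        std::vector<int>& mb) {
  bool improved = true;
  while (improved && !ma.empty()) {
    improved = false;
    for (size_t k = 0; k < ma.size(); ++k) {
      std::vector<int> ta(ma), tb(mb);
      ta.erase(ta.begin() + k); tb.erase(tb.begin() + k);
      double sc = exact_score(mp, ta, tb);
      if (sc > best) { best = sc; ma = ta; mb = tb; improved = true; break; }
    }
  }
}

// [[Rcpp::export]]
List cpp_align_local(int la, int lb, IntegerMatrix obs, NumericMatrix pred,
                     double gap_open, double gap_extend, double sep_tolerance,
                     int refine_iter, int shift_stride) {
  MapPair mp = build_problem(la, lb, obs, pred, gap_open, gap_extend,
                             sep_tolerance);
  double best = 0.0;
  std::vector<int> best_a, best_b;
  std::vector<double> M((size_t)la * lb);

  // neighbourhood-overlap seed
  std::fill(M.begin(), M.end(), 0.0);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double v = 0.0;
      for (int a : mp.nbA[i])
        for (auto& bp : mp.nbB[j])
          if ((a < i) == (bp.first < j))
            v += wfun(std::abs(a - i), std::abs(bp.first - j), bp.second,
                      sep_tolerance);
      M[i + (size_t)j * la] = 0.5 * v;
    }
  run_seed(mp, M, refine_iter, best, best_a, best_b);

  // diagonal-shift seeds
  if (shift_stride < 1) shift_stride = 1;
  for (int s = -(la - 1); s <= lb - 1; s += shift_stride) {
    for (int i = 0; i < la; ++i)
      for (int j = 0; j < lb; ++j)
        M[i + (size_t)j * la] = 0.25 * std::exp(-std::abs((j - i) - s) / 2.0);
    run_seed(mp, M, refine_iter, best, best_a, best_b);
  }

  // contact-pair anchor seeds for small maps: force the order-preserving
  // correspondence of one (or two jointly compatible) obs/pred contact
  // pairs and let refinement grow the alignment around it
  if (la <= 12 && lb <= 12) {
    std::vector<std::pair<int,int>> ca, cb;
    for (int i = 0; i < la; ++i)
      for (int j = i + 1; j < la; ++j)
        if (mp.contA(i, j)) ca.push_back({i, j});
    for (int i = 0; i < lb; ++i)
      for (int j = i + 1; j < lb; ++j)
        if (mp.probB(i, j) >= 0.0) cb.push_back({i, j});
    const double ANCHOR = 10.0;
    for (auto& a : ca)
      for (auto& b : cb) {
        std::fill(M.begin(), M.end(), 0.0);
        M[a.first + (size_t)b.first * la] = ANCHOR;
        M[a.second + (size_t)b.second * la] = ANCHOR;
        run_seed(mp, M, refine_iter, best, best_a, best_b);
      }
    // double-contact anchors: every monotone-compatible union of two
    // correspondences
    for (size_t p = 0; p < ca.size(); ++p)
      for (size_t q = p + 1; q < ca.size(); ++q)
        for (size_t r = 0; r < cb.size(); ++r)
          for (size_t s = 0; s < cb.size(); ++s) {
            if (r == s) continue;
            // pairs: ca[p] -> cb[r], ca[q] -> cb[s]
            std::vector<std::pair<int,int>> cells = {
              {ca[p].first, cb[r].first}, {ca[p].second, cb[r].second},
              {ca[q].first, cb[s].first}, {ca[q].second, cb[s].second}};
            std::sort(cells.begin(), cells.end());
            bool ok = true;
            for (size_t k = 1; k < cells.size(); ++k) {
              if (cells[k].first == cells[k - 1].first) {
                if (cells[k].second != cells[k - 1].second) ok = false;
              } else if (cells[k].second <= cells[k - 1].second) {
                ok = false;
              }
            }
            if (!ok) continue;
            std::fill(M.begin(), M.end(), 0.0);
            for (auto& c : cells) M[c.first + (size_t)c.second * la] = ANCHOR;
            run_seed(mp, M, refine_iter, best, best_a, best_b);
          }
  }

  polish_drop(mp, best, best_a, best_b);

  IntegerMatrix mapping((int)best_a.size(), 2);
  for (size_t k = 0; k < best_a.size(); ++k) {
    mapping(k, 0) = best_a[k] + 1;
    mapping(k, 1) = best_b[k] + 1;
  }
  return List::create(_["score"] = best, _["mapping"] = mapping);
}

// [[Rcpp::export]]
List cpp_affine_dp(NumericMatrix S, double gap_open, double gap_extend,
                   bool local) {
  int la = S.nrow(), lb = S.ncol();
  std::vector<double> M(S.begin(), S.end());
  std::vector<int> ma, mb;
  double sc = affine_dp(M, la, lb, gap_open, gap_extend, local, ma, mb);
  IntegerMatrix mapping((int)ma.size(), 2);
  for (size_t k = 0; k < ma.size(); ++k) {
    mapping(k, 0) = ma[k] + 1;
    mapping(k, 1) = mb[k] + 1;
  }
  return List::create(_["score"] = sc, _["mapping"] = mapping);
}

static void brute_rec(const MapPair& mp, int posA, int posB,
                      std::vector<int>& ma, std::vector<int>& mb, double sc,
                      double& best, std::vector<int>& best_a,
                      std::vector<int>& best_b) {
  if (sc > best) { best = sc; best_a = ma; best_b = mb; }
  for (int a = posA; a < mp.la; ++a) {
    for (int b = posB; b < mp.lb; ++b) {
      double add = 0.0;
      if (!ma.empty()) {
        add += gapcost(a - ma.back() - 1, mp.go, mp.ge);
        add += gapcost(b - mb.back() - 1, mp.go, mp.ge);
      }
      for (size_t k = 0; k < ma.size(); ++k) {
        if (mp.contA(ma[k], a)) {
          double p = mp.probB(mb[k], b);
          if (p >= 0.0) add += wfun(a - ma[k], b - mb[k], p, mp.septol);
        }
      }
      ma.push_back(a); mb.push_back(b);
      brute_rec(mp, a + 1, b + 1, ma, mb, sc + add, best, best_a, best_b);
      ma.pop_back(); mb.pop_back();
    }
  }
}

// [[Rcpp::export]]
List cpp_brute_force_align(int la, int lb, IntegerMatrix obs,
                           NumericMatrix pred, double gap_open,
                           double gap_extend, double sep_tolerance) {
  MapPair mp = build_problem(la, lb, obs, pred, gap_open, gap_extend,
                             sep_tolerance);
  double best = 0.0;
  std::vector<int> ma, mb, best_a, best_b;
  brute_rec(mp, 0, 0, ma, mb, 0.0, best, best_a, best_b);
  IntegerMatrix mapping((int)best_a.size(), 2);
  for (size_t k = 0; k < best_a.size(); ++k) {
    mapping(k, 0) = best_a[k] + 1;
    mapping(k, 1) = best_b[k] + 1;
  }
  return List::create(_["score"] = best, _["mapping"] = mapping);
}

// [[Rcpp::export]]
double cpp_mapping_score(int la, int lb, IntegerMatrix obs, NumericMatrix pred,
                         IntegerMatrix mapping, double gap_open,
                         double gap_extend, double sep_tolerance) {
  MapPair mp = build_problem(la, lb, obs, pred, gap_open, gap_extend,
                             sep_tolerance);
  std::vector<int> ma(mapping.nrow()), mb(mapping.nrow());
  for (int k = 0; k < mapping.nrow(); ++k) {
    ma[k] = mapping(k, 0) - 1;
    mb[k] = mapping(k, 1) - 1;
  }
  return exact_score(mp, ma, mb);
}
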