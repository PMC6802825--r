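#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// TM-score for two equal-length coordinate sets with a fixed residue
// correspondence:
//   TM = (1/L) sum_i 1 / (1 + (d_i/d0)^2),  d0 = 1.24 (L-15)^(1/3) - 1.8
// maximised over rigid-body superpositions. The search seeds Kabsch
// superpositions from contiguous fragments (lengths L, L/2, L/4, stride 4)
// and iterates superpose-on-subset / reselect residues with d_i < d0 until
// the selection is stable (max 20 iterations), keeping the best TM seen.

static arma::mat kabsch_transform(const arma::mat& X, const arma::mat& Y,
                                  const arma::uvec& sel) {
  // returns Y superposed onto X using the selected rows (row vectors, n x 3)
  arma::rowvec cx = arma::mean(X.rows(sel), 0);
  arma::rowvec cy = arma::mean(Y.rows(sel), 0);
  arma::mat A = Y.rows(sel);
  A.each_row() -= cy;
  arma::mat B = X.rows(sel);
  B.each_row() -= cx;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, A.t() * B);
  arma::mat R = U * V.t();
  if (arma::det(R) < 0) {
    U.col(2) *= -1.0;
    R = U * V.t();
  }
  arma::mat Yt = Y;
  Yt.each_row() -= cy;
  Yt = Yt * R;
  Yt.each_row() += cx;
  return Yt;
}

static double tm_from_d2(const arma::vec& d2, double d0) {
  double s = 0.0, d02 = d0 * d0;
  for (arma::uword i = 0; i < d2.n_elem; ++i) s += 1.0 / (1.0 + d2(i) / d02);
  return s / (double)d2.n_elem;
}

static double tm_search(const arma::mat& X, const arma::mat& Y, double d0) {
  int L = (int)X.n_rows;
  double best = 0.0;
  std::vector<int> frag_lens;
  for (int f : {L, L / 2, L / 4})
    if (f >= 4 &&
        std::find(frag_lens.begin(), frag_lens.end(), f) == frag_lens.end())
      frag_lens.push_back(f);
  for (int fl : frag_lens) {
    for (int start = 0; start + fl <= L; start += 4) {
      arma::uvec sel(fl);
      for (int k = 0; k < fl; ++k) sel(k) = start + k;
      arma::uvec prev;
      for (int it = 0; it < 20; ++it) {
        arma::mat Yt = kabsch_transform(X, Y, sel);
        arma::vec d2 = arma::sum(arma::square(X - Yt), 1);
        double tm = tm_from_d2(d2, d0);
        if (tm > best) best = tm;
        arma::uvec nsel = arma::find(arma::sqrt(d2) < d0);
        if (nsel.n_elem < 4) break;
        if (nsel.n_elem == sel.n_elem && arma::all(nsel == sel)) break;
        prev = sel;
        sel = nsel;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
double cpp_tm_score(NumericMatrix x, NumericMatrix y, double d0) {
  arma::mat X(x.begin(), x.nrow(), x.ncol(), false);
  arma::mat Y(y.begin(), y.nrow(), y.ncol(), false);
  // the optimum is direction-symmetric; run the heuristic both ways
  double a = tm_search(X, Y, d0);
  double b = tm_search(Y, X, d0);
  return a > b ? a : b;
}

// [[Rcpp::export]]
NumericMatrix cpp_tm_matrix(List coords, double d0) {
  int n = coords.size();
  std::vector<arma::mat> M(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = coords[i];
    M[i] = arma::mat(m.begin(), m.nrow(), m.ncol());
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double a = tm_search(M[i], M[j], d0);
      double b = tm_search(M[j], M[i], d0);
      double tm = a > b ? a : b; // symmetrised: same L, best superposition
      out(i, j) = tm;
      out(j, i) = tm;
    }
  }
  return out;
}
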