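// Fast least-squares sweeps over allele-grouping models.
//
// Every grouping model is a column-aggregation of the same n x m haplotype
// dosage matrix, so all fits share one Gram matrix G = [1 X]'[1 X] and one
// projection vector xty = [1 X]'y.  For a grouping with block labels
// lab[1..m] in 1..k, the grouped normal equations are obtained by summing
// rows/columns of G, and the residual sum of squares follows from the
// minimum-norm (pseudo-inverse) solution.  Rank deficiency (block dosages
// summing to 2, collinear with the intercept) is handled by eigenvalue
// truncation, matching the scan model's convention.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// G:    (m+1) x (m+1) Gram matrix of [1, X] with X columns in sorted order
// xty:  [1, X]' y
// yty:  y'y
// labels: n_models x m block labels (1..k, contiguous, k = row max)
// panel:  length-m panel indicator (1 = pA, 2 = pB) per sorted haplotype;
//         each (block, panel) combination present receives its own effect
//         column.  Pass all-equal panel values to share one effect per
//         block instead.
// returns n_models x 3 matrix: rss, rank, k (number of blocks)
// [[Rcpp::export]]
arma::mat fit_groupings_gram(const arma::mat& G, const arma::vec& xty,
                             const double yty, const arma::imat& labels,
                             const arma::ivec& panel) {
  const int M = labels.n_rows, m = labels.n_cols;
  if ((int)G.n_rows != m + 1 || (int)xty.n_elem != m + 1)
    Rcpp::stop("Gram matrix does not match the label width");
  if ((int)panel.n_elem != m)
    Rcpp::stop("panel indicator does not match the label width");
  mat out(M, 3);
  std::vector<int> gidx(m + 1);
  std::vector<int> dense(2 * m + 2);
  for (int r = 0; r < M; ++r) {
    int k = 0;
    for (int i = 0; i < m; ++i)
      if (labels(r, i) > k) k = labels(r, i);
    // map (block, panel) pairs to dense effect-column indices
    std::fill(dense.begin(), dense.begin() + 2 * k + 1, -1);
    gidx[0] = 0;
    int p = 1;
    for (int i = 0; i < m; ++i) {
      const int key = 2 * (labels(r, i) - 1) + (panel(i) - 1) + 1;
      if (dense[key] < 0) dense[key] = p++;
      gidx[i + 1] = dense[key];
    }
    mat WtW(p, p, fill::zeros);
    vec wty(p, fill::zeros);
    for (int a = 0; a <= m; ++a) {
      const int ga = gidx[a];
      wty(ga) += xty(a);
      for (int b = 0; b <= m; ++b)
        WtW(ga, gidx[b]) += G(a, b);
    }
    vec eval;
    mat evec;
    eig_sym(eval, evec, WtW);
    const double tol = eval.max() * p * datum::eps;
    const vec z = evec.t() * wty;
    int rank = 0;
    double fit = 0.0;
    for (int i = 0; i < p; ++i) {
      if (eval(i) > tol) {
        ++rank;
        fit += z(i) * z(i) / eval(i);
      }
    }
    double rss = yty - fit;
    if (rss < 0.0) rss = 0.0;
    out(r, 0) = rss;
    out(r, 1) = rank;
    out(r, 2) = k;
  }
  return out;
}
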