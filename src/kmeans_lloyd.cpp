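// Lloyd k-means with the conventions the parcellation pipeline fixes:
// centroids initialized from supplied data-row indices, assignment ties
// broken toward the lowest centroid index, empty clusters re-seeded at the
// point currently farthest from its own centroid, and the best of all
// initializations selected by within-cluster sum of squares.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static void assign_points(const mat& X, const mat& C, const vec& xsq,
                          uvec& labels) {
  // squared distances via ||x||^2 - 2 x.c + ||c||^2; argmin with strict
  // comparison keeps the lowest index on ties
  mat D = -2.0 * (X * C.t());
  rowvec csq = sum(C % C, 1).t();
  D.each_row() += csq;
  D.each_col() += xsq;
  for (uword i = 0; i < X.n_rows; ++i) {
    uword best = 0;
    double bd = D(i, 0);
    for (uword j = 1; j < C.n_rows; ++j) {
      if (D(i, j) < bd) { bd = D(i, j); best = j; }
    }
    labels(i) = best;
  }
}

// [[Rcpp::export]]
Rcpp::List kmeans_lloyd_cpp(const arma::mat& X, const arma::umat& init_rows,
                            const int max_iter) {
  const uword n = X.n_rows;
  const uword k = init_rows.n_cols;
  const vec xsq = sum(X % X, 1);
  uvec best_labels(n);
  double best_wcss = datum::inf;

  for (uword init = 0; init < init_rows.n_rows; ++init) {
    mat C(k, X.n_cols);
    for (uword j = 0; j < k; ++j) C.row(j) = X.row(init_rows(init, j) - 1);
    uvec labels(n, fill::zeros);
    uvec prev(n); prev.fill(n + 1);
    for (int iter = 0; iter < max_iter; ++iter) {
      assign_points(X, C, xsq, labels);
      // re-seed empty clusters at the point farthest from its centroid
      while (true) {
        uvec counts(k, fill::zeros);
        for (uword i = 0; i < n; ++i) counts(labels(i))++;
        uword empty = k;
        for (uword j = 0; j < k; ++j) if (counts(j) == 0) { empty = j; break; }
        if (empty == k) break;
        double worst = -1.0; uword worst_i = 0;
        for (uword i = 0; i < n; ++i) {
          rowvec d = X.row(i) - C.row(labels(i));
          double dd = dot(d, d);
          if (dd > worst) { worst = dd; worst_i = i; }
        }
        C.row(empty) = X.row(worst_i);
        labels(worst_i) = empty;
      }
      if (all(labels == prev)) break;
      prev = labels;
      // update step
      mat newC(k, X.n_cols, fill::zeros);
      uvec counts(k, fill::zeros);
      for (uword i = 0; i < n; ++i) {
        newC.row(labels(i)) += X.row(i);
        counts(labels(i))++;
      }
      for (uword j = 0; j < k; ++j) {
        if (counts(j) > 0) C.row(j) = newC.row(j) / counts(j);
      }
    }
    // final WCSS under the returned labels
    double wcss = 0.0;
    mat C2(k, X.n_cols, fill::zeros);
    uvec counts(k, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      C2.row(labels(i)) += X.row(i);
      counts(labels(i))++;
    }
    for (uword j = 0; j < k; ++j) {
      if (counts(j) > 0) C2.row(j) /= counts(j);
    }
    for (uword i = 0; i < n; ++i) {
      rowvec d = X.row(i) - C2.row(labels(i));
      wcss += dot(d, d);
    }
    if (wcss < best_wcss) {
      best_wcss = wcss;
      best_labels = labels;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("labels") = Rcpp::IntegerVector(best_labels.begin(),
                                                best_labels.end()),
    Rcpp::Named("wcss") = best_wcss);
}
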