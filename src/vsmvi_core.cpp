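// Compiled core of the VSMVI subset search.
//
// Scoring a candidate subset never touches the raw design twice: the full
// Gram matrix [1 X]'[1 X] is built once, a split's construction-set Gram is
// obtained by subtracting the validation rows, and the normal equations of
// the (p+1)-column subset are solved directly. All index vectors arriving
// from R are 1-based.

#include <RcppArmadillo.h>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct SplitData {
  arma::uvec val;       // 0-based validation rows
  double sstot_val;     // total SS about the validation-set mean
  arma::mat Gc;         // construction-set Gram of [1 X] (full width)
  arma::vec ac;         // construction-set [1 X]'y
};

// In-place Cholesky solve of the symmetric positive-definite system held in
// the lower triangle of A (k x k); b is overwritten with the solution.
// Returns false when a pivot collapses (rank-deficient / near-singular).
static bool chol_solve(arma::mat& A, arma::vec& b, int k) {
  double dmax = 0;
  for (int i = 0; i < k; ++i) dmax = std::max(dmax, A(i, i));
  for (int j = 0; j < k; ++j) {
    double d = A(j, j);
    for (int t = 0; t < j; ++t) d -= A(j, t) * A(j, t);
    if (!(d > 1e-12 * dmax)) return false;
    d = std::sqrt(d);
    A(j, j) = d;
    for (int i = j + 1; i < k; ++i) {
      double s = A(i, j);
      for (int t = 0; t < j; ++t) s -= A(i, t) * A(j, t);
      A(i, j) = s / d;
    }
  }
  for (int i = 0; i < k; ++i) {
    double s = b[i];
    for (int t = 0; t < i; ++t) s -= A(i, t) * b[t];
    b[i] = s / A(i, i);
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = b[i];
    for (int t = i + 1; t < k; ++t) s -= A(t, i) * b[t];
    b[i] = s / A(i, i);
  }
  return true;
}

// Shared scoring state for one (X, y, split plan) triple.
struct Scorer {
  const arma::mat& X;
  const arma::vec& y;
  arma::mat G;          // (m+1)x(m+1) Gram of [1 X]
  arma::vec a;          // [1 X]'y
  double yty, sstot_full;
  int n, m;
  std::vector<SplitData> splits;
  arma::mat cormat;     // m x m descriptor correlations
  double max_fail_frac;

  Scorer(const arma::mat& X_, const arma::vec& y_, const List& val_sets)
      : X(X_), y(y_), max_fail_frac(0.10) {
    n = X.n_rows;
    m = X.n_cols;
    arma::mat D(n, m + 1);
    D.col(0).ones();
    if (m > 0) D.cols(1, m) = X;
    G = D.t() * D;
    a = D.t() * y;
    yty = arma::dot(y, y);
    double ym = arma::mean(y);
    sstot_full = arma::accu(arma::square(y - ym));
    cormat = (m > 1) ? arma::mat(arma::cor(X)) : arma::mat(std::max(m, 1), std::max(m, 1), arma::fill::ones);
    int N = val_sets.size();
    splits.resize(N);
    for (int s = 0; s < N; ++s) {
      IntegerVector v = val_sets[s];
      arma::uvec val(v.size());
      for (int i = 0; i < v.size(); ++i) val[i] = (arma::uword)(v[i] - 1);
      arma::vec yv = y.elem(val);
      double mv = arma::mean(yv);
      splits[s].val = val;
      splits[s].sstot_val = arma::accu(arma::square(yv - mv));
      arma::mat V(val.n_elem, m + 1);
      V.col(0).ones();
      if (m > 0) V.cols(1, m) = X.rows(val);
      splits[s].Gc = G - V.t() * V;
      splits[s].ac = a - V.t() * yv;
    }
  }

  // true when every pairwise |r| is strictly below r_int
  bool gate_rint(const std::vector<int>& idx, double r_int) const {
    for (size_t i = 0; i + 1 < idx.size(); ++i)
      for (size_t j = i + 1; j < idx.size(); ++j)
        if (std::abs(cormat(idx[i] - 1, idx[j] - 1)) >= r_int) return false;
    return true;
  }

  double train_r2(const std::vector<int>& idx) const {
    int p = (int)idx.size(), k = p + 1;
    arma::mat A(k, k);
    arma::vec b(k);
    gather(G, a, idx, A, b);
    double bta = 0;
    {
      arma::vec rhs = b;
      if (!chol_solve(A, rhs, k)) return NA_REAL;
      bta = arma::dot(rhs, b);
    }
    double ssres = yty - bta;
    if (ssres < 0) ssres = 0;
    if (sstot_full <= 0) return NA_REAL;
    double r2 = 1.0 - ssres / sstot_full;
    if (!std::isfinite(r2)) return NA_REAL;
    return r2;
  }

  // Per-split q2 / RMSEV; returns false when more than max_fail_frac of
  // folds have a singular construction design.
  bool cv_stats(const std::vector<int>& idx, arma::vec& q2s, arma::vec& rmsevs) const {
    int p = (int)idx.size(), k = p + 1;
    int N = (int)splits.size(), fails = 0;
    q2s.set_size(N);
    rmsevs.set_size(N);
    arma::mat A(k, k);
    arma::vec b(k);
    for (int s = 0; s < N; ++s) {
      const SplitData& sp = splits[s];
      int nv = (int)sp.val.n_elem;
      gather(sp.Gc, sp.ac, idx, A, b);
      if (!chol_solve(A, b, k)) {
        q2s[s] = NA_REAL;
        rmsevs[s] = NA_REAL;
        ++fails;
        continue;
      }
      double ssres = 0;
      for (int r = 0; r < nv; ++r) {
        arma::uword row = sp.val[r];
        double pred = b[0];
        for (int i = 0; i < p; ++i) pred += b[i + 1] * X(row, idx[i] - 1);
        double e = y[row] - pred;
        ssres += e * e;
      }
      q2s[s] = (sp.sstot_val > 0) ? 1.0 - ssres / sp.sstot_val : NA_REAL;
      rmsevs[s] = std::sqrt(ssres / nv);
    }
    return fails <= max_fail_frac * N;
  }

 private:
  // Copy the intercept + subset rows/columns of a full-width Gram system
  // into the k x k workspace (lower triangle) and right-hand side.
  static void gather(const arma::mat& Gfull, const arma::vec& afull,
                     const std::vector<int>& idx, arma::mat& A, arma::vec& b) {
    int k = (int)idx.size() + 1;
    for (int i = 0; i < k; ++i) {
      int gi = (i == 0) ? 0 : idx[i - 1];
      b[i] = afull[gi];
      for (int j = 0; j <= i; ++j) {
        int gj = (j == 0) ? 0 : idx[j - 1];
        A(i, j) = Gfull(gi, gj);
      }
    }
  }
};

// Fixed-capacity pool of the best-scoring subsets. Ordering: higher score
// wins (scores are q2-like, or negated RMSEV when minimizing); exact score
// ties go to the lexicographically smaller index set.
struct Pool {
  int cap;
  bool maximize;
  std::vector<std::vector<int> > idx;
  std::vector<double> sc, r2;
  int worst;

  Pool(int cap_, bool maximize_) : cap(cap_), maximize(maximize_), worst(-1) {}

  bool better(double sa, const std::vector<int>& ia,
              double sb, const std::vector<int>& ib) const {
    double A = maximize ? sa : -sa;
    double B = maximize ? sb : -sb;
    if (A != B) return A > B;
    return ia < ib;
  }

  void find_worst() {
    worst = 0;
    for (int i = 1; i < (int)sc.size(); ++i)
      if (better(sc[worst], idx[worst], sc[i], idx[i])) worst = i;
  }

  bool offer(const std::vector<int>& ind, double s, double r2v) {
    if ((int)idx.size() < cap) {
      idx.push_back(ind);
      sc.push_back(s);
      r2.push_back(r2v);
      find_worst();
      return true;
    }
    if (better(s, ind, sc[worst], idx[worst])) {
      idx[worst] = ind;
      sc[worst] = s;
      r2[worst] = r2v;
      find_worst();
      return true;
    }
    return false;
  }
};

struct StageCounts {
  long long generated, gated_rint, gated_rcri, scored, failed, duplicates;
  StageCounts() : generated(0), gated_rint(0), gated_rcri(0), scored(0),
                  failed(0), duplicates(0) {}
};

void evaluate_candidate(const Scorer& sc, Pool& pool, const std::vector<int>& idx,
                        double r_int, double r_cri, StageCounts& ct) {
  if (!sc.gate_rint(idx, r_int)) {
    ++ct.gated_rint;
    return;
  }
  double r2 = sc.train_r2(idx);
  if (ISNAN(r2)) {
    ++ct.failed;
    return;
  }
  if (r2 < r_cri) {
    ++ct.gated_rcri;
    return;
  }
  arma::vec q2s, rmsevs;
  if (!sc.cv_stats(idx, q2s, rmsevs)) {
    ++ct.failed;
    return;
  }
  arma::uvec ok = arma::find_finite(pool.maximize ? q2s : rmsevs);
  if (ok.n_elem == 0) {
    ++ct.failed;
    return;
  }
  double score = pool.maximize ? arma::mean(q2s.elem(ok))
                               : -arma::mean(rmsevs.elem(arma::find_finite(rmsevs)));
  ++ct.scored;
  pool.offer(idx, score, r2);
}

List pool_to_list(const Pool& pool, int vn, const StageCounts& ct) {
  int nrec = (int)pool.idx.size();
  std::vector<int> ord(nrec);
  for (int i = 0; i < nrec; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    return pool.better(pool.sc[i], pool.idx[i], pool.sc[j], pool.idx[j]);
  });
  IntegerMatrix M(nrec, vn);
  NumericVector scv(nrec), r2v(nrec);
  for (int r = 0; r < nrec; ++r) {
    int i = ord[r];
    for (int j = 0; j < vn; ++j) M(r, j) = pool.idx[i][j];
    scv[r] = pool.maximize ? pool.sc[i] : -pool.sc[i];
    r2v[r] = pool.r2[i];
  }
  return List::create(
      _["indices"] = M, _["sc"] = scv, _["r2"] = r2v,
      _["counts"] = NumericVector::create(
          _["generated"] = (double)ct.generated,
          _["gated_rint"] = (double)ct.gated_rint,
          _["gated_rcri"] = (double)ct.gated_rcri,
          _["scored"] = (double)ct.scored,
          _["failed"] = (double)ct.failed,
          _["duplicates"] = (double)ct.duplicates));
}

}  // namespace

// Exhaustive scan of all size-vn descriptor combinations (stage 1).
// [[Rcpp::export]]
List cpp_exhaustive_stage(const arma::mat& X, const arma::vec& y, int vn,
                          List val_sets, double r_int, double r_cri, int Ns,
                          bool maximize) {
  Scorer sc(X, y, val_sets);
  Pool pool(Ns, maximize);
  StageCounts ct;
  int m = sc.m;
  if (vn > m) stop("subset size exceeds the number of descriptors");
  std::vector<int> idx(vn);
  for (int i = 0; i < vn; ++i) idx[i] = i + 1;
  for (;;) {
    ++ct.generated;
    if (ct.generated % 4096 == 0) Rcpp::checkUserInterrupt();
    evaluate_candidate(sc, pool, idx, r_int, r_cri, ct);
    int i = vn - 1;
    while (i >= 0 && idx[i] == m - (vn - 1 - i)) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < vn; ++j) idx[j] = idx[j - 1] + 1;
  }
  return pool_to_list(pool, vn, ct);
}

// Extension stage: each parent subset combined with every absent descriptor,
// deduplicated by sorted index set (stage 2).
// [[Rcpp::export]]
List cpp_extension_stage(const arma::mat& X, const arma::vec& y,
                         IntegerMatrix parents, List val_sets, double r_int,
                         double r_cri, int Ns, bool maximize) {
  Scorer sc(X, y, val_sets);
  Pool pool(Ns, maximize);
  StageCounts ct;
  int m = sc.m;
  int np = parents.nrow(), pv = parents.ncol();
  int vn = pv + 1;
  std::set<std::vector<int> > seen;
  for (int r = 0; r < np; ++r) {
    std::vector<bool> inparent(m + 1, false);
    std::vector<int> par(pv);
    for (int j = 0; j < pv; ++j) {
      par[j] = parents(r, j);
      inparent[par[j]] = true;
    }
    for (int v = 1; v <= m; ++v) {
      if (inparent[v]) continue;
      ++ct.generated;
      if (ct.generated % 4096 == 0) Rcpp::checkUserInterrupt();
      std::vector<int> child(par);
      child.push_back(v);
      std::sort(child.begin(), child.end());
      if (!seen.insert(child).second) {
        ++ct.duplicates;
        continue;
      }
      evaluate_candidate(sc, pool, child, r_int, r_cri, ct);
    }
  }
  return pool_to_list(pool, vn, ct);
}

// Fit + CV statistics for explicitly given subsets (no gates, no pool).
// [[Rcpp::export]]
List cpp_score_subsets(const arma::mat& X, const arma::vec& y,
                       IntegerMatrix subsets, List val_sets) {
  Scorer sc(X, y, val_sets);
  int ns = subsets.nrow(), p = subsets.ncol();
  NumericVector r2(ns), q2_mean(ns), q2_std(ns), rmsev_mean(ns), rmsev_std(ns),
      n_failed(ns);
  for (int r = 0; r < ns; ++r) {
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = subsets(r, j);
    r2[r] = sc.train_r2(idx);
    arma::vec q2s, rmsevs;
    sc.cv_stats(idx, q2s, rmsevs);
    arma::uvec okq = arma::find_finite(q2s);
    arma::uvec okr = arma::find_finite(rmsevs);
    q2_mean[r] = okq.n_elem ? arma::mean(q2s.elem(okq)) : NA_REAL;
    q2_std[r] = okq.n_elem > 1 ? arma::stddev(q2s.elem(okq)) : NA_REAL;
    rmsev_mean[r] = okr.n_elem ? arma::mean(rmsevs.elem(okr)) : NA_REAL;
    rmsev_std[r] = okr.n_elem > 1 ? arma::stddev(rmsevs.elem(okr)) : NA_REAL;
    n_failed[r] = (double)(q2s.n_elem - okr.n_elem);
  }
  return List::create(_["r2"] = r2, _["q2_mean"] = q2_mean, _["q2_std"] = q2_std,
                      _["rmsev_mean"] = rmsev_mean, _["rmsev_std"] = rmsev_std,
                      _["n_failed"] = n_failed);
}
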