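// Rigid-body superposition and similarity-score searches over Calpha traces.
// Points are stored as n x 3 matrices (rows = residues), all units in Angstrom.
#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-squares (Kabsch) superposition of P onto Q.
// Returns rotation R (applied to column vectors: x -> R x + t) and rmsd.
static void kabsch_core(const mat& P, const mat& Q, mat& R, vec& t,
                        double& rmsd, const vec* w = nullptr) {
  const uword n = P.n_rows;
  rowvec cP, cQ;
  if (w) {
    double sw = accu(*w);
    cP = (w->t() * P) / sw;
    cQ = (w->t() * Q) / sw;
  } else {
    cP = mean(P, 0);
    cQ = mean(Q, 0);
  }
  mat Pc = P.each_row() - cP;
  mat Qc = Q.each_row() - cQ;
  mat H;
  if (w) H = Pc.t() * (Qc.each_col() % (*w));
  else   H = Pc.t() * Qc;
  mat U, V;
  vec s;
  svd(U, s, V, H);
  double d = det(V * U.t()) < 0 ? -1.0 : 1.0;
  mat D = eye<mat>(3, 3);
  D(2, 2) = d;
  R = V * D * U.t();
  t = cQ.t() - R * cP.t();
  mat Pt = Pc * R.t();
  double ss = 0.0;
  for (uword i = 0; i < n; ++i) {
    rowvec diff = Pt.row(i) - Qc.row(i);
    ss += dot(diff, diff);
  }
  rmsd = std::sqrt(ss / n);
}

// Distances of all rows of P to Q after transform (R, t).
static vec all_dists(const mat& P, const mat& Q, const mat& R, const vec& t) {
  mat Pt = P * R.t();
  Pt.each_row() += t.t();
  return sqrt(sum(square(Pt - Q), 1));
}

// Kabsch on the subset given by idx, then distances over all rows.
static void subset_superpose(const mat& P, const mat& Q, const uvec& idx,
                             mat& R, vec& t, double& rms_sub) {
  kabsch_core(P.rows(idx), Q.rows(idx), R, t, rms_sub);
}

// [[Rcpp::export]]
Rcpp::List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
  if (P.n_rows != Q.n_rows) Rcpp::stop("coordinate sets differ in length");
  if (P.n_rows < 3) Rcpp::stop("insufficient points");
  mat R;
  vec t;
  double rmsd;
  kabsch_core(P, Q, R, t, rmsd);
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rmsd") = rmsd);
}

struct SeedSearchResult {
  uword best_count;     // residues under threshold in the best superposition
  double best_rms;      // rmsd over the counted residues (tie-break)
  mat best_R;
  vec best_t;
};

// Fragment-seeded iterative-inclusion search for one GDT distance threshold.
// Seeds: all residues, then sliding windows of length 3..7. Each seed is
// iterated (superpose current subset -> include residues under the
// threshold) to a fixed point, max 20 iterations.
static SeedSearchResult gdt_threshold_search(const mat& P, const mat& Q,
                                             double thr, int max_iter) {
  const uword n = P.n_rows;
  SeedSearchResult best;
  best.best_count = 0;
  best.best_rms = datum::inf;
  std::vector<uvec> seeds;
  uvec all = regspace<uvec>(0, n - 1);
  seeds.push_back(all);
  for (uword w = 3; w <= 7 && w <= n; ++w)
    for (uword s = 0; s + w <= n; ++s)
      seeds.push_back(regspace<uvec>(s, s + w - 1));
  // small cases afford dense seeding: every residue triple, which makes
  // the search match the exhaustive subset oracle in practice
  if (n <= 16) {
    for (uword i = 0; i + 2 < n; ++i)
      for (uword j = i + 1; j + 1 < n; ++j)
        for (uword k = j + 1; k < n; ++k) {
          uvec s(3);
          s[0] = i; s[1] = j; s[2] = k;
          seeds.push_back(s);
        }
  }

  mat R;
  vec t;
  double rms_sub;
  for (const uvec& seed : seeds) {
    uvec sub = seed;
    // every iterate's superposition is a candidate: inclusion can shrink
    // the in-threshold count later, so the best may be an intermediate
    for (int it = 0; it < max_iter; ++it) {
      subset_superpose(P, Q, sub, R, t, rms_sub);
      vec d = all_dists(P, Q, R, t);
      uvec in = find(d <= thr);
      uword cnt = in.n_elem;
      if (cnt > 0) {
        double rms_in = std::sqrt(mean(square(d.elem(in))));
        if (cnt > best.best_count ||
            (cnt == best.best_count && rms_in < best.best_rms)) {
          best.best_count = cnt;
          best.best_rms = rms_in;
          best.best_R = R;
          best.best_t = t;
        }
      }
      if (cnt < 3) break;
      if (cnt == sub.n_elem && accu(in != sub) == 0) break;
      sub = in;
    }
    if (best.best_count == n) return best;  // cannot improve
  }
  // refinement: from the best superposition, superpose on the k nearest
  // residues for every k; repeat while it improves. This reaches
  // non-contiguous subsets the window seeds cannot.
  for (int round = 0; round < 5 && best.best_count < n; ++round) {
    vec d = all_dists(P, Q, best.best_R, best.best_t);
    uvec ord = sort_index(d);
    bool improved = false;
    for (uword k = 3; k <= n; ++k) {
      uvec sub = sort(ord.head(k));
      subset_superpose(P, Q, sub, R, t, rms_sub);
      vec d2 = all_dists(P, Q, R, t);
      uvec in = find(d2 <= thr);
      uword cnt = in.n_elem;
      if (cnt == 0) continue;
      double rms_in = std::sqrt(mean(square(d2.elem(in))));
      if (cnt > best.best_count ||
          (cnt == best.best_count && rms_in < best.best_rms)) {
        best.best_count = cnt;
        best.best_rms = rms_in;
        best.best_R = R;
        best.best_t = t;
        improved = true;
      }
    }
    if (!improved) break;
  }
  return best;
}

// Exact small-case GDT: enumerate the least-squares fit of every subset
// of size >= 3 and count residues under each threshold. Feasible up to
// n ~ 14 (2^14 fits); beyond that the fragment-seeded heuristic search
// above provides a lower bound of the true maximum.
static void gdt_exact_all(const mat& P, const mat& Q,
                          const Rcpp::NumericVector& thresholds,
                          std::vector<SeedSearchResult>& best) {
  const uword n = P.n_rows;
  const uword nthr = best.size();
  mat R;
  vec t;
  double rms_sub;
  for (uword mask = 1; mask < (uword(1) << n); ++mask) {
    uword pc = __builtin_popcountll(mask);
    if (pc < 3) continue;
    uvec idx(pc);
    uword j = 0;
    for (uword i = 0; i < n; ++i)
      if (mask & (uword(1) << i)) idx[j++] = i;
    subset_superpose(P, Q, idx, R, t, rms_sub);
    vec d = all_dists(P, Q, R, t);
    for (uword k = 0; k < nthr; ++k) {
      uvec in = find(d <= thresholds[k]);
      uword cnt = in.n_elem;
      if (cnt == 0) continue;
      double rms_in = std::sqrt(mean(square(d.elem(in))));
      if (cnt > best[k].best_count ||
          (cnt == best[k].best_count && rms_in < best[k].best_rms)) {
        best[k].best_count = cnt;
        best[k].best_rms = rms_in;
      }
    }
  }
}

static double tm_sum(const vec& d, double d0) {
  return accu(1.0 / (1.0 + square(d / d0)));
}

// Local refinement: iteratively reweighted Kabsch with the TM gradient
// weights w_i = (1 + (d_i/d0)^2)^-2, whose fixed points are stationary
// points of the TM sum. Returns the refined TM sum from (R0, t0).
static double tm_polish(const mat& P, const mat& Q, double d0,
                        mat R, vec t) {
  vec d = all_dists(P, Q, R, t);
  double best = tm_sum(d, d0);
  for (int it = 0; it < 200; ++it) {
    vec w = pow(1.0 + square(d / d0), -2.0);
    mat R2;
    vec t2;
    double rms2;
    kabsch_core(P, Q, R2, t2, rms2, &w);
    vec d2 = all_dists(P, Q, R2, t2);
    double s2 = tm_sum(d2, d0);
    if (s2 <= best + 1e-12) break;
    best = s2;
    d = d2;
  }
  return best;
}

// TM objective search: the same fragment-seeded scheme as the GDT search,
// with iteratively reweighted local refinement of each seed's initial
// fragment fit and of its best iterate.
static double tm_search(const mat& P, const mat& Q, double d0, int max_iter) {
  const uword n = P.n_rows;
  std::vector<uvec> seeds;
  seeds.push_back(regspace<uvec>(0, n - 1));
  for (uword w = 3; w <= 7 && w <= n; ++w)
    for (uword s = 0; s + w <= n; ++s)
      seeds.push_back(regspace<uvec>(s, s + w - 1));

  double best = -1.0;
  double cutoff = std::max(d0, 1.0);
  mat R;
  vec t;
  double rms_sub;
  // polish once per distinct converged subset: seeds falling into the
  // same inclusion fixed point share a basin, so re-polishing is wasted
  std::set<std::vector<uword>> polished;
  for (const uvec& seed : seeds) {
    uvec sub = seed;
    mat seedR;
    vec seedT;
    double seed_best = -1.0;
    for (int it = 0; it < max_iter; ++it) {
      subset_superpose(P, Q, sub, R, t, rms_sub);
      vec d = all_dists(P, Q, R, t);
      double s = tm_sum(d, d0);
      if (s > seed_best) {
        seed_best = s;
        seedR = R;
        seedT = t;
      }
      uvec nsub = find(d <= cutoff);
      if (nsub.n_elem < 3) {
        uvec ord = sort_index(d);
        nsub = sort(ord.head(3));
      }
      if (nsub.n_elem == sub.n_elem && accu(nsub != sub) == 0) break;
      sub = nsub;
    }
    std::vector<uword> key = conv_to<std::vector<uword>>::from(sub);
    if (polished.insert(key).second) {
      double cand = tm_polish(P, Q, d0, seedR, seedT);
      if (cand > best) best = cand;
    } else if (seed_best > best) {
      best = tm_polish(P, Q, d0, seedR, seedT);
    }
  }
  return best;
}

// Combined scores for one aligned (model, reference) pair.
// P, Q: aligned coordinates in correspondence order; lref: full reference
// length (denominator for GDT_TS and TM-score); d0: TM-score scale.
// [[Rcpp::export]]
Rcpp::List cpp_pair_scores(const arma::mat& P, const arma::mat& Q,
                           const int lref, const double d0,
                           const Rcpp::NumericVector& gdt_thresholds,
                           const int max_iter = 20) {
  if (P.n_rows != Q.n_rows) Rcpp::stop("coordinate sets differ in length");
  if (P.n_rows < 3) Rcpp::stop("insufficient points");
  mat R;
  vec t;
  double rmsd;
  kabsch_core(P, Q, R, t, rmsd);

  Rcpp::NumericVector frac(gdt_thresholds.size());
  if (P.n_rows <= 14) {
    std::vector<SeedSearchResult> best(gdt_thresholds.size());
    for (auto& b : best) {
      b.best_count = 0;
      b.best_rms = datum::inf;
    }
    gdt_exact_all(P, Q, gdt_thresholds, best);
    for (int k = 0; k < gdt_thresholds.size(); ++k)
      frac[k] = static_cast<double>(best[k].best_count) / lref;
  } else {
    for (int k = 0; k < gdt_thresholds.size(); ++k) {
      SeedSearchResult r = gdt_threshold_search(P, Q, gdt_thresholds[k],
                                                max_iter);
      frac[k] = static_cast<double>(r.best_count) / lref;
    }
  }
  double tm = tm_search(P, Q, d0, max_iter) / lref;
  return Rcpp::List::create(Rcpp::Named("rmsd") = rmsd,
                            Rcpp::Named("gdt_fractions") = frac,
                            Rcpp::Named("tm") = tm);
}

// [[Rcpp::export]]
double cpp_rmsd(const arma::mat& P, const arma::mat& Q) {
  mat R;
  vec t;
  double rmsd;
  if (P.n_rows < 3) Rcpp::stop("insufficient points");
  if (P.n_rows != Q.n_rows) Rcpp::stop("coordinate sets differ in length");
  kabsch_core(P, Q, R, t, rmsd);
  return rmsd;
}
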