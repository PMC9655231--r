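#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Poisson log likelihood ratio of a scan window, clamped one-sided (high
// clusters only): 0 when c <= mu.
static inline double window_llr(double c, double mu, double C) {
  if (c <= mu || mu <= 0.0 || mu >= C) return 0.0;
  double ll = c * std::log(c / mu);
  if (C > c) ll += (C - c) * std::log((C - c) / (C - mu));
  return ll;
}

// Score every enumerated window on one field. Windows are distance-ordered
// prefixes per center: ord_flat holds 0-based unit indices, ord_off the
// per-center offsets, b_flat the valid prefix lengths (tie-group ends under
// the population cap), b_off their offsets.
// [[Rcpp::export(rng = false)]]
List scan_score_cpp(IntegerVector ord_flat, IntegerVector ord_off,
                    IntegerVector b_flat, IntegerVector b_off,
                    NumericVector values, NumericVector pop,
                    double C, double P) {
  int ncent = ord_off.size() - 1;
  int m = b_flat.size();
  IntegerVector w_center(m), w_len(m);
  NumericVector w_cases(m), w_pop(m), w_llr(m);
  int out = 0;
  for (int i = 0; i < ncent; ++i) {
    double cum_v = 0.0, cum_p = 0.0;
    int o0 = ord_off[i];
    int b0 = b_off[i], b1 = b_off[i + 1];
    int pos = 0;
    for (int b = b0; b < b1; ++b) {
      int len = b_flat[b];
      for (; pos < len; ++pos) {
        int u = ord_flat[o0 + pos];
        cum_v += values[u];
        cum_p += pop[u];
      }
      double mu = C * cum_p / P;
      w_center[out] = i + 1;
      w_len[out] = len;
      w_cases[out] = cum_v;
      w_pop[out] = cum_p;
      w_llr[out] = window_llr(cum_v, mu, C);
      ++out;
    }
  }
  return List::create(_["center"] = w_center, _["len"] = w_len,
                      _["cases"] = w_cases, _["pop"] = w_pop,
                      _["llr"] = w_llr);
}

// Maximum window log-LR for each column of V (permuted fields).
// [[Rcpp::export(rng = false)]]
NumericVector scan_null_max_cpp(IntegerVector ord_flat, IntegerVector ord_off,
                                IntegerVector b_flat, IntegerVector b_off,
                                NumericMatrix V, NumericVector pop,
                                double C, double P) {
  int ncent = ord_off.size() - 1;
  int nsim = V.ncol();
  NumericVector out(nsim);
  for (int s = 0; s < nsim; ++s) {
    NumericMatrix::Column v = V(_, s);
    double best = 0.0;
    for (int i = 0; i < ncent; ++i) {
      double cum_v = 0.0, cum_p = 0.0;
      int o0 = ord_off[i];
      int pos = 0;
      for (int b = b_off[i]; b < b_off[i + 1]; ++b) {
        int len = b_flat[b];
        for (; pos < len; ++pos) {
          int u = ord_flat[o0 + pos];
          cum_v += v[u];
          cum_p += pop[u];
        }
        double ll = window_llr(cum_v, C * cum_p / P, C);
        if (ll > best) best = ll;
      }
    }
    out[s] = best;
  }
  return out;
}

// ---- AMOEBA ecotope growth -------------------------------------------------

// z-score of the G* statistic of a W-unit neighbourhood with value sum `sum`
// under the randomization hypothesis (binary weights, self included).
static inline double gstar_z(double sum, int W, int n, double xbar, double s) {
  return (sum - W * xbar) / (s * std::sqrt(W * (double)(n - W) / (n - 1.0)));
}

struct GrowScratch {
  std::vector<int> in_s, excl, seen;   // stamped with the growth id
  std::vector<int> members, frontier;
  GrowScratch(int n) : in_s(n, -1), excl(n, -1), seen(n, -1) {}
};

// Grow one ecotope from `seed` (0-based). Each round ranks the frontier by
// value (ties: lower index) and takes the prefix maximizing the G* z-score;
// rejected frontier units are excluded from all later rounds. Stops when no
// addition strictly increases the statistic.
static double grow_one(int seed, const double *v, int n,
                       const int *nbr_flat, const int *nbr_off,
                       double xbar, double s, int stamp, GrowScratch &sc,
                       int *generation_out, std::vector<int> *members_out) {
  sc.members.clear();
  sc.members.push_back(seed);
  sc.in_s[seed] = stamp;
  double sum_s = v[seed];
  int W = 1, gen = 0;
  double z_cur = gstar_z(sum_s, W, n, xbar, s);
  for (;;) {
    // frontier = first-order neighbours of the ecotope, minus excluded
    sc.frontier.clear();
    for (size_t mi = 0; mi < sc.members.size(); ++mi) {
      int u = sc.members[mi];
      for (int k = nbr_off[u]; k < nbr_off[u + 1]; ++k) {
        int nb = nbr_flat[k];
        if (sc.in_s[nb] != stamp && sc.excl[nb] != stamp && sc.seen[nb] != stamp) {
          sc.seen[nb] = stamp;
          sc.frontier.push_back(nb);
        }
      }
    }
    if (sc.frontier.empty()) break;
    std::sort(sc.frontier.begin(), sc.frontier.end(),
              [&](int a, int b) { return v[a] > v[b] || (v[a] == v[b] && a < b); });
    int best_k = 0;
    double best_z = z_cur, cum = sum_s;
    int F = (int)sc.frontier.size();
    for (int k = 1; k <= F; ++k) {
      if (W + k >= n) break;  // the whole-lattice ecotope has no variance
      cum += v[sc.frontier[k - 1]];
      double z = gstar_z(cum, W + k, n, xbar, s);
      if (z > best_z) { best_z = z; best_k = k; }
    }
    if (best_k == 0) break;
    for (int k = 0; k < best_k; ++k) {
      int u = sc.frontier[k];
      sc.in_s[u] = stamp;
      sc.members.push_back(u);
      sum_s += v[u];
    }
    for (int k = best_k; k < F; ++k) sc.excl[sc.frontier[k]] = stamp;
    W += best_k;
    z_cur = best_z;
    ++gen;
  }
  if (generation_out) *generation_out = gen;
  if (members_out) *members_out = sc.members;
  return z_cur;
}

// Grow ecotopes from every seed on the observed field.
// [[Rcpp::export(rng = false)]]
List amoeba_grow_cpp(IntegerVector nbr_flat, IntegerVector nbr_off,
                     NumericVector values, IntegerVector seeds,
                     double xbar, double s, bool want_members) {
  int n = nbr_off.size() - 1;
  int ns = seeds.size();
  NumericVector z(ns);
  IntegerVector size(ns), gen(ns);
  List members(want_members ? ns : 0);
  GrowScratch sc(n);
  std::vector<int> mem;
  for (int i = 0; i < ns; ++i) {
    int g = 0;
    z[i] = grow_one(seeds[i], REAL(values), n, INTEGER(nbr_flat),
                    INTEGER(nbr_off), xbar, s, i, sc, &g,
                    want_members ? &mem : (std::vector<int> *)nullptr);
    gen[i] = g;
    if (want_members) {
      IntegerVector mv(mem.size());
      for (size_t k = 0; k < mem.size(); ++k) mv[k] = mem[k] + 1;  // 1-based
      members[i] = mv;
      size[i] = mv.size();
    } else {
      size[i] = NA_INTEGER;
    }
  }
  List out = List::create(_["z"] = z, _["size"] = size, _["generation"] = gen);
  if (want_members) out["members"] = members;
  return out;
}

// Null G* z-scores: regrow from every seed on each simulated field (columns
// of V), standardizing by each field's own moments. Returns a
// (seeds x nsim) matrix.
// [[Rcpp::export(rng = false)]]
NumericMatrix amoeba_null_cpp(IntegerVector nbr_flat, IntegerVector nbr_off,
                              NumericMatrix V, IntegerVector seeds) {
  int n = nbr_off.size() - 1;
  int ns = seeds.size(), nsim = V.ncol();
  NumericMatrix out(ns, nsim);
  GrowScratch sc(n);
  int stamp = 0;
  for (int c = 0; c < nsim; ++c) {
    const double *v = &V(0, c);
    double xbar = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) xbar += v[i];
    xbar /= n;
    for (int i = 0; i < n; ++i) s2 += (v[i] - xbar) * (v[i] - xbar);
    double s = std::sqrt(s2 / n);
    for (int i = 0; i < ns; ++i) {
      out(i, c) = s > 0.0
        ? grow_one(seeds[i], v, n, INTEGER(nbr_flat), INTEGER(nbr_off),
                   xbar, s, stamp++, sc, nullptr, nullptr)
        : 0.0;
    }
  }
  return out;
}
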