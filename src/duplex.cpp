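// Intermolecular RNA-RNA duplex minimum-free-energy dynamic program.
//
// Bases are encoded A=0, C=1, G=2, U=3.  x is the lncRNA 5'->3'; yr is the
// mRNA already reversed, so index j counts from the mRNA's 3' end and
// admissible pairings are monotone in (i, j).
//
// H(i, j) = best energy of a duplex whose rightmost pair is (i, j):
//   H(i,j) = min( init + term(i,j),
//                 min over 1 <= k, l <= max_loop + 1 of
//                   H(i-k, j-l) + [ stack((i-k,j-l),(i,j))    if k = l = 1
//                                   loop_base
//                                     + loop_slope*(k-1 + l-1) otherwise ] )
// MFE = min over admissible (i, j) of H(i, j) + term(i, j).
//
// An exhaustive enumeration of every monotone pairing (duplex_enum_cpp) is
// compiled alongside as an independent test oracle for short sequences.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// pair type over (top base, bottom base): AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 none
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// [[Rcpp::export]]
List duplex_mfe_cpp(IntegerVector x, IntegerVector yr, NumericMatrix stack,
                    NumericVector term, double init, double loop_base,
                    double loop_slope, int max_loop) {
  const int n = x.size(), m = yr.size();
  const int L = max_loop + 1;
  std::vector<double> H((size_t)(n + 1) * (m + 1), INF);
  std::vector<int> Pi((size_t)(n + 1) * (m + 1), 0), Pj((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> ptype((size_t)(n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      ptype[at(i, j)] = pair_type(x[i - 1], yr[j - 1]);

  double best = INF;
  int best_i = 0, best_j = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int t = ptype[at(i, j)];
      if (t < 0) continue;
      double h = init + term[t];
      int pi = 0, pj = 0;
      const int kmax = std::min(L, i - 1), lmax = std::min(L, j - 1);
      for (int k = 1; k <= kmax; ++k) {
        for (int l = 1; l <= lmax; ++l) {
          const size_t prev = at(i - k, j - l);
          if (H[prev] == INF) continue;
          double ext;
          if (k == 1 && l == 1)
            ext = stack(ptype[prev], t);
          else
            ext = loop_base + loop_slope * ((k - 1) + (l - 1));
          const double cand = H[prev] + ext;
          if (cand < h) { h = cand; pi = i - k; pj = j - l; }
        }
      }
      H[at(i, j)] = h;
      Pi[at(i, j)] = pi;
      Pj[at(i, j)] = pj;
      const double closed = h + term[t];
      if (closed < best) { best = closed; best_i = i; best_j = j; }
    }
  }

  if (best == INF)
    return List::create(Named("no_duplex") = true);

  std::vector<int> pis, pjs;
  int ci = best_i, cj = best_j;
  while (ci > 0) {
    pis.push_back(ci);
    pjs.push_back(cj);
    const int ni = Pi[at(ci, cj)], nj = Pj[at(ci, cj)];
    ci = ni; cj = nj;
  }
  std::reverse(pis.begin(), pis.end());
  std::reverse(pjs.begin(), pjs.end());
  return List::create(Named("no_duplex") = false, Named("mfe") = best,
                      Named("pair_i") = wrap(pis), Named("pair_j") = wrap(pjs));
}

// ----------------------------------------------------------------- oracle

struct EnumCtx {
  const IntegerVector* x;
  const IntegerVector* yr;
  const NumericMatrix* stack;
  const NumericVector* term;
  double init, loop_base, loop_slope;
  int max_loop, n, m;
  double best;
};

// extend a chain whose last pair is (i, j) with accumulated open energy e
static void enum_extend(EnumCtx& c, int i, int j, int last_t, double e) {
  // option: close here
  const double closed = e + (*c.term)[last_t];
  if (closed < c.best) c.best = closed;
  const int L = c.max_loop + 1;
  for (int k = 1; k <= L && i + k <= c.n; ++k) {
    for (int l = 1; l <= L && j + l <= c.m; ++l) {
      const int t = pair_type((*c.x)[i + k - 1], (*c.yr)[j + l - 1]);
      if (t < 0) continue;
      double ext = (k == 1 && l == 1)
        ? (*c.stack)(last_t, t)
        : c.loop_base + c.loop_slope * ((k - 1) + (l - 1));
      enum_extend(c, i + k, j + l, t, e + ext);
    }
  }
}

// [[Rcpp::export]]
List duplex_enum_cpp(IntegerVector x, IntegerVector yr, NumericMatrix stack,
                     NumericVector term, double init, double loop_base,
                     double loop_slope, int max_loop) {
  EnumCtx c{&x, &yr, &stack, &term, init, loop_base, loop_slope, max_loop,
            (int)x.size(), (int)yr.size(), INF};
  for (int i = 1; i <= c.n; ++i) {
    for (int j = 1; j <= c.m; ++j) {
      const int t = pair_type(x[i - 1], yr[j - 1]);
      if (t < 0) continue;
      enum_extend(c, i, j, t, init + term[t]);
    }
  }
  if (c.best == INF) return List::create(Named("no_duplex") = true);
  return List::create(Named("no_duplex") = false, Named("mfe") = c.best);
}
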