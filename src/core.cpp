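#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Vietoris-Rips filtration and persistence by boundary-matrix reduction over
// the field with two elements.  Simplices are ordered by (filtration value,
// dimension, lexicographic vertex tuple), which makes reduction, pairing and
// representative cycles fully deterministic.
// ---------------------------------------------------------------------------

namespace {

struct Simp {
  double val;
  int dim;        // simplex dimension, 0..4
  int v[5];       // vertices, ascending, 0-based; only v[0..dim] used
};

inline bool simp_less(const Simp &a, const Simp &b) {
  if (a.val != b.val) return a.val < b.val;
  if (a.dim != b.dim) return a.dim < b.dim;
  for (int i = 0; i <= a.dim; ++i)
    if (a.v[i] != b.v[i]) return a.v[i] < b.v[i];
  return false;
}

// pack a vertex tuple into one 64-bit key (12 bits per vertex, so n < 4095)
inline uint64_t simp_key(const int *v, int dim) {
  uint64_t k = 0;
  for (int i = 0; i <= dim; ++i) k = (k << 12) | (uint64_t)(v[i] + 1);
  return k;
}

// symmetric difference of two ascending index vectors (column addition mod 2)
inline void sym_diff(std::vector<int> &a, const std::vector<int> &b,
                     std::vector<int> &tmp) {
  tmp.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) tmp.push_back(a[i++]);
    else if (b[j] < a[i]) tmp.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) tmp.push_back(a[i++]);
  while (j < b.size()) tmp.push_back(b[j++]);
  a.swap(tmp);
}

} // namespace

// Build the Rips filtration of a dissimilarity matrix up to simplex
// dimension max_dim + 1 (enough to compute homology through max_dim),
// restricted to filtration value <= max_radius.
// [[Rcpp::export]]
List rips_filtration_cpp(NumericMatrix d, int max_dim, double max_radius) {
  const int n = d.nrow();
  if (n >= 4094) stop("too many items for the simplex encoding (n must be < 4094)");
  const int D = max_dim + 1; // top simplex dimension
  std::vector<Simp> S;
  S.reserve((size_t)n * 8);

  for (int i = 0; i < n; ++i) {
    Simp s; s.val = 0.0; s.dim = 0; s.v[0] = i;
    S.push_back(s);
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double e = d(i, j);
      if (e <= max_radius) {
        Simp s; s.val = e; s.dim = 1; s.v[0] = i; s.v[1] = j;
        S.push_back(s);
      }
    }
  if (D >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = d(i, j);
        if (dij > max_radius) continue;
        for (int k = j + 1; k < n; ++k) {
          double e = std::max(dij, std::max(d(i, k), d(j, k)));
          if (e <= max_radius) {
            Simp s; s.val = e; s.dim = 2;
            s.v[0] = i; s.v[1] = j; s.v[2] = k;
            S.push_back(s);
          }
        }
      }
  }
  if (D >= 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (d(i, j) > max_radius) continue;
        for (int k = j + 1; k < n; ++k) {
          double e3 = std::max(d(i, j), std::max(d(i, k), d(j, k)));
          if (e3 > max_radius) continue;
          for (int l = k + 1; l < n; ++l) {
            double e = std::max(e3, std::max(d(i, l), std::max(d(j, l), d(k, l))));
            if (e <= max_radius) {
              Simp s; s.val = e; s.dim = 3;
              s.v[0] = i; s.v[1] = j; s.v[2] = k; s.v[3] = l;
              S.push_back(s);
            }
          }
        }
      }
  }
  if (D >= 4) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (d(i, j) > max_radius) continue;
        for (int k = j + 1; k < n; ++k) {
          double e3 = std::max(d(i, j), std::max(d(i, k), d(j, k)));
          if (e3 > max_radius) continue;
          for (int l = k + 1; l < n; ++l) {
            double e4 = std::max(e3, std::max(d(i, l), std::max(d(j, l), d(k, l))));
            if (e4 > max_radius) continue;
            for (int m = l + 1; m < n; ++m) {
              double e = std::max(e4, std::max(std::max(d(i, m), d(j, m)),
                                               std::max(d(k, m), d(l, m))));
              if (e <= max_radius) {
                Simp s; s.val = e; s.dim = 4;
                s.v[0] = i; s.v[1] = j; s.v[2] = k; s.v[3] = l; s.v[4] = m;
                S.push_back(s);
              }
            }
          }
        }
      }
  }

  std::sort(S.begin(), S.end(), simp_less);

  const int nS = (int)S.size();
  IntegerMatrix verts(nS, D + 1);
  std::fill(verts.begin(), verts.end(), NA_INTEGER);
  NumericVector value(nS);
  IntegerVector dim(nS);
  for (int s = 0; s < nS; ++s) {
    value[s] = S[s].val;
    dim[s] = S[s].dim;
    for (int i = 0; i <= S[s].dim; ++i) verts(s, i) = S[s].v[i] + 1;
  }
  return List::create(_["vertices"] = verts, _["value"] = value,
                      _["dim"] = dim, _["n"] = n);
}

// Persistence of an explicit filtration by column reduction over GF(2).
// verts: 1-based vertex tuples (NA padded), sorted per the filtration order.
// top_dim: highest homology dimension to report.
// Returns the diagram (zero-persistence features dropped, unpaired features
// capped at max_radius) and, optionally, representative cycles for loops.
// [[Rcpp::export]]
List reduce_filtration_cpp(IntegerMatrix verts, NumericVector value,
                           IntegerVector dim, double max_radius, int top_dim,
                           bool want_cycles, bool twist) {
  const int nS = verts.nrow();
  int maxd = 0;
  for (int s = 0; s < nS; ++s) maxd = std::max(maxd, dim[s]);

  // key -> filtration index, for facet lookup
  std::unordered_map<uint64_t, int> index_of;
  index_of.reserve((size_t)nS * 2);
  {
    int vbuf[5];
    for (int s = 0; s < nS; ++s) {
      for (int i = 0; i <= dim[s]; ++i) vbuf[i] = verts(s, i) - 1;
      index_of[simp_key(vbuf, dim[s])] = s;
    }
  }

  auto boundary = [&](int s, std::vector<int> &out) {
    out.clear();
    const int ds = dim[s];
    if (ds == 0) return;
    int vbuf[5], fbuf[5];
    for (int i = 0; i <= ds; ++i) vbuf[i] = verts(s, i) - 1;
    for (int drop = 0; drop <= ds; ++drop) {
      int m = 0;
      for (int i = 0; i <= ds; ++i)
        if (i != drop) fbuf[m++] = vbuf[i];
      std::unordered_map<uint64_t, int>::iterator it =
          index_of.find(simp_key(fbuf, ds - 1));
      if (it == index_of.end()) stop("filtration is missing a facet simplex");
      out.push_back(it->second);
    }
    std::sort(out.begin(), out.end());
  };

  std::vector<std::vector<int> > R(nS);   // reduced columns
  std::vector<std::vector<int> > V1;       // chain columns for edges (cycles)
  if (want_cycles) V1.resize(nS);
  std::vector<int> low_owner(nS, -1);      // pivot row -> owning column
  std::vector<int> pair_death(nS, -1);     // birth column -> death column
  std::vector<char> is_zero(nS, 0);        // column reduced to zero (a birth)
  std::vector<char> cleared(nS, 0);        // known-zero via the twist

  std::vector<int> col, tmp, vtmp;

  auto reduce_col = [&](int j) {
    if (cleared[j]) { is_zero[j] = 1; return; }
    boundary(j, col);
    const bool track = want_cycles && dim[j] == 1;
    if (track) { V1[j].clear(); V1[j].push_back(j); }
    while (!col.empty()) {
      int piv = col.back();
      int k = low_owner[piv];
      if (k < 0) {
        low_owner[piv] = j;
        pair_death[piv] = j;
        if (twist) cleared[piv] = 1;
        break;
      }
      sym_diff(col, R[k], tmp);
      if (track) sym_diff(V1[j], V1[k], vtmp);
    }
    if (col.empty()) is_zero[j] = 1;
    R[j] = col;
  };

  if (twist) {
    for (int d = maxd; d >= 1; --d)
      for (int j = 0; j < nS; ++j)
        if (dim[j] == d) reduce_col(j);
  } else {
    for (int j = 0; j < nS; ++j)
      if (dim[j] >= 1) reduce_col(j);
  }

  // assemble features
  std::vector<int> fdim;
  std::vector<double> fbirth, fdeath;
  std::vector<char> fcap;
  std::vector<int> fcycle_src; // birth column of kept dim-1 features, else -1

  for (int j = 0; j < nS; ++j) {
    const int dj = dim[j];
    if (dj > top_dim) continue;
    bool is_birth = (dj == 0) || is_zero[j];
    if (!is_birth) continue;
    double b = value[j];
    double dth;
    bool cap = false;
    if (pair_death[j] >= 0) dth = value[pair_death[j]];
    else { dth = max_radius; cap = true; }
    if (dth == b) continue; // zero persistence: invisible in the diagram
    fdim.push_back(dj);
    fbirth.push_back(b);
    fdeath.push_back(dth);
    fcap.push_back(cap ? 1 : 0);
    fcycle_src.push_back(dj == 1 ? j : -1);
  }

  // deterministic diagram order: (dim, birth, death)
  const int nf = (int)fdim.size();
  std::vector<int> ord(nf);
  for (int i = 0; i < nf; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (fdim[a] != fdim[b]) return fdim[a] < fdim[b];
    if (fbirth[a] != fbirth[b]) return fbirth[a] < fbirth[b];
    return fdeath[a] < fdeath[b];
  });

  IntegerVector odim(nf);
  NumericVector obirth(nf), odeath(nf);
  LogicalVector ocap(nf);
  List ocycles(want_cycles ? nf : 0);

  for (int i = 0; i < nf; ++i) {
    int s = ord[i];
    odim[i] = fdim[s];
    obirth[i] = fbirth[s];
    odeath[i] = fdeath[s];
    ocap[i] = (bool)fcap[s];
    if (want_cycles && fcycle_src[s] >= 0) {
      int j = fcycle_src[s];
      // paired loop: the reduced column of its death simplex is a cycle of
      // edges whose latest edge is the birth edge; essential loop: the chain
      // accumulated in V while the birth column reduced to zero.
      const std::vector<int> &edges =
          (pair_death[j] >= 0) ? R[pair_death[j]] : V1[j];
      int m = (int)edges.size();
      IntegerMatrix em(m, 2);
      for (int e = 0; e < m; ++e) {
        em(e, 0) = verts(edges[e], 0);
        em(e, 1) = verts(edges[e], 1);
      }
      ocycles[i] = em;
    }
  }

  List out = List::create(_["dimension"] = odim, _["birth"] = obirth,
                          _["death"] = odeath, _["death_capped"] = ocap);
  if (want_cycles) out["cycles"] = ocycles;
  return out;
}

// ---------------------------------------------------------------------------
// Exact bottleneck distance between two persistence diagrams (one dimension).
// Binary search over the finite candidate-cost set {persistence/2 values,
// pairwise L-infinity costs}; feasibility at cost c reduces to two bipartite
// matchings: every feature with persistence > 2c on either side must be
// matched across at L-infinity cost <= c (Mendelsohn-Dulmage guarantees the
// two one-sided matchings combine into one).
// ---------------------------------------------------------------------------

namespace {

struct Kuhn {
  int nl, nr;
  const std::vector<std::vector<int> > *adj;
  std::vector<int> match_l, match_r;
  std::vector<char> used;

  bool try_aug(int u) {
    for (size_t t = 0; t < (*adj)[u].size(); ++t) {
      int v = (*adj)[u][t];
      if (used[v]) continue;
      used[v] = 1;
      if (match_r[v] < 0 || try_aug(match_r[v])) {
        match_l[u] = v;
        match_r[v] = u;
        return true;
      }
    }
    return false;
  }

  // returns true iff every left vertex can be matched
  bool saturates(const std::vector<std::vector<int> > &a, int nleft, int nright) {
    nl = nleft; nr = nright; adj = &a;
    match_l.assign(nl, -1);
    match_r.assign(nr, -1);
    for (int u = 0; u < nl; ++u) {
      used.assign(nr, 0);
      if (!try_aug(u)) return false;
    }
    return true;
  }
};

} // namespace

// [[Rcpp::export]]
List bottleneck_cpp(NumericMatrix A, NumericMatrix B, bool want_matching) {
  const int n1 = A.nrow(), n2 = B.nrow();
  std::vector<double> pa(n1), pb(n2); // persistence / 2 (diagonal costs)
  for (int i = 0; i < n1; ++i) pa[i] = (A(i, 1) - A(i, 0)) / 2.0;
  for (int j = 0; j < n2; ++j) pb[j] = (B(j, 1) - B(j, 0)) / 2.0;

  std::vector<std::vector<double> > cost(n1, std::vector<double>(n2));
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      cost[i][j] = std::max(std::fabs(A(i, 0) - B(j, 0)),
                            std::fabs(A(i, 1) - B(j, 1)));

  std::vector<double> cand;
  cand.reserve((size_t)n1 * n2 + n1 + n2 + 1);
  cand.push_back(0.0);
  cand.insert(cand.end(), pa.begin(), pa.end());
  cand.insert(cand.end(), pb.begin(), pb.end());
  for (int i = 0; i < n1; ++i)
    cand.insert(cand.end(), cost[i].begin(), cost[i].end());
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  Kuhn kuhn;

  // matching covering all persistence-forced features on one side
  auto side_ok = [&](double c, bool a_side,
                     std::vector<int> *forced_out,
                     std::vector<int> *match_out) -> bool {
    const int nf_all = a_side ? n1 : n2;
    const int n_other = a_side ? n2 : n1;
    std::vector<int> forced;
    for (int i = 0; i < nf_all; ++i)
      if ((a_side ? pa[i] : pb[i]) > c) forced.push_back(i);
    std::vector<std::vector<int> > adj(forced.size());
    for (size_t u = 0; u < forced.size(); ++u) {
      int i = forced[u];
      for (int j = 0; j < n_other; ++j) {
        double cc = a_side ? cost[i][j] : cost[j][i];
        if (cc <= c) adj[u].push_back(j);
      }
    }
    bool ok = kuhn.saturates(adj, (int)forced.size(), n_other);
    if (ok && forced_out) *forced_out = forced;
    if (ok && match_out) *match_out = kuhn.match_l;
    return ok;
  };

  auto feasible = [&](double c) -> bool {
    return side_ok(c, true, NULL, NULL) && side_ok(c, false, NULL, NULL);
  };

  double value;
  if (n1 == 0 && n2 == 0) {
    value = 0.0;
  } else {
    int lo = 0, hi = (int)cand.size() - 1; // cand[hi] is always feasible
    while (lo < hi) {
      int mid = lo + (hi - lo) / 2;
      if (feasible(cand[mid])) hi = mid; else lo = mid + 1;
    }
    value = cand[lo];
  }

  List out = List::create(_["value"] = value);

  if (want_matching) {
    // combine the two one-sided matchings (Mendelsohn-Dulmage): start from
    // the A-side matching, then re-route along alternating paths so every
    // forced B feature is covered too.
    std::vector<int> forcedA, mA, forcedB, mB;
    side_ok(value, true, &forcedA, &mA);
    side_ok(value, false, &forcedB, &mB);
    std::vector<int> m_ab(n1, -1), m_ba(n2, -1);
    for (size_t u = 0; u < forcedA.size(); ++u) {
      m_ab[forcedA[u]] = mA[u];
      m_ba[mA[u]] = forcedA[u];
    }
    std::vector<int> m2_ba(n2, -1), m2_ab(n1, -1);
    for (size_t u = 0; u < forcedB.size(); ++u) {
      m2_ba[forcedB[u]] = mB[u];
      m2_ab[mB[u]] = forcedB[u];
    }
    for (size_t u = 0; u < forcedB.size(); ++u) {
      int j = forcedB[u];
      while (j >= 0 && m_ba[j] < 0 && m2_ba[j] >= 0) {
        // give j its M2 partner; if that partner was matched elsewhere in
        // M1, release and re-route that B vertex the same way
        int i = m2_ba[j];
        int j_next = m_ab[i];
        m_ab[i] = j;
        m_ba[j] = i;
        if (j_next >= 0) m_ba[j_next] = -1;
        j = j_next;
      }
    }
    IntegerMatrix match(n1 + n2, 2);
    int rowi = 0;
    for (int i = 0; i < n1; ++i) {
      match(rowi, 0) = i + 1;
      match(rowi, 1) = m_ab[i] >= 0 ? m_ab[i] + 1 : NA_INTEGER;
      ++rowi;
    }
    for (int j = 0; j < n2; ++j)
      if (m_ba[j] < 0) {
        match(rowi, 0) = NA_INTEGER;
        match(rowi, 1) = j + 1;
        ++rowi;
      }
    out["matching"] = match(Range(0, rowi - 1), Range(0, 1));
  }
  return out;
}
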