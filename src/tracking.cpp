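// Core combinatorial machinery for multiple-hypothesis hypergraph tracking:
//  - rectangular linear assignment (shortest augmenting path with duals),
//  - Murty's ranked K-best assignment enumeration,
//  - the depth-N deferred-decision search over gated K-best posture
//    hypotheses with graphical interpolation of missed detections,
//    self-intersection pruning and covariance-weighted cost models.
//
// The search expands ~K^N assignment problems per committed frame, which is
// why this lives in compiled code; the R layer exposes thin wrappers and
// keeps independent reference implementations of the cost models. Gating
// makes each assignment problem sparse (a handful of admissible detections
// per nucleus), so the solver iterates adjacency lists, not full matrices.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e12;          // forbidden-arc cost
static const double INF_D = std::numeric_limits<double>::infinity();
static const double TIE_EPS = 1e-9;      // deterministic lowest-index tie-break

// ---------------------------------------------------------------------------
// Sparse rectangular LAP, shortest augmenting paths with dual potentials.
// Requires non-negative arc costs (callers shift rows when needed).
// ---------------------------------------------------------------------------

struct Arc { int col; double w; };

struct SparseLap {
  int n, mc;
  const std::vector<std::vector<Arc> >* adj;             // per-row finite arcs
  const std::vector<std::pair<int, int> >* excluded;     // may be null
  std::vector<char> active;                              // per column
  std::vector<double> u, v;
  std::vector<int> rowsol, colsol;                       // -1 = unassigned
  // scratch buffers reused across augmentations (hot path)
  std::vector<double> d;
  std::vector<int> pred;
  std::vector<char> in_sc;
  std::vector<int> touched, sr;

  SparseLap(int n_, int mc_, const std::vector<std::vector<Arc> >* adj_)
      : n(n_), mc(mc_), adj(adj_), excluded(0), active(mc_, 1),
        u(n_, 0.0), v(mc_, 0.0), rowsol(n_, -1), colsol(mc_, -1),
        d(mc_, INF_D), pred(mc_, -1), in_sc(mc_, 0) {}

  inline bool is_excluded(int i, int j) const {
    if (!excluded) return false;
    for (size_t k = 0; k < excluded->size(); ++k)
      if ((*excluded)[k].first == i && (*excluded)[k].second == j) return true;
    return false;
  }

  // Augment free row f; Dijkstra over alternating paths with final dual
  // update (scipy-style). Returns false when no finite path exists.
  bool augment(int f) {
    for (size_t k = 0; k < touched.size(); ++k) {
      d[touched[k]] = INF_D;
      in_sc[touched[k]] = 0;
    }
    touched.clear();
    sr.clear();
    double minVal = 0.0;
    int cur = f, sink = -1;
    while (sink < 0) {
      sr.push_back(cur);
      const std::vector<Arc>& arcs = (*adj)[cur];
      for (size_t k = 0; k < arcs.size(); ++k) {
        int j = arcs[k].col;
        if (!active[j] || in_sc[j]) continue;
        if (is_excluded(cur, j)) continue;
        double r = minVal + arcs[k].w - u[cur] - v[j];
        if (r < d[j]) {
          if (d[j] == INF_D) touched.push_back(j);
          d[j] = r;
          pred[j] = cur;
        }
      }
      int jstar = -1;
      double dmin = INF_D;
      for (size_t k = 0; k < touched.size(); ++k) {
        int j = touched[k];
        if (!in_sc[j] && d[j] < dmin) { dmin = d[j]; jstar = j; }
      }
      if (jstar < 0 || dmin >= BIG) return false;
      in_sc[jstar] = 1;
      minVal = dmin;
      if (colsol[jstar] < 0) sink = jstar;
      else cur = colsol[jstar];
    }
    // dual update
    u[f] += minVal;
    for (size_t k = 0; k < sr.size(); ++k) {
      int i = sr[k];
      if (i != f) u[i] += minVal - d[rowsol[i]];
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      int j = touched[k];
      if (in_sc[j]) v[j] -= minVal - d[j];
    }
    // augment along predecessors
    int j = sink;
    while (true) {
      int i = pred[j];
      colsol[j] = i;
      int jnext = rowsol[i];
      rowsol[i] = j;
      if (i == f) break;
      j = jnext;
    }
    return true;
  }
};

// Extract the finite arcs of a dense matrix. Costs must be non-negative
// (callers shift beforehand) so that zero duals are feasible.
static void build_adjacency(const std::vector<double>& base, int n, int mc,
                            std::vector<std::vector<Arc> >& adj) {
  adj.assign(n, std::vector<Arc>());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < mc; ++j) {
      double w = base[(size_t)i * mc + j];
      if (w < BIG) {
        Arc a; a.col = j; a.w = w;
        adj[i].push_back(a);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Murty K-best ranked assignments
// ---------------------------------------------------------------------------

struct MurtyNode {
  std::vector<std::pair<int, int> > forced;    // (row, col)
  std::vector<std::pair<int, int> > excluded;  // (row, col)
  std::vector<int> rowsol;
  double cost;
  std::uint64_t serial;
};

struct MurtyCmp {
  bool operator()(const MurtyNode* a, const MurtyNode* b) const {
    if (a->cost != b->cost) return a->cost > b->cost;
    return a->serial > b->serial;
  }
};

static double solution_cost(const std::vector<double>& base, int mc,
                            const std::vector<int>& rowsol) {
  double c = 0.0;
  for (size_t i = 0; i < rowsol.size(); ++i)
    if (rowsol[i] >= 0) c += base[i * mc + rowsol[i]];
  return c;
}

// Solve a Murty subproblem from scratch: forced arcs pre-assigned and
// their columns deactivated, remaining rows augmented from an empty
// matching with zero duals. (Warm-starting duals from the parent is NOT
// valid for rectangular problems: nonzero duals on unmatched columns
// break the extremeness invariant of successive shortest paths.)
static bool solve_subproblem(const std::vector<double>& base, int n, int mc,
                             const std::vector<std::vector<Arc> >& adj,
                             MurtyNode* node, SparseLap& lap) {
  lap.excluded = &node->excluded;
  std::fill(lap.active.begin(), lap.active.end(), 1);
  std::fill(lap.rowsol.begin(), lap.rowsol.end(), -1);
  std::fill(lap.colsol.begin(), lap.colsol.end(), -1);
  std::fill(lap.u.begin(), lap.u.end(), 0.0);
  std::fill(lap.v.begin(), lap.v.end(), 0.0);
  std::vector<char> locked(n, 0);
  for (size_t k = 0; k < node->forced.size(); ++k) {
    int r = node->forced[k].first, c = node->forced[k].second;
    locked[r] = 1;
    lap.rowsol[r] = c;
    lap.colsol[c] = r;
    lap.active[c] = 0;
  }
  for (int i = 0; i < n; ++i) {
    if (locked[i]) continue;
    if (!lap.augment(i)) return false;
  }
  node->rowsol = lap.rowsol;
  node->cost = solution_cost(base, mc, node->rowsol);
  return node->cost < BIG;
}

static void murty_kbest(const std::vector<double>& base, int n, int mc, int K,
                        std::vector<std::vector<int> >& out_sols,
                        std::vector<double>& out_costs) {
  out_sols.clear();
  out_costs.clear();
  std::vector<std::vector<Arc> > adj;
  build_adjacency(base, n, mc, adj);

  std::priority_queue<MurtyNode*, std::vector<MurtyNode*>, MurtyCmp> pq;
  std::vector<MurtyNode*> all_nodes;
  std::uint64_t serial = 0;

  SparseLap lap(n, mc, &adj);
  MurtyNode* root = new MurtyNode();
  all_nodes.push_back(root);
  if (solve_subproblem(base, n, mc, adj, root, lap)) {
    root->serial = serial++;
    pq.push(root);
  }

  while (!pq.empty() && (int)out_sols.size() < K) {
    MurtyNode* cur = pq.top();
    pq.pop();
    out_sols.push_back(cur->rowsol);
    out_costs.push_back(cur->cost);
    if ((int)out_sols.size() >= K) break;

    std::vector<char> is_forced(n, 0);
    for (size_t k = 0; k < cur->forced.size(); ++k)
      is_forced[cur->forced[k].first] = 1;
    std::vector<std::pair<int, int> > prefix = cur->forced;
    for (int r = 0; r < n; ++r) {
      if (is_forced[r]) continue;
      int c = cur->rowsol[r];
      MurtyNode* ch = new MurtyNode();
      all_nodes.push_back(ch);
      ch->forced = prefix;
      ch->excluded = cur->excluded;
      ch->excluded.push_back(std::make_pair(r, c));
      if (solve_subproblem(base, n, mc, adj, ch, lap)) {
        ch->serial = serial++;
        pq.push(ch);
      }
      prefix.push_back(std::make_pair(r, c));
    }
  }
  for (size_t k = 0; k < all_nodes.size(); ++k) delete all_nodes[k];
}

// [[Rcpp::export(name = ".lap_solve_cpp")]]
List lap_solve_cpp(NumericMatrix cost) {
  int n = cost.nrow(), mc = cost.ncol();
  if (n > mc) stop("cost matrix must have nrow <= ncol");
  std::vector<double> base((size_t)n * mc);
  double cmin = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < mc; ++j) {
      base[(size_t)i * mc + j] = cost(i, j);
      if (cost(i, j) < cmin) cmin = cost(i, j);
    }
  if (cmin < 0.0) {
    // shift all entries: every complete assignment shifts by n * cmin
    for (size_t k = 0; k < base.size(); ++k)
      if (base[k] < BIG) base[k] -= cmin;
  }
  std::vector<std::vector<Arc> > adj;
  build_adjacency(base, n, mc, adj);
  SparseLap lap(n, mc, &adj);
  bool ok = true;
  for (int i = 0; i < n && ok; ++i) ok = lap.augment(i);
  IntegerVector assignment(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    assignment[i] = ok ? lap.rowsol[i] + 1 : NA_INTEGER;
    if (ok && lap.rowsol[i] >= 0) total += cost(i, lap.rowsol[i]);
  }
  return List::create(_["assignment"] = assignment,
                      _["cost"] = ok ? total : NA_REAL,
                      _["feasible"] = ok && total < BIG);
}

// [[Rcpp::export(name = ".murty_cpp")]]
List murty_cpp(NumericMatrix cost, int K) {
  int n = cost.nrow(), mc = cost.ncol();
  if (n > mc) stop("cost matrix must have nrow <= ncol");
  if (K < 1) stop("K must be >= 1");
  std::vector<double> base((size_t)n * mc);
  double cmin = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < mc; ++j) {
      base[(size_t)i * mc + j] = cost(i, j);
      if (cost(i, j) < cmin) cmin = cost(i, j);
    }
  double shift = 0.0;
  if (cmin < 0.0) {
    shift = cmin;
    for (size_t k = 0; k < base.size(); ++k)
      if (base[k] < BIG) base[k] -= shift;
  }
  std::vector<std::vector<int> > sols;
  std::vector<double> costs;
  murty_kbest(base, n, mc, K, sols, costs);
  List out(sols.size());
  for (size_t k = 0; k < sols.size(); ++k) {
    IntegerVector a(n);
    for (int i = 0; i < n; ++i) a[i] = sols[k][i] + 1;
    out[k] = List::create(_["assignment"] = a,
                          _["cost"] = costs[k] + n * shift);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gated assignment problem construction
// ---------------------------------------------------------------------------

// Builds the n x (m + n) gated matrix: squared displacement within the gate,
// forbidden outside; one dedicated MISSING dummy column per object at cost
// gate^2. A tiny index-proportional epsilon makes ties resolve to the lowest
// detection index (and to real detections over MISSING).
static void build_gated(const std::vector<double>& prev,  // n*3
                        const std::vector<double>& det,   // m*3
                        int n, int m, double gate,
                        std::vector<double>& base) {
  double g2 = gate * gate;
  int mc = m + n;
  base.assign((size_t)n * mc, 2.0 * BIG);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = prev[i * 3] - det[j * 3];
      double dy = prev[i * 3 + 1] - det[j * 3 + 1];
      double dz = prev[i * 3 + 2] - det[j * 3 + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= g2) base[(size_t)i * mc + j] = d2 + TIE_EPS * (j + 1);
    }
    base[(size_t)i * mc + (m + i)] = g2 + TIE_EPS * (m + i + 1);
  }
}

// [[Rcpp::export(name = ".gated_murty_cpp")]]
List gated_murty_cpp(NumericMatrix prev, NumericMatrix det, double gate, int K) {
  int n = prev.nrow(), m = det.nrow();
  std::vector<double> pv((size_t)n * 3), dv((size_t)m * 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pv[i * 3 + c] = prev(i, c);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < 3; ++c) dv[j * 3 + c] = det(j, c);
  std::vector<double> base;
  build_gated(pv, dv, n, m, gate, base);
  std::vector<std::vector<int> > sols;
  std::vector<double> costs;
  murty_kbest(base, n, m + n, K, sols, costs);
  double g2 = gate * gate;
  List out(sols.size());
  for (size_t k = 0; k < sols.size(); ++k) {
    IntegerVector a(n);
    double true_cost = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = sols[k][i];
      if (j >= m || j < 0) {
        a[i] = NA_INTEGER;
        true_cost += g2;
      } else {
        a[i] = j + 1;
        double dx = pv[i * 3] - dv[j * 3];
        double dy = pv[i * 3 + 1] - dv[j * 3 + 1];
        double dz = pv[i * 3 + 2] - dv[j * 3 + 2];
        true_cost += dx * dx + dy * dy + dz * dz;
      }
    }
    out[k] = List::create(_["assignment"] = a, _["cost"] = true_cost);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Depth-N MHHT search
// ---------------------------------------------------------------------------

struct TrackProblem {
  std::vector<std::vector<double> > det;  // per frame, m_t x 3 row-major
  std::vector<int> det_n;
  int n;                                   // objects
  int T;                                   // frames
  double gate, g2;
  int K, N;
  int model;                               // 0 gnn 1 embryo 2 posture 3 movement 4 pm
  double unary_weight;
  std::vector<int> e_from, e_to;           // 0-based edge endpoints
  std::vector<double> sigmaP_inv;          // M*M
  std::vector<double> sigmaM_inv;          // (3n)*(3n)
  std::vector<std::vector<int> > nbrs;     // graph adjacency
  std::vector<int> mid_a, mid_b;           // lateral pair rows (rank order)
  double min_sep;
  bool prune_si;
};

static void edge_lengths(const TrackProblem& P, const std::vector<double>& z,
                         std::vector<double>& E) {
  size_t M = P.e_from.size();
  E.resize(M);
  for (size_t j = 0; j < M; ++j) {
    int a = P.e_from[j], b = P.e_to[j];
    double dx = z[a * 3] - z[b * 3];
    double dy = z[a * 3 + 1] - z[b * 3 + 1];
    double dz = z[a * 3 + 2] - z[b * 3 + 2];
    E[j] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
}

static double quad_form(const std::vector<double>& W,
                        const std::vector<double>& d) {
  size_t k = d.size();
  double s = 0.0;
  for (size_t i = 0; i < k; ++i) {
    double ri = 0.0;
    const double* row = &W[i * k];
    for (size_t j = 0; j < k; ++j) ri += row[j] * d[j];
    s += d[i] * ri;
  }
  return s;
}

static double step_cost(const TrackProblem& P, const std::vector<double>& prev,
                        const std::vector<double>& cand) {
  double gnn = 0.0;
  for (int i = 0; i < 3 * P.n; ++i) {
    double d = cand[i] - prev[i];
    gnn += d * d;
  }
  if (P.model == 0) return gnn;
  if (P.model == 3 || P.model == 4) {
    std::vector<double> d(3 * P.n);
    for (int i = 0; i < 3 * P.n; ++i) d[i] = cand[i] - prev[i];
    double fM = quad_form(P.sigmaM_inv, d);
    if (P.model == 3) return fM;
    std::vector<double> Ep, Ec;
    edge_lengths(P, prev, Ep);
    edge_lengths(P, cand, Ec);
    std::vector<double> dE(Ep.size());
    for (size_t j = 0; j < Ep.size(); ++j) dE[j] = Ec[j] - Ep[j];
    return fM + quad_form(P.sigmaP_inv, dE);
  }
  // embryo / posture (plus weighted GNN unary cost)
  std::vector<double> Ep, Ec;
  edge_lengths(P, prev, Ep);
  edge_lengths(P, cand, Ec);
  double f = 0.0;
  if (P.model == 1) {
    for (size_t j = 0; j < Ep.size(); ++j) {
      double d = Ec[j] - Ep[j];
      f += d * d;
    }
  } else {
    std::vector<double> dE(Ep.size());
    for (size_t j = 0; j < Ep.size(); ++j) dE[j] = Ec[j] - Ep[j];
    f = quad_form(P.sigmaP_inv, dE);
  }
  return f + P.unary_weight * gnn;
}

static double seg_seg_dist(const double* p1, const double* q1,
                           const double* p2, const double* q2) {
  double d1[3], d2[3], r[3];
  for (int c = 0; c < 3; ++c) {
    d1[c] = q1[c] - p1[c];
    d2[c] = q2[c] - p2[c];
    r[c] = p1[c] - p2[c];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dd = 0.0;
  for (int c2 = 0; c2 < 3; ++c2) {
    double w = (p1[c2] + s * d1[c2]) - (p2[c2] + t * d2[c2]);
    dd += w * w;
  }
  return std::sqrt(dd);
}

static bool state_self_intersects(const TrackProblem& P,
                                  const std::vector<double>& z) {
  int np = (int)P.mid_a.size();
  if (np < 4) return false;
  std::vector<double> mid(np * 3);
  for (int k = 0; k < np; ++k)
    for (int c = 0; c < 3; ++c)
      mid[k * 3 + c] = 0.5 * (z[P.mid_a[k] * 3 + c] + z[P.mid_b[k] * 3 + c]);
  int ns = np - 1;
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 2; j < ns; ++j) {
      double d = seg_seg_dist(&mid[i * 3], &mid[(i + 1) * 3],
                              &mid[j * 3], &mid[(j + 1) * 3]);
      if (d < P.min_sep) return true;
    }
  }
  return false;
}

// Place missing objects at previous position plus the mean displacement of
// the nearest assigned graph neighborhood (expanding rings).
static void interpolate_state(const TrackProblem& P,
                              const std::vector<double>& prev,
                              std::vector<double>& cand,
                              const std::vector<char>& assigned) {
  int n = P.n;
  bool any_assigned = false;
  for (int i = 0; i < n; ++i) if (assigned[i]) { any_assigned = true; break; }
  if (!any_assigned) {
    cand = prev;  // carry the previous posture when everything is missing
    return;
  }
  for (int i = 0; i < n; ++i) {
    if (assigned[i]) continue;
    std::vector<int> dist(n, -1);
    std::vector<int> queue_;
    queue_.push_back(i);
    dist[i] = 0;
    int found_level = -1;
    double dx = 0, dy = 0, dz = 0;
    int cnt = 0;
    size_t qh = 0;
    while (qh < queue_.size()) {
      int vtx = queue_[qh++];
      if (found_level >= 0 && dist[vtx] > found_level) break;
      if (assigned[vtx]) {
        if (found_level < 0) found_level = dist[vtx];
        dx += cand[vtx * 3] - prev[vtx * 3];
        dy += cand[vtx * 3 + 1] - prev[vtx * 3 + 1];
        dz += cand[vtx * 3 + 2] - prev[vtx * 3 + 2];
        ++cnt;
        continue;
      }
      for (size_t k = 0; k < P.nbrs[vtx].size(); ++k) {
        int w = P.nbrs[vtx][k];
        if (dist[w] < 0) { dist[w] = dist[vtx] + 1; queue_.push_back(w); }
      }
    }
    if (cnt > 0) {
      cand[i * 3] = prev[i * 3] + dx / cnt;
      cand[i * 3 + 1] = prev[i * 3 + 1] + dy / cnt;
      cand[i * 3 + 2] = prev[i * 3 + 2] + dz / cnt;
    } else {
      cand[i * 3] = prev[i * 3];
      cand[i * 3 + 1] = prev[i * 3 + 1];
      cand[i * 3 + 2] = prev[i * 3 + 2];
    }
  }
}

struct Child {
  std::vector<int> assignment;   // det index or -1
  std::vector<double> state;
  double assoc_cost;             // gated GNN association cost
  double model_cost;             // configured cost model on the full posture
  double score;                  // per-step objective used by the search
  bool intersects;
};

static void expand_children(const TrackProblem& P,
                            const std::vector<double>& state, int t,
                            std::vector<Child>& children) {
  children.clear();
  int m = P.det_n[t];
  std::vector<double> base;
  build_gated(state, P.det[t], P.n, m, P.gate, base);
  std::vector<std::vector<int> > sols;
  std::vector<double> costs;
  murty_kbest(base, P.n, m + P.n, P.K, sols, costs);
  for (size_t k = 0; k < sols.size(); ++k) {
    Child ch;
    ch.assignment.assign(P.n, -1);
    ch.state.assign(P.n * 3, 0.0);
    std::vector<char> assigned(P.n, 0);
    for (int i = 0; i < P.n; ++i) {
      int j = sols[k][i];
      if (j >= 0 && j < m) {
        ch.assignment[i] = j;
        assigned[i] = 1;
        for (int c = 0; c < 3; ++c) ch.state[i * 3 + c] = P.det[t][j * 3 + c];
      }
    }
    interpolate_state(P, state, ch.state, assigned);
    ch.assoc_cost = costs[k];
    ch.model_cost = step_cost(P, state, ch.state);
    // Per-step objective. The gated GNN association cost is the unary cost
    // of the hypothesis (it carries the gate^2 penalty per MISSING nucleus):
    // the GNN model *is* that cost; Embryo/Posture add it with weight
    // unary_weight; Movement/PM already subsume positional differences and
    // only add the missing penalty.
    int n_missing = 0;
    for (int i = 0; i < P.n; ++i) if (!assigned[i]) ++n_missing;
    if (P.model == 0) ch.score = ch.assoc_cost;
    else if (P.model == 1 || P.model == 2)
      ch.score = ch.model_cost + P.unary_weight * ch.assoc_cost;
    else ch.score = ch.model_cost + P.g2 * n_missing;
    ch.intersects = P.prune_si ? state_self_intersects(P, ch.state) : false;
    children.push_back(ch);
  }
  // Soft pruning: drop self-intersecting hypotheses unless that would
  // empty the frontier.
  bool all_bad = true;
  for (size_t k = 0; k < children.size(); ++k)
    if (!children[k].intersects) { all_bad = false; break; }
  if (!all_bad) {
    std::vector<Child> keep;
    for (size_t k = 0; k < children.size(); ++k)
      if (!children[k].intersects) keep.push_back(children[k]);
    children.swap(keep);
  }
}

// Minimum summed model cost of any path of length `depth` from `state`.
// Exact branch-and-bound: children are explored cheapest-first and a
// subtree is pruned once its accumulated score reaches `budget` (step
// scores are non-negative, so the bound is admissible).
static double search_cost(const TrackProblem& P,
                          const std::vector<double>& state, int t, int depth,
                          double budget) {
  if (depth <= 0 || t >= P.T) return 0.0;
  std::vector<Child> children;
  expand_children(P, state, t, children);
  if (children.empty()) return 0.0;
  std::vector<size_t> ord(children.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return children[a].score < children[b].score;
  });
  double best = INF_D;
  for (size_t k = 0; k < ord.size(); ++k) {
    const Child& ch = children[ord[k]];
    if (ch.score >= budget) break;  // sorted: no later child can improve
    double c = ch.score +
               search_cost(P, ch.state, t + 1, depth - 1, budget - ch.score);
    if (c < best) {
      best = c;
      if (best < budget) budget = best;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".track_mhht_cpp")]]
List track_mhht_cpp(List detections, NumericMatrix seed,
                    IntegerMatrix edges, NumericMatrix sigmaP_inv,
                    NumericMatrix sigmaM_inv, IntegerMatrix midline_pairs,
                    int K, int N, double gate, int model,
                    double unary_weight, double min_separation,
                    bool prune_self_intersections) {
  TrackProblem P;
  P.n = seed.nrow();
  P.T = detections.size();
  P.gate = gate;
  P.g2 = gate * gate;
  P.K = K;
  P.N = N;
  P.model = model;
  P.unary_weight = unary_weight;
  P.min_sep = min_separation;
  P.prune_si = prune_self_intersections && midline_pairs.nrow() >= 4;
  for (int j = 0; j < edges.nrow(); ++j) {
    P.e_from.push_back(edges(j, 0));
    P.e_to.push_back(edges(j, 1));
  }
  P.nbrs.assign(P.n, std::vector<int>());
  for (int j = 0; j < edges.nrow(); ++j) {
    P.nbrs[edges(j, 0)].push_back(edges(j, 1));
    P.nbrs[edges(j, 1)].push_back(edges(j, 0));
  }
  int M = edges.nrow();
  if (model == 2 || model == 4) {
    P.sigmaP_inv.resize((size_t)M * M);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j) P.sigmaP_inv[(size_t)i * M + j] = sigmaP_inv(i, j);
  }
  if (model == 3 || model == 4) {
    int d = 3 * P.n;
    P.sigmaM_inv.resize((size_t)d * d);
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) P.sigmaM_inv[(size_t)i * d + j] = sigmaM_inv(i, j);
  }
  for (int k = 0; k < midline_pairs.nrow(); ++k) {
    P.mid_a.push_back(midline_pairs(k, 0));
    P.mid_b.push_back(midline_pairs(k, 1));
  }
  P.det.resize(P.T);
  P.det_n.resize(P.T);
  for (int t = 0; t < P.T; ++t) {
    NumericMatrix d = detections[t];
    P.det_n[t] = d.nrow();
    P.det[t].resize((size_t)d.nrow() * 3);
    for (int j = 0; j < d.nrow(); ++j)
      for (int c = 0; c < 3; ++c) P.det[t][j * 3 + c] = d(j, c);
  }

  std::vector<double> cur((size_t)P.n * 3);
  for (int i = 0; i < P.n; ++i)
    for (int c = 0; c < 3; ++c) cur[i * 3 + c] = seed(i, c);

  IntegerMatrix out_assign(P.T, P.n);
  NumericVector out_cost(P.T);
  NumericVector out_assoc(P.T);
  LogicalMatrix out_interp(P.T, P.n);
  NumericMatrix out_pos(P.T, P.n * 3);

  for (int t = 0; t < P.T; ++t) {
    std::vector<Child> children;
    expand_children(P, cur, t, children);
    int best_k = -1;
    double best_total = INF_D;
    int depth = std::min(P.N, P.T - t);
    std::vector<size_t> ord(children.size());
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
      return children[a].score < children[b].score;
    });
    for (size_t k = 0; k < ord.size(); ++k) {
      const Child& ch = children[ord[k]];
      if (ch.score >= best_total) break;
      double tot = ch.score +
                   (depth > 1 ? search_cost(P, ch.state, t + 1, depth - 1,
                                            best_total - ch.score)
                              : 0.0);
      if (tot < best_total) { best_total = tot; best_k = (int)ord[k]; }
    }
    if (best_k < 0) {
      for (int i = 0; i < P.n; ++i) {
        out_assign(t, i) = NA_INTEGER;
        out_interp(t, i) = true;
        for (int c = 0; c < 3; ++c) out_pos(t, i * 3 + c) = cur[i * 3 + c];
      }
      out_cost[t] = P.g2 * P.n;
      out_assoc[t] = P.g2 * P.n;
      continue;
    }
    const Child& ch = children[best_k];
    for (int i = 0; i < P.n; ++i) {
      out_assign(t, i) = ch.assignment[i] >= 0 ? ch.assignment[i] + 1 : NA_INTEGER;
      out_interp(t, i) = ch.assignment[i] < 0;
      for (int c = 0; c < 3; ++c) out_pos(t, i * 3 + c) = ch.state[i * 3 + c];
    }
    out_cost[t] = ch.score;
    out_assoc[t] = ch.assoc_cost;
    cur = ch.state;
  }

  return List::create(_["positions"] = out_pos, _["assignment"] = out_assign,
                      _["interpolated"] = out_interp,
                      _["model_cost"] = out_cost,
                      _["assoc_cost"] = out_assoc);
}
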