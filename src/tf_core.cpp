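#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All randomness goes through R's generator (unif_rand / norm_rand), so a
// set.seed() on the R side makes every simulation bit-reproducible.

static const double EARTH_R = 6371.0;               // km, haversine sphere
static const double KM_PER_DEG = M_PI * EARTH_R / 180.0;
static const double TO_RAD = M_PI / 180.0;

static inline double haversine_km(double lat1, double lon1,
                                  double lat2, double lon2) {
  double phi1 = lat1 * TO_RAD, phi2 = lat2 * TO_RAD;
  double dphi = (lat2 - lat1) * TO_RAD;
  double dlam = (lon2 - lon1) * TO_RAD;
  double a = std::sin(dphi / 2.0) * std::sin(dphi / 2.0) +
    std::cos(phi1) * std::cos(phi2) *
    std::sin(dlam / 2.0) * std::sin(dlam / 2.0);
  if (a > 1.0) a = 1.0;
  if (a < 0.0) a = 0.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// [[Rcpp::export]]
NumericVector cpp_haversine(NumericVector lat1, NumericVector lon1,
                            NumericVector lat2, NumericVector lon2) {
  R_xlen_t n = lat1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = haversine_km(lat1[i], lon1[i], lat2[i], lon2[i]);
  return out;
}

// ---- grid geometry -------------------------------------------------------

struct Grid {
  NumericMatrix counts;  // row 0 = northernmost row (raster convention)
  double xll, yll, cs;
  int nr, nc;
  Grid(NumericMatrix m, double xll_, double yll_, double cs_)
    : counts(m), xll(xll_), yll(yll_), cs(cs_),
      nr(m.nrow()), nc(m.ncol()) {}
  double cell_lat(int i) const { return yll + (nr - i - 0.5) * cs; }
  double cell_lon(int j) const { return xll + (j + 0.5) * cs; }
  // uniform jitter inside cell (i, j)
  void jitter(int i, int j, double &lat, double &lon) const {
    lat = yll + (nr - i - 1) * cs + unif_rand() * cs;
    lon = xll + j * cs + unif_rand() * cs;
  }
  double diag_km(double lat0) const {
    double dy = cs * KM_PER_DEG;
    double dx = cs * KM_PER_DEG * std::cos(lat0 * TO_RAD);
    return std::sqrt(dx * dx + dy * dy);
  }
};

// Sample one landing point at distance ~r from the origin: candidate cells
// are the populated cells whose centre lies in the annulus
// [r - w/2, r + w/2], chosen proportionally to population, then jittered.
// Returns false when no populated cell lies in the annulus.
static bool annulus_sample(const Grid &g, double lat0, double lon0,
                           double r, double wfactor,
                           double &lat_out, double &lon_out) {
  double w = std::max(g.diag_km(lat0), wfactor * r);
  double lo = std::max(0.0, r - w / 2.0), hi = r + w / 2.0;
  // bounding box of the annulus in grid indices
  double dlat = hi / KM_PER_DEG;
  double coslat = std::max(std::cos(lat0 * TO_RAD), 0.05);
  double dlon = hi / (KM_PER_DEG * coslat);
  int i_lo = (int)std::floor((g.yll + g.nr * g.cs - (lat0 + dlat)) / g.cs) - 1;
  int i_hi = (int)std::ceil((g.yll + g.nr * g.cs - (lat0 - dlat)) / g.cs) + 1;
  int j_lo = (int)std::floor((lon0 - dlon - g.xll) / g.cs) - 1;
  int j_hi = (int)std::ceil((lon0 + dlon - g.xll) / g.cs) + 1;
  if (i_lo < 0) i_lo = 0;
  if (j_lo < 0) j_lo = 0;
  if (i_hi > g.nr) i_hi = g.nr;
  if (j_hi > g.nc) j_hi = g.nc;

  std::vector<int> ci, cj;
  std::vector<double> cw;
  double tot = 0.0;
  for (int i = i_lo; i < i_hi; ++i) {
    double clat = g.cell_lat(i);
    for (int j = j_lo; j < j_hi; ++j) {
      double cnt = g.counts(i, j);
      if (cnt <= 0.0) continue;
      double d = haversine_km(lat0, lon0, clat, g.cell_lon(j));
      if (d >= lo && d <= hi) {
        ci.push_back(i); cj.push_back(j); cw.push_back(cnt);
        tot += cnt;
      }
    }
  }
  if (tot <= 0.0) return false;
  double u = unif_rand() * tot, acc = 0.0;
  size_t pick = cw.size() - 1;
  for (size_t k = 0; k < cw.size(); ++k) {
    acc += cw[k];
    if (u <= acc) { pick = k; break; }
  }
  g.jitter(ci[pick], cj[pick], lat_out, lon_out);
  return true;
}

// Populated cell whose centre distance to the origin is closest to r.
static void closest_populated(const Grid &g, double lat0, double lon0,
                              double r, double &lat_out, double &lon_out) {
  double best = R_PosInf;
  int bi = -1, bj = -1;
  for (int i = 0; i < g.nr; ++i) {
    double clat = g.cell_lat(i);
    for (int j = 0; j < g.nc; ++j) {
      if (g.counts(i, j) <= 0.0) continue;
      double d = std::fabs(haversine_km(lat0, lon0, clat, g.cell_lon(j)) - r);
      if (d < best) { best = d; bi = i; bj = j; }
    }
  }
  g.jitter(bi, bj, lat_out, lon_out);
}

// [[Rcpp::export]]
List cpp_jump_targets(NumericMatrix counts, double xll, double yll, double cs,
                      double lat0, double lon0, NumericVector r,
                      double wfactor, bool fallback_closest) {
  Grid g(counts, xll, yll, cs);
  R_xlen_t n = r.size();
  NumericVector lat(n), lon(n);
  LogicalVector ok(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    double la, lo;
    bool hit = annulus_sample(g, lat0, lon0, r[k], wfactor, la, lo);
    if (!hit) {
      if (fallback_closest) {
        closest_populated(g, lat0, lon0, r[k], la, lo);
      } else {
        la = NA_REAL; lo = NA_REAL;
      }
    }
    lat[k] = la; lon[k] = lo; ok[k] = hit;
  }
  return List::create(_["lat"] = lat, _["lon"] = lon, _["ok"] = ok);
}

// ---- jump lengths --------------------------------------------------------

// family: 0 = truncated power law (inverse CDF), 1 = normal truncated at
// d_min, 2 = uniform on [d_min, d_max]
static double draw_jump(int family, double expo, double dmin, double dmax,
                        double mu, double sd) {
  if (family == 0) {
    double u = unif_rand();
    double a = 1.0 - expo;
    return std::pow(std::pow(dmin, a) + u * (std::pow(dmax, a) -
                    std::pow(dmin, a)), 1.0 / a);
  } else if (family == 1) {
    double x;
    do { x = mu + sd * norm_rand(); } while (x < dmin);
    return x;
  }
  return dmin + unif_rand() * (dmax - dmin);
}

// ---- TF model ------------------------------------------------------------

struct AdjState {
  int N;
  std::vector< std::unordered_set<int> > out_set, uni_set;
  std::vector< std::vector<int> > out_vec, uni_vec;
  std::vector<int> src, dst;
  AdjState(int n) : N(n), out_set(n), uni_set(n), out_vec(n), uni_vec(n) {}
  bool has(int a, int b) const { return out_set[a].count(b) > 0; }
  void add(int a, int b) {
    out_set[a].insert(b);
    out_vec[a].push_back(b);
    src.push_back(a); dst.push_back(b);
    if (!uni_set[a].count(b)) {
      uni_set[a].insert(b); uni_vec[a].push_back(b);
      uni_set[b].insert(a); uni_vec[b].push_back(a);
    }
  }
  int n_edges() const { return (int)src.size(); }
};

// [[Rcpp::export]]
List cpp_run_tf(NumericVector lat0, NumericVector lon0,
                NumericMatrix counts, double xll, double yll, double cs,
                double p_v, double p, double p_c, double delta_km,
                int jump_family, double expo, double dmin, double dmax,
                double jmean, double jsd, double wfactor,
                int L_target, int max_sweeps,
                bool visit_union, bool per_neighbor_gate,
                bool log_creation) {
  Grid g(counts, xll, yll, cs);
  int N = lat0.size();
  NumericVector lat = clone(lat0), lon = clone(lon0);
  AdjState A(N);
  std::vector<double> cre_dist;
  std::vector<int> cre_mech;  // 1 = neighbourhood, 2 = random link

  IntegerVector links_per_sweep(max_sweeps);
  IntegerVector jumps_per_sweep(max_sweeps);
  long n_jumps = 0;
  bool done = false, hit_max = false;
  int sweep = 0;
  long n_act = 0;
  double half = delta_km / 2.0;

  auto add_edge = [&](int a, int b, int mech) {
    A.add(a, b);
    if (log_creation) {
      cre_dist.push_back(haversine_km(lat[a], lon[a], lat[b], lon[b]));
      cre_mech.push_back(mech);
    }
  };

  for (sweep = 0; sweep < max_sweeps && !done; ++sweep) {
    for (int act = 0; act < N && !done; ++act) {
      ++n_act;
      int a = (int)(unif_rand() * N);
      if (a == N) a = N - 1;

      // Travel stage: friend visit, else density-guided random jump
      const std::vector<int> &fr = visit_union ? A.uni_vec[a] : A.out_vec[a];
      bool visited = false;
      if (!fr.empty() && unif_rand() < p_v) {
        int idx = (int)(unif_rand() * fr.size());
        if (idx >= (int)fr.size()) idx = (int)fr.size() - 1;
        int f = fr[idx];
        lat[a] = lat[f]; lon[a] = lon[f];
        visited = true;
      }
      if (!visited) {
        double la, lo, r = dmin;
        bool hit = false;
        for (int tr = 0; tr < 10 && !hit; ++tr) {
          r = draw_jump(jump_family, expo, dmin, dmax, jmean, jsd);
          hit = annulus_sample(g, lat[a], lon[a], r, wfactor, la, lo);
        }
        if (!hit) closest_populated(g, lat[a], lon[a], r, la, lo);
        lat[a] = la; lon[a] = lo;
        ++n_jumps;
      }

      // Friendship stage: neighbourhood links and one global random link
      double coslat = std::cos(lat[a] * TO_RAD);
      bool gate = per_neighbor_gate ? true : (unif_rand() < p);
      if (gate) {
        for (int j = 0; j < N && !done; ++j) {
          if (j == a) continue;
          if (std::fabs(lat[j] - lat[a]) * KM_PER_DEG > half) continue;
          if (std::fabs(lon[j] - lon[a]) * KM_PER_DEG * coslat > half)
            continue;
          if (per_neighbor_gate && unif_rand() >= p) continue;
          if (!A.has(a, j)) {
            add_edge(a, j, 1);
            if (A.n_edges() >= L_target) done = true;
          }
        }
      }
      if (!done && unif_rand() < p_c && N > 1) {
        for (int tr = 0; tr < 50; ++tr) {
          int b = (int)(unif_rand() * N);
          if (b == N) b = N - 1;
          if (b == a) continue;
          if (!A.has(a, b)) {
            add_edge(a, b, 2);
            if (A.n_edges() >= L_target) done = true;
            break;
          }
        }
      }
    }
    links_per_sweep[sweep] = A.n_edges();
    jumps_per_sweep[sweep] = (int)n_jumps;
  }
  if (!done) hit_max = true;
  int ns = sweep;

  return List::create(
    _["src"] = IntegerVector(A.src.begin(), A.src.end()),
    _["dst"] = IntegerVector(A.dst.begin(), A.dst.end()),
    _["lat"] = lat, _["lon"] = lon,
    _["links_per_sweep"] = links_per_sweep[Range(0, std::max(ns - 1, 0))],
    _["jumps_per_sweep"] = jumps_per_sweep[Range(0, std::max(ns - 1, 0))],
    _["n_sweeps"] = ns,
    _["n_activations"] = (double)n_act,
    _["hit_max_steps"] = hit_max,
    _["creation_dist"] = NumericVector(cre_dist.begin(), cre_dist.end()),
    _["creation_mech"] = IntegerVector(cre_mech.begin(), cre_mech.end()));
}

// ---- L model -------------------------------------------------------------

// Linking model: no geography. Agents visit a random out-neighbour with
// probability p_v (abstract co-presence at the host); with probability p_c
// they add a random directed link. At sweep end co-visitors of a host link
// with probability p_enc per missing direction, and each visitor's link to
// the host is reciprocated with probability q.
// Triads/triangles of the undirected union graph are tracked incrementally.
// [[Rcpp::export]]
List cpp_run_l_model(int N, double p_v, double p_c, double p_enc, double q,
                     int sweeps, bool log_events) {
  std::vector< std::unordered_set<int> > out_set(N), uni_set(N);
  std::vector< std::vector<int> > out_vec(N);
  std::vector<int> deg(N, 0);
  std::vector<int> src, dst, mech;  // mech: 0 random, 1 closure, 2 recip
  double n_tri = 0.0, n_triad = 0.0;  // triangles; open+closed triads
  long L_r = 0, L_dir = 0;

  auto add_edge = [&](int a, int b, int m) {
    out_set[a].insert(b);
    out_vec[a].push_back(b);
    ++L_dir;
    if (out_set[b].count(a)) L_r += 2;
    if (log_events) { src.push_back(a); dst.push_back(b); mech.push_back(m); }
    else { src.push_back(a); dst.push_back(b); }
    if (!uni_set[a].count(b)) {
      // union edge appears: count new triangles through common neighbours
      const std::unordered_set<int> &sa =
        uni_set[a].size() < uni_set[b].size() ? uni_set[a] : uni_set[b];
      const std::unordered_set<int> &sb =
        uni_set[a].size() < uni_set[b].size() ? uni_set[b] : uni_set[a];
      int common = 0;
      for (int x : sa) if (sb.count(x)) ++common;
      n_tri += common;
      n_triad += deg[a] + deg[b];
      uni_set[a].insert(b); uni_set[b].insert(a);
      ++deg[a]; ++deg[b];
    }
  };

  NumericVector C_t(sweeps), R_t(sweeps);
  IntegerVector L_t(sweeps);
  std::vector< std::vector<int> > visitors(N);
  std::vector<int> hosts_touched;

  for (int s = 0; s < sweeps; ++s) {
    hosts_touched.clear();
    for (int i = 0; i < N; ++i) {
      if (!out_vec[i].empty() && unif_rand() < p_v) {
        int idx = (int)(unif_rand() * out_vec[i].size());
        if (idx >= (int)out_vec[i].size()) idx = (int)out_vec[i].size() - 1;
        int h = out_vec[i][idx];
        if (visitors[h].empty()) hosts_touched.push_back(h);
        visitors[h].push_back(i);
      }
      if (unif_rand() < p_c && N > 1) {
        for (int tr = 0; tr < 50; ++tr) {
          int b = (int)(unif_rand() * N);
          if (b == N) b = N - 1;
          if (b == i) continue;
          if (!out_set[i].count(b)) { add_edge(i, b, 0); break; }
        }
      }
    }
    for (int h : hosts_touched) {
      std::vector<int> &vis = visitors[h];
      // encounter closure among co-visitors
      for (size_t x = 0; x + 1 < vis.size(); ++x)
        for (size_t y = x + 1; y < vis.size(); ++y) {
          int u = vis[x], v = vis[y];
          if (!out_set[u].count(v) && unif_rand() < p_enc) add_edge(u, v, 1);
          if (!out_set[v].count(u) && unif_rand() < p_enc) add_edge(v, u, 1);
        }
      // hosts reciprocate their visitors' links
      for (int v : vis)
        if (!out_set[h].count(v) && unif_rand() < q) add_edge(h, v, 2);
      vis.clear();
    }
    C_t[s] = n_triad > 0 ? 3.0 * n_tri / n_triad : 0.0;
    R_t[s] = L_dir > 0 ? (double)L_r / (double)L_dir : 0.0;
    L_t[s] = (int)L_dir;
  }

  IntegerVector degv(deg.begin(), deg.end());
  List out = List::create(
    _["src"] = IntegerVector(src.begin(), src.end()),
    _["dst"] = IntegerVector(dst.begin(), dst.end()),
    _["C"] = C_t, _["R"] = R_t, _["L"] = L_t,
    _["degree"] = degv,
    _["n_triads"] = n_triad, _["n_triangles"] = n_tri);
  if (log_events)
    out["mech"] = IntegerVector(mech.begin(), mech.end());
  return out;
}
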