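#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// order-1 (von Neumann) neighbourhood, used for copy candidates,
// boundary-link counting and contact energy alike
static const int DR[4] = {-1, 1, 0, 0};
static const int DC[4] = {0, 0, -1, 1};

// event codes shared with the R side
enum { EV_DEATH = 1, EV_DIVISION = 2, EV_REMOVAL = 3, EV_DIV_SKIPPED = 4 };

// columns of the per-type parameter table
enum { TT_LAREA = 0, TT_LCONT = 1, TT_LADH = 2, TT_A0 = 3, TT_B = 4, TT_M = 5 };

namespace {

struct EventLog {
  std::vector<int> mcs, code, id, d1, d2;
  void add(int m, int c, int i, int a = 0, int b = 0) {
    mcs.push_back(m); code.push_back(c); id.push_back(i);
    d1.push_back(a); d2.push_back(b);
  }
  IntegerMatrix as_matrix() const {
    int n = (int)mcs.size();
    IntegerMatrix out(n, 5);
    for (int i = 0; i < n; ++i) {
      out(i, 0) = mcs[i]; out(i, 1) = code[i]; out(i, 2) = id[i];
      out(i, 3) = d1[i]; out(i, 4) = d2[i];
    }
    colnames(out) = CharacterVector::create("mcs", "code", "cell_id", "d1", "d2");
    return out;
  }
};

struct Model {
  int H, W;
  std::vector<int> owner;            // column-major; 0 = wall/barrier sentinel
  std::vector<int> type, alive;      // indexed by cell id, slot 0 unused;
                                     // alive: 1 live, 0 dead, -1 vacant
  std::vector<double> area, perim;
  std::vector<double> la, lc, ladh, a0;  // effective parameters in force
  NumericMatrix tt;                  // per-type table, columns as TT_*
  double T;
  long nfree;                        // non-wall (owned) pixel count

  int ncell() const { return (int)type.size() - 1; }
  int at(int r, int c) const { return owner[(size_t)c * H + r]; }
  void put(int r, int c, int v) { owner[(size_t)c * H + r] = v; }
  // out-of-bounds behaves as wall
  int nb(int r, int c) const {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return at(r, c);
  }

  // dead-cell switch: contractility and adhesion off, target area zero,
  // strong area compressibility so the corpse shrinks and is extruded
  void set_effective(int id) {
    if (alive[id] == 1) {
      int t = type[id] - 1;
      la[id] = tt(t, TT_LAREA); lc[id] = tt(t, TT_LCONT);
      ladh[id] = tt(t, TT_LADH); a0[id] = tt(t, TT_A0);
    } else {
      la[id] = 200.0; lc[id] = 0.0; ladh[id] = 0.0; a0[id] = 0.0;
    }
  }

  // boundary energy per link: zero against walls, otherwise the mean of the
  // two cells' effective adhesion coefficients (symmetric cross-type rule)
  double phi(int a, int b) const {
    if (a == 0 || b == 0) return 0.0;
    return 0.5 * (ladh[a] + ladh[b]);
  }

  int new_cell(int type_id) {
    type.push_back(type_id); alive.push_back(1);
    area.push_back(0.0); perim.push_back(0.0);
    la.push_back(0.0); lc.push_back(0.0); ladh.push_back(0.0); a0.push_back(0.0);
    int id = ncell();
    set_effective(id);
    return id;
  }
};

Model load(const IntegerMatrix& owner, const IntegerVector& type,
           const IntegerVector& alive, const NumericVector& area,
           const NumericVector& perim, const NumericMatrix& tt,
           double temperature) {
  Model M;
  M.H = owner.nrow(); M.W = owner.ncol();
  M.owner.assign(owner.begin(), owner.end());
  int n = type.size();
  M.type.assign(n + 1, 0); M.alive.assign(n + 1, -1);
  M.area.assign(n + 1, 0.0); M.perim.assign(n + 1, 0.0);
  M.la.assign(n + 1, 0.0); M.lc.assign(n + 1, 0.0);
  M.ladh.assign(n + 1, 0.0); M.a0.assign(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    M.type[i + 1] = type[i]; M.alive[i + 1] = alive[i];
    M.area[i + 1] = area[i]; M.perim[i + 1] = perim[i];
  }
  M.tt = tt; M.T = temperature;
  M.nfree = 0;
  for (size_t i = 0; i < M.owner.size(); ++i) if (M.owner[i] != 0) ++M.nfree;
  for (int id = 1; id <= M.ncell(); ++id) {
    if (M.alive[id] >= 0) {
      if (M.alive[id] == 1 && (M.type[id] < 1 || M.type[id] > tt.nrow()))
        stop("live cell %d has unknown type_id %d", id, M.type[id]);
      M.set_effective(id);
    }
  }
  return M;
}

List dump(const Model& M, List extra) {
  int n = M.ncell();
  IntegerMatrix owner(M.H, M.W);
  std::copy(M.owner.begin(), M.owner.end(), owner.begin());
  IntegerVector type(n), alive(n);
  NumericVector area(n), perim(n);
  for (int i = 0; i < n; ++i) {
    type[i] = M.type[i + 1]; alive[i] = M.alive[i + 1];
    area[i] = M.area[i + 1]; perim[i] = M.perim[i + 1];
  }
  List out = List::create(_["owner"] = owner, _["type"] = type,
                          _["alive"] = alive, _["area"] = area,
                          _["perim"] = perim);
  for (int i = 0; i < extra.size(); ++i) {
    CharacterVector nm = extra.names();
    out[std::string(nm[i])] = extra[i];
  }
  return out;
}

double total_energy_impl(const Model& M) {
  double E = 0.0;
  for (int id = 1; id <= M.ncell(); ++id) {
    if (M.alive[id] < 0) continue;
    double d = M.area[id] - M.a0[id];
    E += M.la[id] * d * d + M.lc[id] * M.perim[id] * M.perim[id];
  }
  // each unordered boundary link counted once (right and down scans)
  for (int c = 0; c < M.W; ++c) {
    for (int r = 0; r < M.H; ++r) {
      int a = M.at(r, c);
      if (c + 1 < M.W) { int b = M.at(r, c + 1); if (a != b) E += M.phi(a, b); }
      if (r + 1 < M.H) { int b = M.at(r + 1, c); if (a != b) E += M.phi(a, b); }
    }
  }
  return E;
}

// energy change of copying cell index s into target pixel (tr, tc),
// computed from the local neighbourhood only
double delta_impl(const Model& M, int s, int tr, int tc) {
  int t = M.at(tr, tc);
  int cs = 0, ct = 0;
  double dphi = 0.0;
  for (int k = 0; k < 4; ++k) {
    int b = M.nb(tr + DR[k], tc + DC[k]);
    if (b == s) ++cs;
    if (b == t) ++ct;
    if (b != s) dphi += M.phi(s, b);
    if (b != t) dphi -= M.phi(t, b);
  }
  double dE = dphi;
  double s1 = M.area[s] + 1.0 - M.a0[s], s0 = M.area[s] - M.a0[s];
  dE += M.la[s] * (s1 * s1 - s0 * s0);
  double t1 = M.area[t] - 1.0 - M.a0[t], t0 = M.area[t] - M.a0[t];
  dE += M.la[t] * (t1 * t1 - t0 * t0);
  double Ls = M.perim[s], dLs = 4.0 - 2.0 * cs;
  dE += M.lc[s] * ((Ls + dLs) * (Ls + dLs) - Ls * Ls);
  double Lt = M.perim[t], dLt = 2.0 * ct - 4.0;
  dE += M.lc[t] * ((Lt + dLt) * (Lt + dLt) - Lt * Lt);
  return dE;
}

void apply_copy(Model& M, int s, int tr, int tc) {
  int t = M.at(tr, tc);
  int cs = 0, ct = 0;
  for (int k = 0; k < 4; ++k) {
    int b = M.nb(tr + DR[k], tc + DC[k]);
    if (b == s) ++cs;
    if (b == t) ++ct;
  }
  M.put(tr, tc, s);
  M.area[s] += 1.0; M.area[t] -= 1.0;
  M.perim[s] += 4.0 - 2.0 * cs;
  M.perim[t] += 2.0 * ct - 4.0;
}

// one MCS: as many elementary attempts as there are non-wall pixels;
// draw order per attempt: site, neighbour, then (only if dE > 0) acceptance
void sweep_impl(Model& M, long& att, long& acc) {
  const long n = M.nfree;
  const double HW = (double)M.H * (double)M.W;
  for (long a = 0; a < n; ++a) {
    ++att;
    int idx = (int)(unif_rand() * HW);
    if (idx >= (int)HW) idx = (int)HW - 1;
    int r = idx % M.H, c = idx / M.H;
    int k = (int)(unif_rand() * 4.0);
    if (k > 3) k = 3;
    int nr = r + DR[k], nc = c + DC[k];
    if (nr < 0 || nr >= M.H || nc < 0 || nc >= M.W) continue;
    int s = M.at(r, c), t = M.at(nr, nc);
    if (s == t || s == 0 || t == 0) continue;
    double dE = delta_impl(M, s, nr, nc);
    bool accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / M.T));
    if (accept) { apply_copy(M, s, nr, nc); ++acc; }
  }
}

// one uniform draw per live cell in registry-id order, applied immediately
void deaths_impl(Model& M, EventLog& ev, int mcs) {
  int n = M.ncell();
  for (int id = 1; id <= n; ++id) {
    if (M.alive[id] == 1 && M.type[id] >= 1) {
      double u = unif_rand();
      if (u < M.tt(M.type[id] - 1, TT_M)) {
        M.alive[id] = 0;
        M.set_effective(id);
        ev.add(mcs, EV_DEATH, id);
      }
    }
  }
}

std::vector<int> sample_deaths_impl(Model& M) {
  std::vector<int> sel;
  int n = M.ncell();
  for (int id = 1; id <= n; ++id) {
    if (M.alive[id] == 1 && M.type[id] >= 1) {
      double u = unif_rand();
      if (u < M.tt(M.type[id] - 1, TT_M)) sel.push_back(id);
    }
  }
  return sel;
}

// live cells at or above their type's target area, one draw each in id order
std::vector<int> sample_divisions_impl(Model& M) {
  std::vector<int> sel;
  int n = M.ncell();
  for (int id = 1; id <= n; ++id) {
    if (M.alive[id] == 1 && M.type[id] >= 1) {
      int t = M.type[id] - 1;
      if (M.area[id] >= M.tt(t, TT_A0)) {
        double u = unif_rand();
        if (u < M.tt(t, TT_B)) sel.push_back(id);
      }
    }
  }
  return sel;
}

void recount_cell(Model& M, int id, const std::vector<int>& pxl) {
  double L = 0.0;
  for (size_t i = 0; i < pxl.size(); ++i) {
    int r = pxl[i] % M.H, c = pxl[i] / M.H;
    for (int k = 0; k < 4; ++k)
      if (M.nb(r + DR[k], c + DC[k]) != id) L += 1.0;
  }
  M.area[id] = (double)pxl.size();
  M.perim[id] = L;
}

// split along a straight line through the area centroid at a uniformly
// random orientation; redraw up to 8 times if a side is empty, then fall
// back to a pixel-count median split along the longer bounding-box axis
void do_divide(Model& M, int id, const std::vector<int>& pxl, EventLog& ev,
               int mcs, int* daughters) {
  int n = (int)pxl.size();
  daughters[0] = daughters[1] = 0;
  if (n < 2) { ev.add(mcs, EV_DIV_SKIPPED, id); return; }
  std::vector<int> rr(n), cc(n);
  double cr = 0.0, ccm = 0.0;
  for (int i = 0; i < n; ++i) {
    rr[i] = pxl[i] % M.H; cc[i] = pxl[i] / M.H;
    cr += rr[i]; ccm += cc[i];
  }
  cr /= n; ccm /= n;
  std::vector<char> keep(n, 1);
  bool ok = false;
  for (int tr = 0; tr < 9 && !ok; ++tr) {
    double th = unif_rand() * M_PI;
    double nx = std::cos(th), ny = std::sin(th);
    int n1 = 0;
    for (int i = 0; i < n; ++i) {
      keep[i] = ((cc[i] - ccm) * nx + (rr[i] - cr) * ny) >= 0.0 ? 1 : 0;
      n1 += keep[i];
    }
    ok = (n1 > 0 && n1 < n);
  }
  if (!ok) {
    int rmin = rr[0], rmax = rr[0], cmin = cc[0], cmax = cc[0];
    for (int i = 1; i < n; ++i) {
      rmin = std::min(rmin, rr[i]); rmax = std::max(rmax, rr[i]);
      cmin = std::min(cmin, cc[i]); cmax = std::max(cmax, cc[i]);
    }
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    if (cmax - cmin >= rmax - rmin)
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return cc[a] != cc[b] ? cc[a] < cc[b] : rr[a] < rr[b];
      });
    else
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return rr[a] != rr[b] ? rr[a] < rr[b] : cc[a] < cc[b];
      });
    int half = (n + 1) / 2;
    for (int i = 0; i < n; ++i) keep[ord[i]] = (i < half) ? 1 : 0;
  }
  int nid = M.new_cell(M.type[id]);
  std::vector<int> pa, pb;
  for (int i = 0; i < n; ++i) {
    if (keep[i]) pa.push_back(pxl[i]);
    else { M.owner[pxl[i]] = nid; pb.push_back(pxl[i]); }
  }
  // the parent becomes a live daughter again with its type's target area
  M.alive[id] = 1;
  M.set_effective(id);
  recount_cell(M, id, pa);
  recount_cell(M, nid, pb);
  ev.add(mcs, EV_DIVISION, id, id, nid);
}

void divisions_impl(Model& M, EventLog& ev, int mcs) {
  std::vector<int> sel = sample_divisions_impl(M);
  if (sel.empty()) return;
  int n = M.ncell();
  std::vector<int> slot(n + 1, -1);
  for (size_t k = 0; k < sel.size(); ++k) slot[sel[k]] = (int)k;
  std::vector<std::vector<int> > px(sel.size());
  for (size_t i = 0; i < M.owner.size(); ++i) {
    int o = M.owner[i];
    if (o > 0 && o <= n && slot[o] >= 0) px[slot[o]].push_back((int)i);
  }
  int d[2];
  for (size_t k = 0; k < sel.size(); ++k)
    do_divide(M, sel[k], px[slot[sel[k]]], ev, mcs, d);
}

void purge_impl(Model& M, EventLog& ev, int mcs) {
  for (int id = 1; id <= M.ncell(); ++id) {
    if (M.alive[id] >= 0 && M.area[id] <= 0.0) {
      if (M.alive[id] == 1)
        stop("integrity error: live cell %d has zero area", id);
      M.alive[id] = -1;
      ev.add(mcs, EV_REMOVAL, id);
    }
  }
}

void count_types(const Model& M, int ntypes, std::vector<int>& live,
                 std::vector<int>& dead) {
  std::fill(live.begin(), live.end(), 0);
  std::fill(dead.begin(), dead.end(), 0);
  for (int id = 1; id <= M.ncell(); ++id) {
    int t = M.type[id];
    if (M.alive[id] < 0 || t < 1 || t > ntypes) continue;
    if (M.alive[id] == 1) ++live[t - 1]; else ++dead[t - 1];
  }
}

} // namespace

//' @noRd
// [[Rcpp::export]]
double cpm_total_energy_cpp(IntegerMatrix owner, IntegerVector type,
                            IntegerVector alive, NumericVector area,
                            NumericVector perim, NumericMatrix type_table,
                            double temperature) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  return total_energy_impl(M);
}

// [[Rcpp::export]]
double cpm_delta_energy_cpp(IntegerMatrix owner, IntegerVector type,
                            IntegerVector alive, NumericVector area,
                            NumericVector perim, NumericMatrix type_table,
                            double temperature, int src_r, int src_c,
                            int tgt_r, int tgt_c) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  int s = M.at(src_r - 1, src_c - 1);
  return delta_impl(M, s, tgt_r - 1, tgt_c - 1);
}

// [[Rcpp::export]]
bool cpm_metropolis_cpp(double delta_e, double temperature) {
  if (delta_e <= 0.0) return true;
  return unif_rand() < std::exp(-delta_e / temperature);
}

// [[Rcpp::export]]
List cpm_recount_cpp(IntegerMatrix owner, int max_id) {
  int H = owner.nrow(), W = owner.ncol();
  NumericVector area(max_id), perim(max_id);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int a = owner(r, c);
      if (a < 1 || a > max_id) continue;
      area[a - 1] += 1.0;
      for (int k = 0; k < 4; ++k) {
        int nr = r + DR[k], nc = c + DC[k];
        int b = (nr < 0 || nr >= H || nc < 0 || nc >= W) ? 0 : owner(nr, nc);
        if (b != a) perim[a - 1] += 1.0;
      }
    }
  }
  return List::create(_["area"] = area, _["perim"] = perim);
}

// [[Rcpp::export]]
IntegerVector cpm_sample_deaths_cpp(IntegerMatrix owner, IntegerVector type,
                                    IntegerVector alive, NumericVector area,
                                    NumericVector perim,
                                    NumericMatrix type_table,
                                    double temperature) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  std::vector<int> sel = sample_deaths_impl(M);
  return wrap(sel);
}

// [[Rcpp::export]]
IntegerVector cpm_sample_divisions_cpp(IntegerMatrix owner, IntegerVector type,
                                       IntegerVector alive, NumericVector area,
                                       NumericVector perim,
                                       NumericMatrix type_table,
                                       double temperature) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  std::vector<int> sel = sample_divisions_impl(M);
  return wrap(sel);
}

// [[Rcpp::export]]
List cpm_divide_cell_cpp(IntegerMatrix owner, IntegerVector type,
                         IntegerVector alive, NumericVector area,
                         NumericVector perim, NumericMatrix type_table,
                         double temperature, int cell_id, int mcs) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  if (cell_id < 1 || cell_id > M.ncell() || M.alive[cell_id] < 0)
    stop("unknown cell_id");
  EventLog ev;
  std::vector<int> pxl;
  for (size_t i = 0; i < M.owner.size(); ++i)
    if (M.owner[i] == cell_id) pxl.push_back((int)i);
  int d[2];
  do_divide(M, cell_id, pxl, ev, mcs, d);
  IntegerVector daughters;
  if (!ev.code.empty() && ev.code.back() == EV_DIVISION)
    daughters = IntegerVector::create(ev.d1.back(), ev.d2.back());
  return dump(M, List::create(_["daughters"] = daughters,
                              _["events"] = ev.as_matrix()));
}

// [[Rcpp::export]]
List cpm_run_cpp(IntegerMatrix owner, IntegerVector type, IntegerVector alive,
                 NumericVector area, NumericVector perim,
                 NumericMatrix type_table, double temperature, int n_mcs,
                 bool turnover, bool stop_extinct, int mcs0) {
  Model M = load(owner, type, alive, area, perim, type_table, temperature);
  int ntypes = type_table.nrow();
  IntegerMatrix live(n_mcs, ntypes), dead(n_mcs, ntypes);
  std::vector<int> lv(ntypes), dd(ntypes);
  EventLog ev;
  long att = 0, acc = 0;
  int done = 0;
  for (int m = 1; m <= n_mcs; ++m) {
    int mcs = mcs0 + m;
    sweep_impl(M, att, acc);
    if (turnover) {
      deaths_impl(M, ev, mcs);
      divisions_impl(M, ev, mcs);
      purge_impl(M, ev, mcs);
    }
    count_types(M, ntypes, lv, dd);
    for (int t = 0; t < ntypes; ++t) { live(m - 1, t) = lv[t]; dead(m - 1, t) = dd[t]; }
    done = m;
    if (stop_extinct) {
      bool any_zero = false;
      for (int t = 0; t < ntypes; ++t) if (lv[t] == 0) any_zero = true;
      if (any_zero) break;
    }
    if ((m & 255) == 0) Rcpp::checkUserInterrupt();
  }
  if (done < n_mcs) {
    live = live(Range(0, done - 1), Range(0, ntypes - 1));
    dead = dead(Range(0, done - 1), Range(0, ntypes - 1));
  }
  return dump(M, List::create(_["live"] = live, _["dead"] = dead,
                              _["events"] = ev.as_matrix(),
                              _["attempts"] = (double)att,
                              _["accepts"] = (double)acc,
                              _["n_done"] = done));
}
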