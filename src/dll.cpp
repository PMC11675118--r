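// Dynamic lattice liquid engine on a periodic triangular lattice.
//
// Axial coordinates (q, r), 0 <= q, r < L, site index = q + r*L (0-based
// here; the R interface is 1-based).  Cartesian embedding x = q + r/2,
// y = r*sqrt(3)/2, lattice constant 1.  Direction k and (k+3) mod 6 are
// inverses.  All randomness goes through R's RNG (unif_rand) so set.seed()
// on the R side makes every run reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

const double SQ32 = 0.86602540378443864676; // sqrt(3)/2
const int DQ[6] = {1, 0, -1, -1, 0, 1};
const int DR[6] = {0, 1, 1, 0, -1, -1};
const double UX[6] = {1.0, 0.5, -0.5, -1.0, -0.5, 0.5};
const double UY[6] = {0.0, SQ32, SQ32, 0.0, -SQ32, -SQ32};

enum Species { SOLVENT = 0, MER = 1, OBSTACLE = 2 };

const int HIST_MAX = 256; // loop-length histogram cap (overflow binned at cap)

inline int imod(int a, int L) { int r = a % L; return r < 0 ? r + L : r; }

inline int runif_int(int k) { // uniform on 0..k-1
  int d = (int)(unif_rand() * k);
  return d >= k ? k - 1 : d;
}

struct Lattice {
  int L, N;
  std::vector<int> nbr;                       // site*6 + k -> neighbor site
  std::vector<std::pair<int, int> > hood3;    // axial offsets, hex dist 1..3

  explicit Lattice(int L_) : L(L_), N(L_ * L_) {
    nbr.resize((size_t)N * 6);
    for (int r = 0; r < L; ++r)
      for (int q = 0; q < L; ++q) {
        int s = q + r * L;
        for (int k = 0; k < 6; ++k)
          nbr[(size_t)s * 6 + k] = imod(q + DQ[k], L) + imod(r + DR[k], L) * L;
      }
    for (int dq = -3; dq <= 3; ++dq)
      for (int dr = -3; dr <= 3; ++dr) {
        int h = (std::abs(dq) + std::abs(dr) + std::abs(dq + dr)) / 2;
        if (h >= 1 && h <= 3) hood3.push_back(std::make_pair(dq, dr));
      }
  }

  int shift(int s, int dq, int dr) const {
    int q = s % L, r = s / L;
    return imod(q + dq, L) + imod(r + dr, L) * L;
  }

  // minimal-image Cartesian displacement from site a to site b
  void mindisp(int a, int b, double &x, double &y) const {
    int dq = b % L - a % L, dr = b / L - a / L;
    double best = 1e300;
    for (int i = -1; i <= 1; ++i)
      for (int j = -1; j <= 1; ++j) {
        double xx = (dq + i * L) + 0.5 * (dr + j * L);
        double yy = SQ32 * (dr + j * L);
        double n2 = xx * xx + yy * yy;
        if (n2 < best) { best = n2; x = xx; y = yy; }
      }
  }
};

struct State {
  int L, n_obj, m_dimers;
  std::vector<int> species;  // per site
  std::vector<int> obj_at;   // site -> object (0-based)
  std::vector<int> site_of;  // object -> site
  std::vector<int> obj_sp;   // object species
  std::vector<int> partner;  // object -> partner object, -1 if none
  std::vector<double> dx, dy;
  double t;
};

State unpack(const List &st) {
  State S;
  S.L = as<int>(st["L"]);
  IntegerVector sp = st["species"], oa = st["obj_at"], so = st["site_of"],
                os = st["obj_species"], pt = st["partner"];
  NumericVector ddx = st["dispx"], ddy = st["dispy"];
  S.t = as<double>(st["t"]);
  int N = S.L * S.L;
  S.n_obj = so.size();
  S.species.assign(sp.begin(), sp.end());
  S.obj_at.resize(N);
  for (int i = 0; i < N; ++i) S.obj_at[i] = oa[i] - 1;
  S.site_of.resize(S.n_obj);
  for (int i = 0; i < S.n_obj; ++i) S.site_of[i] = so[i] - 1;
  S.obj_sp.assign(os.begin(), os.end());
  S.partner.resize(S.n_obj);
  for (int i = 0; i < S.n_obj; ++i) S.partner[i] = pt[i] - 1; // 0 -> -1
  S.dx.assign(ddx.begin(), ddx.end());
  S.dy.assign(ddy.begin(), ddy.end());
  S.m_dimers = 0;
  for (int i = 0; i < S.n_obj; ++i) if (S.obj_sp[i] == MER) ++S.m_dimers;
  S.m_dimers /= 2;
  return S;
}

void repack(const State &S, List &st) {
  int N = S.L * S.L;
  IntegerVector oa(N), so(S.n_obj);
  for (int i = 0; i < N; ++i) oa[i] = S.obj_at[i] + 1;
  for (int i = 0; i < S.n_obj; ++i) so[i] = S.site_of[i] + 1;
  IntegerVector sp(S.species.begin(), S.species.end());
  st["species"] = sp;
  st["obj_at"] = oa;
  st["site_of"] = so;
  st["dispx"] = NumericVector(S.dx.begin(), S.dx.end());
  st["dispy"] = NumericVector(S.dy.begin(), S.dy.end());
  st["t"] = S.t;
}

void gen_field(const State &S, std::vector<int> &field) {
  int N = S.L * S.L;
  field.resize(N);
  for (int s = 0; s < N; ++s)
    field[s] = (S.species[s] == OBSTACLE) ? -1 : runif_int(6);
}

// Cycles of the successor map restricted to non-obstacle sites.  Loops of
// length >= 3 are returned sorted by (and rotated to start at) their
// smallest site; 2-cycles (mutual exchange) are tallied separately and
// never executed.
void find_cycles(const Lattice &lat, const State &S, const std::vector<int> &field,
                 std::vector<std::vector<int> > &loops, int &two_cycles,
                 std::vector<std::vector<int> > *twocycle_list) {
  int N = lat.N;
  std::vector<int> color(N, 0), pos(N, -1);
  std::vector<int> path;
  loops.clear();
  two_cycles = 0;
  for (int s0 = 0; s0 < N; ++s0) {
    if (color[s0] || S.species[s0] == OBSTACLE) continue;
    path.clear();
    int cur = s0;
    while (true) {
      if (S.species[cur] == OBSTACLE || color[cur] == 2) break;
      if (color[cur] == 1) {
        std::vector<int> cyc(path.begin() + pos[cur], path.end());
        int mi = (int)(std::min_element(cyc.begin(), cyc.end()) - cyc.begin());
        std::rotate(cyc.begin(), cyc.begin() + mi, cyc.end());
        if ((int)cyc.size() >= 3) {
          loops.push_back(cyc);
        } else {
          ++two_cycles;
          if (twocycle_list) twocycle_list->push_back(cyc);
        }
        break;
      }
      color[cur] = 1;
      pos[cur] = (int)path.size();
      path.push_back(cur);
      cur = lat.nbr[(size_t)cur * 6 + field[cur]];
    }
    for (size_t i = 0; i < path.size(); ++i) color[path[i]] = 2;
  }
  std::sort(loops.begin(), loops.end(),
            [](const std::vector<int> &a, const std::vector<int> &b) {
              return a[0] < b[0];
            });
}

inline double crossp(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Does a point moving p0 -> p0+dp pass through the open segment between
// dimer-bond endpoints that simultaneously move b1 -> b1+d1, b2 -> b2+d2?
// All motions are linear in the step fraction s in (0, 1]; the signed area
// f(s) = cross(b2(s)-b1(s), p(s)-b1(s)) is quadratic in s.  A crossing needs
// a root of f in (0, 1] at which p projects strictly inside the segment;
// endpoint contact (projection 0 or 1) is excluded.
bool crossing_test_impl(double p0x, double p0y, double dpx, double dpy,
                        double b1x, double b1y, double d1x, double d1y,
                        double b2x, double b2y, double d2x, double d2y) {
  const double EPS = 1e-9;
  if (std::fabs(dpx) < EPS && std::fabs(dpy) < EPS) return false; // zero path
  double u0x = b2x - b1x, u0y = b2y - b1y;
  double dux = d2x - d1x, duy = d2y - d1y;
  double w0x = p0x - b1x, w0y = p0y - b1y;
  double dwx = dpx - d1x, dwy = dpy - d1y;
  double a0 = crossp(u0x, u0y, w0x, w0y);
  double a1 = crossp(u0x, u0y, dwx, dwy) + crossp(dux, duy, w0x, w0y);
  double a2 = crossp(dux, duy, dwx, dwy);
  double roots[4];
  int nr = 0;
  if (std::fabs(a2) > EPS) {
    double disc = a1 * a1 - 4.0 * a2 * a0;
    if (disc >= 0.0) {
      double sd = std::sqrt(disc);
      roots[nr++] = (-a1 - sd) / (2.0 * a2);
      roots[nr++] = (-a1 + sd) / (2.0 * a2);
    }
  } else if (std::fabs(a1) > EPS) {
    roots[nr++] = -a0 / a1;
  } else if (std::fabs(a0) <= EPS) {
    // degenerate: point collinear with the bond for every s
    roots[nr++] = 0.5;
    roots[nr++] = 1.0;
  }
  for (int i = 0; i < nr; ++i) {
    double s = roots[i];
    if (s <= 1e-12 || s > 1.0 + 1e-9) continue;
    if (s > 1.0) s = 1.0;
    double usx = u0x + s * dux, usy = u0y + s * duy;
    double uu = usx * usx + usy * usy;
    if (uu < EPS) continue;
    double wsx = w0x + s * dwx, wsy = w0y + s * dwy;
    double tt = (wsx * usx + wsy * usy) / uu;
    if (tt > 1e-9 && tt < 1.0 - 1e-9) return true;
  }
  return false;
}

struct StepTally {
  int loops_found, two_cycles, accepted, rej_break, rej_cross, moved;
};

// Iterative fixed-point rejection, deterministic ascending loop order
// (loops pre-sorted by smallest site).  status: 0 accepted, 1 bond_break,
// 2 bond_cross.  The accepted set shrinks monotonically.
void validate(const Lattice &lat, const State &S, const std::vector<int> &field,
              const std::vector<std::vector<int> > &loops,
              std::vector<int> &status, StepTally &tal) {
  int K = (int)loops.size(), N = lat.N;
  status.assign(K, 0);
  std::vector<int> loop_of(N, -1);
  for (int j = 0; j < K; ++j)
    for (size_t i = 0; i < loops[j].size(); ++i) loop_of[loops[j][i]] = j;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int j = 0; j < K; ++j) {
      if (status[j]) continue;
      int reason = 0;
      // rigid-bond preservation: every dimer with a mer in this loop must
      // end the step at nearest-neighbor separation
      for (size_t i = 0; i < loops[j].size() && !reason; ++i) {
        int s = loops[j][i], o = S.obj_at[s];
        if (S.obj_sp[o] != MER) continue;
        int p = S.partner[o], sp = S.site_of[p];
        int lp = loop_of[sp];
        bool pmove = (lp >= 0 && status[lp] == 0);
        double bx, by;
        lat.mindisp(s, sp, bx, by);
        double vx = bx - UX[field[s]], vy = by - UY[field[s]];
        if (pmove) { vx += UX[field[sp]]; vy += UY[field[sp]]; }
        if (std::fabs(vx * vx + vy * vy - 1.0) > 1e-6) reason = 1;
      }
      // no moving object may jump over a moving dimer bond; candidate bonds
      // are confined to graph distance <= 3 of the mover (a crossing farther
      // away is geometrically impossible for unit hops)
      if (!reason && S.m_dimers > 0) {
        int seen[128];
        for (size_t i = 0; i < loops[j].size() && !reason; ++i) {
          int s = loops[j][i], o = S.obj_at[s];
          int nseen = 0;
          for (size_t h = 0; h < lat.hood3.size() && !reason; ++h) {
            int s1 = lat.shift(s, lat.hood3[h].first, lat.hood3[h].second);
            int m = S.obj_at[s1];
            if (S.obj_sp[m] != MER) continue;
            if (m == o || S.partner[m] == o) continue;
            int rep = std::min(m, S.partner[m]);
            bool dup = false;
            for (int z = 0; z < nseen; ++z)
              if (seen[z] == rep) { dup = true; break; }
            if (dup) continue;
            if (nseen < 128) seen[nseen++] = rep;
            int m1 = rep, m2 = S.partner[rep];
            int sm1 = S.site_of[m1], sm2 = S.site_of[m2];
            int l1 = loop_of[sm1], l2 = loop_of[sm2];
            bool mv1 = (l1 >= 0 && status[l1] == 0);
            bool mv2 = (l2 >= 0 && status[l2] == 0);
            if (!mv1 && !mv2) continue; // static bonds cannot be crossed
            double b1x, b1y, bdx, bdy;
            lat.mindisp(s, sm1, b1x, b1y);
            lat.mindisp(sm1, sm2, bdx, bdy);
            if (crossing_test_impl(0.0, 0.0, UX[field[s]], UY[field[s]],
                                   b1x, b1y,
                                   mv1 ? UX[field[sm1]] : 0.0,
                                   mv1 ? UY[field[sm1]] : 0.0,
                                   b1x + bdx, b1y + bdy,
                                   mv2 ? UX[field[sm2]] : 0.0,
                                   mv2 ? UY[field[sm2]] : 0.0))
              reason = 2;
          }
        }
      }
      if (reason) {
        status[j] = reason;
        changed = true;
        if (reason == 1) ++tal.rej_break; else ++tal.rej_cross;
      }
    }
  }
}

// Cyclic permutation along every accepted loop; loops are vertex-disjoint so
// per-loop read-then-write is safe.
int execute(const Lattice &lat, State &S, const std::vector<int> &field,
            const std::vector<std::vector<int> > &loops,
            const std::vector<int> &status) {
  int moved = 0;
  std::vector<int> objs, dsts, dirs;
  for (size_t j = 0; j < loops.size(); ++j) {
    if (status[j]) continue;
    const std::vector<int> &cyc = loops[j];
    objs.clear(); dsts.clear(); dirs.clear();
    for (size_t i = 0; i < cyc.size(); ++i) {
      int s = cyc[i], d = field[s];
      objs.push_back(S.obj_at[s]);
      dirs.push_back(d);
      dsts.push_back(lat.nbr[(size_t)s * 6 + d]);
    }
    for (size_t i = 0; i < cyc.size(); ++i) {
      int o = objs[i], dst = dsts[i], d = dirs[i];
      S.obj_at[dst] = o;
      S.species[dst] = S.obj_sp[o];
      S.site_of[o] = dst;
      S.dx[o] += UX[d];
      S.dy[o] += UY[d];
      ++moved;
    }
  }
  return moved;
}

StepTally one_step(const Lattice &lat, State &S, const std::vector<int> &field,
                   std::vector<std::vector<int> > &loops, std::vector<int> &status,
                   std::vector<int> *len_hist_found, std::vector<int> *len_hist_acc) {
  StepTally tal;
  tal.rej_break = tal.rej_cross = 0;
  find_cycles(lat, S, field, loops, tal.two_cycles, NULL);
  tal.loops_found = (int)loops.size();
  validate(lat, S, field, loops, status, tal);
  tal.accepted = 0;
  for (size_t j = 0; j < loops.size(); ++j) {
    int len = std::min((int)loops[j].size(), HIST_MAX);
    if (len_hist_found) (*len_hist_found)[len] += 1;
    if (status[j] == 0) {
      ++tal.accepted;
      if (len_hist_acc) (*len_hist_acc)[len] += 1;
    }
  }
  tal.moved = execute(lat, S, field, loops, status);
  S.t += 1.0;
  return tal;
}

List loops_to_list(const std::vector<std::vector<int> > &loops) {
  List out(loops.size());
  for (size_t j = 0; j < loops.size(); ++j) {
    IntegerVector v(loops[j].size());
    for (size_t i = 0; i < loops[j].size(); ++i) v[i] = loops[j][i] + 1;
    out[j] = v;
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_mindisp(int L, int site_a, int site_b) {
  Lattice lat(L);
  double x, y;
  lat.mindisp(site_a - 1, site_b - 1, x, y);
  return NumericVector::create(x, y);
}

// [[Rcpp::export]]
bool cpp_crossing_test(NumericVector p0, NumericVector p1, NumericVector b1_0,
                       NumericVector b1_1, NumericVector b2_0, NumericVector b2_1) {
  return crossing_test_impl(p0[0], p0[1], p1[0] - p0[0], p1[1] - p0[1],
                            b1_0[0], b1_0[1], b1_1[0] - b1_0[0], b1_1[1] - b1_0[1],
                            b2_0[0], b2_0[1], b2_1[0] - b2_0[0], b2_1[1] - b2_0[1]);
}

// [[Rcpp::export]]
IntegerVector cpp_gen_field(List state) {
  State S = unpack(state);
  std::vector<int> field;
  gen_field(S, field);
  IntegerVector out(field.size());
  for (size_t i = 0; i < field.size(); ++i)
    out[i] = field[i] < 0 ? NA_INTEGER : field[i];
  return out;
}

// [[Rcpp::export]]
List cpp_loops_field(List state, IntegerVector field) {
  State S = unpack(state);
  Lattice lat(S.L);
  std::vector<int> f(lat.N);
  for (int i = 0; i < lat.N; ++i)
    f[i] = (field[i] == NA_INTEGER) ? -1 : field[i];
  std::vector<std::vector<int> > loops, twos;
  int two_cycles = 0;
  find_cycles(lat, S, f, loops, two_cycles, &twos);
  StepTally tal;
  tal.rej_break = tal.rej_cross = 0;
  std::vector<int> status;
  validate(lat, S, f, loops, status, tal);
  return List::create(_["loops"] = loops_to_list(loops),
                      _["status"] = IntegerVector(status.begin(), status.end()),
                      _["two_cycles"] = loops_to_list(twos));
}

// [[Rcpp::export]]
List cpp_step_field(List state, IntegerVector field) {
  State S = unpack(state);
  Lattice lat(S.L);
  std::vector<int> f(lat.N);
  for (int i = 0; i < lat.N; ++i)
    f[i] = (field[i] == NA_INTEGER) ? -1 : field[i];
  std::vector<std::vector<int> > loops;
  std::vector<int> status;
  StepTally tal = one_step(lat, S, f, loops, status, NULL, NULL);
  List st = clone(state);
  repack(S, st);
  return List::create(
      _["state"] = st, _["loops"] = loops_to_list(loops),
      _["status"] = IntegerVector(status.begin(), status.end()),
      _["tally"] = List::create(
          _["loops_found"] = tal.loops_found, _["two_cycles"] = tal.two_cycles,
          _["accepted"] = tal.accepted, _["rejected_bond_break"] = tal.rej_break,
          _["rejected_bond_cross"] = tal.rej_cross, _["objects_moved"] = tal.moved));
}

// [[Rcpp::export]]
List cpp_run(List state, int n_steps, IntegerVector sample_steps,
             IntegerMatrix dimers) {
  State S = unpack(state);
  Lattice lat(S.L);
  int n_samp = sample_steps.size();
  int n_obj = S.n_obj, m = dimers.nrow();

  NumericVector x0 = state["x0"], y0 = state["y0"];
  NumericMatrix posx(n_samp, n_obj), posy(n_samp, n_obj);
  IntegerMatrix sitem(n_samp, n_obj);
  NumericMatrix eex(n_samp, m), eey(n_samp, m);

  int n_dec = 1;
  while (std::pow(10.0, n_dec) < (double)n_steps) ++n_dec;
  IntegerMatrix dec(n_dec, 7); // steps, loops, 2cyc, acc, rej_break, rej_cross, moved
  std::vector<int> hist_found(HIST_MAX + 1, 0), hist_acc(HIST_MAX + 1, 0);

  std::vector<int> field;
  std::vector<std::vector<int> > loops;
  std::vector<int> status;

  int next = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (next < n_samp && sample_steps[next] == step) {
      for (int o = 0; o < n_obj; ++o) {
        posx(next, o) = x0[o] + S.dx[o];
        posy(next, o) = y0[o] + S.dy[o];
        sitem(next, o) = S.site_of[o] + 1;
      }
      for (int k = 0; k < m; ++k) {
        double ex, ey;
        lat.mindisp(S.site_of[dimers(k, 0) - 1], S.site_of[dimers(k, 1) - 1], ex, ey);
        eex(next, k) = ex;
        eey(next, k) = ey;
      }
      ++next;
    }
    if (step == n_steps) break;
    gen_field(S, field);
    StepTally tal = one_step(lat, S, field, loops, status, &hist_found, &hist_acc);
    int d = (step == 0) ? 0 : (int)std::floor(std::log10((double)(step + 1)));
    if (d >= n_dec) d = n_dec - 1;
    dec(d, 0) += 1;
    dec(d, 1) += tal.loops_found;
    dec(d, 2) += tal.two_cycles;
    dec(d, 3) += tal.accepted;
    dec(d, 4) += tal.rej_break;
    dec(d, 5) += tal.rej_cross;
    dec(d, 6) += tal.moved;
  }

  List st = clone(state);
  repack(S, st);
  return List::create(
      _["state"] = st, _["posx"] = posx, _["posy"] = posy, _["site"] = sitem,
      _["eex"] = eex, _["eey"] = eey, _["decade_tally"] = dec,
      _["length_hist_found"] = IntegerVector(hist_found.begin(), hist_found.end()),
      _["length_hist_accepted"] = IntegerVector(hist_acc.begin(), hist_acc.end()));
}

// Random initialization: obstacles uniformly at random, dimers by random
// sequential adsorption on free edges followed, if RSA stalls short of the
// target count, by vacancy-diffusion repair (dimer flips random-walk the
// vacancies until two meet and a fresh dimer is placed).
// [[Rcpp::export]]
List cpp_init(int L, int n_obst, int m_dimers, double rsa_factor,
              double repair_factor, int max_restarts,
              IntegerVector obstacle_sites) {
  Lattice lat(L);
  int N = lat.N;
  std::vector<int> species;
  std::vector<std::pair<int, int> > dimer_sites;
  bool fixed_obst = obstacle_sites.size() > 0;
  if (fixed_obst && obstacle_sites.size() != n_obst)
    stop("obstacle_sites length disagrees with the obstacle count");

  bool ok = false;
  for (int attempt = 0; attempt <= max_restarts && !ok; ++attempt) {
    species.assign(N, SOLVENT);
    dimer_sites.clear();
    if (fixed_obst) {
      for (int i = 0; i < n_obst; ++i) species[obstacle_sites[i] - 1] = OBSTACLE;
    } else {
      // obstacles: partial Fisher-Yates
      std::vector<int> perm(N);
      for (int i = 0; i < N; ++i) perm[i] = i;
      for (int i = 0; i < n_obst; ++i) {
        int j = i + runif_int(N - i);
        std::swap(perm[i], perm[j]);
        species[perm[i]] = OBSTACLE;
      }
    }
    // RSA on edges with both endpoints free
    int placed = 0;
    double budget = rsa_factor * std::max(1, m_dimers);
    double tries = 0;
    while (placed < m_dimers && tries < budget) {
      ++tries;
      int s = runif_int(N);
      if (species[s] != SOLVENT) continue;
      int k = runif_int(6);
      int s2 = lat.nbr[(size_t)s * 6 + k];
      if (species[s2] != SOLVENT) continue;
      species[s] = MER;
      species[s2] = MER;
      dimer_sites.push_back(std::make_pair(s, s2));
      ++placed;
    }
    // vacancy-diffusion repair
    if (placed < m_dimers) {
      std::vector<int> vac;
      for (int s = 0; s < N; ++s)
        if (species[s] == SOLVENT) vac.push_back(s);
      // map mer site -> index in dimer_sites
      std::vector<int> dimer_at(N, -1);
      for (size_t i = 0; i < dimer_sites.size(); ++i) {
        dimer_at[dimer_sites[i].first] = (int)i;
        dimer_at[dimer_sites[i].second] = (int)i;
      }
      double moves = 0, cap = repair_factor * (double)N;
      while (placed < m_dimers && moves < cap && !vac.empty()) {
        ++moves;
        int vi = runif_int((int)vac.size());
        int v = vac[vi];
        // adjacent vacancy? place a dimer
        int cand[6], nc = 0, merc[6], nm = 0;
        for (int k = 0; k < 6; ++k) {
          int s2 = lat.nbr[(size_t)v * 6 + k];
          if (species[s2] == SOLVENT) cand[nc++] = s2;
          else if (species[s2] == MER) merc[nm++] = s2;
        }
        if (nc > 0) {
          int w = cand[runif_int(nc)];
          species[v] = MER;
          species[w] = MER;
          dimer_at[v] = (int)dimer_sites.size();
          dimer_at[w] = (int)dimer_sites.size();
          dimer_sites.push_back(std::make_pair(v, w));
          ++placed;
          // remove v and w from vacancy list
          vac[vi] = vac.back(); vac.pop_back();
          for (size_t z = 0; z < vac.size(); ++z)
            if (vac[z] == w) { vac[z] = vac.back(); vac.pop_back(); break; }
          continue;
        }
        if (nm == 0) continue; // vacancy boxed in by obstacles
        // flip a neighboring dimer into the vacancy; its far mer site opens
        int a = merc[runif_int(nm)];
        int di = dimer_at[a];
        int b = (dimer_sites[di].first == a) ? dimer_sites[di].second
                                             : dimer_sites[di].first;
        species[v] = MER;
        species[b] = SOLVENT;
        dimer_at[v] = di;
        dimer_at[a] = di;
        dimer_at[b] = -1;
        dimer_sites[di] = std::make_pair(v, a);
        vac[vi] = b;
      }
    }
    ok = (placed == m_dimers);
  }
  if (!ok) stop("infeasible-packing: dimer placement failed after restart cap");

  // object enumeration: dimers first (placement order), then remaining sites
  // ascending
  int n_obj = N;
  IntegerVector obj_at(N), site_of(n_obj), obj_species(n_obj), partner(n_obj);
  NumericVector x0(n_obj), y0(n_obj), dispx(n_obj), dispy(n_obj);
  IntegerMatrix dimers(m_dimers, 2);
  int next_obj = 0;
  for (int i = 0; i < m_dimers; ++i) {
    int s1 = dimer_sites[i].first, s2 = dimer_sites[i].second;
    int o1 = next_obj++, o2 = next_obj++;
    site_of[o1] = s1 + 1; site_of[o2] = s2 + 1;
    obj_species[o1] = MER; obj_species[o2] = MER;
    partner[o1] = o2 + 1; partner[o2] = o1 + 1;
    obj_at[s1] = o1 + 1; obj_at[s2] = o2 + 1;
    dimers(i, 0) = o1 + 1; dimers(i, 1) = o2 + 1;
  }
  for (int s = 0; s < N; ++s) {
    if (species[s] == MER) continue;
    int o = next_obj++;
    site_of[o] = s + 1;
    obj_species[o] = species[s];
    partner[o] = 0;
    obj_at[s] = o + 1;
  }
  for (int o = 0; o < n_obj; ++o) {
    int s = site_of[o] - 1;
    int q = s % L, r = s / L;
    x0[o] = q + 0.5 * r;
    y0[o] = SQ32 * r;
    dispx[o] = 0.0;
    dispy[o] = 0.0;
  }
  return List::create(
      _["L"] = L, _["species"] = IntegerVector(species.begin(), species.end()),
      _["obj_at"] = obj_at, _["site_of"] = site_of, _["obj_species"] = obj_species,
      _["partner"] = partner, _["dimers"] = dimers, _["x0"] = x0, _["y0"] = y0,
      _["dispx"] = dispx, _["dispy"] = dispy, _["t"] = 0.0);
}

// Union-find with displacement tracking: a cluster wraps the torus iff a
// union of two sites already in one cluster arrives with an inconsistent
// relative displacement.
// [[Rcpp::export]]
IntegerVector cpp_perc_sweep(int L, NumericVector p, int n_real) {
  Lattice lat(L);
  int N = lat.N;
  IntegerVector wraps(p.size());
  std::vector<char> open(N);
  std::vector<int> parent(N), sz(N), dq(N), dr(N);

  for (int ip = 0; ip < p.size(); ++ip) {
    double pp = p[ip];
    int count = 0;
    for (int rep = 0; rep < n_real; ++rep) {
      for (int s = 0; s < N; ++s) open[s] = (unif_rand() < pp);
      for (int s = 0; s < N; ++s) {
        parent[s] = s; sz[s] = 1; dq[s] = 0; dr[s] = 0;
      }
      bool wrapped = false;
      for (int s = 0; s < N && !wrapped; ++s) {
        if (!open[s]) continue;
        int q = s % L, r = s / L;
        for (int k = 0; k < 3; ++k) { // 3 directions cover each edge once
          int s2 = lat.nbr[(size_t)s * 6 + k];
          if (!open[s2]) continue;
          // find roots with accumulated displacement
          int a = s, ax = 0, ay = 0;
          while (parent[a] != a) { ax += dq[a]; ay += dr[a]; a = parent[a]; }
          // path compression for s
          int cur = s, cx = 0, cy = 0;
          while (parent[cur] != cur) {
            int nx = cx + dq[cur], ny = cy + dr[cur], pnt = parent[cur];
            dq[cur] = ax - cx; dr[cur] = ay - cy;
            parent[cur] = a;
            cx = nx; cy = ny; cur = pnt;
          }
          int b = s2, bx = 0, by = 0;
          while (parent[b] != b) { bx += dq[b]; by += dr[b]; b = parent[b]; }
          int cur2 = s2, ex = 0, ey = 0;
          while (parent[cur2] != cur2) {
            int nx = ex + dq[cur2], ny = ey + dr[cur2], pnt = parent[cur2];
            dq[cur2] = bx - ex; dr[cur2] = by - ey;
            parent[cur2] = b;
            ex = nx; ey = ny; cur2 = pnt;
          }
          // edge: pos(s2) = pos(s) + offset(k) in unwrapped axial coords
          int ox = DQ[k], oy = DR[k];
          if (a == b) {
            if (ax + ox != bx || ay + oy != by) { wrapped = true; break; }
          } else {
            if (sz[a] < sz[b]) {
              // link a under b: disp(a) = pos(s2)-offset... derive:
              // pos(s) rel b must equal ax' = dq[a] + (pos rel a of s)
              dq[a] = bx - ox - ax;
              dr[a] = by - oy - ay;
              parent[a] = b;
              sz[b] += sz[a];
            } else {
              dq[b] = ax + ox - bx;
              dr[b] = ay + oy - by;
              parent[b] = a;
              sz[a] += sz[b];
            }
          }
        }
        (void)q; (void)r;
      }
      if (wrapped) ++count;
    }
    wraps[ip] = count;
  }
  return wraps;
}
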