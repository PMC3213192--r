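// Brownian-dynamics variant with a finitely diffusing inactive pool.
// Geometries: plane ("disk2d", unit square with periodic wrap), volume
// ("box3d", unit cube with periodic wrap), and "sphere_surface_interior"
// (active molecules on the surface of a sphere of radius R, inactive
// molecules inside the ball; distances are 3-D Euclidean). Recruitment is a
// proximity reaction: an (active, inactive) pair closer than reaction_radius
// reacts with probability p_react per step; at most one recruitment per
// inactive molecule per step, the recruiter drawn uniformly among its active
// neighbors. Neighbor queries use uniform spatial binning with cell size =
// reaction_radius.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum Geom { PLANE2D = 0, BOX3D = 1, SPHERE = 2 };

struct Grid {
  int nc;           // cells per axis
  int dim;          // 2 or 3
  double cell;      // cell width
  double lo;        // domain lower corner (0 for boxes, -R for sphere)
  bool periodic;
  std::vector<std::vector<int>> cells;

  void init(int nc_, int dim_, double cell_, double lo_, bool periodic_) {
    nc = nc_; dim = dim_; cell = cell_; lo = lo_; periodic = periodic_;
    int total = nc;
    for (int d = 1; d < dim; ++d) total *= nc;
    cells.assign(total, std::vector<int>());
  }
  int coord(double x) const {
    int c = (int)std::floor((x - lo) / cell);
    if (c < 0) c = 0;
    if (c >= nc) c = nc - 1;
    return c;
  }
  int flat(const int *ix) const {
    int f = ix[0];
    for (int d = 1; d < dim; ++d) f = f * nc + ix[d];
    return f;
  }
  void insert(const double *x, int id) {
    int ix[3];
    for (int d = 0; d < dim; ++d) ix[d] = coord(x[d]);
    cells[flat(ix)].push_back(id);
  }
};

static double pair_dist2(const double *a, const double *b, int dim,
                         bool periodic) {
  double s = 0;
  for (int d = 0; d < dim; ++d) {
    double dx = std::fabs(a[d] - b[d]);
    if (periodic && dx > 0.5) dx = 1.0 - dx;
    s += dx * dx;
  }
  return s;
}

static void wrap01(double *x, int dim) {
  for (int d = 0; d < dim; ++d) x[d] -= std::floor(x[d]);
}

// [[Rcpp::export]]
List run_geometry_core(NumericMatrix act0, IntegerMatrix clan0_,
                       NumericMatrix inact0, int next_clan0, int geom_code,
                       double R_sphere, double k_off, double k_on,
                       double p_react, double reaction_radius,
                       double D_m, double D_c, double t0, double t_end,
                       double dt, int record_stride, bool record_full) {
  const Geom geom = (Geom)geom_code;
  const int dim = (geom == PLANE2D) ? 2 : 3;
  const bool periodic = (geom != SPHERE);
  const double r2 = reaction_radius * reaction_radius;

  long n_steps = (long)std::floor((t_end - t0) / dt + 1e-9);
  double p_off = k_off * dt, p_on = k_on * dt;
  if (p_off >= 0.1) stop("dt too large: k_off*dt = %g >= 0.1", p_off);
  if (p_on >= 0.1) stop("dt too large: k_on*dt = %g >= 0.1", p_on);
  if (p_react < 0 || p_react > 1) stop("p_react must be in [0,1]");

  // flat coordinate storage
  std::vector<double> act, inact;
  std::vector<int> clan;
  for (int i = 0; i < act0.nrow(); ++i)
    for (int d = 0; d < dim; ++d) act.push_back(act0(i, d));
  for (int i = 0; i < act0.nrow(); ++i) clan.push_back(clan0_(i, 0));
  for (int i = 0; i < inact0.nrow(); ++i)
    for (int d = 0; d < dim; ++d) inact.push_back(inact0(i, d));
  int next_clan = next_clan0;

  const double sd_m = std::sqrt(2.0 * D_m * dt);
  const double sd_c = std::sqrt(2.0 * D_c * dt);
  const double span = periodic ? 1.0 : 2.0 * R_sphere;
  int nc = (int)std::floor(span / reaction_radius);
  if (nc < 1) nc = 1;
  if (nc > 64) nc = 64;
  const double cell = span / nc;
  const double lo = periodic ? 0.0 : -R_sphere;

  std::vector<double> rec_t;
  std::vector<int> rec_Na, rec_Ni, rec_clans;
  List rec_apos, rec_ipos, rec_clanid;
  if (record_full) {
    long cap = n_steps / record_stride + 2;
    rec_apos = List((int)cap); rec_ipos = List((int)cap);
    rec_clanid = List((int)cap);
  }
  int n_rec = 0;

  Grid grid;
  std::vector<int> neigh;
  std::vector<int> order;

  for (long step = 1; step <= n_steps; ++step) {
    int N_a = (int)clan.size();

    // (a) inactivation: active -> inactive in place
    //     (sphere: released just inside the surface)
    if (N_a > 0 && p_off > 0) {
      for (int i = N_a - 1; i >= 0; --i) {
        if (unif_rand() < p_off) {
          double x[3];
          for (int d = 0; d < dim; ++d) x[d] = act[(size_t)i * dim + d];
          if (geom == SPHERE) {
            for (int d = 0; d < 3; ++d) x[d] *= 0.999;
          }
          for (int d = 0; d < dim; ++d) inact.push_back(x[d]);
          // swap-remove active i
          int last = (int)clan.size() - 1;
          for (int d = 0; d < dim; ++d)
            act[(size_t)i * dim + d] = act[(size_t)last * dim + d];
          clan[i] = clan[last];
          act.resize((size_t)last * dim);
          clan.resize(last);
        }
      }
    }

    // (b) recruitment via proximity reaction
    N_a = (int)clan.size();
    int N_i = (int)(inact.size() / dim);
    if (N_a > 0 && N_i > 0 && p_react > 0) {
      grid.init(nc, dim, cell, lo, periodic);
      for (int i = 0; i < N_a; ++i) grid.insert(&act[(size_t)i * dim], i);
      // randomized order over inactive molecules
      order.resize(N_i);
      for (int i = 0; i < N_i; ++i) order[i] = i;
      for (int i = N_i - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      std::vector<int> converted;
      for (int oi = 0; oi < N_i; ++oi) {
        int i = order[oi];
        const double *xi = &inact[(size_t)i * dim];
        neigh.clear();
        int ix[3], jx[3];
        for (int d = 0; d < dim; ++d) ix[d] = grid.coord(xi[d]);
        int lo_d[3], hi_d[3];
        for (int d = 0; d < dim; ++d) {
          // nc <= 2 with periodic wrap would revisit cells; scan each cell once
          if (periodic && nc <= 2) { lo_d[d] = 0; hi_d[d] = nc - 1; }
          else { lo_d[d] = ix[d] - 1; hi_d[d] = ix[d] + 1; }
        }
        for (int a = lo_d[0]; a <= hi_d[0]; ++a) {
          jx[0] = periodic ? ((a % nc) + nc) % nc : std::min(std::max(a, 0), nc - 1);
          if (!periodic && (a < 0 || a >= nc)) continue;
          for (int b = lo_d[1]; b <= hi_d[1]; ++b) {
            jx[1] = periodic ? ((b % nc) + nc) % nc : b;
            if (!periodic && (b < 0 || b >= nc)) continue;
            if (dim == 2) {
              for (int id : grid.cells[grid.flat(jx)])
                if (pair_dist2(xi, &act[(size_t)id * dim], dim, periodic) <= r2)
                  neigh.push_back(id);
            } else {
              for (int cidx = lo_d[2]; cidx <= hi_d[2]; ++cidx) {
                jx[2] = periodic ? ((cidx % nc) + nc) % nc : cidx;
                if (!periodic && (cidx < 0 || cidx >= nc)) continue;
                for (int id : grid.cells[grid.flat(jx)])
                  if (pair_dist2(xi, &act[(size_t)id * dim], dim, periodic) <= r2)
                    neigh.push_back(id);
              }
            }
          }
        }
        if (neigh.empty()) continue;
        // one recruitment max per inactive molecule: pair order randomized,
        // overall conversion prob 1 - (1-p_react)^k
        double p_conv = 1.0 - std::pow(1.0 - p_react, (double)neigh.size());
        if (unif_rand() < p_conv) {
          int rid = neigh[(int)(unif_rand() * neigh.size()) % neigh.size()];
          converted.push_back(i);
          for (int d = 0; d < dim; ++d)
            act.push_back(act[(size_t)rid * dim + d]);
          clan.push_back(clan[rid]);
        }
      }
      // remove converted inactive molecules (descending order, swap-remove)
      std::sort(converted.begin(), converted.end(), std::greater<int>());
      for (int i : converted) {
        int last = (int)(inact.size() / dim) - 1;
        for (int d = 0; d < dim; ++d)
          inact[(size_t)i * dim + d] = inact[(size_t)last * dim + d];
        inact.resize((size_t)last * dim);
      }
    }

    // (c) spontaneous activation at current position
    N_i = (int)(inact.size() / dim);
    if (N_i > 0 && p_on > 0) {
      for (int i = N_i - 1; i >= 0; --i) {
        if (unif_rand() < p_on) {
          double x[3];
          for (int d = 0; d < dim; ++d) x[d] = inact[(size_t)i * dim + d];
          if (geom == SPHERE) { // project to surface
            double nrm = std::sqrt(x[0]*x[0] + x[1]*x[1] + x[2]*x[2]);
            if (nrm < 1e-12) { x[0] = R_sphere; x[1] = 0; x[2] = 0; }
            else for (int d = 0; d < 3; ++d) x[d] *= R_sphere / nrm;
          }
          for (int d = 0; d < dim; ++d) act.push_back(x[d]);
          clan.push_back(next_clan++);
          int last = (int)(inact.size() / dim) - 1;
          for (int d = 0; d < dim; ++d)
            inact[(size_t)i * dim + d] = inact[(size_t)last * dim + d];
          inact.resize((size_t)last * dim);
        }
      }
    }

    // (d) diffusion
    int N_a2 = (int)clan.size();
    for (int i = 0; i < N_a2; ++i) {
      double *x = &act[(size_t)i * dim];
      if (geom == SPHERE) {
        // tangent-plane Gaussian step + radial re-projection
        double g[3] = {norm_rand() * sd_m, norm_rand() * sd_m, norm_rand() * sd_m};
        double dot = (g[0]*x[0] + g[1]*x[1] + g[2]*x[2]) / (R_sphere * R_sphere);
        for (int d = 0; d < 3; ++d) x[d] += g[d] - dot * x[d];
        double nrm = std::sqrt(x[0]*x[0] + x[1]*x[1] + x[2]*x[2]);
        for (int d = 0; d < 3; ++d) x[d] *= R_sphere / nrm;
      } else {
        for (int d = 0; d < dim; ++d) x[d] += norm_rand() * sd_m;
        wrap01(x, dim);
      }
    }
    int N_i2 = (int)(inact.size() / dim);
    for (int i = 0; i < N_i2; ++i) {
      double *x = &inact[(size_t)i * dim];
      for (int d = 0; d < dim; ++d) x[d] += norm_rand() * sd_c;
      if (geom == SPHERE) {
        double nrm = std::sqrt(x[0]*x[0] + x[1]*x[1] + x[2]*x[2]);
        if (nrm > R_sphere) { // radial reflection at the surface
          double target = 2.0 * R_sphere - nrm;
          if (target < 0) target = 0.5 * R_sphere * unif_rand();
          for (int d = 0; d < 3; ++d) x[d] *= (nrm > 1e-12 ? target / nrm : 0.0);
        }
      } else {
        wrap01(x, dim);
      }
    }

    if (step % record_stride == 0) {
      rec_t.push_back(t0 + step * dt);
      rec_Na.push_back((int)clan.size());
      rec_Ni.push_back((int)(inact.size() / dim));
      std::unordered_set<int> s(clan.begin(), clan.end());
      rec_clans.push_back((int)s.size());
      if (record_full) {
        int na = (int)clan.size(), ni = (int)(inact.size() / dim);
        NumericMatrix ap(na, dim), ip(ni, dim);
        for (int i = 0; i < na; ++i)
          for (int d = 0; d < dim; ++d) ap(i, d) = act[(size_t)i * dim + d];
        for (int i = 0; i < ni; ++i)
          for (int d = 0; d < dim; ++d) ip(i, d) = inact[(size_t)i * dim + d];
        rec_apos[n_rec] = ap;
        rec_ipos[n_rec] = ip;
        rec_clanid[n_rec] = IntegerVector(clan.begin(), clan.end());
      }
      ++n_rec;
    }
  }

  int na = (int)clan.size(), ni = (int)(inact.size() / dim);
  NumericMatrix ap(na, dim), ip(ni, dim);
  for (int i = 0; i < na; ++i)
    for (int d = 0; d < dim; ++d) ap(i, d) = act[(size_t)i * dim + d];
  for (int i = 0; i < ni; ++i)
    for (int d = 0; d < dim; ++d) ip(i, d) = inact[(size_t)i * dim + d];
  List out = List::create(
    _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["N_active"] = IntegerVector(rec_Na.begin(), rec_Na.end()),
    _["N_inactive"] = IntegerVector(rec_Ni.begin(), rec_Ni.end()),
    _["n_clans"] = IntegerVector(rec_clans.begin(), rec_clans.end()),
    _["final_t"] = t0 + n_steps * dt,
    _["final_active"] = ap, _["final_inactive"] = ip,
    _["final_clan"] = IntegerVector(clan.begin(), clan.end()),
    _["final_next_clan"] = next_clan);
  if (record_full && n_rec > 0) {
    List a(n_rec), b(n_rec), c(n_rec);
    for (int i = 0; i < n_rec; ++i) {
      a[i] = rec_apos[i]; b[i] = rec_ipos[i]; c[i] = rec_clanid[i];
    }
    out["active_positions"] = a;
    out["inactive_positions"] = b;
    out["clan_ids"] = c;
  }
  return out;
}
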