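// Fixed-step operator-split particle simulation on a 1-D circular membrane
// with a well-mixed cytosol. Positions are stored as fractions of the
// circumference in [0,1). Order of sub-steps within one dt: dissociation
// (sampled on the pre-step membrane set), recruitment, spontaneous
// activation, lateral diffusion. Uses R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Draw k distinct indices from 0..n-1 (Floyd's algorithm); k << n typically.
static void sample_distinct(int n, int k, std::vector<int> &out) {
  out.clear();
  std::unordered_set<int> seen;
  for (int j = n - k; j < n; ++j) {
    int t = (int)(unif_rand() * (j + 1));
    if (t > j) t = j;
    if (seen.count(t)) t = j;
    seen.insert(t);
    out.push_back(t);
  }
}

static int count_distinct(const std::vector<int> &clan) {
  std::unordered_set<int> s(clan.begin(), clan.end());
  return (int)s.size();
}

// [[Rcpp::export]]
List run_membrane_core(NumericVector pos0, IntegerVector clan0,
                       int N_c0, int next_clan0, int N_T,
                       double k_off, double k_on_eff, double k_fb_eff,
                       double D_frac, double t0, double t_end, double dt,
                       int record_stride, bool record_full) {
  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<int> clan(clan0.begin(), clan0.end());
  int N_c = N_c0, next_clan = next_clan0;
  long n_steps = (long)std::floor((t_end - t0) / dt + 1e-9);
  if (n_steps < 0) stop("t_end before t0");

  double p_off = k_off * dt;
  if (p_off >= 0.1)
    stop("dt too large: per-molecule dissociation probability k_off*dt = %g >= 0.1",
         p_off);
  if (k_fb_eff * N_T * dt >= 0.1)
    stop("dt too large: per-molecule recruitment probability bound k_fb*(V_fb/V)*N_T*dt = %g >= 0.1",
         k_fb_eff * N_T * dt);

  double sd_step = std::sqrt(2.0 * D_frac * dt);

  long n_rec_max = n_steps / record_stride + 2;
  std::vector<double> rec_t;   rec_t.reserve(n_rec_max);
  std::vector<int> rec_Nc;     rec_Nc.reserve(n_rec_max);
  std::vector<int> rec_Nm;     rec_Nm.reserve(n_rec_max);
  std::vector<int> rec_clans;  rec_clans.reserve(n_rec_max);
  List rec_pos, rec_clanid;
  if (record_full) {
    rec_pos = List((int)n_rec_max);
    rec_clanid = List((int)n_rec_max);
  }
  int n_rec = 0;

  std::vector<int> pick;
  for (long step = 1; step <= n_steps; ++step) {
    int N_m = (int)pos.size();

    // (a) dissociation: each membrane molecule leaves w.p. k_off*dt
    if (N_m > 0 && p_off > 0) {
      int n_off = (int)R::rbinom(N_m, p_off);
      if (n_off > 0) {
        sample_distinct(N_m, n_off, pick);
        // remove by swap-with-back; iterate picks in decreasing order safe via sort
        std::sort(pick.begin(), pick.end(), std::greater<int>());
        for (int idx : pick) {
          pos[idx] = pos.back(); pos.pop_back();
          clan[idx] = clan.back(); clan.pop_back();
        }
        N_c += n_off;
      }
    }

    // (b) recruitment: each surviving membrane molecule recruits
    //     w.p. k_fb*(V_fb/V)*N_c*dt (N_c at sub-step start), capped by N_c
    int N_m2 = (int)pos.size();
    if (N_m2 > 0 && N_c > 0 && k_fb_eff > 0) {
      double p_fb = k_fb_eff * N_c * dt;
      int n_rcr = (int)R::rbinom(N_m2, p_fb);
      if (n_rcr > N_c) n_rcr = N_c;
      if (n_rcr > 0) {
        sample_distinct(N_m2, n_rcr, pick);
        for (int idx : pick) {
          pos.push_back(pos[idx]);
          clan.push_back(clan[idx]);
        }
        N_c -= n_rcr;
      }
    }

    // (c) spontaneous on-events: Poisson(k_on*(V_on/V)*N_c*dt), fresh clans
    if (N_c > 0 && k_on_eff > 0) {
      int n_on = (int)R::rpois(k_on_eff * N_c * dt);
      if (n_on > N_c) n_on = N_c;
      for (int j = 0; j < n_on; ++j) {
        pos.push_back(unif_rand());
        clan.push_back(next_clan++);
      }
      N_c -= n_on;
    }

    // (d) lateral diffusion with periodic wrap
    if (sd_step > 0) {
      for (size_t i = 0; i < pos.size(); ++i) {
        double x = pos[i] + norm_rand() * sd_step;
        x -= std::floor(x);
        pos[i] = x;
      }
    }

    if (step % record_stride == 0) {
      rec_t.push_back(t0 + step * dt);
      rec_Nc.push_back(N_c);
      rec_Nm.push_back((int)pos.size());
      rec_clans.push_back(count_distinct(clan));
      if (record_full) {
        rec_pos[n_rec] = NumericVector(pos.begin(), pos.end());
        rec_clanid[n_rec] = IntegerVector(clan.begin(), clan.end());
      }
      ++n_rec;
    }
  }

  List out = List::create(
    _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["N_c"] = IntegerVector(rec_Nc.begin(), rec_Nc.end()),
    _["N_m"] = IntegerVector(rec_Nm.begin(), rec_Nm.end()),
    _["n_clans"] = IntegerVector(rec_clans.begin(), rec_clans.end()),
    _["final_t"] = t0 + n_steps * dt,
    _["final_pos"] = NumericVector(pos.begin(), pos.end()),
    _["final_clan"] = IntegerVector(clan.begin(), clan.end()),
    _["final_N_c"] = N_c,
    _["final_next_clan"] = next_clan);
  if (record_full && n_rec > 0) {
    List rp(n_rec), rc(n_rec);
    for (int i = 0; i < n_rec; ++i) { rp[i] = rec_pos[i]; rc[i] = rec_clanid[i]; }
    out["positions"] = rp;
    out["clan_ids"] = rc;
  }
  return out;
}
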