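// Single-molecule stochastic simulation of transcription, termination,
// RNase cleavage and directional 5'->3' degradation on a linear genome.
//
// Event engine: Gillespie direct method over a small set of aggregated
// channels. Per-nucleotide polymerase translocation and degradation-front
// progression are exponential-clock channels; terminator passage is a
// one-shot Bernoulli draw resolved at the translocation that lands on the
// terminator. Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pol {
  int pos;  // active-site position, 1-based
  int mol;  // index into mols
};

struct Mol {
  int a;          // first intact (non-degraded) position
  int b;          // last transcribed position
  int pol;        // index into pols, -1 once released
  bool cleaved5;  // 5' end created by cleavage (fast degradation)
  int deg;        // 0 = not yet degrading, 1 = degrading
  bool stalled;   // degrading but front caught up with an attached pol
  bool alive;
};

// swap-remove by position, returns nothing; caller must know idx
inline void swap_remove(std::vector<int>& v, int idx) {
  v[idx] = v.back();
  v.pop_back();
}

inline int find_in(const std::vector<int>& v, int id) {
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] == id) return (int)i;
  return -1;
}

struct EventLog {
  std::vector<double> time;
  std::vector<int> code;
  std::vector<int> mol;
  std::vector<double> value;
  void add(double t, int c, int m, double v) {
    time.push_back(t); code.push_back(c); mol.push_back(m); value.push_back(v);
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int L, IntegerVector gene_start, IntegerVector gene_end,
              IntegerVector prom_pos, NumericVector prom_strength,
              IntegerVector term_pos, NumericVector term_strength,
              IntegerVector site_pos, NumericVector site_strength,
              int n_pol, int footprint, double pol_speed, double horizon,
              double sample_interval, double binding_scale,
              double k_deg_nascent, double deg_fold, double deg_speed,
              bool check_invariants, bool log_events) {
  const int M = gene_start.size();
  const int nP = prom_pos.size();
  const int nT = term_pos.size();
  const int nR = site_pos.size();
  const int n_samples = (int)std::floor(horizon / sample_interval + 1e-9) + 1;

  // position lookup tables
  std::vector<int> term_at(L + 2, -1), site_at(L + 2, -1);
  for (int j = 0; j < nT; ++j) term_at[term_pos[j]] = j;
  for (int j = 0; j < nR; ++j) site_at[site_pos[j]] = j;

  std::vector<Pol> pols;
  std::vector<Mol> mols;
  std::vector<int> wait_nasc, wait_clv, deg_active, deg_stalled;
  std::vector<std::vector<int>> site_mols(nR);

  IntegerMatrix counts(n_samples, M);
  NumericVector sample_times(n_samples);
  for (int i = 0; i < n_samples; ++i) sample_times[i] = i * sample_interval;

  EventLog log;
  long n_checks = 0, n_violations = 0;
  const double k_clv_end = k_deg_nascent * deg_fold;

  // channel propensity buffer: nP bindings, n_pol translocations,
  // deg-init nascent, deg-init cleaved, deg-step, nR cleavage channels
  std::vector<double> prop(nP + n_pol + 3 + nR);

  auto occluded = [&](int p) {
    for (size_t i = 0; i < pols.size(); ++i)
      if (std::abs(pols[i].pos - p) < footprint) return true;
    return false;
  };
  auto can_move = [&](int i) {
    int x = pols[i].pos;
    if (x >= L) return true;  // moving "off" the end = release, always allowed
    for (size_t j = 0; j < pols.size(); ++j) {
      if ((int)j == (int)i) continue;
      if (pols[j].pos > x && pols[j].pos - (x + 1) < footprint) return false;
    }
    return true;
  };

  auto record_sample = [&](int s) {
    for (size_t m = 0; m < mols.size(); ++m) {
      if (!mols[m].alive) continue;
      for (int g = 0; g < M; ++g)
        if (mols[m].a <= gene_start[g] && gene_end[g] <= mols[m].b)
          counts(s, g) += 1;
    }
  };

  auto release_pol = [&](int pi) {
    // detach polymerase pi from its molecule and return it to the pool
    int mid = pols[pi].mol;
    mols[mid].pol = -1;
    if (mols[mid].deg == 1 && mols[mid].a > mols[mid].b) {
      // degradation had consumed everything up to the stalled front
      mols[mid].alive = false;
      int k = find_in(deg_stalled, mid);
      if (k >= 0) swap_remove(deg_stalled, k);
    }
    // swap-remove pol, fixing the moved pol's back-reference
    pols[pi] = pols.back();
    pols.pop_back();
    if (pi < (int)pols.size()) mols[pols[pi].mol].pol = pi;
  };

  double t = 0.0;
  int next_sample = 0;

  for (;;) {
    // ---- propensities ----
    int free_pols = n_pol - (int)pols.size();
    int nc = 0;
    double total = 0.0;
    for (int j = 0; j < nP; ++j) {
      double a = (free_pols > 0 && !occluded(prom_pos[j]))
                     ? prom_strength[j] * free_pols * binding_scale
                     : 0.0;
      prop[nc++] = a; total += a;
    }
    int pol_base = nc;
    for (int i = 0; i < n_pol; ++i) {
      double a = (i < (int)pols.size() && can_move(i)) ? pol_speed : 0.0;
      prop[nc++] = a; total += a;
    }
    int deg_base = nc;
    prop[nc] = k_deg_nascent * wait_nasc.size(); total += prop[nc]; ++nc;
    prop[nc] = k_clv_end * wait_clv.size();      total += prop[nc]; ++nc;
    prop[nc] = deg_speed * deg_active.size();    total += prop[nc]; ++nc;
    int clv_base = nc;
    for (int j = 0; j < nR; ++j) {
      double a = site_strength[j] * site_mols[j].size();
      prop[nc++] = a; total += a;
    }

    double t_next = (total > 0.0) ? t + exp_rand() / total : horizon + 1.0;

    // ---- emit samples the event jump passes over ----
    while (next_sample < n_samples && sample_times[next_sample] <= t_next) {
      record_sample(next_sample);
      ++next_sample;
    }
    if (next_sample >= n_samples || t_next > horizon) break;
    t = t_next;

    // ---- select channel ----
    double u = unif_rand() * total;
    int ch = 0;
    double acc = prop[0];
    while (acc < u && ch < nc - 1) acc += prop[++ch];

    if (ch < pol_base) {
      // ---- promoter binding ----
      int p = prom_pos[ch];
      Mol m;
      m.a = p; m.b = p; m.pol = (int)pols.size();
      m.cleaved5 = false; m.deg = 0; m.stalled = false; m.alive = true;
      int mid = (int)mols.size();
      mols.push_back(m);
      Pol pl; pl.pos = p; pl.mol = mid;
      pols.push_back(pl);
      wait_nasc.push_back(mid);
      if (log_events) {
        log.add(t, 3, mid, prom_strength[ch]);
        log.add(t, 1, mid, k_deg_nascent);  // molecule created, nascent 5' end
      }
    } else if (ch < deg_base) {
      // ---- polymerase translocation (+ terminator / end-of-genome) ----
      int pi = ch - pol_base;
      int mid = pols[pi].mol;
      int x = pols[pi].pos + 1;
      if (x > L) {
        if (log_events) log.add(t, 7, mid, 0);
        release_pol(pi);
      } else {
        pols[pi].pos = x;
        mols[mid].b = x;
        if (mols[mid].stalled) {
          // degradation front can advance again now that b grew
          mols[mid].stalled = false;
          int k = find_in(deg_stalled, mid);
          if (k >= 0) { swap_remove(deg_stalled, k); deg_active.push_back(mid); }
        }
        // the site at x-1 is now fully transcribed (b > site position)
        int s = site_at[x - 1];
        if (s >= 0 && mols[mid].a <= site_pos[s])
          site_mols[s].push_back(mid);
        int tj = term_at[x];
        if (tj >= 0) {
          if (unif_rand() < term_strength[tj]) {
            if (log_events) log.add(t, 4, mid, term_pos[tj]);
            release_pol(pi);
          } else if (log_events) {
            log.add(t, 5, mid, term_pos[tj]);
          }
        }
      }
    } else if (ch == deg_base || ch == deg_base + 1) {
      // ---- degradation initiation at a 5' end ----
      std::vector<int>& wl = (ch == deg_base) ? wait_nasc : wait_clv;
      int idx = (int)(unif_rand() * wl.size());
      if (idx >= (int)wl.size()) idx = (int)wl.size() - 1;
      int mid = wl[idx];
      swap_remove(wl, idx);
      mols[mid].deg = 1;
      deg_active.push_back(mid);
      if (log_events) log.add(t, 8, mid, mols[mid].cleaved5 ? 1.0 : 0.0);
    } else if (ch == deg_base + 2) {
      // ---- degradation front consumes one nucleotide ----
      int idx = (int)(unif_rand() * deg_active.size());
      if (idx >= (int)deg_active.size()) idx = (int)deg_active.size() - 1;
      int mid = deg_active[idx];
      int s = site_at[mols[mid].a];
      if (s >= 0) {
        int k = find_in(site_mols[s], mid);
        if (k >= 0) swap_remove(site_mols[s], k);
      }
      mols[mid].a += 1;
      if (mols[mid].a > mols[mid].b) {
        swap_remove(deg_active, idx);
        if (mols[mid].pol >= 0) {
          mols[mid].stalled = true;
          deg_stalled.push_back(mid);
        } else {
          mols[mid].alive = false;
        }
      }
    } else {
      // ---- RNase cleavage: split a molecule at site j ----
      int j = ch - clv_base;
      int idx = (int)(unif_rand() * site_mols[j].size());
      if (idx >= (int)site_mols[j].size()) idx = (int)site_mols[j].size() - 1;
      int mid = site_mols[j][idx];
      int s = site_pos[j];
      int old_b = mols[mid].b;
      Mol m2;
      m2.a = s + 1; m2.b = old_b; m2.pol = mols[mid].pol;
      m2.cleaved5 = true; m2.deg = 0; m2.stalled = false; m2.alive = true;
      int mid2 = (int)mols.size();
      mols.push_back(m2);
      if (m2.pol >= 0) pols[m2.pol].mol = mid2;
      mols[mid].pol = -1;
      mols[mid].b = s;
      // transfer downstream site memberships to the new fragment;
      // the cut site itself is destroyed for the upstream fragment
      for (int q = 0; q < nR; ++q) {
        int sp = site_pos[q];
        if (sp < mols[mid].a || sp >= old_b) continue;
        if (sp == s) {
          int k = find_in(site_mols[q], mid);
          if (k >= 0) swap_remove(site_mols[q], k);
        } else if (sp > s) {
          int k = find_in(site_mols[q], mid);
          if (k >= 0) site_mols[q][k] = mid2;
        }
      }
      wait_clv.push_back(mid2);
      if (log_events) {
        log.add(t, 6, mid, (double)s);
        log.add(t, 2, mid2, k_clv_end);  // molecule created, cleaved 5' end
      }
    }

    if (check_invariants) {
      ++n_checks;
      if ((int)pols.size() > n_pol) ++n_violations;
      for (size_t i = 0; i < pols.size(); ++i)
        for (size_t j = i + 1; j < pols.size(); ++j)
          if (std::abs(pols[i].pos - pols[j].pos) < footprint) ++n_violations;
      for (size_t m = 0; m < mols.size(); ++m)
        if (mols[m].alive && mols[m].a > mols[m].b + 1) ++n_violations;
    }
  }

  List out = List::create(
      Named("times") = sample_times, Named("counts") = counts,
      Named("n_checks") = (double)n_checks,
      Named("n_violations") = (double)n_violations);
  if (log_events) {
    out["events"] = DataFrame::create(
        Named("time") = wrap(log.time), Named("code") = wrap(log.code),
        Named("molecule") = wrap(log.mol), Named("value") = wrap(log.value));
  }
  return out;
}
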