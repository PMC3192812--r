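// Exact stochastic simulation (Gillespie direct method) of the sectioned
// transcription / splicing / 3' maturation network, with staged activation:
// gene activation at t_act, an initiation burst of n_burst events, and
// splicing activation after an exponential delay at rate k_on.
//
// The reaction set mirrors the declarative network built in R (build_pathway);
// it is compiled here because the simulator fires 1e4-1e5 events per run and
// ensembles of hundreds of runs are routine in fitting.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// mechanism codes
enum { MECH_SINGLE = 0, MECH_MULTI = 1, MECH_FEEDBACK = 2 };
enum { MUT_NONE = 0, MUT_SS3 = 1, MUT_SS5 = 2 };

// action codes for reaction channels
enum {
  A_INIT, A_ESC, A_HOP, A_COMPLETE, A_COTRANS,
  A_KS, A_KE,
  A_UPRE, A_POST1, A_POST2, A_CO2, A_ULP, A_UMRNA,
  A_DEG_PRE, A_DEG_LAR, A_DEG_MRNA
};

struct Act { int type; int idx; };

inline int pick_weighted(const std::vector<int> &a, const std::vector<int> &b,
                         int extra, double u, int &which) {
  // select a pool index proportional to counts over concat(a, b, {extra});
  // which = 0 for a, 1 for b, 2 for extra scalar
  double tot = extra;
  for (size_t i = 0; i < a.size(); ++i) tot += a[i];
  for (size_t i = 0; i < b.size(); ++i) tot += b[i];
  double target = u * tot;
  double acc = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    acc += a[i];
    if (target < acc) { which = 0; return (int)i; }
  }
  for (size_t i = 0; i < b.size(); ++i) {
    acc += b[i];
    if (target < acc) { which = 1; return (int)i; }
  }
  which = 2;
  return 0;
}

} // namespace

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(List p, NumericVector sample_times, bool audit) {
  const int NS = as<int>(p["n_sections"]);
  const int branch = as<int>(p["branch_section"]) - 1; // 0-based
  const int m = as<int>(p["n_substeps"]);
  const int co2_mech = as<int>(p["co2_mech"]);
  const int post_mech = as<int>(p["post_mech"]);
  const int elong_multi = as<int>(p["elong_multi"]);
  const int mutant = as<int>(p["mutant"]);
  const bool allow_ulp = as<bool>(p["allow_ulp"]);

  const double k_init = as<double>(p["k_init"]);
  const double k_elong = as<double>(p["k_elong"]);
  const double eta = as<double>(p["eta"]);
  const double k_on = as<double>(p["k_on"]);
  const double c1 = as<double>(p["c1"]);
  const double c2 = as<double>(p["c2"]);
  const double k1_post = as<double>(p["k1_post"]);
  const double k2_post = as<double>(p["k2_post"]);
  const double k2_co = as<double>(p["k2_co"]);
  const double ks = as<double>(p["ks"]);
  const double ke = as<double>(p["ke"]);
  const double d_ppre = as<double>(p["d_ppre"]);
  const double d_plar = as<double>(p["d_plar"]);
  const double d_mrna = as<double>(p["d_mrna"]);
  const double t_act = as<double>(p["t_act"]);
  const int n_burst = as<int>(p["n_burst"]);

  const double k_trans = (eta > 0) ? k_elong / eta : 0.0;

  // pool sizes
  const int n_ppre = (post_mech == MECH_MULTI) ? m : 1;
  const int n_plar = (post_mech == MECH_MULTI) ? m : 1;
  const int n_ular = (mutant == MUT_SS3) ? m
                     : ((co2_mech == MECH_MULTI) ? m : 1);

  // state
  std::vector<int> occ(NS, 0); // 0 empty, 1 post track, 2 co track
  std::vector<int> polpos;     // sorted positions of in-flight polymerases
  polpos.reserve(NS);
  int apc = 0;
  std::vector<int> upre(m, 0), ppre(n_ppre, 0), plar(n_plar, 0),
      ular(n_ular, 0), umrna(m, 0);
  int pmrna = 0, lariat = 0, deg_pre = 0, deg_lar = 0, deg_mrna = 0;
  double y_co2 = 1, y_post1 = 1, y_post2 = 1;
  long cum_init = 0, cum_cotrans = 0, cum_post_exit = 0, cum_co_exit = 0;
  bool gene_active = false, splicing_active = false;
  int burst_used = 0;
  double t = 0.0, t_splice = R_PosInf;
  bool conservation_ok = true, exclusion_ok = true;

  const int nsamp = sample_times.size();
  const int nspec = 23;
  NumericMatrix counts(nsamp, nspec);
  IntegerMatrix occ_post(nsamp, NS), occ_co(nsamp, NS);
  int si = 0;

  std::vector<double> prop;
  std::vector<Act> acts;
  prop.reserve(4 * NS + 64);
  acts.reserve(4 * NS + 64);

  auto total_pools = [&]() {
    long s = 0;
    for (int j = 0; j < m; ++j) s += upre[j] + umrna[j];
    for (int j = 0; j < n_ppre; ++j) s += ppre[j];
    for (int j = 0; j < n_plar; ++j) s += plar[j];
    for (int j = 0; j < n_ular; ++j) s += ular[j];
    return s;
  };

  auto record = [&](int i) {
    int j = 0;
    long su = 0, sp = 0, sl = 0, spl = 0, sm = 0;
    for (int q = 0; q < m; ++q) { su += upre[q]; sm += umrna[q]; }
    for (int q = 0; q < n_ppre; ++q) sp += ppre[q];
    for (int q = 0; q < n_plar; ++q) spl += plar[q];
    for (int q = 0; q < n_ular; ++q) sl += ular[q];
    int inflight = 0, inpost = 0, inco = 0;
    for (int q = 0; q < NS; ++q) {
      occ_post(i, q) = (occ[q] == 1) ? 1 : 0;
      occ_co(i, q) = (occ[q] == 2) ? 1 : 0;
      if (occ[q] == 1) ++inpost;
      if (occ[q] == 2) ++inco;
    }
    inflight = inpost + inco;
    counts(i, j++) = su;        // U_pre
    counts(i, j++) = sp;        // P_pre
    counts(i, j++) = sl;        // U_lar
    counts(i, j++) = spl;       // P_lar
    counts(i, j++) = sm;        // U_mRNA
    counts(i, j++) = pmrna;     // P_mRNA
    counts(i, j++) = lariat;
    counts(i, j++) = deg_pre;
    counts(i, j++) = deg_lar;
    counts(i, j++) = deg_mrna;
    counts(i, j++) = apc;
    counts(i, j++) = inpost;    // pol_post
    counts(i, j++) = inco;      // pol_co
    counts(i, j++) = y_co2;
    counts(i, j++) = y_post1;
    counts(i, j++) = y_post2;
    counts(i, j++) = cum_init;
    counts(i, j++) = cum_cotrans;
    counts(i, j++) = cum_post_exit;
    counts(i, j++) = cum_co_exit;
    counts(i, j++) = gene_active ? 1 : 0;
    counts(i, j++) = splicing_active ? 1 : 0;
    counts(i, j++) = burst_used;
    if (audit) {
      // conservation: initiations == exits + APC + in-flight polymerases
      long exits = cum_post_exit + cum_co_exit;
      if (cum_init != exits + apc + inflight) conservation_ok = false;
      // releases == sum of pools + final products + degraded
      long released = su + sp + sl + spl + sm + pmrna + deg_pre + deg_lar +
                      deg_mrna;
      if (exits != released) conservation_ok = false;
      int npol = 0;
      for (int q = 0; q < NS; ++q) if (occ[q] != 0) ++npol;
      if (npol != inflight) exclusion_ok = false;
    }
  };

  while (si < nsamp) {
    // build propensities
    prop.clear();
    acts.clear();
    bool can_init = gene_active && apc == 0 &&
                    (splicing_active || burst_used < n_burst);
    if (can_init && k_init > 0) { prop.push_back(k_init); acts.push_back({A_INIT, 0}); }
    if (elong_multi) {
      if (apc == 1 && occ[0] == 0 && k_elong > 0) {
        prop.push_back(k_elong); acts.push_back({A_ESC, 0});
      }
      const bool cotrans_on = splicing_active && mutant != MUT_SS5 &&
                              k_trans > 0;
      for (size_t q = 0; q < polpos.size(); ++q) {
        const int i = polpos[q];
        if (i == NS - 1) {
          prop.push_back(k_elong); acts.push_back({A_COMPLETE, 0});
        } else if (occ[i + 1] == 0 && k_elong > 0) {
          prop.push_back(k_elong); acts.push_back({A_HOP, i});
        }
        if (cotrans_on && i >= branch && occ[i] == 1) {
          prop.push_back(k_trans); acts.push_back({A_COTRANS, i});
        }
      }
    } else {
      if (apc == 1) {
        if (ke > 0) { prop.push_back(ke); acts.push_back({A_KE, 0}); }
        if (splicing_active && mutant != MUT_SS5 && ks > 0) {
          prop.push_back(ks); acts.push_back({A_KS, 0});
        }
      }
    }
    for (int j = 0; j < m; ++j) {
      if (upre[j] > 0 && c1 > 0) { prop.push_back(c1 * upre[j]); acts.push_back({A_UPRE, j}); }
    }
    if (splicing_active && mutant != MUT_SS5 && k1_post > 0) {
      if (post_mech == MECH_MULTI) {
        for (int j = 0; j < n_ppre; ++j)
          if (ppre[j] > 0) { prop.push_back(k1_post * ppre[j]); acts.push_back({A_POST1, j}); }
      } else if (ppre[0] > 0) {
        double a = k1_post * ppre[0];
        if (post_mech == MECH_FEEDBACK) a *= y_post1;
        prop.push_back(a); acts.push_back({A_POST1, 0});
      }
    }
    if (splicing_active && mutant != MUT_SS3 && k2_post > 0) {
      if (post_mech == MECH_MULTI) {
        for (int j = 0; j < n_plar; ++j)
          if (plar[j] > 0) { prop.push_back(k2_post * plar[j]); acts.push_back({A_POST2, j}); }
      } else if (plar[0] > 0) {
        double a = k2_post * plar[0];
        if (post_mech == MECH_FEEDBACK) a *= y_post2;
        prop.push_back(a); acts.push_back({A_POST2, 0});
      }
    }
    if (mutant == MUT_SS3) {
      // uncleaved lariat-exon2 matures (m stages at c2) into P-lariat-exon2
      for (int j = 0; j < n_ular; ++j)
        if (ular[j] > 0 && c2 > 0) { prop.push_back(c2 * ular[j]); acts.push_back({A_CO2, j}); }
    } else if (mutant != MUT_SS5) {
      if (splicing_active && k2_co > 0) {
        if (co2_mech == MECH_MULTI) {
          for (int j = 0; j < n_ular; ++j)
            if (ular[j] > 0) { prop.push_back(k2_co * ular[j]); acts.push_back({A_CO2, j}); }
        } else if (ular[0] > 0) {
          double a = k2_co * ular[0];
          if (co2_mech == MECH_FEEDBACK) a *= y_co2;
          prop.push_back(a); acts.push_back({A_CO2, 0});
        }
      }
      if (allow_ulp && ular[0] > 0 && c2 > 0) {
        prop.push_back(c2 * ular[0]); acts.push_back({A_ULP, 0});
      }
    }
    for (int j = 0; j < m; ++j) {
      if (umrna[j] > 0 && c2 > 0) { prop.push_back(c2 * umrna[j]); acts.push_back({A_UMRNA, j}); }
    }
    if (d_ppre > 0) {
      long s = 0;
      for (int j = 0; j < m; ++j) s += upre[j];
      for (int j = 0; j < n_ppre; ++j) s += ppre[j];
      if (s > 0) { prop.push_back(d_ppre * s); acts.push_back({A_DEG_PRE, 0}); }
    }
    if (d_plar > 0 && mutant != MUT_SS5) {
      long s = 0;
      for (int j = 0; j < n_ular; ++j) s += ular[j];
      for (int j = 0; j < n_plar; ++j) s += plar[j];
      if (s > 0) { prop.push_back(d_plar * s); acts.push_back({A_DEG_LAR, 0}); }
    }
    if (d_mrna > 0) {
      long s = pmrna;
      for (int j = 0; j < m; ++j) s += umrna[j];
      if (s > 0) { prop.push_back(d_mrna * s); acts.push_back({A_DEG_MRNA, 0}); }
    }

    double a0 = 0.0;
    for (size_t i = 0; i < prop.size(); ++i) a0 += prop[i];
    double t_event = (a0 > 0) ? t + R::rexp(1.0 / a0) : R_PosInf;
    double t_sched = R_PosInf;
    if (!gene_active) t_sched = t_act;
    else if (!splicing_active) t_sched = t_splice;
    double t_stop = std::min(t_event, t_sched);

    // emit samples falling strictly before the next state change
    while (si < nsamp && sample_times[si] < t_stop) {
      record(si);
      ++si;
    }
    if (si >= nsamp) break;

    if (!R_FINITE(t_stop)) {
      // terminal: no reaction possible and no pending scheduled event
      while (si < nsamp) { record(si); ++si; }
      break;
    }

    if (t_sched <= t_event) {
      t = t_sched;
      if (!gene_active) {
        gene_active = true;
        t_splice = (k_on > 0) ? t + R::rexp(1.0 / k_on) : R_PosInf;
      } else {
        splicing_active = true;
      }
      continue;
    }

    t = t_event;
    double u = R::unif_rand() * a0;
    double acc = 0.0;
    int sel = (int)prop.size() - 1;
    for (size_t i = 0; i < prop.size(); ++i) {
      acc += prop[i];
      if (u < acc) { sel = (int)i; break; }
    }
    const Act act = acts[sel];
    switch (act.type) {
    case A_INIT:
      apc = 1; ++cum_init;
      if (!splicing_active) ++burst_used;
      break;
    case A_ESC:
      apc = 0; occ[0] = 1;
      polpos.insert(polpos.begin(), 0);
      break;
    case A_HOP: {
      occ[act.idx + 1] = occ[act.idx]; occ[act.idx] = 0;
      std::vector<int>::iterator it =
          std::lower_bound(polpos.begin(), polpos.end(), act.idx);
      *it = act.idx + 1; // stays sorted: next pol is beyond idx+1
      break;
    }
    case A_COMPLETE:
      if (occ[NS - 1] == 1) { ++upre[0]; ++cum_post_exit; }
      else { ++ular[0]; ++cum_co_exit; }
      occ[NS - 1] = 0;
      polpos.pop_back(); // the completing pol holds the largest position
      break;
    case A_COTRANS: occ[act.idx] = 2; ++cum_cotrans; break;
    case A_KS: apc = 0; ++ular[0]; ++cum_co_exit; ++cum_cotrans; break;
    case A_KE: apc = 0; ++upre[0]; ++cum_post_exit; break;
    case A_UPRE:
      --upre[act.idx];
      if (act.idx == m - 1) ++ppre[0]; else ++upre[act.idx + 1];
      break;
    case A_POST1:
      --ppre[act.idx];
      if (act.idx == n_ppre - 1) ++plar[0]; else ++ppre[act.idx + 1];
      if (post_mech == MECH_FEEDBACK) y_post1 += 1;
      break;
    case A_POST2:
      --plar[act.idx];
      if (act.idx == n_plar - 1) { ++pmrna; ++lariat; }
      else ++plar[act.idx + 1];
      if (post_mech == MECH_FEEDBACK) y_post2 += 1;
      break;
    case A_CO2:
      --ular[act.idx];
      if (mutant == MUT_SS3) {
        if (act.idx == n_ular - 1) ++plar[0]; else ++ular[act.idx + 1];
      } else {
        if (act.idx == n_ular - 1) { ++umrna[0]; ++lariat; }
        else ++ular[act.idx + 1];
        if (co2_mech == MECH_FEEDBACK) y_co2 += 1;
      }
      break;
    case A_ULP: --ular[0]; ++plar[0]; break;
    case A_UMRNA:
      --umrna[act.idx];
      if (act.idx == m - 1) ++pmrna; else ++umrna[act.idx + 1];
      break;
    case A_DEG_PRE: {
      int which; double u2 = R::unif_rand();
      int idx = pick_weighted(upre, ppre, 0, u2, which);
      if (which == 0) --upre[idx]; else --ppre[idx];
      ++deg_pre;
      break;
    }
    case A_DEG_LAR: {
      int which; double u2 = R::unif_rand();
      int idx = pick_weighted(ular, plar, 0, u2, which);
      if (which == 0) --ular[idx]; else --plar[idx];
      ++deg_lar;
      break;
    }
    case A_DEG_MRNA: {
      long s = pmrna;
      for (int j = 0; j < m; ++j) s += umrna[j];
      double target = R::unif_rand() * s, acc2 = 0.0;
      bool done = false;
      for (int j = 0; j < m && !done; ++j) {
        acc2 += umrna[j];
        if (target < acc2) { --umrna[j]; done = true; }
      }
      if (!done) --pmrna;
      ++deg_mrna;
      break;
    }
    }
  }

  CharacterVector spnames = CharacterVector::create(
      "U_pre", "P_pre", "U_lar", "P_lar", "U_mRNA", "P_mRNA", "lariat",
      "deg_pre", "deg_lar", "deg_mrna", "apc", "pol_post", "pol_co",
      "y_co2", "y_post1", "y_post2",
      "cum_init", "cum_cotrans", "cum_post_exit", "cum_co_exit",
      "gene_active", "splicing_active", "burst_used");
  colnames(counts) = spnames;

  return List::create(
      _["counts"] = counts,
      _["occ_post"] = occ_post,
      _["occ_co"] = occ_co,
      _["conservation_ok"] = conservation_ok,
      _["exclusion_ok"] = exclusion_ok);
}

// Single-polymerase walkers through the transition window: each walker faces,
// on each of n_choices sections, an exponential race between hopping onward
// (rate k_elong) and transitioning to the co-transcriptional track (rate
// k_elong / eta). Returns the number exiting with no transition.
// [[Rcpp::export(name = ".single_pol_walkers_cpp")]]
int single_pol_walkers_cpp(int n_walkers, int n_choices, double k_elong,
                           double eta) {
  const double k_trans = k_elong / eta;
  int n_post = 0;
  for (int w = 0; w < n_walkers; ++w) {
    bool transitioned = false;
    for (int i = 0; i < n_choices; ++i) {
      double t_hop = R::rexp(1.0 / k_elong);
      double t_tr = R::rexp(1.0 / k_trans);
      if (t_tr < t_hop) { transitioned = true; break; }
    }
    if (!transitioned) ++n_post;
  }
  return n_post;
}
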