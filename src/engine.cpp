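// Research-cycle engine.
//
// Implements the full evolutionary loop: per-lab hypothesis tackling /
// testing / publication, the death-birth replacement step with mutation,
// scheduled audits (false-positive, alpha or mistake based) with removal,
// effort boosts for the audited lab and its parent/child network, and audit
// cost accounting.
//
// All randomness is drawn from R's global RNG (unif_rand / norm_rand) in a
// fixed, documented order so that a pure-R reference implementation of the
// same loop produces bit-identical trajectories under the same seed.  The
// draw order per cycle is:
//   1. labs in storage order: tackle; if tackled: truth, result;
//      if false positive published: mistake
//   2. death: partial Fisher-Yates sample of `death_sample` indices;
//      one extra uniform draw only if the oldest-lab tie has >1 member
//   3. birth: same sampling over the survivors; tie draw only if needed;
//      one uniform for the mutation test, one normal only if it fires
//   4. audit (when scheduled and an eligible lab exists): one uniform to
//      select the lab; one normal for reviewer noise only when
//      review_error_pct > 0 and the audited count is positive; on removal,
//      the birth sampling of step 3 is repeated for the replacement.
// Changing this order is a breaking change for the engine-parity tests.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double EFFORT_MIN = 1.0;
const double EFFORT_MAX = 100.0;

inline double clamp_effort(double e) {
  return std::min(EFFORT_MAX, std::max(EFFORT_MIN, e));
}

inline double tackle_prob(double e, double eta) {
  return 1.0 - eta * std::log10(e);
}

inline double fp_prob(double W, double e) {
  return W / (1.0 + (1.0 - W) * e);
}

// uniform index in 0..n-1 (unif_rand() is in (0,1))
inline int runif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// inverse-ECDF (type 1) quantile of a copy of x
double quantile_type1(std::vector<double> x, double p) {
  std::sort(x.begin(), x.end());
  int n = (int)x.size();
  int k = (int)std::ceil(n * p - 1e-9);
  if (k < 1) k = 1;
  if (k > n) k = n;
  return x[k - 1];
}

struct Labs {
  std::vector<double> id, effort, power, payoff, parent; // parent: NA_REAL for founders
  std::vector<int> birth, papers, fps, mistakes;
  std::vector<int> audited;
  std::vector<double> tackle_p, alpha; // caches, recomputed on effort change

  int size() const { return (int)id.size(); }

  void recache(int i, double eta) {
    tackle_p[i] = tackle_prob(effort[i], eta);
    alpha[i] = fp_prob(power[i], effort[i]);
  }

  void erase(int i) {
    id.erase(id.begin() + i);
    effort.erase(effort.begin() + i);
    power.erase(power.begin() + i);
    payoff.erase(payoff.begin() + i);
    parent.erase(parent.begin() + i);
    birth.erase(birth.begin() + i);
    papers.erase(papers.begin() + i);
    fps.erase(fps.begin() + i);
    mistakes.erase(mistakes.begin() + i);
    audited.erase(audited.begin() + i);
    tackle_p.erase(tackle_p.begin() + i);
    alpha.erase(alpha.begin() + i);
  }
};

// partial Fisher-Yates: first k entries of a freshly built 0..n-1 pool
void sample_indices(int n, int k, std::vector<int>& pool, std::vector<int>& out) {
  pool.resize(n);
  for (int i = 0; i < n; i++) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; i++) {
    int j = i + runif_index(n - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

// index (into labs) of the sampled lab with the highest payoff, ties uniform
int pick_parent(const Labs& L, const std::vector<int>& sampled) {
  double best = -1.0;
  for (int idx : sampled) best = std::max(best, L.payoff[idx]);
  std::vector<int> tied;
  for (int idx : sampled) if (L.payoff[idx] == best) tied.push_back(idx);
  if (tied.size() == 1) return tied[0];
  return tied[runif_index((int)tied.size())];
}

// append a child of labs[parent_idx]; consumes 1 uniform (+1 normal if mutating)
void make_child(Labs& L, int parent_idx, int cycle, double& next_id,
                double mutation_prob, double mutation_sd, double eta) {
  double e = L.effort[parent_idx];
  if (unif_rand() < mutation_prob) e = clamp_effort(e + norm_rand() * mutation_sd);
  L.id.push_back(next_id);
  L.effort.push_back(e);
  L.power.push_back(L.power[parent_idx]);
  L.payoff.push_back(0.0);
  L.parent.push_back(L.id[parent_idx]);
  L.birth.push_back(cycle);
  L.papers.push_back(0);
  L.fps.push_back(0);
  L.mistakes.push_back(0);
  L.audited.push_back(0);
  L.tackle_p.push_back(tackle_prob(e, eta));
  L.alpha.push_back(fp_prob(L.power[parent_idx], e));
  next_id += 1.0;
}

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(int n_cycles, int record_every,
                 int pop_size, double eta, double truth_prior, double W,
                 double e0, double mutation_prob, double mutation_sd,
                 double mistake_prob, bool publish_negatives,
                 int death_sample, int birth_sample,
                 bool audit_enabled, int cycles_per_audit, int burn_in,
                 int min_papers, int statistic, double cutoff_percentile,
                 double cutoff_floor, double review_error_pct,
                 double el_plus, double en_plus,
                 double annual_salary, double papers_per_auditor,
                 int cost_mode) {
  Labs L;
  double next_id = 1.0;
  for (int i = 0; i < pop_size; i++) {
    L.id.push_back(next_id); next_id += 1.0;
    L.effort.push_back(e0);
    L.power.push_back(W);
    L.payoff.push_back(0.0);
    L.parent.push_back(NA_REAL);
    L.birth.push_back(0);
    L.papers.push_back(0);
    L.fps.push_back(0);
    L.mistakes.push_back(0);
    L.audited.push_back(0);
    L.tackle_p.push_back(tackle_prob(e0, eta));
    L.alpha.push_back(fp_prob(W, e0));
  }

  // world cumulative totals (include output of labs later removed)
  double tot_papers = 0, tot_fps = 0, tot_mistakes = 0;
  double tot_audits = 0, tot_removals = 0, tot_audited_papers = 0, tot_cost = 0;
  double monthly_salary = annual_salary / 12.0;

  // record buffers
  int n_rec = n_cycles / record_every;
  NumericVector rec_cycle(n_rec), rec_eff(n_rec), rec_alpha(n_rec),
      rec_papers(n_rec), rec_fps(n_rec), rec_mist(n_rec), rec_audits(n_rec),
      rec_removals(n_rec), rec_audpap(n_rec), rec_cost(n_rec);
  int rec_i = 0;

  // audit record buffers
  std::vector<double> a_cycle, a_id, a_papers, a_stat, a_obs, a_cut, a_removed, a_cost;

  std::vector<int> pool, sampled;
  std::vector<double> stats(pop_size);

  for (int cycle = 1; cycle <= n_cycles; cycle++) {
    // --- research phase: every lab, in storage order ---
    // Every tested hypothesis is written up; only positive results earn a
    // pay-off.  With publish_negatives = false, negative results are
    // discarded and do not count as papers.
    for (int i = 0; i < pop_size; i++) {
      if (unif_rand() >= L.tackle_p[i]) continue;       // no new hypothesis
      bool true_hyp = unif_rand() < truth_prior;
      double p_pos = true_hyp ? L.power[i] : L.alpha[i];
      bool positive = unif_rand() < p_pos;
      if (positive || publish_negatives) {
        L.papers[i]++; tot_papers += 1;
      }
      if (!positive) continue;
      L.payoff[i] += 1.0;
      if (!true_hyp) {
        L.fps[i]++; tot_fps += 1;
        if (unif_rand() < mistake_prob) { L.mistakes[i]++; tot_mistakes += 1; }
      }
    }

    // --- death: oldest of a random sample dies ---
    sample_indices(pop_size, death_sample, pool, sampled);
    int oldest_birth = L.birth[sampled[0]];
    for (int idx : sampled) oldest_birth = std::min(oldest_birth, L.birth[idx]);
    std::vector<int> tied;
    for (int idx : sampled) if (L.birth[idx] == oldest_birth) tied.push_back(idx);
    int dead = (tied.size() == 1) ? tied[0] : tied[runif_index((int)tied.size())];
    L.erase(dead);

    // --- birth: highest payoff of a random sample of survivors reproduces ---
    sample_indices(pop_size - 1, birth_sample, pool, sampled);
    int par = pick_parent(L, sampled);
    make_child(L, par, cycle, next_id, mutation_prob, mutation_sd, eta);

    // --- audit ---
    if (audit_enabled && cycle > burn_in &&
        (cycle - burn_in) % cycles_per_audit == 0) {
      std::vector<int> eligible;
      for (int i = 0; i < pop_size; i++)
        if (!L.audited[i] && L.papers[i] >= min_papers) eligible.push_back(i);
      if (!eligible.empty()) {
        int sel = eligible[runif_index((int)eligible.size())];
        // un-noised statistics of all current labs -> empirical cut-off
        for (int i = 0; i < pop_size; i++) {
          if (statistic == 0)
            stats[i] = L.papers[i] > 0 ? (double)L.fps[i] / L.papers[i] : 0.0;
          else if (statistic == 1)
            stats[i] = L.alpha[i];
          else
            stats[i] = L.papers[i] > 0 ? (double)L.mistakes[i] / L.papers[i] : 0.0;
        }
        double cutoff = (cutoff_percentile >= 1.0)
            ? R_PosInf
            : std::max(quantile_type1(stats, cutoff_percentile), cutoff_floor);
        // observed (possibly reviewer-noised) statistic of the audited lab
        double stat_true = stats[sel];
        double stat_obs = stat_true;
        if (review_error_pct > 0 && statistic != 1) {
          double cnt = (statistic == 0) ? L.fps[sel] : L.mistakes[sel];
          if (cnt > 0) {
            double sd = (review_error_pct / 100.0) * cnt / 1.96;
            double noised = cnt + std::nearbyint(norm_rand() * sd);
            noised = std::min((double)L.papers[sel], std::max(0.0, noised));
            stat_obs = noised / L.papers[sel];
          }
        }
        int papers_at_audit = L.papers[sel];
        double cost = (cost_mode == 0)
            ? papers_at_audit * monthly_salary
            : std::ceil(papers_at_audit / papers_per_auditor) * monthly_salary;
        double audited_id = L.id[sel];
        double audited_parent = L.parent[sel];
        bool removed = stat_obs > cutoff;
        if (removed) {
          L.erase(sel);
          sample_indices(pop_size - 1, birth_sample, pool, sampled);
          int rpar = pick_parent(L, sampled);
          make_child(L, rpar, cycle, next_id, mutation_prob, mutation_sd, eta);
          tot_removals += 1;
        } else {
          L.audited[sel] = 1;
          L.effort[sel] = clamp_effort(L.effort[sel] + el_plus);
          L.recache(sel, eta);
        }
        // network effect: direct parent and direct children still alive
        for (int i = 0; i < pop_size; i++) {
          bool is_parent = !ISNA(audited_parent) && L.id[i] == audited_parent;
          bool is_child = !ISNA(L.parent[i]) && L.parent[i] == audited_id;
          if (is_parent || is_child) {
            L.effort[i] = clamp_effort(L.effort[i] + en_plus);
            L.recache(i, eta);
          }
        }
        tot_audits += 1;
        tot_audited_papers += papers_at_audit;
        tot_cost += cost;
        a_cycle.push_back(cycle); a_id.push_back(audited_id);
        a_papers.push_back(papers_at_audit); a_stat.push_back(stat_true);
        a_obs.push_back(stat_obs); a_cut.push_back(cutoff);
        a_removed.push_back(removed ? 1.0 : 0.0); a_cost.push_back(cost);
      }
    }

    // --- record ---
    if (cycle % record_every == 0) {
      // long-double accumulation to agree bitwise with R's mean()
      long double me = 0, ma = 0;
      for (int i = 0; i < pop_size; i++) { me += L.effort[i]; ma += L.alpha[i]; }
      rec_cycle[rec_i] = cycle;
      rec_eff[rec_i] = (double)(me / pop_size);
      rec_alpha[rec_i] = (double)(ma / pop_size);
      rec_papers[rec_i] = tot_papers;
      rec_fps[rec_i] = tot_fps;
      rec_mist[rec_i] = tot_mistakes;
      rec_audits[rec_i] = tot_audits;
      rec_removals[rec_i] = tot_removals;
      rec_audpap[rec_i] = tot_audited_papers;
      rec_cost[rec_i] = tot_cost;
      rec_i++;
    }
  }

  List records = List::create(
      _["cycle"] = rec_cycle, _["mean_effort"] = rec_eff,
      _["mean_alpha"] = rec_alpha, _["cum_papers"] = rec_papers,
      _["cum_false_positives"] = rec_fps, _["cum_mistakes"] = rec_mist,
      _["cum_audits"] = rec_audits, _["cum_removals"] = rec_removals,
      _["cum_audited_papers"] = rec_audpap, _["cum_cost"] = rec_cost);
  List audits = List::create(
      _["cycle"] = wrap(a_cycle), _["lab_id"] = wrap(a_id),
      _["papers_at_audit"] = wrap(a_papers), _["statistic"] = wrap(a_stat),
      _["statistic_observed"] = wrap(a_obs), _["cutoff"] = wrap(a_cut),
      _["removed"] = wrap(a_removed), _["cost"] = wrap(a_cost));
  List labs = List::create(
      _["id"] = wrap(L.id), _["effort"] = wrap(L.effort),
      _["power"] = wrap(L.power), _["birth_cycle"] = wrap(L.birth),
      _["payoff"] = wrap(L.payoff), _["papers"] = wrap(L.papers),
      _["false_positives"] = wrap(L.fps), _["mistakes"] = wrap(L.mistakes),
      _["parent_id"] = wrap(L.parent), _["audited"] = wrap(L.audited));
  List totals = List::create(
      _["papers"] = tot_papers, _["false_positives"] = tot_fps,
      _["mistakes"] = tot_mistakes, _["audits"] = tot_audits,
      _["removals"] = tot_removals, _["audited_papers"] = tot_audited_papers,
      _["cost"] = tot_cost);
  return List::create(_["records"] = records, _["audits"] = audits,
                      _["labs"] = labs, _["totals"] = totals);
}
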