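#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent simulation of a single non-recombining locus.
//
// Time runs backward from the present in generations. Within each
// population, pairs of lineages coalesce at rate k(k-1)/(4N) per
// generation (N = diploid effective size, constant per population).
// Two kinds of scheduled events interrupt the continuous process:
//   * migration-pulse generations: every lineage currently in `dest`
//     moves to `source` with probability `rate` (applied once per
//     listed generation, backward in time);
//   * population splits: all lineages in `derived` move to `ancestral`.
// Mutations follow the infinite-sites model: when a branch terminates
// (its lineage coalesces), the number of mutations on it is Poisson
// with mean theta * branch length, each creating one segregating site
// carried by the leaves below the branch. The branch above the final
// common ancestor carries no observable mutations.
//
// events: matrix with columns (time, type, a, b, rate), sorted by time
//         with pulses (type 0) before splits (type 1) at equal times;
//         pulse rows: a = dest, b = source; split rows: a = derived,
//         b = ancestral. Population indices are 0-based.
// Returns the leaf x site 0/1 haplotype matrix plus, per leaf, the
// population from which its lineage most recently arrived through a
// pulse (-1 when no pulse affected that leaf's ancestry).

struct Lineage {
  int pop;
  double birth;
  std::vector<int> leaves;
};

// [[Rcpp::export(name = ".sim_locus")]]
List sim_locus(IntegerVector sample_pop,
               NumericVector pop_ne,
               NumericMatrix events,
               double theta) {
  const int n = sample_pop.size();
  const int n_pop = pop_ne.size();
  const int n_ev = events.nrow();

  std::vector<Lineage> act;
  act.reserve(n);
  for (int i = 0; i < n; ++i) {
    Lineage l;
    l.pop = sample_pop[i];
    l.birth = 0.0;
    l.leaves.assign(1, i);
    act.push_back(l);
  }
  IntegerVector origin(n, -1);
  std::vector< std::vector<int> > sites;

  std::vector<double> rate(n_pop);
  std::vector<int> cnt(n_pop);

  double t = 0.0;
  int iev = 0;

  // emit mutations for a finished branch
  auto emit = [&](const Lineage &l, double t_end) {
    if (theta <= 0.0) return;
    double len = t_end - l.birth;
    if (len <= 0.0) return;
    int m = (int) R::rpois(theta * len);
    for (int j = 0; j < m; ++j) sites.push_back(l.leaves);
  };

  while ((int) act.size() > 1) {
    double t_stop = (iev < n_ev) ? events(iev, 0) : R_PosInf;

    // continuous coalescence phase until the next scheduled event
    while ((int) act.size() > 1) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (size_t i = 0; i < act.size(); ++i) cnt[act[i].pop]++;
      double total = 0.0;
      for (int p = 0; p < n_pop; ++p) {
        rate[p] = (cnt[p] > 1) ? cnt[p] * (cnt[p] - 1.0) / (4.0 * pop_ne[p]) : 0.0;
        total += rate[p];
      }
      if (total <= 0.0) {
        if (!R_finite(t_stop))
          stop("lineages cannot coalesce: disconnected demographic model");
        t = t_stop;
        break;
      }
      double dt = R::exp_rand() / total;
      if (t + dt >= t_stop) { t = t_stop; break; }
      t += dt;

      // choose population proportional to rate, then a uniform pair
      double u = unif_rand() * total;
      int p = 0;
      for (; p < n_pop - 1; ++p) { u -= rate[p]; if (u <= 0.0) break; }
      int k = cnt[p];
      int ia = (int) std::floor(unif_rand() * k);
      int ib = (int) std::floor(unif_rand() * (k - 1));
      if (ib >= ia) ib++;
      // map within-pop indices to positions in act
      int pos_a = -1, pos_b = -1, seen = 0;
      for (size_t i = 0; i < act.size(); ++i) {
        if (act[i].pop == p) {
          if (seen == ia) pos_a = (int) i;
          if (seen == ib) pos_b = (int) i;
          seen++;
        }
      }
      emit(act[pos_a], t);
      emit(act[pos_b], t);
      Lineage merged;
      merged.pop = p;
      merged.birth = t;
      merged.leaves.reserve(act[pos_a].leaves.size() + act[pos_b].leaves.size());
      merged.leaves = act[pos_a].leaves;
      merged.leaves.insert(merged.leaves.end(), act[pos_b].leaves.begin(),
                           act[pos_b].leaves.end());
      if (pos_a < pos_b) std::swap(pos_a, pos_b);
      act.erase(act.begin() + pos_a);
      act.erase(act.begin() + pos_b);
      act.push_back(merged);
    }

    if ((int) act.size() <= 1) break;

    if (iev < n_ev) {
      int type = (int) events(iev, 1);
      int a = (int) events(iev, 2);
      int b = (int) events(iev, 3);
      if (type == 0) {
        double r = events(iev, 4);
        for (size_t i = 0; i < act.size(); ++i) {
          if (act[i].pop == a && unif_rand() < r) {
            act[i].pop = b;
            for (size_t j = 0; j < act[i].leaves.size(); ++j) {
              int lf = act[i].leaves[j];
              if (origin[lf] < 0) origin[lf] = b;
            }
          }
        }
      } else {
        for (size_t i = 0; i < act.size(); ++i)
          if (act[i].pop == a) act[i].pop = b;
      }
      iev++;
    }
  }

  const int S = (int) sites.size();
  IntegerMatrix H(n, S);
  for (int s = 0; s < S; ++s)
    for (size_t j = 0; j < sites[s].size(); ++j)
      H(sites[s][j], s) = 1;

  return List::create(_["hap"] = H, _["origin"] = origin);
}
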