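// Agent-based growth/death engine for snowflake clusters.
//
// Cells live in flat arrays; each cluster is a rooted lineage tree. One
// generation = synchronized reproduction (gated by life state, degree cap
// and shell-volume room), optional mutation of the heritable per-cell death
// probability, then death: each susceptible living cell dies independently
// and severs one of its incident links (uniform or branch-size biased),
// splitting its cluster in two. Severed fragments are re-rooted at the
// severed child and shells recomputed by subtraction. Severance frees the
// attachment site on both endpoints of the broken link, so a saturated
// survivor can bud again. All randomness comes from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<int> parent;      // -1 for a cluster root
  std::vector<int> birth, last_repro, shell, links, cluster;
  std::vector<char> alive;
  std::vector<double> pdeath;
  std::vector<std::vector<int>> kids;
  std::vector<double> csize;    // cells (living + dead) per cluster id
  size_t n() const { return parent.size(); }
};

Pop unpack(const List& state) {
  Pop p;
  IntegerVector parent = state["parent"], birth = state["birth_gen"],
    last = state["last_repro_gen"], shell = state["shell"],
    links = state["links_used"], cluster = state["cluster"];
  LogicalVector alive = state["alive"];
  NumericVector pd = state["p_death"];
  size_t n = parent.size();
  p.parent.assign(parent.begin(), parent.end());
  for (size_t i = 0; i < n; ++i) p.parent[i] -= 1; // R 1-based, 0 = none
  p.birth.assign(birth.begin(), birth.end());
  p.last_repro.assign(last.begin(), last.end());
  p.shell.assign(shell.begin(), shell.end());
  p.links.assign(links.begin(), links.end());
  p.cluster.assign(cluster.begin(), cluster.end());
  for (size_t i = 0; i < n; ++i) p.cluster[i] -= 1;
  p.alive.resize(n);
  for (size_t i = 0; i < n; ++i) p.alive[i] = alive[i];
  p.pdeath.assign(pd.begin(), pd.end());
  p.kids.assign(n, {});
  int n_clus = 0;
  for (size_t i = 0; i < n; ++i) n_clus = std::max(n_clus, p.cluster[i] + 1);
  p.csize.assign(n_clus, 0.0);
  for (size_t i = 0; i < n; ++i) {
    if (p.parent[i] >= 0) p.kids[p.parent[i]].push_back((int)i);
    p.csize[p.cluster[i]] += 1.0;
  }
  return p;
}

List pack(const Pop& p) {
  size_t n = p.n();
  IntegerVector parent(n), birth(n), last(n), shell(n), links(n), cluster(n);
  LogicalVector alive(n);
  NumericVector pd(n);
  for (size_t i = 0; i < n; ++i) {
    parent[i] = p.parent[i] + 1;
    birth[i] = p.birth[i]; last[i] = p.last_repro[i];
    shell[i] = p.shell[i]; links[i] = p.links[i];
    cluster[i] = p.cluster[i] + 1;
    alive[i] = p.alive[i] != 0;
    pd[i] = p.pdeath[i];
  }
  return List::create(_["parent"] = parent, _["birth_gen"] = birth,
                      _["last_repro_gen"] = last, _["shell"] = shell,
                      _["links_used"] = links, _["cluster"] = cluster,
                      _["alive"] = alive, _["p_death"] = pd);
}

inline double cap_of(int k) {
  double m = 2.0 * k + 1.0;
  return m * m * m;
}

// count the cells in the subtree rooted at r
long long subtree_count(const Pop& p, int r) {
  long long cnt = 0;
  std::vector<int> stack{r};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    ++cnt;
    for (int c : p.kids[v]) stack.push_back(c);
  }
  return cnt;
}

// detach subtree at r into a fresh cluster; returns its size
long long split_off(Pop& p, int r) {
  int old_c = p.cluster[r];
  int new_c = (int)p.csize.size();
  p.csize.push_back(0.0);
  int base_shell = p.shell[r];
  if (p.parent[r] >= 0) {
    auto& sib = p.kids[p.parent[r]];
    sib.erase(std::find(sib.begin(), sib.end(), r));
    p.parent[r] = -1;
  }
  long long cnt = 0;
  std::vector<int> stack{r};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    p.cluster[v] = new_c;
    p.shell[v] -= base_shell;
    ++cnt;
    for (int c : p.kids[v]) stack.push_back(c);
  }
  p.csize[new_c] = (double)cnt;
  p.csize[old_c] -= (double)cnt;
  return cnt;
}

} // namespace

// Run the generational engine. degree_cap < 0 means no cap; budget < 0 means
// run exactly `generations` rounds, otherwise stop after the first round at
// which cumulative births reach `budget` (still capped at `generations`).
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List state, int generations, double budget,
                int degree_cap, bool volume_limited, int death_delay,
                bool biased_severance, double mutation_prob,
                double p_min, double p_max, int gen0) {
  Pop p = unpack(state);
  RNGScope scope;

  std::vector<int> stat_gen;
  std::vector<double> stat_births, stat_deaths, stat_living, stat_dead,
    stat_clusters;
  std::vector<int> sp_gen;
  std::vector<double> sp_parent, sp_a, sp_b;
  double total_births = 0.0;
  bool extinct = false;

  for (int g = gen0 + 1; g <= gen0 + generations; ++g) {
    size_t n0 = p.n();

    // --- synchronized reproduction ------------------------------------
    std::vector<int> parents;
    parents.reserve(n0);
    for (size_t i = 0; i < n0; ++i) {
      if (!p.alive[i]) continue;
      if (degree_cap >= 0 && p.links[i] >= degree_cap) continue;
      parents.push_back((int)i);
    }
    if (volume_limited && !parents.empty()) {
      // per-cluster slack: capacity minus cumulative occupancy, per shell
      int n_clus = (int)p.csize.size();
      std::vector<int> max_shell(n_clus, 0);
      for (size_t i = 0; i < n0; ++i)
        max_shell[p.cluster[i]] = std::max(max_shell[p.cluster[i]], p.shell[i]);
      std::vector<size_t> offset(n_clus + 1, 0);
      for (int c = 0; c < n_clus; ++c)
        offset[c + 1] = offset[c] + (size_t)max_shell[c] + 2;
      std::vector<double> occ(offset[n_clus], 0.0);
      for (size_t i = 0; i < n0; ++i)
        occ[offset[p.cluster[i]] + p.shell[i]] += 1.0;
      for (int c = 0; c < n_clus; ++c) {
        double cum = 0.0;
        for (int k = 0; k <= max_shell[c] + 1; ++k) {
          cum += occ[offset[c] + k];
          double slack = cap_of(k) - cum;
          occ[offset[c] + k] = slack > 0.0 ? slack : 0.0;
        }
      }
      // grant births inner shells first, older cells (smaller index) first
      std::stable_sort(parents.begin(), parents.end(), [&](int a, int b) {
        if (p.cluster[a] != p.cluster[b]) return p.cluster[a] < p.cluster[b];
        if (p.shell[a] != p.shell[b]) return p.shell[a] < p.shell[b];
        return a < b;
      });
      std::vector<int> granted;
      granted.reserve(parents.size());
      for (int i : parents) {
        int c = p.cluster[i];
        int s = p.shell[i] + 1; // child's shell
        double room = R_PosInf;
        for (int k = s; k <= max_shell[c] + 1; ++k)
          room = std::min(room, occ[offset[c] + k]);
        if (room >= 1.0) {
          for (int k = s; k <= max_shell[c] + 1; ++k) occ[offset[c] + k] -= 1.0;
          granted.push_back(i);
        }
      }
      parents = granted;
    }
    for (int i : parents) {
      int child = (int)p.n();
      p.parent.push_back(i);
      p.birth.push_back(g);
      p.last_repro.push_back(g);
      p.shell.push_back(p.shell[i] + 1);
      p.links.push_back(1);
      p.cluster.push_back(p.cluster[i]);
      p.alive.push_back(1);
      p.pdeath.push_back(p.pdeath[i]);
      p.kids.push_back({});
      p.kids[i].push_back(child);
      p.links[i] += 1;
      p.last_repro[i] = g;
      p.csize[p.cluster[i]] += 1.0;
    }
    double births = (double)parents.size();
    total_births += births;

    // --- mutation of the heritable death probability -------------------
    if (mutation_prob > 0.0) {
      for (size_t i = 0; i < p.n(); ++i) {
        if (p.alive[i] && unif_rand() < mutation_prob)
          p.pdeath[i] = p_min + unif_rand() * (p_max - p_min);
      }
    }

    // --- death and link severance --------------------------------------
    double deaths = 0.0;
    size_t n_now = p.n();
    for (size_t i = 0; i < n_now; ++i) {
      if (!p.alive[i]) continue;
      // cells enter the death lottery the generation after their birth;
      // a delay > 0 additionally protects recently reproducing cells
      if (p.birth[i] == g) continue;
      if (g - p.last_repro[i] < death_delay) continue;
      if (unif_rand() >= p.pdeath[i]) continue;
      p.alive[i] = 0;
      deaths += 1.0;
      int c = p.cluster[i];
      if (p.csize[c] <= 1.0) continue; // lone cell: death without severance
      // branch weights over incident links
      std::vector<int> roots;   // severed-subtree root per link
      std::vector<double> w;
      long long below = 1;      // cells in subtree(i)
      for (int ch : p.kids[i]) {
        long long sz = subtree_count(p, ch);
        below += sz;
        roots.push_back(ch);
        w.push_back((double)sz);
      }
      if (p.parent[i] >= 0) {
        roots.push_back((int)i); // severing the parent link splits off subtree(i)
        w.push_back(p.csize[c] - (double)below);
      }
      if (roots.empty()) continue;
      int pick = 0;
      if (roots.size() > 1) {
        double tot = 0.0;
        if (biased_severance) { for (double x : w) tot += x; }
        else tot = (double)w.size();
        double u = unif_rand() * tot, acc = 0.0;
        for (size_t j = 0; j < w.size(); ++j) {
          acc += biased_severance ? w[j] : 1.0;
          if (u < acc) { pick = (int)j; break; }
          pick = (int)j;
        }
      }
      double parent_size = p.csize[c];
      // breaking the link frees the attachment site on both endpoints:
      // the surviving neighbour of the dead cell can bud again
      int r = roots[pick];
      int other = (r == (int)i) ? p.parent[i] : (int)i;
      p.links[r] -= 1;
      p.links[other] -= 1;
      long long frag = split_off(p, r);
      sp_gen.push_back(g);
      sp_parent.push_back(parent_size);
      sp_b.push_back((double)frag);
      sp_a.push_back(parent_size - (double)frag);
    }

    double living = 0.0;
    for (size_t i = 0; i < p.n(); ++i) living += p.alive[i] ? 1.0 : 0.0;
    stat_gen.push_back(g);
    stat_births.push_back(births);
    stat_deaths.push_back(deaths);
    stat_living.push_back(living);
    stat_dead.push_back((double)p.n() - living);
    stat_clusters.push_back((double)p.csize.size());

    if (living == 0.0) { extinct = true; break; }
    if (budget >= 0.0 && total_births >= budget) break;
  }

  DataFrame stats = DataFrame::create(
    _["gen"] = stat_gen, _["births"] = stat_births, _["deaths"] = stat_deaths,
    _["living"] = stat_living, _["dead"] = stat_dead,
    _["clusters"] = stat_clusters);
  DataFrame splits = DataFrame::create(
    _["gen"] = sp_gen, _["parent_size"] = sp_parent,
    _["fragment_kept"] = sp_a, _["fragment_severed"] = sp_b);
  return List::create(_["state"] = pack(p), _["stats"] = stats,
                      _["splits"] = splits, _["extinct"] = extinct,
                      _["total_births"] = total_births);
}

// Per-cluster summaries: living cells, total cells, and tree diameter
// (longest path in edges, over living and dead cells alike).
// [[Rcpp::export(name = ".engine_cluster_stats")]]
DataFrame engine_cluster_stats(List state) {
  Pop p = unpack(state);
  size_t n = p.n();
  int n_clus = (int)p.csize.size();
  std::vector<double> living(n_clus, 0.0), total(n_clus, 0.0);
  std::vector<int> diam(n_clus, 0);
  for (size_t i = 0; i < n; ++i) {
    total[p.cluster[i]] += 1.0;
    if (p.alive[i]) living[p.cluster[i]] += 1.0;
  }
  // two tallest downward paths through each cell, processed leaves-first
  std::vector<int> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return p.shell[a] > p.shell[b];
  });
  std::vector<int> best1(n, 0), best2(n, 0);
  for (int i : order) {
    int c = p.cluster[i];
    diam[c] = std::max(diam[c], best1[i] + best2[i]);
    int pa = p.parent[i];
    if (pa >= 0) {
      int h = best1[i] + 1;
      if (h > best1[pa]) { best2[pa] = best1[pa]; best1[pa] = h; }
      else if (h > best2[pa]) best2[pa] = h;
    }
  }
  IntegerVector cl(n_clus);
  for (int c = 0; c < n_clus; ++c) cl[c] = c + 1;
  return DataFrame::create(_["cluster"] = cl, _["living"] = living,
                           _["total"] = total, _["diameter"] = diam);
}
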