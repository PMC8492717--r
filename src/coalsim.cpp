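// Single-locus haploid coalescent under a population-split scenario,
// with finite-sites HKY mutations.  Backwards in time: each population
// has a constant effective size (in gene copies); at each event time
// every lineage of the derived population moves into the source
// population.  Randomness comes from R's RNG so set.seed() governs
// reproducibility end to end.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline bool is_transition(int a, int b) {
  // bases coded 0=A,1=C,2=G,3=T: transitions A<->G, C<->T
  return (a == 0 && b == 2) || (a == 2 && b == 0) ||
         (a == 1 && b == 3) || (a == 3 && b == 1);
}

// HKY jump chain: from state cur, pick a different base with
// probability proportional to pi[j] * (kappa for transitions)
static int hky_jump(int cur, double kappa, const std::vector<double>& pi) {
  double w[4], tot = 0.0;
  for (int j = 0; j < 4; ++j) {
    if (j == cur) { w[j] = 0.0; continue; }
    w[j] = pi[j] * (is_transition(cur, j) ? kappa : 1.0);
    tot += w[j];
  }
  double u = R::runif(0.0, tot), acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    acc += w[j];
    if (u <= acc) return j;
  }
  return 3;
}

static int draw_base(const std::vector<double>& pi) {
  double u = R::runif(0.0, 1.0), acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    acc += pi[j];
    if (u <= acc) return j;
  }
  return 3;
}

// [[Rcpp::export]]
List sim_coal_cpp(IntegerVector nsam, NumericVector ne,
                  NumericVector ev_time, IntegerVector ev_derived,
                  IntegerVector ev_source,
                  double mu, int L, double kappa, NumericVector basefreq,
                  IntegerVector root_seq) {
  // root_seq: length L of 1..4 codes fixing the ancestral state per
  // site, or length 0 to draw ancestral states from basefreq
  const int P = nsam.size();
  int ntot = 0;
  for (int p = 0; p < P; ++p) ntot += nsam[p];
  if (ntot < 1) stop("zero sample total");
  const int nnode = 2 * ntot - 1;
  std::vector<double> ntime(nnode, 0.0);
  std::vector<int> parent(nnode, -1);
  std::vector<int> popof(ntot);
  std::vector<std::vector<int> > active(P);
  {
    int id = 0;
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < nsam[p]; ++i) { active[p].push_back(id); popof[id] = p; ++id; }
  }
  int next_node = ntot, eidx = 0, nactive = ntot;
  const int E = ev_time.size();
  double t = 0.0;
  while (nactive > 1) {
    double R_tot = 0.0;
    std::vector<double> rate(P, 0.0);
    for (int p = 0; p < P; ++p) {
      double k = (double)active[p].size();
      if (k >= 2.0 && ne[p] > 0) { rate[p] = k * (k - 1.0) / (2.0 * ne[p]); R_tot += rate[p]; }
    }
    double next_ev = (eidx < E) ? ev_time[eidx] : R_PosInf;
    double dt = (R_tot > 0.0) ? R::rexp(1.0 / R_tot) : R_PosInf;
    if (t + dt >= next_ev) {
      if (eidx >= E) stop("scenario does not coalesce all lineages");
      t = next_ev;
      int d = ev_derived[eidx], s = ev_source[eidx];
      for (size_t i = 0; i < active[d].size(); ++i) active[s].push_back(active[d][i]);
      active[d].clear();
      ++eidx;
      continue;
    }
    t += dt;
    double u = R::runif(0.0, R_tot), acc = 0.0;
    int p = 0;
    for (; p < P; ++p) { acc += rate[p]; if (u <= acc) break; }
    if (p == P) p = P - 1;
    int k = active[p].size();
    int i1 = (int)std::floor(R::runif(0.0, 1.0) * k); if (i1 >= k) i1 = k - 1;
    int i2 = (int)std::floor(R::runif(0.0, 1.0) * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
    if (i2 >= i1) ++i2;
    int a = active[p][i1], b = active[p][i2];
    int anc = next_node++;
    ntime[anc] = t;
    parent[a] = anc; parent[b] = anc;
    // remove the two (larger index first), push ancestor
    if (i1 < i2) std::swap(i1, i2);
    active[p].erase(active[p].begin() + i1);
    active[p].erase(active[p].begin() + i2);
    active[p].push_back(anc);
    --nactive;
  }
  const int root = nnode - 1;

  // branch lengths and mutation placement
  std::vector<double> blen(nnode, 0.0);
  double TL = 0.0;
  for (int v = 0; v < nnode - 1; ++v) { blen[v] = ntime[parent[v]] - ntime[v]; TL += blen[v]; }
  int nmut = (int)R::rpois(mu * (double)L * TL);
  std::vector<int> mut_site(nmut), mut_branch(nmut);
  std::vector<double> mut_t(nmut);
  std::vector<double> cum(nnode - 1);
  double run = 0.0;
  for (int v = 0; v < nnode - 1; ++v) { run += blen[v]; cum[v] = run; }
  for (int m = 0; m < nmut; ++m) {
    double u = R::runif(0.0, TL);
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= nnode - 1) v = nnode - 2;
    mut_branch[m] = v;
    mut_site[m] = (int)std::floor(R::runif(0.0, 1.0) * L);
    if (mut_site[m] >= L) mut_site[m] = L - 1;
    mut_t[m] = ntime[v] + R::runif(0.0, 1.0) * blen[v]; // age on the branch
  }

  // children lists for the top-down state walk
  std::vector<std::vector<int> > child(nnode);
  for (int v = 0; v < nnode - 1; ++v) child[parent[v]].push_back(v);

  std::vector<double> pi(4);
  for (int j = 0; j < 4; ++j) pi[j] = basefreq[j];

  // distinct mutated sites
  std::vector<int> sites(mut_site);
  std::sort(sites.begin(), sites.end());
  sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  const int S = sites.size();
  IntegerMatrix seqs(ntot, S);
  std::vector<int> state(nnode);
  std::vector<std::pair<double,int> > branch_muts; // (age, order) per branch@site

  for (int sidx = 0; sidx < S; ++sidx) {
    int site = sites[sidx];
    // per-branch mutation ages at this site
    std::vector<std::vector<double> > bm(nnode);
    for (int m = 0; m < nmut; ++m)
      if (mut_site[m] == site) bm[mut_branch[m]].push_back(mut_t[m]);
    state[root] = (root_seq.size() == L) ? (root_seq[site] - 1) : draw_base(pi);
    // preorder walk (iterative)
    std::vector<int> stack; stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v != root) {
        int st = state[parent[v]];
        std::vector<double>& mm = bm[v];
        // apply mutations oldest (largest age) first
        std::sort(mm.begin(), mm.end(), std::greater<double>());
        for (size_t q = 0; q < mm.size(); ++q) st = hky_jump(st, kappa, pi);
        state[v] = st;
      }
      for (size_t c = 0; c < child[v].size(); ++c) stack.push_back(child[v][c]);
    }
    for (int i = 0; i < ntot; ++i) seqs(i, sidx) = state[i] + 1; // 1..4
  }

  IntegerVector popv(ntot);
  for (int i = 0; i < ntot; ++i) popv[i] = popof[i];
  IntegerVector posv(S);
  for (int s = 0; s < S; ++s) posv[s] = sites[s] + 1; // 1-based
  return List::create(_["seqs"] = seqs, _["positions"] = posv,
                      _["pop"] = popv, _["tmrca"] = ntime[root],
                      _["tree_length"] = TL, _["n_mutations"] = nmut);
}

// Per-population and per-pair summary statistics from an integer
// (1..4 coded) site matrix.  Mirrors the R implementation in
// summary_stats(); kept in C++ for the reference-table hot loop.
// [[Rcpp::export]]
NumericVector sumstats_cpp(IntegerMatrix seqs, IntegerVector pop, int P) {
  const int n = seqs.nrow(), S = seqs.ncol();
  std::vector<int> nsam(P, 0);
  for (int i = 0; i < n; ++i) nsam[pop[i]]++;
  const int npair = P * (P - 1) / 2;
  NumericVector out(3 * P + 2 * npair);
  // counts[p][b] per site
  std::vector<std::vector<int> > cnt(P, std::vector<int>(4, 0));
  std::vector<double> pi_w(P, 0.0), rare_sum(P, 0.0), rare_sq(P, 0.0);
  std::vector<int> nseg(P, 0);
  std::vector<std::vector<double> > dxy(P, std::vector<double>(P, 0.0));
  for (int s = 0; s < S; ++s) {
    for (int p = 0; p < P; ++p) std::fill(cnt[p].begin(), cnt[p].end(), 0);
    for (int i = 0; i < n; ++i) cnt[pop[i]][seqs(i, s) - 1]++;
    for (int p = 0; p < P; ++p) {
      if (nsam[p] < 2) continue;
      double same = 0.0; int nb = 0, rare = 0;
      int mn = 0;
      for (int b = 0; b < 4; ++b) {
        int c = cnt[p][b];
        same += (double)c * (c - 1) / 2.0;
        if (c > 0) { ++nb; if (mn == 0 || c < mn) mn = c; }
      }
      double pairs = (double)nsam[p] * (nsam[p] - 1) / 2.0;
      pi_w[p] += (pairs - same) / pairs;
      if (nb >= 2) { rare = mn; nseg[p]++; rare_sum[p] += rare; rare_sq[p] += (double)rare * rare; }
    }
    for (int p = 0; p < P - 1; ++p) for (int q = p + 1; q < P; ++q) {
      if (nsam[p] < 1 || nsam[q] < 1) continue;
      double cross_same = 0.0;
      for (int b = 0; b < 4; ++b) cross_same += (double)cnt[p][b] * cnt[q][b];
      dxy[p][q] += 1.0 - cross_same / ((double)nsam[p] * nsam[q]);
    }
  }
  int k = 0;
  for (int p = 0; p < P; ++p) {
    double mean_rare = 0.0, var_rare = 0.0;
    if (nseg[p] > 0) {
      mean_rare = rare_sum[p] / nseg[p];
      if (nseg[p] > 1)
        var_rare = (rare_sq[p] - nseg[p] * mean_rare * mean_rare) / (nseg[p] - 1);
    }
    out[k++] = pi_w[p];
    out[k++] = mean_rare;
    out[k++] = var_rare;
  }
  for (int p = 0; p < P - 1; ++p) for (int q = p + 1; q < P; ++q) {
    double n1 = nsam[p], n2 = nsam[q], N = n1 + n2;
    double sw1 = pi_w[p] * n1 * (n1 - 1) / 2.0;
    double sw2 = pi_w[q] * n2 * (n2 - 1) / 2.0;
    double sb = dxy[p][q] * n1 * n2;
    double ss_t = (sw1 + sw2 + sb) / N;
    double ss_w = sw1 / n1 + sw2 / n2;
    double ms_w = ss_w / (N - 2.0);
    double ms_a = ss_t - ss_w;
    double nc = (N - (n1 * n1 + n2 * n2) / N);
    double sa = (ms_a - ms_w) / nc;
    if (sa < 0) sa = 0;
    double fst = (sa + ms_w > 0) ? sa / (sa + ms_w) : 0.0;
    out[k++] = dxy[p][q];
    out[k++] = fst;
  }
  return out;
}
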