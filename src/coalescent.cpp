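// Structured coalescent under the isolation-with-migration model for an
// arbitrary number of extant demes merging into a single ancestral pool
// at the split time. Mutation models: finite-sites Jukes-Cantor on a
// sequence locus, unbounded single-step (SMM) on microsatellites.
//
// Uses R's RNG throughout so results are reproducible via set.seed().

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> parent;   // -1 = root
  std::vector<double> time;  // node age in generations
  int n_leaves;
};

// k: sampled lineages per deme; g: gene copies per deme (2N diploid, N
// haploid); migBack(i,j): per-lineage backward migration rate from deme i
// to deme j per generation; at T_gen all lineages merge into a pool of
// g_anc copies.
static Tree sim_tree(const std::vector<int>& k, const std::vector<double>& g,
                     const NumericMatrix& migBack, double T_gen, double g_anc) {
  const int d = (int)k.size();
  int n = 0;
  for (int i = 0; i < d; ++i) n += k[i];
  Tree tr;
  tr.n_leaves = n;
  const int n_nodes = 2 * n - 1;
  tr.parent.assign(n_nodes, -1);
  tr.time.assign(n_nodes, 0.0);
  if (n == 1) return tr;

  std::vector<std::vector<int>> act(d);
  int id = 0;
  for (int i = 0; i < d; ++i)
    for (int c = 0; c < k[i]; ++c) act[i].push_back(id++);

  std::vector<double> gg(g);
  std::vector<double> mrow(d, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j)
      if (j != i) mrow[i] += migBack(i, j);

  int next_node = n, remaining = n;
  double t = 0.0;
  bool merged = (T_gen <= 0.0);
  if (merged) {
    for (int i = 1; i < d; ++i) {
      for (size_t x = 0; x < act[i].size(); ++x) act[0].push_back(act[i][x]);
      act[i].clear();
    }
    gg[0] = g_anc;
  }

  std::vector<double> coalr(d), migr(d);
  while (remaining > 1) {
    double total = 0.0;
    for (int i = 0; i < d; ++i) {
      double ki = (double)act[i].size();
      coalr[i] = ki * (ki - 1.0) / 2.0 / gg[i];
      migr[i] = merged ? 0.0 : ki * mrow[i];
      total += coalr[i] + migr[i];
    }
    double dt = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
    if (!merged && t + dt >= T_gen) {
      t = T_gen;
      for (int i = 1; i < d; ++i) {
        for (size_t x = 0; x < act[i].size(); ++x) act[0].push_back(act[i][x]);
        act[i].clear();
      }
      gg[0] = g_anc;
      merged = true;
      continue;
    }
    t += dt;
    double u = unif_rand() * total;
    int ev = -1;
    bool is_coal = true;
    for (int i = 0; i < d; ++i) {
      if (u < coalr[i]) { ev = i; is_coal = true; break; }
      u -= coalr[i];
      if (u < migr[i]) { ev = i; is_coal = false; break; }
      u -= migr[i];
    }
    if (ev < 0) {  // numeric guard: take last deme with lineages
      for (int i = d - 1; i >= 0; --i)
        if (act[i].size() > 1) { ev = i; is_coal = true; break; }
      if (ev < 0) continue;
    }
    if (is_coal) {
      int ki = (int)act[ev].size();
      int a = (int)(unif_rand() * ki); if (a >= ki) a = ki - 1;
      int b = (int)(unif_rand() * (ki - 1)); if (b >= ki - 1) b = ki - 2;
      if (b >= a) ++b;
      int na = act[ev][a], nb = act[ev][b];
      int par = next_node++;
      tr.parent[na] = par;
      tr.parent[nb] = par;
      tr.time[par] = t;
      if (a > b) std::swap(a, b);
      act[ev].erase(act[ev].begin() + b);
      act[ev].erase(act[ev].begin() + a);
      act[ev].push_back(par);
      --remaining;
    } else {
      int ki = (int)act[ev].size();
      int a = (int)(unif_rand() * ki); if (a >= ki) a = ki - 1;
      double v = unif_rand() * mrow[ev];
      int dest = -1;
      for (int j = 0; j < d; ++j) {
        if (j == ev) continue;
        if (v < migBack(ev, j)) { dest = j; break; }
        v -= migBack(ev, j);
      }
      if (dest < 0) for (int j = d - 1; j >= 0; --j) if (j != ev) { dest = j; break; }
      int node = act[ev][a];
      act[ev].erase(act[ev].begin() + a);
      act[dest].push_back(node);
    }
  }
  return tr;
}

// Finite-sites Jukes-Cantor: Poisson mutations on branches, uniform site,
// cyclic step of 1..3 (equivalent to uniform choice among the other three
// bases). Root state is the all-zero reference. Returns leaves x L matrix
// of base codes 0..3.
static IntegerMatrix mutate_seq(const Tree& tr, int L, double mu_per_gen) {
  const int n_nodes = (int)tr.parent.size();
  const int n = tr.n_leaves;
  std::vector<std::vector<std::pair<int, int>>> muts(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    int p = tr.parent[v];
    if (p < 0) continue;
    double len = tr.time[p] - tr.time[v];
    int nm = (int)R::rpois(len * mu_per_gen);
    for (int m = 0; m < nm; ++m) {
      int site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
      int step = 1 + (int)(unif_rand() * 3.0); if (step > 3) step = 3;
      muts[v].push_back(std::make_pair(site, step));
    }
  }
  IntegerMatrix out(n, L);
  std::vector<int> path;
  std::vector<int> state(L);
  for (int leaf = 0; leaf < n; ++leaf) {
    path.clear();
    for (int v = leaf; v >= 0; v = tr.parent[v]) path.push_back(v);
    std::fill(state.begin(), state.end(), 0);
    for (int idx = (int)path.size() - 1; idx >= 0; --idx)
      for (size_t m = 0; m < muts[path[idx]].size(); ++m)
        state[muts[path[idx]][m].first] =
          (state[muts[path[idx]][m].first] + muts[path[idx]][m].second) % 4;
    for (int s = 0; s < L; ++s) out(leaf, s) = state[s];
  }
  return out;
}

// Unbounded stepwise mutation: +-1 repeat with equal probability.
static IntegerVector mutate_smm(const Tree& tr, double mu_per_gen,
                                int root_allele) {
  const int n_nodes = (int)tr.parent.size();
  const int n = tr.n_leaves;
  std::vector<int> net(n_nodes, 0);
  for (int v = 0; v < n_nodes; ++v) {
    int p = tr.parent[v];
    if (p < 0) continue;
    double len = tr.time[p] - tr.time[v];
    int nm = (int)R::rpois(len * mu_per_gen);
    int s = 0;
    for (int m = 0; m < nm; ++m) s += (unif_rand() < 0.5) ? -1 : 1;
    net[v] = s;
  }
  IntegerVector out(n);
  for (int leaf = 0; leaf < n; ++leaf) {
    int a = root_allele;
    for (int v = leaf; v >= 0; v = tr.parent[v]) a += net[v];
    out[leaf] = a;
  }
  return out;
}

// Backward per-lineage migration rates from forward fractions:
// rate(i -> j) = m_{j->i, forward} * N_j / N_i.
static NumericMatrix backward_rates(const NumericVector& N,
                                    const NumericMatrix& mForward) {
  const int d = N.size();
  NumericMatrix out(d, d);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j)
      if (i != j) out(i, j) = mForward(j, i) * N[j] / N[i];
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_dataset(IntegerVector nSeq, IntegerVector nInd,
                          NumericVector Ndeme, double Nanc,
                          NumericMatrix mForward, double T_gen,
                          int L, double muSeqPerGen,
                          NumericVector muMicroPerGen,
                          NumericVector selfing, int microsatRoot) {
  const int d = Ndeme.size();
  NumericMatrix migB = backward_rates(Ndeme, mForward);

  List out;
  // haploid organelle locus: effective gene copies = N per deme
  if (sum(nSeq) > 0) {
    std::vector<int> k(d);
    std::vector<double> g(d);
    for (int i = 0; i < d; ++i) { k[i] = nSeq[i]; g[i] = Ndeme[i]; }
    Tree tr = sim_tree(k, g, migB, T_gen, Nanc);
    out["seq"] = mutate_seq(tr, L, muSeqPerGen);
  } else {
    out["seq"] = R_NilValue;
  }

  const int nLoci = muMicroPerGen.size();
  int totInd = sum(nInd);
  if (nLoci > 0 && totInd > 0) {
    std::vector<int> selfed(totInd, 0);
    {
      int idx = 0;
      for (int i = 0; i < d; ++i)
        for (int c = 0; c < nInd[i]; ++c, ++idx)
          selfed[idx] = (unif_rand() < selfing[i]) ? 1 : 0;
    }
    IntegerMatrix Amat(totInd, nLoci), Bmat(totInd, nLoci);
    std::vector<int> k(d);
    std::vector<double> g(d);
    for (int i = 0; i < d; ++i) { k[i] = 2 * nInd[i]; g[i] = 2.0 * Ndeme[i]; }
    for (int l = 0; l < nLoci; ++l) {
      Tree tr = sim_tree(k, g, migB, T_gen, 2.0 * Nanc);
      IntegerVector al = mutate_smm(tr, muMicroPerGen[l], microsatRoot);
      for (int i = 0; i < totInd; ++i) {
        int a = al[2 * i], b = al[2 * i + 1];
        if (selfed[i] && unif_rand() < 0.5) b = a;  // IBD with prob 1/2 per locus
        Amat(i, l) = a;
        Bmat(i, l) = b;
      }
    }
    out["microA"] = Amat;
    out["microB"] = Bmat;
  } else {
    out["microA"] = R_NilValue;
    out["microB"] = R_NilValue;
  }
  return out;
}

// ---- summary statistics (must mirror the R-level summarize path) ----

// two-level distance AMOVA Phi_ST from a (pop x hap) counts matrix and a
// hap x hap squared-distance matrix; 0 when undefined (monomorphic).
static double phi_st(const std::vector<std::vector<double>>& cnt,
                     const std::vector<std::vector<double>>& D) {
  const int P = (int)cnt.size();
  const int H = (int)D.size();
  std::vector<double> np(P, 0.0), tot(H, 0.0);
  double N = 0.0;
  for (int p = 0; p < P; ++p)
    for (int h = 0; h < H; ++h) { np[p] += cnt[p][h]; tot[h] += cnt[p][h]; }
  for (int p = 0; p < P; ++p) N += np[p];
  double ssd_t = 0.0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < H; ++j) ssd_t += tot[i] * tot[j] * D[i][j];
  ssd_t /= 2.0 * N;
  double ssd_w = 0.0;
  for (int p = 0; p < P; ++p) {
    if (np[p] <= 0) continue;
    double s = 0.0;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < H; ++j) s += cnt[p][i] * cnt[p][j] * D[i][j];
    ssd_w += s / (2.0 * np[p]);
  }
  double ssd_a = ssd_t - ssd_w;
  double df_a = P - 1.0, df_w = N - P;
  if (df_w <= 0) return 0.0;
  double sw = ssd_w / df_w;
  double sum_np2 = 0.0;
  for (int p = 0; p < P; ++p) sum_np2 += np[p] * np[p];
  double nc = (N - sum_np2 / N) / df_a;
  double sa = (ssd_a / df_a - sw) / nc;
  double denom = sa + sw;
  if (!(denom > 0.0) || !R_finite(denom)) return 0.0;
  return sa / denom;
}

// three-level components for one diploid locus; appends sigma_a,b,c.
static void locus_sigma(const std::vector<int>& pop, const IntegerVector& a,
                        const IntegerVector& b, int P,
                        double* sa, double* sb, double* sc) {
  const int n = a.size();
  std::map<int, int> lev;
  for (int i = 0; i < n; ++i) {
    if (!lev.count(a[i])) { int s = (int)lev.size(); lev[a[i]] = s; }
    if (!lev.count(b[i])) { int s = (int)lev.size(); lev[b[i]] = s; }
  }
  const int K = (int)lev.size();
  std::vector<double> np(P, 0.0);
  std::vector<std::vector<double>> cnt(P, std::vector<double>(K, 0.0));
  int n_het = 0;
  for (int i = 0; i < n; ++i) {
    np[pop[i]] += 1.0;
    cnt[pop[i]][lev[a[i]]] += 1.0;
    cnt[pop[i]][lev[b[i]]] += 1.0;
    if (a[i] != b[i]) ++n_het;
  }
  double N = n, G = 2.0 * n;
  auto ch2 = [](double x) { return x * (x - 1.0) / 2.0; };
  std::vector<double> ctot(K, 0.0);
  for (int p = 0; p < P; ++p)
    for (int k = 0; k < K; ++k) ctot[k] += cnt[p][k];
  double s_ct = 0.0;
  for (int k = 0; k < K; ++k) s_ct += ch2(ctot[k]);
  double ssd_t = (ch2(G) - s_ct) / G;
  double ssd_wp = 0.0, sum_gp2 = 0.0;
  for (int p = 0; p < P; ++p) {
    double gp = 2.0 * np[p];
    sum_gp2 += gp * gp;
    if (gp <= 0) continue;
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += ch2(cnt[p][k]);
    ssd_wp += (ch2(gp) - s) / gp;
  }
  double ssd_wi = n_het / 2.0;
  double ssd_ai = ssd_wp - ssd_wi;
  double ssd_ap = ssd_t - ssd_wp;
  double df_ap = P - 1.0, df_ai = N - P, df_wi = N;
  double sigc = ssd_wi / df_wi;
  double sigb = (df_ai > 0) ? (ssd_ai / df_ai - sigc) / 2.0 : 0.0;
  double nc = (G - sum_gp2 / G) / df_ap;
  double siga = (ssd_ap / df_ap - sigc - 2.0 * sigb) / nc;
  *sa += siga; *sb += sigb; *sc += sigc;
}

// Summaries of a 2-deme simulated dataset; layout documented in the R
// wrapper (summaryNames()).
// [[Rcpp::export]]
NumericVector cpp_im_summaries(double Na, double Nb, double Nanc, double T_gen,
                               double mAB, double mBA,
                               int nSeqA, int nSeqB, int nIndA, int nIndB,
                               int L, double muSeqPerGen,
                               NumericVector muMicroPerGen, int microsatRoot) {
  NumericVector Nd = NumericVector::create(Na, Nb);
  NumericMatrix mF(2, 2);
  mF(0, 1) = mAB;  // forward a -> b
  mF(1, 0) = mBA;
  NumericVector self(2);
  IntegerVector nSeq = IntegerVector::create(nSeqA, nSeqB);
  IntegerVector nInd = IntegerVector::create(nIndA, nIndB);
  List ds = cpp_simulate_dataset(nSeq, nInd, Nd, Nanc, mF, T_gen, L,
                                 muSeqPerGen, muMicroPerGen, self, microsatRoot);
  std::vector<double> out;

  if (nSeqA + nSeqB > 0) {
    IntegerMatrix seq = ds["seq"];
    const int n = seq.nrow();
    // collapse to haplotypes in order of first appearance
    std::vector<int> hap(n, -1);
    std::vector<int> reps;
    for (int i = 0; i < n; ++i) {
      for (size_t r = 0; r < reps.size(); ++r) {
        bool same = true;
        for (int s = 0; s < L; ++s)
          if (seq(i, s) != seq(reps[r], s)) { same = false; break; }
        if (same) { hap[i] = (int)r; break; }
      }
      if (hap[i] < 0) { reps.push_back(i); hap[i] = (int)reps.size() - 1; }
    }
    const int H = (int)reps.size();
    std::vector<std::vector<double>> cnt(2, std::vector<double>(H, 0.0));
    for (int i = 0; i < n; ++i) cnt[i < nSeqA ? 0 : 1][hap[i]] += 1.0;
    std::vector<std::vector<double>> D(H, std::vector<double>(H, 0.0));
    for (int i = 0; i < H; ++i)
      for (int j = i + 1; j < H; ++j) {
        int dd = 0;
        for (int s = 0; s < L; ++s)
          if (seq(reps[i], s) != seq(reps[j], s)) ++dd;
        D[i][j] = D[j][i] = dd;
      }
    for (int p = 0; p < 2; ++p) {
      double np = 0.0, sp2 = 0.0, pi = 0.0;
      int nh = 0;
      for (int h = 0; h < H; ++h) { np += cnt[p][h]; if (cnt[p][h] > 0) ++nh; }
      if (np == 0.0) { out.push_back(0); out.push_back(0); out.push_back(0); continue; }
      for (int h = 0; h < H; ++h) {
        double f = cnt[p][h] / np;
        sp2 += f * f;
      }
      for (int i = 0; i < H; ++i)
        for (int j = 0; j < H; ++j) pi += cnt[p][i] * cnt[p][j] * D[i][j];
      double hdiv = (np > 1) ? np * (1.0 - sp2) / (np - 1.0) : 0.0;
      pi = (np > 1) ? pi / (np * (np - 1.0)) / (double)L : 0.0;
      out.push_back((double)nh);
      out.push_back(hdiv);
      out.push_back(pi);
    }
    int shared = 0;
    for (int h = 0; h < H; ++h)
      if (cnt[0][h] > 0 && cnt[1][h] > 0) ++shared;
    out.push_back((double)shared);
    out.push_back(phi_st(cnt, D));
  }

  if (muMicroPerGen.size() > 0 && nIndA + nIndB > 0) {
    IntegerMatrix A = ds["microA"], B = ds["microB"];
    const int nL = A.ncol();
    const int n = A.nrow();
    std::vector<int> pop(n);
    for (int i = 0; i < n; ++i) pop[i] = (i < nIndA) ? 0 : 1;
    double kbar[2] = {0, 0}, hebar[2] = {0, 0}, vbar[2] = {0, 0};
    double dmu2 = 0.0, shared = 0.0;
    double sa = 0, sb = 0, sc = 0;
    for (int l = 0; l < nL; ++l) {
      IntegerVector al = A(_, l), bl = B(_, l);
      std::map<int, double> f[2];
      double mean[2] = {0, 0}, g[2] = {0, 0};
      for (int p = 0; p < 2; ++p) {
        for (int i = 0; i < n; ++i) {
          if (pop[i] != p) continue;
          f[p][al[i]] += 1.0; f[p][bl[i]] += 1.0;
          mean[p] += al[i] + bl[i];
          g[p] += 2.0;
        }
        if (g[p] == 0.0) continue;
        mean[p] /= g[p];
        double sp2 = 0.0, ss = 0.0;
        for (std::map<int, double>::iterator it = f[p].begin();
             it != f[p].end(); ++it) {
          double fr = it->second / g[p];
          sp2 += fr * fr;
          ss += it->second * (it->first - mean[p]) * (it->first - mean[p]);
        }
        kbar[p] += (double)f[p].size();
        hebar[p] += (g[p] > 1) ? g[p] / (g[p] - 1.0) * (1.0 - sp2) : 0.0;
        vbar[p] += (g[p] > 1) ? ss / (g[p] - 1.0) : 0.0;
      }
      if (g[0] > 0 && g[1] > 0) {
        dmu2 += (mean[0] - mean[1]) * (mean[0] - mean[1]);
        for (std::map<int, double>::iterator it = f[0].begin();
             it != f[0].end(); ++it)
          if (f[1].count(it->first)) shared += 1.0;
      }
      locus_sigma(pop, al, bl, 2, &sa, &sb, &sc);
    }
    for (int p = 0; p < 2; ++p) out.push_back(kbar[p] / nL);
    for (int p = 0; p < 2; ++p) out.push_back(hebar[p] / nL);
    for (int p = 0; p < 2; ++p) out.push_back(vbar[p] / nL);
    out.push_back(dmu2 / nL);
    out.push_back(shared / nL);
    double tot = sa + sb + sc;
    out.push_back((tot > 0.0 && R_finite(tot)) ? sa / tot : 0.0);
  }
  return wrap(out);
}

// ABC inner loop: one summary row per parameter draw.
// params columns: Na, Nb, Nanc, T_gen, mAB, mBA.
// [[Rcpp::export]]
NumericMatrix cpp_abc_summaries(NumericMatrix params,
                                int nSeqA, int nSeqB, int nIndA, int nIndB,
                                int L, double muSeqPerGen,
                                NumericVector muMicroPerGen, int microsatRoot) {
  const int n = params.nrow();
  NumericMatrix out;
  for (int i = 0; i < n; ++i) {
    NumericVector s = cpp_im_summaries(params(i, 0), params(i, 1), params(i, 2),
                                       params(i, 3), params(i, 4), params(i, 5),
                                       nSeqA, nSeqB, nIndA, nIndB, L,
                                       muSeqPerGen, muMicroPerGen, microsatRoot);
    if (i == 0) out = NumericMatrix(n, s.size());
    out(i, _) = s;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
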