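// Forward Wright-Fisher simulator for one chromosome: discrete generations,
// fitness-weighted multinomial resampling of diploid parents, uniform
// recombination and infinite-sites mutation.  An ancestral population is
// burnt in to mutation-drift equilibrium, then splits into a "wild" lineage
// of constant size and a "cultivated" lineage that passes through a
// bottleneck before recovering; beneficial alleles at user-supplied sweep
// loci are selected (multiplicative fitness 1+s per allele copy) in the
// cultivated lineage only, with bounded re-introduction on stochastic loss.
//
// Layout: haplotypes are rows (2N x S, row-major) over position-sorted
// segregating-site columns, so a gamete is a handful of memcpys between
// crossover breakpoints.  Columns are pruned/merged only every
// REBUILD_EVERY generations; mutations younger than that live in a sparse
// "nursery" (per-site carrier lists) and are transmitted through the same
// recorded crossover breakpoints, which keeps the per-generation cost close
// to one matrix copy.  All randomness comes from R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

constexpr int REBUILD_EVERY = 10;

struct PopMat {
  int N = 0;                  // diploids
  std::vector<uint8_t> M;     // 2N x S, row-major
};

struct NurserySite {
  int pos;
  int pop;                    // carriers live in this population only
  std::vector<int> carriers;  // haplotype indices
};

struct GameteRec {            // crossover record of one gamete
  int parent;                 // diploid index in the parent population
  int start;                  // starting haplotype (0/1)
  int nbp;
  int bp[4];                  // inline storage for the common case
  std::vector<int> bp_ext;    // spill-over

  int source_hap(int p) const {
    int t = 0;
    for (int i = 0; i < nbp && i < 4; ++i) t += (bp[i] <= p);
    for (int b : bp_ext) t += (b <= p);
    return start ^ (t & 1);
  }
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

int sample_parent(const std::vector<double>& cumfit, int N) {
  if (cumfit.empty()) return runif_int(N);
  double u = unif_rand() * cumfit.back();
  return static_cast<int>(
      std::lower_bound(cumfit.begin(), cumfit.end(), u) - cumfit.begin());
}

struct Sim {
  int L;
  double mu, rr;
  std::vector<int> pos;                 // sorted positions of matrix columns
  std::unordered_set<int> used;         // positions in play or reserved
  std::vector<int> sweep_pos;           // reserved positions
  std::vector<double> sweep_s;
  std::vector<PopMat> pops;
  std::vector<PopMat> scratch;
  std::vector<NurserySite> nursery;
  int retries_used = 0;
  int max_retries;
  bool sweeps_active = false;
  int gens_since_rebuild = 0;

  int S() const { return static_cast<int>(pos.size()); }

  int col_of(int p) const {
    auto it = std::lower_bound(pos.begin(), pos.end(), p);
    if (it == pos.end() || *it != p) return -1;
    return static_cast<int>(it - pos.begin());
  }

  // copy one recombinant gamete of the main matrix; rec must be filled in
  void copy_gamete(const PopMat& par, const GameteRec& rec, uint8_t* dst) {
    int S0 = S();
    if (S0 == 0) return;
    const uint8_t* h[2] = {
        par.M.data() + static_cast<size_t>(2 * rec.parent) * S0,
        par.M.data() + static_cast<size_t>(2 * rec.parent + 1) * S0};
    if (rec.nbp == 0) {
      std::memcpy(dst, h[rec.start], S0);
      return;
    }
    int cur = rec.start, from = 0;
    auto seg = [&](int b) {
      int to = static_cast<int>(
          std::lower_bound(pos.begin() + from, pos.end(), b) - pos.begin());
      if (to > from) std::memcpy(dst + from, h[cur] + from, to - from);
      cur ^= 1;
      from = to;
    };
    for (int i = 0; i < rec.nbp && i < 4; ++i) seg(rec.bp[i]);
    for (int b : rec.bp_ext) seg(b);
    if (S0 > from) std::memcpy(dst + from, h[cur] + from, S0 - from);
  }

  void fill_breakpoints(GameteRec& rec, double exp_xo) {
    rec.start = (unif_rand() < 0.5) ? 1 : 0;
    rec.bp_ext.clear();
    int k = (exp_xo > 0) ? static_cast<int>(R::rpois(exp_xo)) : 0;
    rec.nbp = k;
    if (k == 0) return;
    if (k <= 4) {
      for (int i = 0; i < k; ++i) rec.bp[i] = runif_int(L) + 1;
      std::sort(rec.bp, rec.bp + k);
    } else {
      rec.bp_ext.resize(k);
      for (int i = 0; i < k; ++i) rec.bp_ext[i] = runif_int(L) + 1;
      std::sort(rec.bp_ext.begin(), rec.bp_ext.end());
      rec.nbp = 0;  // all in ext
      // keep total count: source_hap/copy_gamete walk bp (none) then ext
    }
  }

  // fitness (cumulative) of cultivated diploids from the main matrix
  std::vector<double> cum_fitness(int ip) const {
    std::vector<double> cum;
    if (!sweeps_active) return cum;
    const PopMat& P = pops[ip];
    int S0 = S();
    std::vector<double> w(P.N, 1.0);
    bool any = false;
    for (size_t j = 0; j < sweep_pos.size(); ++j) {
      int c = col_of(sweep_pos[j]);
      if (c < 0) continue;
      double s = sweep_s[j];
      for (int i = 0; i < P.N; ++i) {
        int g = P.M[static_cast<size_t>(2 * i) * S0 + c] +
                P.M[static_cast<size_t>(2 * i + 1) * S0 + c];
        if (g) {
          w[i] *= std::pow(1.0 + s, g);
          any = true;
        }
      }
    }
    if (!any) return std::vector<double>();
    cum.resize(P.N);
    double acc = 0;
    for (int i = 0; i < P.N; ++i) {
      acc += w[i];
      cum[i] = acc;
    }
    return cum;
  }

  // fold the nursery into the matrix, prune lost/fixed columns
  void rebuild() {
    int S0 = S();
    int npop = static_cast<int>(pops.size());
    int tot_hap = 0;
    for (auto& P : pops) tot_hap += 2 * P.N;

    std::vector<int> cnt(S0, 0);
    for (auto& P : pops) {
      for (int r = 0; r < 2 * P.N; ++r) {
        const uint8_t* row = P.M.data() + static_cast<size_t>(r) * S0;
        for (int s = 0; s < S0; ++s) cnt[s] += row[s];
      }
    }

    std::unordered_set<int> reserved(sweep_pos.begin(), sweep_pos.end());
    std::vector<int> keep;
    keep.reserve(S0);
    for (int s = 0; s < S0; ++s) {
      if ((cnt[s] > 0 && cnt[s] < tot_hap) ||
          (sweeps_active && reserved.count(pos[s]))) {
        keep.push_back(s);
      } else {
        used.erase(pos[s]);
      }
    }

    // nursery sites, position-sorted (lost ones were dropped on the fly;
    // a nursery site fixed in the whole panel is still impossible to carry
    // in the matrix representation minus pruning, so check anyway)
    std::vector<int> nidx;
    for (size_t j = 0; j < nursery.size(); ++j) {
      int c = static_cast<int>(nursery[j].carriers.size());
      if (c > 0 && c < tot_hap) {
        nidx.push_back(static_cast<int>(j));
      } else {
        used.erase(nursery[j].pos);
      }
    }
    std::sort(nidx.begin(), nidx.end(), [&](int a, int b) {
      return nursery[a].pos < nursery[b].pos;
    });

    int S1 = static_cast<int>(keep.size() + nidx.size());
    std::vector<int> newpos(S1), src(S1);
    std::vector<int> nurcol(nidx.size());
    {
      size_t a = 0, b = 0, o = 0;
      while (a < keep.size() || b < nidx.size()) {
        bool take_old = b >= nidx.size() ||
                        (a < keep.size() &&
                         pos[keep[a]] < nursery[nidx[b]].pos);
        if (take_old) {
          newpos[o] = pos[keep[a]];
          src[o] = keep[a];
          ++a;
        } else {
          newpos[o] = nursery[nidx[b]].pos;
          src[o] = -1;
          nurcol[b] = static_cast<int>(o);
          ++b;
        }
        ++o;
      }
    }

    struct Run {
      int dst, srcc, len;
    };
    std::vector<Run> runs;
    for (int o = 0; o < S1;) {
      if (src[o] < 0) {
        ++o;
        continue;
      }
      int len = 1;
      while (o + len < S1 && src[o + len] == src[o + len - 1] + 1) ++len;
      runs.push_back({o, src[o], len});
      o += len;
    }

    for (int k = 0; k < npop; ++k) {
      PopMat& P = pops[k];
      std::vector<uint8_t> nm(static_cast<size_t>(2 * P.N) * S1, 0);
      for (int r = 0; r < 2 * P.N; ++r) {
        const uint8_t* srow = P.M.data() + static_cast<size_t>(r) * S0;
        uint8_t* drow = nm.data() + static_cast<size_t>(r) * S1;
        for (const Run& ru : runs)
          std::memcpy(drow + ru.dst, srow + ru.srcc, ru.len);
      }
      P.M.swap(nm);
    }
    for (size_t b = 0; b < nidx.size(); ++b) {
      const NurserySite& ns = nursery[nidx[b]];
      PopMat& P = pops[ns.pop];
      for (int hap : ns.carriers)
        P.M[static_cast<size_t>(hap) * S1 + nurcol[b]] = 1;
    }
    pos.swap(newpos);
    nursery.clear();
    gens_since_rebuild = 0;
  }

  // one generation: output pop k draws parents from pops[parent_of[k]]
  // with new size newN[k]; cul_index marks the cultivated output pop.
  bool advance(const std::vector<int>& parent_of, const std::vector<int>& newN,
               int cul_index) {
    if (gens_since_rebuild >= REBUILD_EVERY) rebuild();
    ++gens_since_rebuild;

    int S0 = S();
    int npop = static_cast<int>(newN.size());
    double exp_xo = rr * static_cast<double>(L);

    std::vector<std::vector<double>> cum(pops.size());
    if (sweeps_active && cul_index >= 0)
      cum[parent_of[cul_index]] = cum_fitness(parent_of[cul_index]);

    // per-parent-individual nursery index, per parent population
    // entry: (nursery site id, haplotype bit)
    std::vector<std::vector<std::vector<std::pair<int, int>>>> byind(
        pops.size());
    if (!nursery.empty()) {
      for (size_t p = 0; p < pops.size(); ++p)
        byind[p].resize(pops[p].N);
      for (size_t j = 0; j < nursery.size(); ++j) {
        const NurserySite& ns = nursery[j];
        for (int hap : ns.carriers)
          byind[ns.pop][hap / 2].push_back(
              {static_cast<int>(j), hap & 1});
      }
    }
    std::vector<std::vector<int>> newcarriers(nursery.size());

    scratch.resize(npop);
    GameteRec rec;
    static const std::vector<double> nofit;
    for (int k = 0; k < npop; ++k) {
      PopMat& out = scratch[k];
      const PopMat& par = pops[parent_of[k]];
      const std::vector<double>& cfit =
          (k == cul_index) ? cum[parent_of[k]] : nofit;
      out.N = newN[k];
      out.M.resize(static_cast<size_t>(2 * out.N) * S0);
      const auto* nur_ind =
          nursery.empty() ? nullptr : &byind[parent_of[k]];
      for (int g = 0; g < 2 * out.N; ++g) {
        rec.parent = sample_parent(cfit, par.N);
        fill_breakpoints(rec, exp_xo);
        copy_gamete(par, rec, out.M.data() + static_cast<size_t>(g) * S0);
        if (nur_ind) {
          const auto& entries = (*nur_ind)[rec.parent];
          for (const auto& e : entries) {
            // nursery sites stay in their own lineage: transmission only
            // into the same population index as the carriers
            if (nursery[e.first].pop != k) continue;
            if (rec.source_hap(nursery[e.first].pos) == e.second)
              newcarriers[e.first].push_back(g);
          }
        }
      }
    }
    pops.swap(scratch);

    // update nursery carrier lists; drop extinct sites
    if (!nursery.empty()) {
      std::vector<NurserySite> kept;
      kept.reserve(nursery.size());
      for (size_t j = 0; j < nursery.size(); ++j) {
        if (newcarriers[j].empty()) {
          used.erase(nursery[j].pos);
          continue;
        }
        nursery[j].carriers.swap(newcarriers[j]);
        kept.push_back(std::move(nursery[j]));
      }
      nursery.swap(kept);
    }

    // new mutations enter the nursery
    for (int k = 0; k < npop; ++k) {
      double lam = 2.0 * pops[k].N * mu * static_cast<double>(L);
      int m = (lam > 0) ? static_cast<int>(R::rpois(lam)) : 0;
      for (int j = 0; j < m; ++j) {
        int tries = 0, p;
        do {
          p = runif_int(L) + 1;
          ++tries;
        } while (used.count(p) && tries < 100);
        if (used.count(p)) continue;  // saturated; skip
        used.insert(p);
        NurserySite ns;
        ns.pos = p;
        ns.pop = k;
        ns.carriers.push_back(runif_int(2 * pops[k].N));
        nursery.push_back(std::move(ns));
      }
    }

    // sweep allele maintenance: re-introduce on loss (bounded)
    if (sweeps_active && cul_index >= 0) {
      PopMat& C = pops[cul_index];
      for (size_t j = 0; j < sweep_pos.size(); ++j) {
        int c = col_of(sweep_pos[j]);
        if (c < 0) continue;
        int cc = 0;
        for (int r = 0; r < 2 * C.N; ++r)
          cc += C.M[static_cast<size_t>(r) * S0 + c];
        if (cc == 0) {
          if (retries_used >= max_retries) return false;
          ++retries_used;
          C.M[static_cast<size_t>(runif_int(2 * C.N)) * S0 + c] = 1;
        }
      }
    }
    return true;
  }

  // insert a brand-new allele at position p on haplotype hap of pop ip
  // (used for the planted sweep alleles; goes straight into the matrix)
  void add_site(int p, int ip, int hap) {
    int S0 = S();
    int at = static_cast<int>(
        std::lower_bound(pos.begin(), pos.end(), p) - pos.begin());
    if (at < S0 && pos[at] == p) {
      pops[ip].M[static_cast<size_t>(hap) * S0 + at] = 1;
      return;
    }
    pos.insert(pos.begin() + at, p);
    used.insert(p);
    int S1 = S0 + 1;
    for (size_t k = 0; k < pops.size(); ++k) {
      PopMat& P = pops[k];
      std::vector<uint8_t> nm(static_cast<size_t>(2 * P.N) * S1, 0);
      for (int r = 0; r < 2 * P.N; ++r) {
        const uint8_t* srow = P.M.data() + static_cast<size_t>(r) * S0;
        uint8_t* drow = nm.data() + static_cast<size_t>(r) * S1;
        if (at > 0) std::memcpy(drow, srow, at);
        if (S0 > at) std::memcpy(drow + at + 1, srow + at, S0 - at);
      }
      P.M.swap(nm);
    }
    pops[ip].M[static_cast<size_t>(hap) * S1 + at] = 1;
  }
};

std::vector<int> sample_without_replacement(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(n - i);
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

}  // namespace

// [[Rcpp::export(name = ".wf_sim_chrom")]]
List wf_sim_chrom(int L, double mu, double rr, int N_anc, int N_wild,
                  int N_cul, int T_split, int N_bot, int T_bot,
                  IntegerVector sweep_pos, NumericVector sweep_s,
                  int n_burnin, int n_sam_wild, int n_sam_cul,
                  int max_retries) {
  if (L <= 0 || mu < 0 || rr < 0) stop("invalid genome parameters");
  if (N_anc <= 0 || N_wild <= 0 || N_cul <= 0 || N_bot <= 0)
    stop("population sizes must be positive");
  if (T_bot > T_split) stop("bottleneck_duration must not exceed T_split");
  if (n_sam_wild > N_wild || n_sam_cul > N_cul)
    stop("sample sizes exceed population sizes");
  if (T_split == 0 && n_sam_wild + n_sam_cul > N_anc)
    stop("with T_split = 0 both samples are drawn from the ancestral population");

  Sim sim;
  sim.L = L;
  sim.mu = mu;
  sim.rr = rr;
  sim.max_retries = max_retries;
  for (int j = 0; j < sweep_pos.size(); ++j) {
    sim.sweep_pos.push_back(sweep_pos[j]);
    sim.sweep_s.push_back(sweep_s[j]);
    sim.used.insert(sweep_pos[j]);  // reserve: no neutral mutation here
  }

  sim.pops.resize(1);
  sim.pops[0].N = N_anc;

  for (int g = 0; g < n_burnin; ++g) {
    if (g % 128 == 0) checkUserInterrupt();
    sim.advance({0}, {N_anc}, -1);
  }

  std::vector<int> wild_idx, cul_idx;
  int wild_pop = 0, cul_pop = 0;
  std::vector<double> traj;
  std::vector<int> traj_gen, traj_locus;

  if (T_split == 0) {
    sim.rebuild();
    std::vector<int> both =
        sample_without_replacement(N_anc, n_sam_wild + n_sam_cul);
    wild_idx.assign(both.begin(), both.begin() + n_sam_wild);
    cul_idx.assign(both.begin() + n_sam_wild, both.end());
  } else {
    sim.rebuild();  // empty the nursery: post-split sites stay per-lineage
    // planted sweeps are conditioned on (near-)completion: if a sweep
    // allele is lost beyond the retry budget or fails to reach 0.99 by
    // sampling time, the whole post-split phase is resampled from the
    // ancestral snapshot (bounded number of attempts)
    const Sim snapshot = sim;
    const int max_attempts = 25;
    bool done = false;
    for (int attempt = 0; attempt < max_attempts && !done; ++attempt) {
      if (attempt > 0) sim = snapshot;
      sim.retries_used = 0;
      int nb = (T_bot > 0) ? N_bot : N_cul;
      sim.advance({0, 0}, {N_wild, nb}, -1);
      wild_pop = 0;
      cul_pop = 1;
      for (size_t j = 0; j < sim.sweep_pos.size(); ++j)
        sim.add_site(sim.sweep_pos[j], cul_pop,
                     runif_int(2 * sim.pops[cul_pop].N));
      sim.sweeps_active = !sim.sweep_pos.empty();
      traj.clear();
      traj_gen.clear();
      traj_locus.clear();
      bool lost = false;
      for (int g = 1; g < T_split && !lost; ++g) {
        if (g % 128 == 0) checkUserInterrupt();
        int nc = (g < T_bot) ? N_bot : N_cul;
        if (!sim.advance({0, 1}, {N_wild, nc}, cul_pop)) {
          lost = true;
          break;
        }
        for (size_t j = 0; j < sim.sweep_pos.size(); ++j) {
          int c = sim.col_of(sim.sweep_pos[j]);
          if (c < 0) continue;
          const PopMat& C = sim.pops[cul_pop];
          int cc = 0;
          for (int r = 0; r < 2 * C.N; ++r)
            cc += C.M[static_cast<size_t>(r) * sim.S() + c];
          traj.push_back(cc / (2.0 * C.N));
          traj_gen.push_back(g);
          traj_locus.push_back(static_cast<int>(j) + 1);
        }
      }
      if (lost) continue;
      done = true;
      for (size_t j = 0; j < sim.sweep_pos.size(); ++j) {
        int c = sim.col_of(sim.sweep_pos[j]);
        double freq = 0;
        if (c >= 0) {
          const PopMat& C = sim.pops[cul_pop];
          int cc = 0;
          for (int r = 0; r < 2 * C.N; ++r)
            cc += C.M[static_cast<size_t>(r) * sim.S() + c];
          freq = cc / (2.0 * C.N);
        }
        if (freq < 0.99) {
          done = false;
          break;
        }
      }
    }
    if (!done)
      stop("sweeps failed to complete within %d post-split attempts",
           max_attempts);
    sim.rebuild();
    wild_idx = sample_without_replacement(N_wild, n_sam_wild);
    cul_idx = sample_without_replacement(sim.pops[cul_pop].N, n_sam_cul);
  }

  // dosage matrix of the sampled individuals, sites polymorphic in the sample
  int S = sim.S();
  int n = n_sam_wild + n_sam_cul;
  std::vector<int> dsum(S, 0);
  IntegerMatrix dos(S, n);
  for (int i = 0; i < n; ++i) {
    int ip = (i < n_sam_wild) ? wild_pop : cul_pop;
    int ind = (i < n_sam_wild) ? wild_idx[i] : cul_idx[i - n_sam_wild];
    const PopMat& P = sim.pops[ip];
    const uint8_t* h0 = P.M.data() + static_cast<size_t>(2 * ind) * S;
    const uint8_t* h1 = P.M.data() + static_cast<size_t>(2 * ind + 1) * S;
    for (int s = 0; s < S; ++s) {
      int d = h0[s] + h1[s];
      dos(s, i) = d;
      dsum[s] += d;
    }
  }
  std::vector<int> keep;
  for (int s = 0; s < S; ++s)
    if (dsum[s] > 0 && dsum[s] < 2 * n) keep.push_back(s);

  IntegerMatrix out(static_cast<int>(keep.size()), n);
  IntegerVector outpos(static_cast<int>(keep.size()));
  for (size_t k = 0; k < keep.size(); ++k) {
    outpos[k] = sim.pos[keep[k]];
    for (int i = 0; i < n; ++i) out(static_cast<int>(k), i) = dos(keep[k], i);
  }

  // realized cultivated-sample frequency of each sweep allele
  NumericVector swfreq(sweep_pos.size(), NA_REAL);
  for (int j = 0; j < sweep_pos.size(); ++j) {
    int c = sim.col_of(sweep_pos[j]);
    if (c < 0) {
      swfreq[j] = 0.0;
      continue;
    }
    double tot = 0;
    for (int i = n_sam_wild; i < n; ++i) tot += dos(c, i);
    swfreq[j] = tot / (2.0 * n_sam_cul);
  }

  return List::create(_["pos"] = outpos, _["dosage"] = out,
                      _["sweep_freq"] = swfreq,
                      _["retries"] = sim.retries_used,
                      _["traj"] = DataFrame::create(
                          _["gen"] = traj_gen, _["locus"] = traj_locus,
                          _["freq"] = traj));
}
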