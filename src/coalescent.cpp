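// Structured-coalescent core: piecewise-constant epochs, backward migration,
// population merges, infinite-sites mutations.  Uses R's RNG so results are
// reproducible under set.seed().  Limited to <= 64 haploid lineages (carrier
// sets are stored as 64-bit masks).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct SimTree {
  std::vector<int> parent;
  std::vector<double> ntime;
  std::vector<uint64_t> mask; // carrier bitmask per node
  int nnode;
};

// One genealogy under the epoch model.
// epoch_end: increasing backward times, last must be +Inf.
// nu:  E x P scaled sizes (pairwise coalescence rate 1/nu per unit time).
// mig: E x (P*P), backward rate of a lineage in p jumping to q at [p*P+q].
// merges: rows (time, from, to), sorted by time; at `time` all lineages in
// `from` move to `to` (population split viewed backward in time).
static void sim_tree(const std::vector<int> &spop, int P,
                     const NumericVector &epoch_end, const NumericMatrix &nu,
                     const NumericMatrix &mig, const NumericMatrix &merges,
                     SimTree &out) {
  const int n = (int)spop.size();
  const int E = epoch_end.size();
  const int nm = merges.nrow();
  const int nnode = 2 * n - 1;
  out.parent.assign(nnode, -1);
  out.ntime.assign(nnode, 0.0);
  out.mask.assign(nnode, 0);
  out.nnode = nnode;

  std::vector<int> pop(nnode, -1);
  std::vector<int> active;
  active.reserve(n);
  for (int i = 0; i < n; ++i) {
    pop[i] = spop[i];
    out.mask[i] = (uint64_t)1 << i;
    active.push_back(i);
  }

  double t = 0.0;
  int e = 0, mi = 0, nxt = n;
  std::vector<double> crate(P), mrate(P * P);
  std::vector<int> kp(P);

  while ((int)active.size() > 1) {
    while (e + 1 < E && epoch_end[e] <= t) ++e;
    std::fill(kp.begin(), kp.end(), 0);
    for (int id : active) kp[pop[id]]++;

    double tot = 0.0;
    for (int p = 0; p < P; ++p) {
      crate[p] = 0.5 * (double)kp[p] * (kp[p] - 1) / nu(e, p);
      tot += crate[p];
      for (int q = 0; q < P; ++q) {
        double r = (p == q) ? 0.0 : (double)kp[p] * mig(e, p * P + q);
        mrate[p * P + q] = r;
        tot += r;
      }
    }

    double bound = epoch_end[e];
    if (mi < nm && merges(mi, 0) < bound) bound = merges(mi, 0);
    double dt = (tot > 0.0) ? R::exp_rand() / tot : R_PosInf;

    if (t + dt >= bound) {
      if (!R_FINITE(bound))
        stop("lineages cannot coalesce: disconnected populations with no migration or merge");
      t = bound;
      while (mi < nm && merges(mi, 0) <= t) {
        int from = (int)merges(mi, 1), to = (int)merges(mi, 2);
        for (int id : active) if (pop[id] == from) pop[id] = to;
        ++mi;
      }
      continue;
    }

    t += dt;
    double u = unif_rand() * tot;
    int done = 0;
    for (int p = 0; p < P && !done; ++p) {
      if (u < crate[p]) {
        // coalesce two random lineages in p
        int a = -1, b = -1, seen = 0;
        for (int idx = 0; idx < (int)active.size(); ++idx)
          if (pop[active[idx]] == p) ++seen;
        int ia = (int)(unif_rand() * seen); if (ia >= seen) ia = seen - 1;
        int ib = (int)(unif_rand() * (seen - 1)); if (ib >= seen - 1) ib = seen - 2;
        if (ib >= ia) ++ib;
        int cnt = 0;
        for (int idx = 0; idx < (int)active.size(); ++idx) {
          if (pop[active[idx]] == p) {
            if (cnt == ia) a = idx;
            if (cnt == ib) b = idx;
            ++cnt;
          }
        }
        int na = active[a], nb = active[b];
        int w = nxt++;
        out.parent[na] = w; out.parent[nb] = w;
        out.ntime[w] = t; pop[w] = p;
        out.mask[w] = out.mask[na] | out.mask[nb];
        // remove a,b; add w
        if (a > b) std::swap(a, b);
        active[a] = w;
        active.erase(active.begin() + b);
        done = 1;
        break;
      }
      u -= crate[p];
      for (int q = 0; q < P; ++q) {
        double r = mrate[p * P + q];
        if (u < r) {
          int seen = 0;
          for (int id : active) if (pop[id] == p) ++seen;
          int pick = (int)(unif_rand() * seen); if (pick >= seen) pick = seen - 1;
          int cnt = 0;
          for (int id : active)
            if (pop[id] == p) { if (cnt == pick) { pop[id] = q; break; } ++cnt; }
          done = 1;
          break;
        }
        u -= r;
      }
    }
  }
}

// Simulate independent loci.
//
// mode 0: genotype matrices -> List of IntegerMatrix (sites x haplotypes, 0/1)
// mode 1: empirical joint SFS of mutations over (axis0, axis1) lineages
// mode 2: branch-length accumulation (Monte-Carlo expected SFS): per-locus
//         bin totals are accumulated as sum and sum of squares for SEs
//
// axis: per-lineage axis assignment (0 -> rows, 1 -> cols, -1 -> excluded).
// theta_half: mutation rate per lineage per unit of coalescent time.
// [[Rcpp::export]]
List sim_loci_cpp(IntegerVector sample_pop, int n_pops,
                  NumericVector epoch_end, NumericMatrix nu, NumericMatrix mig,
                  NumericMatrix merges, double theta_half, int n_loci,
                  int mode, IntegerVector axis) {
  const int n = sample_pop.size();
  if (n > 64) stop("at most 64 haploid lineages are supported");
  if (n < 2) stop("need at least two lineages");
  std::vector<int> spop(sample_pop.begin(), sample_pop.end());

  uint64_t m0 = 0, m1 = 0;
  for (int i = 0; i < n; ++i) {
    if (axis[i] == 0) m0 |= (uint64_t)1 << i;
    else if (axis[i] == 1) m1 |= (uint64_t)1 << i;
  }
  const int n1 = popcount64(m0), n2 = popcount64(m1);

  SimTree tr;
  List geno_out(mode == 0 ? n_loci : 0);
  NumericMatrix sfs(n1 + 1, n2 + 1);
  NumericMatrix bsum(n1 + 1, n2 + 1), bsq(n1 + 1, n2 + 1);
  NumericMatrix bloc(n1 + 1, n2 + 1);

  for (int l = 0; l < n_loci; ++l) {
    sim_tree(spop, n_pops, epoch_end, nu, mig, merges, tr);
    const int nb = tr.nnode - 1; // all but root carry a branch
    double total = 0.0;
    std::vector<double> blen(nb);
    for (int v = 0; v < nb; ++v) {
      blen[v] = tr.ntime[tr.parent[v]] - tr.ntime[v];
      total += blen[v];
    }

    if (mode == 2) {
      std::fill(bloc.begin(), bloc.end(), 0.0);
      for (int v = 0; v < nb; ++v) {
        int i = popcount64(tr.mask[v] & m0);
        int j = popcount64(tr.mask[v] & m1);
        bloc(i, j) += blen[v];
      }
      for (int i = 0; i <= n1; ++i)
        for (int j = 0; j <= n2; ++j) {
          bsum(i, j) += bloc(i, j);
          bsq(i, j) += bloc(i, j) * bloc(i, j);
        }
      continue;
    }

    int nmut = (int)R::rpois(theta_half * total);
    if (mode == 1) {
      for (int m = 0; m < nmut; ++m) {
        double u = unif_rand() * total, c = 0.0;
        int v = nb - 1;
        for (int w = 0; w < nb; ++w) { c += blen[w]; if (u < c) { v = w; break; } }
        sfs(popcount64(tr.mask[v] & m0), popcount64(tr.mask[v] & m1)) += 1.0;
      }
    } else {
      IntegerMatrix g(nmut, n);
      for (int m = 0; m < nmut; ++m) {
        double u = unif_rand() * total, c = 0.0;
        int v = nb - 1;
        for (int w = 0; w < nb; ++w) { c += blen[w]; if (u < c) { v = w; break; } }
        for (int s = 0; s < n; ++s)
          g(m, s) = (tr.mask[v] >> s) & 1 ? 1 : 0;
      }
      geno_out[l] = g;
    }
  }

  if (mode == 0) return List::create(_["loci"] = geno_out);
  if (mode == 1) return List::create(_["sfs"] = sfs);
  return List::create(_["sum"] = bsum, _["sumsq"] = bsq, _["n"] = n_loci);
}
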