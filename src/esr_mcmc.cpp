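// Component-wise random-walk Metropolis sampler for the hierarchical drift
// model on a rooted 3-leaf population tree with autosome/X contrast.
//
// Tree:   root -> C (branch 2),  root -> inner (branch 3),
//         inner -> A (branch 0), inner -> B (branch 1).
//
// Latent allele frequencies are parameterized on Fisher's angular scale
// z = arcsin(sqrt(p)), z in [0, pi/2], on which genetic drift of strength
// tau = t/2Ne is approximately Gaussian with constant variance tau/4 (the
// classical variance-stabilizing transformation of the Wright-Fisher
// diffusion).  The kernel is truncated with absorbing atoms at the
// boundaries: the Nicholson-style truncated-Gaussian surrogate applied on
// the angular scale, which keeps its accuracy for rare alleles.
// X-linked branch lengths are tied to autosomal ones by
// tau_X = tau_A * (16 - 8 xi) / 9.
//
// Per SNP: root z_r, inner z_w, leaf z_a, z_b, z_c; leaf counts are
// binomial with p = sin^2(z).  Root frequencies follow hierarchical
// Beta(a, b) priors with separate hyper-parameters for the autosomal and
// X-linked marker classes (their ancestral spectra differ).
// Priors: tau ~ U(0, tau_max); xi ~ U(0, 1); log a, log b uniform.
// Proposal scales are adapted during pilot runs, then frozen.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;
static const double ZMAX = M_PI_2;

// log standard-normal lower-tail probability via erfc
static inline double log_pnorm_lower(double z) {
  return std::log(0.5 * std::erfc(-z * M_SQRT1_2));
}

// drift kernel on the angular scale: child z given parent zq, sd in z
// units; absorbing atoms at 0 and ZMAX; boundary parents are fixed points
static inline double logkern(double z, double zq, double sd) {
  if (zq <= 0.0 || zq >= ZMAX || sd <= 0.0)
    return (z == zq) ? 0.0 : R_NegInf;
  if (z <= 0.0) return log_pnorm_lower(-zq / sd);
  if (z >= ZMAX) return log_pnorm_lower(-(ZMAX - zq) / sd);
  double u = (z - zq) / sd;
  return -0.5 * u * u - std::log(sd) - LOG_SQRT_2PI;
}

static inline double binll(int y, int n, double z) {
  double s = std::sin(z);
  double p = s * s;
  if (p <= 0.0) return (y > 0) ? R_NegInf : 0.0;
  if (p >= 1.0) return (y < n) ? R_NegInf : 0.0;
  return y * std::log(p) + (n - y) * std::log1p(-p);
}

// censored random-walk proposal log-density (atoms at 0 and ZMAX)
static inline double qld(double from, double to, double s) {
  if (to <= 0.0) return log_pnorm_lower(-from / s);
  if (to >= ZMAX) return log_pnorm_lower(-(ZMAX - from) / s);
  double u = (to - from) / s;
  return -0.5 * u * u - std::log(s) - LOG_SQRT_2PI;
}

static inline double clampz(double x) {
  if (x <= 0.0) return 0.0;
  if (x >= ZMAX) return ZMAX;
  return x;
}

static inline double reflect_in(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

struct EsrState {
  std::vector<int> ya, yb, yc, na, nb, nc; // counts per leaf
  int La, L; // autosomal count, total count
  std::vector<double> r, w, pa, pb, pc; // latents on the angular scale
  double tau[4], xi[4];
  double beta_a[2], beta_b[2]; // root prior per marker class
  double tau_max;

  inline bool isx(int l) const { return l >= La; }
  // kernel sd on the angular scale: sqrt(tau_eff) / 2
  inline double sdeff(int b, int l) const {
    double t = isx(l) ? tau[b] * (16.0 - 8.0 * xi[b]) / 9.0 : tau[b];
    return 0.5 * std::sqrt(t);
  }
};

// log root-prior density in z: Beta(a, b) on p = sin^2(z) with Jacobian
// dp/dz = sin(2z); the Beta normalizer is handled in the hyper updates
static inline double logroot(double z, double a, double b) {
  double s = std::sin(z), c = std::cos(z);
  double p = s * s;
  if (p <= 0.0 || p >= 1.0) return R_NegInf;
  return (a - 1.0) * std::log(p) + (b - 1.0) * std::log1p(-p) +
         std::log(2.0 * s * c);
}

// single-pass log-density difference for a branch-parameter move
// (sa/sx are the autosomal and X kernel sds before and after the move)
static double branch_delta(const EsrState &st, int b,
                           double sa_old, double sa_new,
                           double sx_old, double sx_new, bool x_only) {
  double d = 0.0;
  for (int l = 0; l < st.L; ++l) {
    bool xl = st.isx(l);
    if (x_only && !xl) continue;
    double s0 = xl ? sx_old : sa_old;
    double s1 = xl ? sx_new : sa_new;
    double child, par;
    switch (b) {
      case 0: child = st.pa[l]; par = st.w[l]; break;
      case 1: child = st.pb[l]; par = st.w[l]; break;
      case 2: child = st.pc[l]; par = st.r[l]; break;
      default: child = st.w[l]; par = st.r[l]; break;
    }
    double vn = logkern(child, par, s1);
    if (!R_FINITE(vn)) return R_NegInf;
    d += vn - logkern(child, par, s0);
  }
  return d;
}

// combined log-density difference for a simultaneous move of branches
// 0 (A), 1 (B) and 3 (inner); sd_old/sd_new are indexed [branch][class]
// with class 0 = autosomal, 1 = X
static double cherry_delta(const EsrState &st, const double sd_old[4][2],
                           const double sd_new[4][2]) {
  double d = 0.0;
  for (int l = 0; l < st.L; ++l) {
    int s = st.isx(l) ? 1 : 0;
    double v = logkern(st.pa[l], st.w[l], sd_new[0][s]) +
               logkern(st.pb[l], st.w[l], sd_new[1][s]) +
               logkern(st.w[l], st.r[l], sd_new[3][s]);
    if (!R_FINITE(v)) return R_NegInf;
    d += v - logkern(st.pa[l], st.w[l], sd_old[0][s]) -
         logkern(st.pb[l], st.w[l], sd_old[1][s]) -
         logkern(st.w[l], st.r[l], sd_old[3][s]);
  }
  return d;
}

// [[Rcpp::export]]
List esr_mcmc_cpp(IntegerMatrix auto_y, IntegerMatrix auto_n,
                  IntegerMatrix x_y, IntegerMatrix x_n,
                  int n_pilot, int pilot_iter, int n_iter, int burnin,
                  int thin, double tau_max) {
  EsrState st;
  st.La = auto_y.nrow();
  st.L = st.La + x_y.nrow();
  st.tau_max = tau_max;
  st.ya.resize(st.L); st.yb.resize(st.L); st.yc.resize(st.L);
  st.na.resize(st.L); st.nb.resize(st.L); st.nc.resize(st.L);
  for (int l = 0; l < st.La; ++l) {
    st.ya[l] = auto_y(l, 0); st.yb[l] = auto_y(l, 1); st.yc[l] = auto_y(l, 2);
    st.na[l] = auto_n(l, 0); st.nb[l] = auto_n(l, 1); st.nc[l] = auto_n(l, 2);
  }
  for (int l = 0; l < st.L - st.La; ++l) {
    st.ya[st.La + l] = x_y(l, 0); st.yb[st.La + l] = x_y(l, 1);
    st.yc[st.La + l] = x_y(l, 2);
    st.na[st.La + l] = x_n(l, 0); st.nb[st.La + l] = x_n(l, 1);
    st.nc[st.La + l] = x_n(l, 2);
  }

  st.r.resize(st.L); st.w.resize(st.L);
  st.pa.resize(st.L); st.pb.resize(st.L); st.pc.resize(st.L);
  auto ztrans = [](double f) {
    return std::asin(std::sqrt(std::min(0.99, std::max(0.01, f))));
  };
  for (int l = 0; l < st.L; ++l) {
    double fa = st.na[l] > 0 ? (double)st.ya[l] / st.na[l] : 0.5;
    double fb = st.nb[l] > 0 ? (double)st.yb[l] / st.nb[l] : 0.5;
    double fc = st.nc[l] > 0 ? (double)st.yc[l] / st.nc[l] : 0.5;
    st.r[l] = ztrans((fa + fb + fc) / 3.0);
    st.w[l] = ztrans((fa + fb) / 2.0);
    st.pa[l] = ztrans(fa);
    st.pb[l] = ztrans(fb);
    st.pc[l] = ztrans(fc);
  }
  for (int b = 0; b < 4; ++b) { st.tau[b] = 0.05; st.xi[b] = 0.5; }
  st.beta_a[0] = st.beta_a[1] = 1.0;
  st.beta_b[0] = st.beta_b[1] = 1.0;

  // running per-class sums of log p and log(1 - p) at the root
  double sum_lr[2] = {0.0, 0.0}, sum_l1r[2] = {0.0, 0.0};
  int Lset[2] = {st.La, st.L - st.La};
  for (int l = 0; l < st.L; ++l) {
    int s = st.isx(l) ? 1 : 0;
    double sp = std::sin(st.r[l]);
    sum_lr[s] += std::log(sp * sp);
    sum_l1r[s] += std::log1p(-sp * sp);
  }

  // proposal scales: 0 r, 1 w, 2 pa, 3 pb, 4 pc, 5..8 tau, 9..12 xi,
  // 13..16 root-prior hyper-parameters (log scale, per marker class),
  // 17 tau ridge, 18 xi ridge
  const int NSC = 19;
  double sc[NSC];
  for (int i = 0; i < 5; ++i) sc[i] = 0.15;
  for (int i = 5; i < 9; ++i) sc[i] = 0.02;
  for (int i = 9; i < 13; ++i) sc[i] = 0.2;
  for (int i = 13; i < 17; ++i) sc[i] = 0.3;
  sc[17] = 0.02; sc[18] = 0.1;
  double acc[NSC], tries[NSC];

  const int nkeep = (n_iter > burnin) ? (n_iter - burnin) / thin : 0;
  NumericMatrix samples(nkeep, 8);
  int kept = 0;

  auto sweep = [&](bool record) {
    for (int l = 0; l < st.L; ++l) {
      double s0 = st.sdeff(0, l), s1 = st.sdeff(1, l), s2 = st.sdeff(2, l),
             s3 = st.sdeff(3, l);
      int cls = st.isx(l) ? 1 : 0;
      // root (reflected into the open interval; hierarchical Beta prior)
      {
        double cur = st.r[l];
        double prop = reflect_in(cur + sc[0] * norm_rand(), 1e-9,
                                 ZMAX - 1e-9);
        double lo = logkern(st.w[l], cur, s3) + logkern(st.pc[l], cur, s2) +
                    logroot(cur, st.beta_a[cls], st.beta_b[cls]);
        double ln = logkern(st.w[l], prop, s3) + logkern(st.pc[l], prop, s2) +
                    logroot(prop, st.beta_a[cls], st.beta_b[cls]);
        tries[0] += 1;
        if (std::log(unif_rand()) < ln - lo) {
          double spn = std::sin(prop), spc = std::sin(cur);
          sum_lr[cls] += std::log(spn * spn) - std::log(spc * spc);
          sum_l1r[cls] += std::log1p(-spn * spn) - std::log1p(-spc * spc);
          st.r[l] = prop;
          acc[0] += 1;
        }
      }
      // inner node (censored RW, atoms allowed)
      {
        double cur = st.w[l];
        double prop = clampz(cur + sc[1] * norm_rand());
        double lo = logkern(cur, st.r[l], s3) + logkern(st.pa[l], cur, s0) +
                    logkern(st.pb[l], cur, s1);
        double ln = logkern(prop, st.r[l], s3) + logkern(st.pa[l], prop, s0) +
                    logkern(st.pb[l], prop, s1);
        double lr = ln - lo + qld(prop, cur, sc[1]) - qld(cur, prop, sc[1]);
        tries[1] += 1;
        if (std::log(unif_rand()) < lr) { st.w[l] = prop; acc[1] += 1; }
      }
      // leaves
      {
        double cur = st.pa[l];
        double prop = clampz(cur + sc[2] * norm_rand());
        double lo = logkern(cur, st.w[l], s0) + binll(st.ya[l], st.na[l], cur);
        double ln = logkern(prop, st.w[l], s0) + binll(st.ya[l], st.na[l], prop);
        double lr = ln - lo + qld(prop, cur, sc[2]) - qld(cur, prop, sc[2]);
        tries[2] += 1;
        if (std::log(unif_rand()) < lr) { st.pa[l] = prop; acc[2] += 1; }
      }
      {
        double cur = st.pb[l];
        double prop = clampz(cur + sc[3] * norm_rand());
        double lo = logkern(cur, st.w[l], s1) + binll(st.yb[l], st.nb[l], cur);
        double ln = logkern(prop, st.w[l], s1) + binll(st.yb[l], st.nb[l], prop);
        double lr = ln - lo + qld(prop, cur, sc[3]) - qld(cur, prop, sc[3]);
        tries[3] += 1;
        if (std::log(unif_rand()) < lr) { st.pb[l] = prop; acc[3] += 1; }
      }
      {
        double cur = st.pc[l];
        double prop = clampz(cur + sc[4] * norm_rand());
        double lo = logkern(cur, st.r[l], s2) + binll(st.yc[l], st.nc[l], cur);
        double ln = logkern(prop, st.r[l], s2) + binll(st.yc[l], st.nc[l], prop);
        double lr = ln - lo + qld(prop, cur, sc[4]) - qld(cur, prop, sc[4]);
        tries[4] += 1;
        if (std::log(unif_rand()) < lr) { st.pc[l] = prop; acc[4] += 1; }
      }
    }

    // branch parameters: random-walk moves mixed with occasional
    // independence draws from the prior (faster burn-in escape)
    for (int b = 0; b < 4; ++b) {
      bool indep = unif_rand() < 0.1;
      double prop = indep ? unif_rand() * st.tau_max
                          : reflect_in(st.tau[b] + sc[5 + b] * norm_rand(),
                                       1e-8, st.tau_max);
      double xf = (16.0 - 8.0 * st.xi[b]) / 9.0;
      double d = branch_delta(st, b,
                              0.5 * std::sqrt(st.tau[b]),
                              0.5 * std::sqrt(prop),
                              0.5 * std::sqrt(st.tau[b] * xf),
                              0.5 * std::sqrt(prop * xf), false);
      if (!indep) tries[5 + b] += 1;
      if (std::log(unif_rand()) < d) {
        st.tau[b] = prop;
        if (!indep) acc[5 + b] += 1;
      }
    }
    for (int b = 0; b < 4; ++b) {
      bool indep = unif_rand() < 0.1;
      double prop = indep ? unif_rand()
                          : reflect_in(st.xi[b] + sc[9 + b] * norm_rand(),
                                       1e-8, 1.0 - 1e-8);
      double sx0 = 0.5 * std::sqrt(st.tau[b] * (16.0 - 8.0 * st.xi[b]) / 9.0);
      double sx1 = 0.5 * std::sqrt(st.tau[b] * (16.0 - 8.0 * prop) / 9.0);
      double d = branch_delta(st, b, 0.0, 0.0, sx0, sx1, true);
      if (!indep) tries[9 + b] += 1;
      if (std::log(unif_rand()) < d) {
        st.xi[b] = prop;
        if (!indep) acc[9 + b] += 1;
      }
    }

    // root-prior hyper-parameters: log-scale random walk with a
    // log-uniform prior on [0.05, 50] (prior and Jacobian cancel)
    for (int s = 0; s < 2; ++s) {
      if (Lset[s] == 0) continue;
      for (int h = 0; h < 2; ++h) {
        int k = 13 + 2 * s + h;
        double cur = h == 0 ? st.beta_a[s] : st.beta_b[s];
        double prop = std::exp(reflect_in(std::log(cur) +
                                          sc[k] * norm_rand(),
                                          std::log(0.05), std::log(50.0)));
        double a0 = st.beta_a[s], b0 = st.beta_b[s];
        double a1 = h == 0 ? prop : a0, b1 = h == 0 ? b0 : prop;
        double d = (a1 - a0) * sum_lr[s] + (b1 - b0) * sum_l1r[s] -
                   Lset[s] * (R::lbeta(a1, b1) - R::lbeta(a0, b0));
        tries[k] += 1;
        if (std::log(unif_rand()) < d) {
          if (h == 0) st.beta_a[s] = prop; else st.beta_b[s] = prop;
          acc[k] += 1;
        }
      }
    }

    if (record) {
      for (int b = 0; b < 4; ++b) {
        samples(kept, b) = st.tau[b];
        samples(kept, 4 + b) = st.xi[b];
      }
      ++kept;
    }
  };

  // pilot runs with step adaptation, frozen afterwards
  for (int p = 0; p < n_pilot; ++p) {
    for (int i = 0; i < NSC; ++i) { acc[i] = 0; tries[i] = 0; }
    for (int it = 0; it < pilot_iter; ++it) sweep(false);
    for (int i = 0; i < NSC; ++i) {
      double rate = tries[i] > 0 ? acc[i] / tries[i] : 0.3;
      double f = rate / 0.30;
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      sc[i] *= f;
      if (sc[i] < 1e-5) sc[i] = 1e-5;
      if (sc[i] > 2.0) sc[i] = 2.0;
    }
  }

  for (int i = 0; i < NSC; ++i) { acc[i] = 0; tries[i] = 0; }
  for (int it = 0; it < n_iter; ++it) {
    bool rec = (it >= burnin) && ((it - burnin) % thin == thin - 1) &&
               kept < nkeep;
    sweep(rec);
  }

  NumericVector arate(NSC), scales(NSC);
  for (int i = 0; i < NSC; ++i) {
    arate[i] = tries[i] > 0 ? acc[i] / tries[i] : NA_REAL;
    scales[i] = sc[i];
  }
  return List::create(_["samples"] = samples, _["accept"] = arate,
                      _["scales"] = scales);
}
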