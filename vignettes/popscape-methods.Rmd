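---
title: "Methods: divergence modelling, effective sex ratios, and linked-selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence modelling, effective sex ratios, and linked-selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popscape quantifies three processes that shape genomic landscapes of
diversity and divergence between closely related populations: the timing
and heterogeneity of gene flow after a population split, sex-biased
contributions to the gene pool, and linked selection interacting with
recombination.  This vignette documents the models, the numerical choices,
and what the synthetic-data experiments shipped with the package do and do
not demonstrate.

## Two-population divergence models on the joint SFS

The observed data are an unfolded joint site frequency spectrum (SFS): for
haploid sample sizes $n_1$, $n_2$, entry $(i, j)$ counts the SNPs with $i$
derived copies in population 1 and $j$ in population 2.  Polarization
against two outgroup individuals uses a 75% frequency rule; its residual
error is captured by a model parameter $O$ (the fraction of correctly
polarized sites), applied as a mixture of the model spectrum with its
derived/ancestral mirror image.

Six scenario categories describe divergence from a common ancestral
population: strict isolation (SI), isolation with migration (IM), ancient
migration with one (AM) or two (PAM) contact episodes, and secondary
contact with one (SC) or two (PSC) contact episodes.  Three modifiers add
realism: `ex` (exponential size change over the final `t_scg` time units),
`2N` (a fraction `nr` of loci evolves with all effective sizes multiplied
by a background-selection factor `bf`, a locus-class caricature of linked
selection), and `2M2P` (fractions `P1`, `P2` of loci receive no migration
into population 1 resp. 2 — genomic islands resisting gene flow).
Excluding combinations a category cannot express, the catalogue has 34
scenarios (`model_catalogue()`).

All parameters are scaled by a reference diploid size $N_{\mathrm{ref}}$:
sizes $\nu = N/N_{\mathrm{ref}}$, times $t$ in units of
$2N_{\mathrm{ref}}$ generations, and migration $M = 2N_{\mathrm{ref}} m$.
`to_demographic_units()` converts back given $N_{\mathrm{ref}}$ (in
practice the harmonic mean of an external single-population size
reconstruction before the split) and a generation time.

For `PAM`/`PSC` the two isolation episodes each last `t_iso/2` and the two
contact episodes `t_sc/2`; `PSC` ends in contact, `PAM` in isolation.  The
published description of PAM is ambiguous about which of the two durations
is halved per episode; we implement alternating contact/isolation with
both halved, ending isolated, and the epoch builder is exposed
(`build_epochs()`) so users can inspect exactly what is fitted.

### Expected spectra

Two engines compute the model expectation (up to a global scale):

* **exact** — deterministic integration of the moment system of the
  two-population diffusion.  The expected SFS entries evolve under linear
  ODEs: drift is a closed tridiagonal operator per population axis;
  migration couples to the spectrum at sample sizes $(n_1-1, n_2+1)$
  (resp. mirrored), obtained by an exact hypergeometric down-projection on
  one axis and a quadratic-jackknife extrapolation on the other; new
  mutations enter as a constant source at the two singleton entries.  Each
  constant-rate epoch is advanced with a matrix exponential of the affine
  system; exponential-growth epochs are discretized into (by default) 24
  geometric piecewise-constant steps.  The jackknife closure is exact for
  locally quadratic frequency densities but biased near the $1/x$-like
  singular part of the spectrum; the engine therefore integrates at an
  internally padded sample size (default: the larger sample padded to 12)
  and projects down exactly, which reduces the worst-entry relative error
  to the 1-2% range for migration rates $M \le 8$ at $n = 8$ per
  population.  The two fixed corners are boundary atoms, not density, and
  are excluded from the dynamics.  The same padding logic gives the final
  polish stage of `fit_model()` a higher-accuracy objective (`pad_polish`).
* **mc** — a seeded Monte-Carlo structured coalescent (the same core as
  the data generator): the expectation of the branch length subtending
  $(i, j)$ sampled descendants, averaged over independent genealogies,
  with per-entry Monte-Carlo standard errors.  It is unbiased for any
  sample size and serves as the independent cross-check of the exact
  engine in the test suite.

A single-population constant-size population has the classical $1/i$
equilibrium; `equilibrium_sfs_single()` recovers it by solving the
steady state of the same discrete system, which is how the engine's
drift-mutation balance is validated.

### Fitting and comparison

`composite_loglik()` treats unmasked entries as independent Poisson counts
with the overall scale profiled analytically, so $\theta$ never needs to
be specified.  `fit_model()` runs derivative-free Nelder-Mead searches on
logistic-transformed parameters from log-uniform random starts (the
default, 30, mirrors common practice; the examples below use fewer),
keeps the best replicate, and polishes it under the higher-accuracy
engine configuration.  Default bounds are $\nu \in [10^{-3}, 10^2]$,
$M \in [10^{-2}, 40]$, $t \in [0.01, 20]$; the lower time bound
corresponds to roughly fifty thousand years at a reference size of order
two million and one generation per year.  Models are compared by
$\mathrm{AIC} = 2k - 2\ln L$ with $k$ the catalogue's free-parameter
count.  Parameter uncertainty comes from a nonparametric bootstrap: 100
multinomial resamples of the SFS, each refitted from the best-fit
parameters, summarized by per-parameter standard deviations with
star-coded bands (below 20%, 20-50%, 50-150% of the estimate).  This
replaces analytic Godambe-information intervals with a simpler,
directly testable procedure using the same resampling source.

Identifiability caveat: with small samples ($n = 8$ haploids per
population and below) the composite-likelihood surface of SC-type models
has a pronounced ridge trading migration rate against contact duration
and sizes — parameter sets along the ridge differ by only a few
log-likelihood units, i.e. by less than sampling noise.  Absolute times
of isolation and contact should therefore be interpreted cautiously at
desk scales; sizes and migration rates are recovered reliably at
$2 \times 8 + 2 \times 8$ haplotypes and $\sim$30,000 SNPs (the scale
exercised in the test suite), total times much better than their split
into episodes.

## Effective sex ratios from the autosome/X contrast

Because males are XY and females XX, autosomes and X chromosomes
experience different effective sizes whenever the sexes contribute
unequally.  With female fraction $\xi$, the classical expectation is
$N_X / N_A = 9 / (16 - 8\xi)$ (0.75 at $\xi = 0.5$).  The package
estimates per-branch $\xi$ on a rooted three-leaf population tree by
contrasting drift at autosomal and X-linked SNPs.

The hierarchical model follows the time-dependent diffusion tradition:
each SNP has a root frequency, latent frequencies at the inner node and
the three leaves, and observed counts that are binomial draws from the
leaf frequencies (X counts male-adjusted: one haplotype per XY
individual, two per XX).  Drift along a branch of length
$\tau = t / 2N_e$ is modelled as a truncated Gaussian with variance
$\tau\,p(1-p)$ and absorbing mass at the boundaries — the standard
computational surrogate of the Kimura diffusion, exposed through
`drift_transition()`.  Inside the sampler the kernel is applied on
Fisher's angular scale $z = \arcsin\sqrt{p}$, where drift has constant
variance $\tau/4$: the variance-stabilized form of the same surrogate,
which remains accurate for rare alleles (the regime that dominates
SNP panels) where the untransformed Gaussian is badly skewed.  Root
frequencies carry hierarchical $\mathrm{Beta}(a, b)$ priors with
separate hyper-parameters for autosomal and X-linked markers, learned
from the data — the ancestral spectra of the two classes differ, and a
flat root prior demonstrably distorts the branch estimates on
SFS-shaped data.  X-linked branch lengths are tied to autosomal ones by
$\tau_X = \tau_A (16 - 8\xi)/9$, which is what identifies $\xi$.
Priors: $\tau \sim U(0, 10)$, $\xi \sim U(0, 1)$, log-uniform
hyper-priors on $(a, b)$.

Sampling is component-wise random-walk Metropolis over all latents and
branch parameters, with proposal scales adapted during pilot runs (by
default 25 pilots of 1,000 iterations, mirroring the published schedule)
and frozen before the recorded phase (100,000 iterations, burn-in 50,000,
thinning 25 by default; the test suite uses shorter, documented
schedules).  Two additions improve mixing: occasional independence draws
from the prior for $\tau$ and $\xi$ (burn-in escape), and joint "ridge"
shears that trade drift between the inner branch and the two cherry
leaves.  The ridge direction matters because the decomposition of a
root-to-leaf path into inner and outer segments is unidentified from
second moments of the leaf frequencies alone (only $\tau_A$, $\tau_B$
and the sums $\tau_{\mathrm{inner}}+\tau_C$ are); the split — and hence
$\xi$ on the inner and outer-leaf branches — rests on the shape of the
root distribution and higher moments, and is correspondingly fragile.
Leaf-branch sex ratios are the robustly estimated quantities; inner and
outer-branch estimates should be read with their pseudoreplicate spread.
Split-chain potential-scale-reduction factors are reported and the
result flagged when any exceeds 1.1.

Support for a biased sex ratio on branch $i$ is summarized as
$S_i = 1 - 2 |p_i - 0.5|$ with $p_i$ the posterior fraction of samples
with $\xi > 0.5$; $S_i < 0.05$ is read as strong support.  Confidence
comes from pseudoreplication (`replicate_esr()`): by default 50 seeded
redraws of 5,000 autosomal and 5,000 X-linked complete SNPs, each
refitted, reporting the fraction of replicates with $S_i$ below the
threshold.

The generator's sex-linked mode simulates X loci with per-branch sizes
scaled by $9/(16 - 8\xi)$ and emits per-sample depths with XY individuals
at half the autosomal coverage on the X (gamma noise with coefficient of
variation 0.2 by default — only the X/autosome ratio matters for sexing,
so the noise model is deliberately simple).  Depth-based sexing classifies
the ratio below 0.625 as XY and above 0.875 as XX, midpoints around the
expected 0.5 and 1.0 with a guard band; simulated coverage at that noise
level is sexed without error given a few hundred sites per class.

## Windowed statistics and linked-selection contrasts

Scan statistics are computed in non-overlapping windows (0-based
half-open; windows intersecting any mask interval are dropped entirely):
nucleotide diversity $\theta_\pi$ per bp and Tajima's $D$ (classical
constants; complete genotypes only), Hudson's
$F_{ST} = 1 - H_w / H_b$ as a ratio of window sums with the unbiased
(pairs-without-replacement) within-population heterozygosity, absolute
divergence $d_{XY}$ per bp, genotype $r^2$ (dosage correlation, the
standard convention for unphased data), the $ZZ$ contrast between
adjacent-pair and all-pair $r^2$ (elevated values indicate intragenic
recombination), and the mean derived allele frequency (DAF) over
polymorphic polarized sites genotyped in at least 6 of 8 focal
individuals — the published site rule reads as its own converse and is
implemented as a genotyped-individuals minimum, exposed as arguments.
$\rho / \theta_\pi$ rescales a windowed recombination map (an input; the
package does not estimate $\rho$) into an $r/\mu$-like quantity less
confounded by local effective size, with five-quantile DAF profiles and
Spearman correlations (average ranks) as the downstream contrasts, and
divergence islands defined as the intersection of the top-20% $F_{ST}$
and bottom-20% $d_{XY}$ tails.

Because all estimators work from allele counts (unphased data), both
$F_{ST}$ and $d_{XY}$ are invariant to reshuffling genotypes within a
population at constant per-site counts; haplotype-based estimators of
within-population diversity would not be.  The LD statistics do respond
to such reshuffling, which the tests exercise.  With the unbiased $H_w$,
$F_{ST}$ between two samples of one panmictic population is centred on
zero (small negative values are possible); a plug-in $H_w$ would instead
be biased upward by $\approx 1/n$.

## The synthetic-data generator

All tests run against a seeded structured-coalescent generator (compiled
core, R's RNG, bit-reproducible): independent loci under piecewise
constant epochs with backward migration and population merges, locus
classes drawn per the `2M2P`/`2N` weights, infinite-sites mutations,
diploid genotypes, per-genotype depth and quality, and VCF/TSV/JSON/BED
writers plus a machine-readable truth record.  Exponential epochs are
discretized into at least 20 piecewise-constant steps (24 by default).
Design choices worth knowing:

* Loci are non-recombining and independent by default.  The optional
  recombining mode used for LD experiments approximates the ancestral
  recombination graph by Poisson-distributed breakpoints with independent
  genealogies between blocks and none within.  That preserves rank-level
  relationships between recombination and LD summaries (windowed $ZZ$
  correlates with true $\rho$ at Spearman $\approx 0.45$ in the shipped
  regime of tens of SNPs per window) but does not reproduce fine-scale
  distance-dependent LD decay.
* Mis-polarization is simulated by flipping each site to its mirrored
  spectrum entry with probability $1 - O$, matching how $O$ enters the
  likelihood.
* Outgroups for the polarization pipeline can be emitted as two
  individuals fixed for the true ancestral allele; coalescent outgroup
  divergence is not simulated, so polarization error rates on synthetic
  data are zero by construction unless $O < 1$ is requested.

The default study conditions for the divergence experiments are a clear
secondary-contact history ($\nu_1 = 1$, $\nu_2 = 3$, $M_{12} = 4$,
$M_{21} = 1.5$, $t_{\mathrm{iso}} = 0.4$, $t_{\mathrm{sc}} = 0.2$,
$O = 0.97$): with a reference size of order $2 \times 10^6$ and one
generation per year these correspond to splits a few million years ago,
contact episodes of several hundred thousand years, and per-generation
migration around $10^{-6}$ — the regime reported for subtropical anole
lizard populations, and one in which both isolation and contact leave
detectable footprints.  Sample sizes (4 + 4 diploids), 20,000 loci and
roughly one SNP per locus mirror a thinned whole-genome SNP set.  What
passing recovery tests show is that the estimator works at these scales
under the model's own assumptions (free recombination between loci, no
selection, correct polarization model); they do not certify performance
on real data with linked loci, reference bias, or unmodeled population
structure.

Problem sizes in the test suite are chosen to keep the full run within a
few minutes per module: 20,000-50,000 loci for SFS laws and recovery,
500 neutral 5-kb windows for the Tajima's $D$ calibration, 200 windows
for the LD-recombination contrast, 2,000 + 2,000 SNPs and 10
pseudoreplicates drawn from a 12,000 + 12,000-locus panel for the
sex-ratio experiments (the panel is kept much larger than the
per-replicate draw so pseudoreplicates measure estimator noise rather
than panel noise), with MCMC schedules of 4,500-8,000 iterations after
5-6 pilot runs (the package defaults remain the full published
schedule).

## Known limitations

* The exact SFS engine is supported to $n = 8$ haploids per population;
  beyond that the Monte-Carlo engine must be used and fitting becomes
  stochastic (common random numbers keep it deterministic per seed).
* The jackknife closure degrades for very strong migration; bounds cap
  $M$ at 40, and the padded configuration has been validated against the
  Monte-Carlo engine up to $M = 8$ (worst-entry error $\sim$2%) and for
  stability at $M = 40$.
* Composite likelihood ignores linkage between SNPs; AIC comparisons are
  heuristic model ranking, not calibrated tests.
* The drift kernel is a truncated-Gaussian surrogate; for very long
  branches ($\tau > 1$) its boundary atoms distort the posterior and the
  uniform $\tau$ prior caps at 10.
* Three-population trees only (the published design); larger trees would
  need a generalized pruning scheme.
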