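# Hierarchical Bayesian drift model on a rooted 3-leaf population tree,
# contrasting autosomal and X-linked allele frequencies to estimate
# per-branch effective sex ratios (female fraction xi).  The drift kernel
# is a truncated Gaussian with variance tau * p(1-p) and absorbing mass at
# the boundaries; X-linked branch lengths are tied to autosomal ones by
# tau_X = tau_A * (16 - 8 xi) / 9.

#' Drift transition kernel
#'
#' Distribution of a descendant allele frequency after drift of strength
#' `tau = t / 2Ne` from an ancestral frequency `p0`: a Gaussian with mean
#' `p0` and variance `tau * p0 * (1 - p0)` truncated to (0, 1), with the
#' excess mass absorbed as atoms at 0 and 1.  `tau = 0` or a boundary `p0`
#' give a point mass.
#'
#' @param p0 Ancestral frequency in \[0, 1\].
#' @param tau Drift branch length (>= 0).
#' @return List with `mean`, `var` (pre-truncation), `sd`, `mass0`,
#'   `mass1`, and `point_mass` (the location of a degenerate distribution,
#'   or `NA`).
#' @export
drift_transition <- function(p0, tau) {
  stopifnot(p0 >= 0, p0 <= 1, tau >= 0)
  v <- tau * p0 * (1 - p0)
  if (tau == 0 || p0 <= 0 || p0 >= 1)
    return(list(mean = p0, var = v, sd = 0, mass0 = as.numeric(p0 == 0),
                mass1 = as.numeric(p0 == 1), point_mass = p0))
  s <- sqrt(v)
  list(mean = p0, var = v, sd = s, mass0 = pnorm(0, p0, s),
       mass1 = pnorm(1, p0, s, lower.tail = FALSE), point_mass = NA_real_)
}

#' Drift kernel density
#'
#' Density (interior) or atom mass (at exactly 0 or 1) of the
#' [drift_transition()] kernel; the reference implementation mirrored by
#' the MCMC core.
#'
#' @param x Descendant frequency.
#' @param p0,tau Kernel parameters.
#' @param log Return the logarithm.
#' @return Density or atom probability.
#' @export
ddrift <- function(x, p0, tau, log = FALSE) {
  k <- drift_transition(p0, tau)
  val <- if (!is.na(k$point_mass)) {
    ifelse(x == k$point_mass, 1, 0)
  } else if (x <= 0) {
    k$mass0
  } else if (x >= 1) {
    k$mass1
  } else {
    dnorm(x, p0, k$sd)
  }
  if (log) base::log(val) else val
}

#' MCMC schedule for the drift-tree sampler
#'
#' Defaults follow the scheme of 25 pilot runs of 1,000 iterations for step
#' adaptation, then 100,000 recorded iterations thinned every 25 after a
#' burn-in of 50,000.
#'
#' @param n_pilot,pilot_iter Pilot runs and their length.
#' @param n_iter Main-run iterations.
#' @param burnin Burn-in iterations.
#' @param thin Thinning interval.
#' @param tau_max Upper bound of the uniform prior on tau.
#' @return Config list.
#' @export
esr_mcmc_config <- function(n_pilot = 25, pilot_iter = 1000,
                            n_iter = 100000, burnin = 50000, thin = 25,
                            tau_max = 10) {
  list(n_pilot = n_pilot, pilot_iter = pilot_iter, n_iter = n_iter,
       burnin = burnin, thin = thin, tau_max = tau_max)
}

# split-chain potential-scale-reduction factor of one scalar chain
rhat_split <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- ncol(halves)
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# resolve a 3-leaf newick into (cherryA, cherryB, outer)
resolve_tree <- function(tree) {
  tr <- ape::read.tree(text = tree)
  if (is.null(tr) || length(tr$tip.label) != 3)
    stop("tree must be a rooted newick topology with exactly 3 leaves")
  inner <- setdiff(unique(tr$edge[, 1]), ape::Ntip(tr) + 1)
  if (length(inner) != 1)
    stop("tree must be rooted with a single cherry")
  cherry <- tr$tip.label[tr$edge[tr$edge[, 1] == inner, 2]]
  c(cherry, setdiff(tr$tip.label, cherry))
}

#' Fit the drift tree and effective sex ratios
#'
#' Component-wise random-walk Metropolis over per-SNP latent frequencies
#' (root, inner node, leaves) and the per-branch parameters `tau_A` and
#' `xi`, with pilot-run step adaptation frozen before the recorded phase.
#' Branches are the three leaf branches plus the internal branch leading to
#' the cherry.
#'
#' @param auto_counts List with integer matrices `y` (derived or alt
#'   copies) and `n` (sampled copies), SNPs x 3 leaves, columns named by
#'   leaf.
#' @param x_counts Same for X-linked SNPs (male-adjusted counts from
#'   [adjust_x_counts()]).
#' @param tree Newick topology with the same three leaf names.
#' @param mcmc [esr_mcmc_config()].
#' @param seed Integer seed.
#' @return Object of class `ps_esr`: `samples` (data frame of posterior
#'   draws of `tau_*` and `xi_*` per branch), `branches`, `p` (posterior
#'   fraction with `xi > 0.5`), `S` (support statistic), `rhat`,
#'   `flagged` (TRUE when any split-chain R-hat exceeds 1.1), `accept`.
#' @export
fit_drift_tree <- function(auto_counts, x_counts, tree,
                           mcmc = esr_mcmc_config(), seed = 1) {
  leaves <- resolve_tree(tree)
  ord <- function(m) as.matrix(m[, leaves, drop = FALSE])
  ya <- ord(auto_counts$y); na <- ord(auto_counts$n)
  yx <- ord(x_counts$y); nx <- ord(x_counts$n)
  storage.mode(ya) <- "integer"; storage.mode(na) <- "integer"
  storage.mode(yx) <- "integer"; storage.mode(nx) <- "integer"

  res <- with_seed(seed, {
    esr_mcmc_cpp(ya, na, yx, nx, mcmc$n_pilot, mcmc$pilot_iter,
                 mcmc$n_iter, mcmc$burnin, mcmc$thin, mcmc$tau_max)
  })
  branches <- c(leaves, "inner")
  sm <- as.data.frame(res$samples)
  names(sm) <- c(paste0("tau_", branches), paste0("xi_", branches))
  p <- vapply(branches, function(b) mean(sm[[paste0("xi_", b)]] > 0.5), 0)
  S <- 1 - 2 * abs(p - 0.5)
  rh <- vapply(names(sm), function(cn) rhat_split(sm[[cn]]), 0)
  structure(list(samples = sm, branches = branches, p = p, S = S,
                 rhat = rh, flagged = any(rh > 1.1, na.rm = TRUE),
                 accept = res$accept, tree = tree),
            class = "ps_esr")
}

#' @export
print.ps_esr <- function(x, ...) {
  cat("Effective sex-ratio posterior (", nrow(x$samples), " draws)\n",
      sep = "")
  med <- vapply(x$branches, function(b)
    median(x$samples[[paste0("xi_", b)]]), 0)
  print(data.frame(branch = x$branches, xi_median = round(med, 3),
                   p = round(x$p, 3), S = round(x$S, 3)))
  if (x$flagged) cat("warning: split-chain R-hat above 1.1\n")
  invisible(x)
}

#' Support statistic for a biased sex ratio
#'
#' `S = 1 - 2 |p - 0.5|` where `p` is the fraction of retained posterior
#' samples with effective sex ratio above 0.5.  Values near 1 indicate no
#' evidence of bias; small values (below 0.05) indicate strong support for
#' a biased sex ratio in either direction.
#'
#' @param posterior A `ps_esr` object, or a numeric vector of posterior
#'   `xi` samples for one branch.
#' @param branch Branch name (required for a `ps_esr`).
#' @return The support statistic in \[0, 1\].
#' @export
support_statistic <- function(posterior, branch = NULL) {
  if (inherits(posterior, "ps_esr")) {
    stopifnot(!is.null(branch), branch %in% posterior$branches)
    xi <- posterior$samples[[paste0("xi_", branch)]]
  } else {
    xi <- as.numeric(posterior)
  }
  if (length(xi) < 1) stop("posterior has no retained samples")
  p <- mean(xi > 0.5)
  1 - 2 * abs(p - 0.5)
}

#' Complete-case allele counts for the drift tree
#'
#' Extracts male-adjusted per-population allele counts from a genotype
#' table and keeps SNPs with no missing genotype (full copy count in every
#' population), separately for autosomal and X-linked markers.
#'
#' @param table A [genotype_table()].
#' @param sexes Sex assignments (see [adjust_x_counts()]).
#' @param populations The three populations to contrast (tree leaves).
#' @return List with `auto` and `x`, each `list(y =, n =)` matrices.
#' @export
esr_counts <- function(table, sexes, populations) {
  ac <- adjust_x_counts(table, sexes)
  cls <- table$chrom_class[table$sites$chrom]
  y <- ac$alt[, populations, drop = FALSE]
  n <- ac$copies[, populations, drop = FALSE]
  # full copy counts differ between autosomes (2 per individual) and the X
  # (2 per XX, 1 per XY), so completeness is judged within each class
  complete_in <- function(klass) {
    rows <- cls == klass
    if (!any(rows)) return(logical(length(cls)))
    full <- apply(n[rows, , drop = FALSE], 2, max)
    ok <- n == matrix(full, nrow(n), ncol(n), byrow = TRUE)
    rows & rowSums(ok) == length(populations)
  }
  keep_a <- complete_in("autosome")
  keep_x <- complete_in("X")
  # polymorphic within the three populations
  poly <- function(k) {
    tot <- rowSums(y[k, , drop = FALSE])
    cap <- rowSums(n[k, , drop = FALSE])
    k[tot > 0 & tot < cap]
  }
  ka <- poly(which(keep_a)); kx <- poly(which(keep_x))
  list(auto = list(y = y[ka, , drop = FALSE], n = n[ka, , drop = FALSE]),
       x = list(y = y[kx, , drop = FALSE], n = n[kx, , drop = FALSE]))
}

#' Pseudoreplicated effective-sex-ratio estimation
#'
#' Draws seeded replicates of `n_autosomal` autosomal and `n_x` X-linked
#' complete SNPs, runs [fit_drift_tree()] on each, and summarizes per
#' branch the fraction of replicates with strong support for a biased sex
#' ratio (`S < support_threshold`).
#'
#' @param table A [genotype_table()].
#' @param sexes Sex assignments.
#' @param tree Newick topology (3 leaves = 3 populations in `table`).
#' @param n_replicates Number of pseudoreplicates.
#' @param n_autosomal,n_x SNPs drawn per replicate (scaled down with a
#'   warning when fewer are available).
#' @param seed Integer seed.
#' @param mcmc [esr_mcmc_config()].
#' @param support_threshold Threshold on `S`.
#' @return List with `replicates` (list of `ps_esr`) and `summary` (per
#'   branch: median xi, mean p, fraction of replicates supporting bias).
#' @export
replicate_esr <- function(table, sexes, tree, n_replicates = 50,
                          n_autosomal = 5000, n_x = 5000, seed = 1,
                          mcmc = esr_mcmc_config(),
                          support_threshold = 0.05) {
  leaves <- resolve_tree(tree)
  cnt <- esr_counts(table, sexes, leaves)
  La <- nrow(cnt$auto$y); Lx <- nrow(cnt$x$y)
  if (Lx == 0) stop("no complete X-linked SNPs after adjustment")
  if (La == 0) stop("no complete autosomal SNPs")
  if (La < n_autosomal) {
    warning(sprintf("only %d autosomal SNPs available (requested %d)",
                    La, n_autosomal))
    n_autosomal <- La
  }
  if (Lx < n_x) {
    warning(sprintf("only %d X-linked SNPs available (requested %d)",
                    Lx, n_x))
    n_x <- Lx
  }
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      ia <- sample.int(La, n_autosomal)
      ix <- sample.int(Lx, n_x)
      sub <- list(auto = list(y = cnt$auto$y[ia, , drop = FALSE],
                              n = cnt$auto$n[ia, , drop = FALSE]),
                  x = list(y = cnt$x$y[ix, , drop = FALSE],
                           n = cnt$x$n[ix, , drop = FALSE]))
      fit_drift_tree(sub$auto, sub$x, tree, mcmc = mcmc,
                     seed = sample.int(.Machine$integer.max, 1))
    })
  })
  branches <- reps[[1]]$branches
  summary <- data.frame(
    branch = branches,
    xi_median = vapply(branches, function(b)
      median(vapply(reps, function(r)
        median(r$samples[[paste0("xi_", b)]]), 0)), 0),
    p_mean = vapply(branches, function(b)
      mean(vapply(reps, function(r) r$p[b], 0)), 0),
    support_fraction = vapply(branches, function(b)
      mean(vapply(reps, function(r)
        support_statistic(r, b) < support_threshold, TRUE)), 0),
    row.names = NULL)
  list(replicates = reps, summary = summary)
}
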