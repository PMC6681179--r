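# Seeded synthetic-data generator: structured-coalescent genotype tables
# plus a machine-readable truth record.

class_label <- function(modifiers) {
  if ("noM12" %in% modifiers) return("no-mig-into-pop1")
  if ("noM21" %in% modifiers) return("no-mig-into-pop2")
  if ("bf" %in% modifiers) return("reduced-Ne")
  "base"
}

draw_depth <- function(n, mean_depth, cv) {
  if (cv <= 0) return(rep(round(mean_depth), n))
  pmax(0, round(rgamma(n, shape = 1 / cv^2, scale = mean_depth * cv^2)))
}

#' Simulate a two-population data set with known truth
#'
#' Independent loci are generated under the structured coalescent for the
#' epoch schedule of `model` (locus classes drawn according to the `2M2P`
#' and `2N` flags), mutations dropped on branches under the infinite-sites
#' model, and haplotypes paired into diploid genotypes.  The REF allele is
#' the true ancestral allele.  With `outgroup = "fixed_ancestral"` two
#' outgroup individuals homozygous for the ancestral allele are appended,
#' supporting the polarization pipeline.
#'
#' @param model A [demographic_model()] (scaled parameters).
#' @param n1,n2 Diploid sample counts for the two populations.
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param mu Mutation rate per bp per generation.
#' @param seed Integer seed; identical inputs give identical output.
#' @param Nref Reference diploid size used to de-scale the model.
#' @param depth_mean Mean sequencing depth per genotype.
#' @param depth_cv Coefficient of variation of depth (0 for constant).
#' @param outgroup `"none"` or `"fixed_ancestral"`.
#' @param pop_names Labels for the two populations.
#' @param growth_steps Piecewise-constant steps per exponential epoch.
#' @return List with `table` (a [genotype_table()]) and `truth`
#'   (scenario, parameter values in demographic units, per-locus class
#'   assignments, seed).
#' @export
simulate_pair_dataset <- function(model, n1, n2, n_loci, locus_length = 1000,
                                  mu = 2.1e-10, seed = 1, Nref = 1e5,
                                  depth_mean = 12, depth_cv = 0.2,
                                  outgroup = c("none", "fixed_ancestral"),
                                  pop_names = c("pop1", "pop2"),
                                  growth_steps = 24) {
  outgroup <- match.arg(outgroup)
  if (n1 <= 0 || n2 <= 0 || n_loci <= 0)
    stop("sample counts and locus number must be positive")
  theta_half <- 2 * Nref * mu * locus_length
  nh <- 2 * (n1 + n2)
  spop <- c(rep(0L, 2 * n1), rep(1L, 2 * n2))

  with_seed(seed, {
    cls <- model_classes(model)
    w <- vapply(cls, `[[`, 0, "weight")
    assign_cls <- sample.int(length(cls), n_loci, replace = TRUE, prob = w)
    loci <- vector("list", n_loci)
    for (ci in seq_along(cls)) {
      idx <- which(assign_cls == ci)
      if (length(idx) == 0) next
      bk <- backward_epochs(build_epochs(model, c("base", cls[[ci]]$class)),
                            growth_steps)
      res <- sim_loci_cpp(spop, 2L, bk$epoch_end, bk$nu, bk$mig, bk$merges,
                          theta_half, length(idx), 0L, spop)
      loci[idx] <- res$loci
    }

    sites_list <- list()
    gt_list <- list()
    chroms <- sprintf("locus%05d", seq_len(n_loci))
    for (l in seq_len(n_loci)) {
      h <- loci[[l]]
      ns <- min(nrow(h), locus_length)
      if (ns == 0) next
      h <- h[seq_len(ns), , drop = FALSE]
      pos <- sort(sample.int(locus_length, ns))
      sites_list[[length(sites_list) + 1]] <-
        data.frame(chrom = chroms[l], pos = pos,
                   ref = "A", alt = "T", qual = 100,
                   stringsAsFactors = FALSE)
      # pair haplotypes (2s-1, 2s) into diploid dosage
      gt_list[[length(gt_list) + 1]] <-
        h[, seq(1, nh, 2), drop = FALSE] + h[, seq(2, nh, 2), drop = FALSE]
    }
    sites <- do.call(rbind, sites_list)
    gt <- do.call(rbind, gt_list)
    if (is.null(sites)) {
      sites <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric())
      gt <- matrix(integer(), 0, n1 + n2)
    }

    samples <- data.frame(
      sample = c(sprintf("%s_ind%02d", pop_names[1], seq_len(n1)),
                 sprintf("%s_ind%02d", pop_names[2], seq_len(n2))),
      population = c(rep(pop_names[1], n1), rep(pop_names[2], n2)),
      stringsAsFactors = FALSE)
    if (outgroup == "fixed_ancestral") {
      samples <- rbind(samples,
                       data.frame(sample = c("outgroup1", "outgroup2"),
                                  population = "outgroup"))
      gt <- cbind(gt, matrix(0L, nrow(gt), 2))
    }
    dp <- matrix(draw_depth(length(gt), depth_mean, depth_cv), nrow(gt))
    gq <- matrix(99, nrow(gt), ncol(gt))
    chrom_class <- setNames(rep("autosome", n_loci), chroms)
    tab <- genotype_table(sites, gt, dp, gq, samples, chrom_class,
                          ancestral = rep("ref", nrow(sites)))
  })

  pars <- model$params
  demog <- to_demographic_units(pars, Nref)
  truth <- list(scenario = model_name(model),
                parameter_values = as.list(c(pars, Nref = Nref, mu = mu)),
                parameter_values_demographic = as.list(demog),
                locus_class_assignments =
                  vapply(model_classes(model)[assign_cls],
                         function(x) class_label(x$class), ""),
                sex_assignments = NULL, xi = NA_real_, seed = seed)
  list(table = tab, truth = truth)
}

#' Simulate an observed joint SFS with known truth
#'
#' Fast path used for inference experiments: mutations are tallied directly
#' into the joint spectrum (ancestral states known), without constructing
#' genotype tables.  Mis-polarization is applied by flipping each site to
#' its mirrored entry with probability `1 - O`.
#'
#' @param model A [demographic_model()].
#' @param n1,n2 Haploid sample sizes.
#' @param n_loci Number of independent loci.
#' @param theta_locus Population mutation rate `4*Nref*mu*L` per locus.
#' @param seed Integer seed.
#' @param growth_steps Steps per exponential epoch.
#' @return List with `sfs` (a [joint_sfs()]) and `truth`.
#' @export
simulate_joint_sfs <- function(model, n1, n2, n_loci, theta_locus = 1,
                               seed = 1, growth_steps = 24) {
  spop <- c(rep(0L, n1), rep(1L, n2))
  with_seed(seed, {
    cls <- model_classes(model)
    w <- vapply(cls, `[[`, 0, "weight")
    nper <- as.vector(rmultinom(1, n_loci, w))
    counts <- matrix(0, n1 + 1, n2 + 1)
    for (ci in seq_along(cls)) {
      if (nper[ci] == 0) next
      bk <- backward_epochs(build_epochs(model, c("base", cls[[ci]]$class)),
                            growth_steps)
      res <- sim_loci_cpp(spop, 2L, bk$epoch_end, bk$nu, bk$mig, bk$merges,
                          theta_locus / 2, nper[ci], 1L, spop)
      counts <- counts + res$sfs
    }
    O <- unname(model$params["O"])
    if (!is.na(O) && O < 1) {
      flipped <- matrix(rbinom(length(counts), as.vector(counts), 1 - O),
                        nrow(counts))
      counts <- counts - flipped +
        flipped[nrow(counts):1, ncol(counts):1]
    }
  })
  truth <- list(scenario = model_name(model),
                parameter_values = as.list(model$params),
                n_loci = n_loci, theta_locus = theta_locus, seed = seed)
  list(sfs = joint_sfs(counts, polarized = TRUE), truth = truth)
}

#' Simulate autosomal and X-linked loci on a three-leaf population tree
#'
#' Generates a data set for effective-sex-ratio inference: autosomal loci
#' under a three-population coalescent following a rooted tree
#' `((A, B), C)`, and X-linked loci with per-branch effective sizes scaled
#' by `9 / (16 - 8 xi)` (`xi` the female fraction of breeders).  XY
#' individuals carry one X haplotype and half the autosomal depth at X
#' sites; XX individuals carry two and equal depth.
#'
#' @param tree Newick string with three leaves, e.g. `"((CA,GA),EF);"`
#'   (branch lengths, if present, are ignored; times are given below).
#' @param t_split Generations back to the split of the two cherry leaves.
#' @param t_root Generations back to the root.
#' @param Ne Named diploid sizes: one entry per leaf, `"inner"` for the
#'   cherry ancestor and `"anc"` for the root population.
#' @param xi Named female fractions in (0,1): per leaf and `"inner"`
#'   (the root population uses 0.5).
#' @param n_per_leaf Diploid samples per leaf (scalar or named).
#' @param sex_ratio Fraction of XX individuals per leaf sample (default
#'   half, rounded up).
#' @param n_auto_loci,n_x_loci Locus counts for the two marker classes.
#' @param locus_length,mu,depth_mean,depth_cv,seed As in
#'   [simulate_pair_dataset()].
#' @return List with `table`, `depth_report` (per-sample mean depths), and
#'   `truth` (per-branch `tau = t/2Ne`, `xi`, sex assignments, seed).
#' @export
simulate_sex_linked_dataset <- function(tree, t_split, t_root, Ne, xi,
                                        n_per_leaf = 8, sex_ratio = 0.5,
                                        n_auto_loci = 400, n_x_loci = 400,
                                        locus_length = 1000, mu = 2.1e-10,
                                        depth_mean = 12, depth_cv = 0.2,
                                        seed = 1) {
  if (any(xi <= 0 | xi >= 1)) stop("xi must lie strictly inside (0, 1)")
  tr <- ape::read.tree(text = tree)
  if (is.null(tr) || length(tr$tip.label) != 3)
    stop("tree must be a rooted newick topology with exactly 3 leaves")
  # identify the cherry (the two leaves sharing the inner node)
  inner <- setdiff(unique(tr$edge[, 1]), ape::Ntip(tr) + 1)
  cherry <- tr$tip.label[tr$edge[tr$edge[, 1] == inner, 2]]
  outer <- setdiff(tr$tip.label, cherry)
  leaves <- c(cherry, outer) # A, B, C
  if (t_root <= t_split) stop("t_root must exceed t_split")
  need <- c(leaves, "inner", "anc")
  if (!all(need %in% names(Ne)))
    stop("Ne needs entries: ", paste(need, collapse = ", "))
  needx <- c(leaves, "inner")
  if (!all(needx %in% names(xi)))
    stop("xi needs entries: ", paste(needx, collapse = ", "))
  if (length(n_per_leaf) == 1)
    n_per_leaf <- setNames(rep(n_per_leaf, 3), leaves)

  Nref <- unname(Ne["anc"])
  ts <- t_split / (2 * Nref)
  tr_s <- t_root / (2 * Nref)
  theta_half <- 2 * Nref * mu * locus_length
  xratio <- function(x) 9 / (16 - 8 * x)

  # per-epoch scaled sizes for pops (A, B, C); A hosts inner then anc
  nu_auto <- rbind(Ne[leaves] / Nref,
                   c(Ne["inner"] / Nref, 1, Ne[outer] / Nref),
                   c(1, 1, 1))
  nu_x <- rbind(Ne[leaves] * xratio(xi[leaves]) / Nref,
                c(Ne["inner"] * xratio(xi["inner"]) / Nref, 1,
                  Ne[outer] * xratio(xi[outer]) / Nref),
                c(xratio(0.5), 1, 1))
  epoch_end <- c(ts, tr_s, Inf)
  mig <- matrix(0, 3, 9)
  merges <- matrix(c(ts, 1, 0, tr_s, 2, 0), 2, 3, byrow = TRUE)

  with_seed(seed, {
    samples <- do.call(rbind, lapply(leaves, function(lf) {
      n <- n_per_leaf[lf]
      nxx <- ceiling(n * sex_ratio)
      data.frame(sample = sprintf("%s_ind%02d", lf, seq_len(n)),
                 population = lf,
                 sex = c(rep("XX", nxx), rep("XY", n - nxx)),
                 stringsAsFactors = FALSE)
    }))
    popidx <- setNames(0:2, leaves)

    build_tab <- function(n_loci, nu, prefix, x_linked) {
      hap_per <- if (x_linked) ifelse(samples$sex == "XX", 2L, 1L)
                 else rep(2L, nrow(samples))
      spop <- rep.int(popidx[samples$population], hap_per)
      res <- sim_loci_cpp(as.integer(spop), 3L, epoch_end, nu, mig, merges,
                          theta_half, n_loci, 0L, as.integer(spop))
      chroms <- sprintf("%s%05d", prefix, seq_len(n_loci))
      sl <- list(); gl <- list()
      col0 <- cumsum(c(0, hap_per))
      for (l in seq_len(n_loci)) {
        h <- res$loci[[l]]
        ns <- min(nrow(h), locus_length)
        if (ns == 0) next
        h <- h[seq_len(ns), , drop = FALSE]
        g <- matrix(0L, ns, nrow(samples))
        for (s in seq_len(nrow(samples))) {
          cols <- (col0[s] + 1):(col0[s] + hap_per[s])
          gs <- rowSums(h[, cols, drop = FALSE])
          # a hemizygous haplotype is reported as a homozygous diploid call
          if (hap_per[s] == 1) gs <- 2L * gs
          g[, s] <- as.integer(gs)
        }
        sl[[length(sl) + 1]] <- data.frame(
          chrom = chroms[l], pos = sort(sample.int(locus_length, ns)),
          ref = "A", alt = "T", qual = 100, stringsAsFactors = FALSE)
        gl[[length(gl) + 1]] <- g
      }
      sites <- do.call(rbind, sl)
      if (is.null(sites))
        sites <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            qual = numeric())
      gt <- do.call(rbind, gl)
      if (is.null(gt)) gt <- matrix(0L, 0, nrow(samples))
      list(sites = sites, gt = gt, chroms = chroms)
    }

    auto <- build_tab(n_auto_loci, nu_auto, "auto", FALSE)
    xl <- build_tab(n_x_loci, nu_x, "x", TRUE)
    sites <- rbind(auto$sites, xl$sites)
    gt <- rbind(auto$gt, xl$gt)
    mean_auto <- rep(depth_mean, nrow(samples))
    mean_x <- ifelse(samples$sex == "XY", depth_mean / 2, depth_mean)
    na <- nrow(auto$sites)
    dp <- matrix(0, nrow(gt), nrow(samples))
    for (s in seq_len(nrow(samples))) {
      dp[seq_len(na), s] <- draw_depth(na, mean_auto[s], depth_cv)
      if (nrow(gt) > na)
        dp[(na + 1):nrow(gt), s] <- draw_depth(nrow(gt) - na, mean_x[s],
                                               depth_cv)
    }
    gq <- matrix(99, nrow(gt), ncol(gt))
    chrom_class <- setNames(c(rep("autosome", n_auto_loci),
                              rep("X", n_x_loci)),
                            c(auto$chroms, xl$chroms))
    tab <- genotype_table(sites, gt, dp, gq,
                          samples[, c("sample", "population")],
                          chrom_class, ancestral = rep("ref", nrow(sites)))
  })

  tau <- c(t_split / (2 * Ne[leaves[1]]), t_split / (2 * Ne[leaves[2]]),
           t_root / (2 * Ne[outer]),
           (t_root - t_split) / (2 * Ne["inner"]))
  names(tau) <- c(leaves, "inner")
  truth <- list(tree = tree, leaves = leaves,
                tau_autosomal = as.list(tau), xi = as.list(xi[needx]),
                ne_x_over_ne_a = as.list(xratio(xi[needx])),
                sex_assignments = setNames(samples$sex, samples$sample),
                t_split = t_split, t_root = t_root, seed = seed)
  depth_report <- data.frame(sample = samples$sample, sex = samples$sex,
                             mean_auto = mean_auto, mean_x = mean_x)
  list(table = tab, depth_report = depth_report, truth = truth)
}

#' Simulate neutral windows from one panmictic population
#'
#' Each window is one chromosome of a constant-size population.
#' Recombination is approximated by Poisson-distributed breakpoints with
#' independent genealogies between the resulting blocks and none within
#' (the expected breakpoint count is `rho * L * a` with `a` the harmonic
#' number of the sample size); `rho = 0` gives single-genealogy windows.
#'
#' @param n_samples Diploid sample count.
#' @param n_windows Number of windows.
#' @param window_length Window length in bp.
#' @param mu Mutation rate per bp per generation.
#' @param Nref Diploid effective size.
#' @param rho_per_bp Population recombination rate 4*Ne*r per bp; scalar or
#'   one value per window.
#' @param seed Integer seed.
#' @param depth_mean,depth_cv Depth model.
#' @return List with `table`, `windows` (0-based half-open), `rho`
#'   (chrom, start, end, rho), and `truth`.
#' @export
simulate_neutral_windows <- function(n_samples, n_windows, window_length,
                                     mu = 1e-8, Nref = 2.5e4,
                                     rho_per_bp = 0, seed = 1,
                                     depth_mean = 12, depth_cv = 0.2) {
  nh <- 2 * n_samples
  if (length(rho_per_bp) == 1) rho_per_bp <- rep(rho_per_bp, n_windows)
  stopifnot(length(rho_per_bp) == n_windows)
  theta_half_bp <- 2 * Nref * mu
  a_n <- sum(1 / seq_len(nh - 1))
  spop <- rep(0L, nh)
  epoch_end <- Inf
  nu <- matrix(1, 1, 1)
  mig <- matrix(0, 1, 1)
  merges <- matrix(0, 0, 3)
  chroms <- sprintf("win%05d", seq_len(n_windows))

  with_seed(seed, {
    sl <- list(); gl <- list()
    for (wi in seq_len(n_windows)) {
      nbreak <- rpois(1, rho_per_bp[wi] * window_length * a_n / 2)
      cuts <- sort(sample.int(window_length - 1, min(nbreak,
                                                     window_length - 1)))
      bounds <- c(0, cuts, window_length)
      pos_all <- c(); gt_all <- NULL
      for (b in seq_len(length(bounds) - 1)) {
        L <- bounds[b + 1] - bounds[b]
        res <- sim_loci_cpp(spop, 1L, epoch_end, nu, mig, merges,
                            theta_half_bp * L, 1L, 0L, spop)
        h <- res$loci[[1]]
        ns <- min(nrow(h), L)
        if (ns == 0) next
        h <- h[seq_len(ns), , drop = FALSE]
        pos <- bounds[b] + sort(sample.int(L, ns))
        g <- h[, seq(1, nh, 2), drop = FALSE] +
          h[, seq(2, nh, 2), drop = FALSE]
        pos_all <- c(pos_all, pos)
        gt_all <- rbind(gt_all, g)
      }
      if (length(pos_all) == 0) next
      sl[[length(sl) + 1]] <- data.frame(
        chrom = chroms[wi], pos = pos_all, ref = "A", alt = "T",
        qual = 100, stringsAsFactors = FALSE)
      gl[[length(gl) + 1]] <- gt_all
    }
    sites <- do.call(rbind, sl)
    gt <- do.call(rbind, gl)
    samples <- data.frame(sample = sprintf("ind%02d", seq_len(n_samples)),
                          population = "pop", stringsAsFactors = FALSE)
    dp <- matrix(draw_depth(length(gt), depth_mean, depth_cv), nrow(gt))
    gq <- matrix(99, nrow(gt), ncol(gt))
    tab <- genotype_table(sites, gt, dp, gq, samples,
                          setNames(rep("autosome", n_windows), chroms),
                          ancestral = rep("ref", nrow(sites)))
  })

  windows <- data.frame(chrom = chroms, start = 0, end = window_length)
  rho <- data.frame(chrom = chroms, start = 0, end = window_length,
                    rho = rho_per_bp)
  truth <- list(Nref = Nref, mu = mu, theta_per_bp = 4 * Nref * mu,
                rho_per_bp = rho_per_bp, seed = seed)
  list(table = tab, windows = windows, rho = rho, truth = truth)
}

#' Write simulation truth as JSON
#' @param truth Truth record from a simulator function.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write sample metadata (sample, population, sex) as TSV
#' @param samples Data frame with at least `sample` and `population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a windowed recombination-rate table as TSV
#' @param rho Data frame `chrom`, `start`, `end`, `rho` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rho_tsv <- function(rho, path) {
  write.table(rho, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mask intervals as BED (0-based half-open, no header)
#' @param mask Data frame `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  write.table(mask[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read mask intervals from BED
#' @param path BED file (first three columns used).
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = b[[2]], end = b[[3]])
}
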