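# Monte-Carlo coalescent engine and the forward->backward epoch conversion
# shared with the simulator.

# Convert a forward ps_epochs schedule (oldest first) into the backward
# representation used by the coalescent core: epoch end times measured from
# the present, per-epoch sizes and backward migration rates, and the merge
# of population 2 into population 1 at the split time.  Exponential-growth
# epochs are discretized into `growth_steps` geometric piecewise-constant
# steps.
backward_epochs <- function(epochs, growth_steps = 24) {
  ends <- c()
  nus <- c()
  migs <- c()
  t <- 0
  for (r in rev(seq_len(nrow(epochs)))) {
    e <- epochs[r, ]
    growing <- (e$nu1_start != e$nu1_end) || (e$nu2_start != e$nu2_end)
    steps <- if (growing) growth_steps else 1
    for (s in seq_len(steps)) {
      f <- 1 - (s - 0.5) / steps # forward fraction at backward sub-step midpoint
      nu1 <- e$nu1_start * (e$nu1_end / e$nu1_start)^f
      nu2 <- e$nu2_start * (e$nu2_end / e$nu2_start)^f
      t <- t + e$duration / steps
      ends <- c(ends, t)
      nus <- rbind(nus, c(nu1, nu2))
      # backward: a lineage in pop 1 jumps to pop 2 at the rate of forward
      # migration into pop 1 (M12), and vice versa
      migs <- rbind(migs, c(0, e$M12, e$M21, 0))
    }
  }
  T_split <- t
  ends <- c(ends, Inf)
  nus <- rbind(nus, c(attr(epochs, "nu_anc"), 1))
  migs <- rbind(migs, c(0, 0, 0, 0))
  list(epoch_end = ends, nu = nus, mig = migs,
       merges = matrix(c(T_split, 1, 0), 1, 3), T_split = T_split)
}

# Monte-Carlo expected SFS for one epoch schedule: mean branch length
# subtending (i, j) descendants, times theta/2 with theta = 1.
mc_expected_sfs <- function(epochs, n1, n2, n_loci = 20000, seed = 1,
                            growth_steps = 24) {
  bk <- backward_epochs(epochs, growth_steps)
  spop <- c(rep(0L, n1), rep(1L, n2))
  with_seed(seed, {
    res <- sim_loci_cpp(spop, 2L, bk$epoch_end, bk$nu, bk$mig, bk$merges,
                        0, as.integer(n_loci), 2L, spop)
  })
  mean_b <- res$sum / res$n
  var_b <- pmax(res$sumsq / res$n - mean_b^2, 0)
  M <- 0.5 * mean_b
  attr(M, "se") <- 0.5 * sqrt(var_b / res$n)
  M
}
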