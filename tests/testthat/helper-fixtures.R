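# Small in-code fixtures shared across tests.

# genotype table built directly from matrices
toy_table <- function(gt, chrom = NULL, pos = NULL, pops = NULL,
                      dp = NULL, gq = NULL, cls = NULL, qual = 100,
                      ancestral = NULL) {
  S <- nrow(gt); N <- ncol(gt)
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 10
  if (is.null(pops)) pops <- rep("pop1", N)
  samples <- data.frame(sample = sprintf("s%02d", seq_len(N)),
                        population = pops, stringsAsFactors = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      qual = qual, stringsAsFactors = FALSE)
  if (is.null(cls))
    cls <- setNames(rep("autosome", length(unique(chrom))), unique(chrom))
  genotype_table(sites, gt, dp, gq, samples, cls, ancestral = ancestral)
}

# brute-force pairwise statistics on haplotype/genotype matrices; used as
# independent oracles for the windowed estimators
brute_pi_sum <- function(d, n) {
  # d: derived counts per site; enumerate haplotype pairs
  sum(vapply(d, function(di) {
    diff <- di * (n - di) # ordered pairs differing
    diff / choose(n, 2) / 2 * 1 # unordered pairs: di*(n-di)/C(n,2)... keep simple
  }, 0))
}

# random dosage matrix with optional missingness
random_gt <- function(S, N, miss = 0) {
  g <- matrix(sample(0:2, S * N, replace = TRUE), S, N)
  if (miss > 0) g[runif(S * N) < miss] <- NA
  g
}

# a quick SC model used in several demography tests
quick_sc_model <- function()
  demographic_model("SC", c(nu1 = 1, nu2 = 3, M12 = 4, M21 = 1.5,
                            t_iso = 0.4, t_sc = 0.2, O = 0.97))
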