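# Expected joint SFS via the moment closure of the two-population diffusion.
#
# The expected unfolded SFS entries Phi_n(i) = E[ C(n,i) x^i (1-x)^(n-i) ]
# evolve under linear ODEs.  Genetic drift is closed at sample size n (a
# tridiagonal operator per population axis); migration couples to the SFS at
# sample size (n1-1, n2+1) (resp. (n1+1, n2-1)), which is obtained by an
# exact hypergeometric down-projection on one axis and a quadratic-jackknife
# up-closure on the other.  New mutations enter as a constant source at the
# per-population singleton entries.  Each constant-rate epoch is propagated
# with a matrix exponential of the affine system; exponential-growth epochs
# are discretized into geometric piecewise-constant steps.
#
# Time is measured in units of 2*Nref generations, sizes relative to Nref,
# and the overall theta scale is arbitrary (profiled out of the composite
# likelihood).

.ps_cache <- new.env(parent = emptyenv())

# closed drift operator at sample size n (acts on entries 0..n)
drift_tridiag <- function(n) {
  T <- matrix(0, n + 1, n + 1)
  for (i in 0:n) {
    if (i >= 1) T[i + 1, i] <- (i - 1) * (n - i + 1)
    T[i + 1, i + 1] <- -2 * i * (n - i)
    if (i <= n - 1) T[i + 1, i + 2] <- (i + 1) * (n - i - 1)
  }
  T
}

# exact projection from sample size n to n-1 (rows 0..n-1, cols 0..n)
proj_down <- function(n) {
  P <- matrix(0, n, n + 1)
  for (a in 0:(n - 1)) {
    P[a + 1, a + 1] <- (n - a) / n
    P[a + 1, a + 2] <- (a + 1) / n
  }
  P
}

# quadratic-jackknife extrapolation from sample size n to n+1
# (rows 0..n+1, cols 0..n); exact for underlying densities that are
# polynomials of degree <= 2
jack_up <- function(n) {
  if (n < 2) stop("jackknife closure needs sample size >= 2")
  m <- function(nn, k, p) {
    if (p == 0) return(1 / (nn + 1))
    if (p == 1) return((k + 1) / ((nn + 1) * (nn + 2)))
    (k + 1) * (k + 2) / ((nn + 1) * (nn + 2) * (nn + 3))
  }
  J <- matrix(0, n + 2, n + 1)
  for (l in 0:(n + 1)) {
    k0 <- min(max(round(l * n / (n + 1)) - 1, 0), n - 2)
    A <- matrix(0, 3, 3)
    b <- numeric(3)
    for (p in 0:2) {
      for (s in 0:2) A[p + 1, s + 1] <- m(n, k0 + s, p)
      b[p + 1] <- m(n + 1, l, p)
    }
    J[l + 1, k0 + (1:3)] <- solve(A, b)
  }
  J
}

# operator pieces for a given (n1, n2), cached
sfs_operators <- function(n1, n2) {
  key <- paste0("ops_", n1, "_", n2)
  if (!is.null(.ps_cache[[key]])) return(.ps_cache[[key]])
  K <- (n1 + 1) * (n2 + 1)
  idx <- function(i, j) i + (n1 + 1) * j + 1

  D1 <- kronecker(diag(n2 + 1), drift_tridiag(n1))
  D2 <- kronecker(drift_tridiag(n2), diag(n1 + 1))

  # migration into population 1 (rate M12):
  # d Phi(i,j) += M12 [ n1 (j+1)/(n2+1) (Psi(i-1,j+1) - Psi(i,j+1))
  #                     - i Phi(i,j) + (i+1) Phi(i+1,j) ]
  # with Psi the SFS at sizes (n1-1, n2+1)
  P1 <- proj_down(n1); J2 <- jack_up(n2)
  pidx <- function(a, b) a + n1 * b + 1 # Psi dims n1 x (n2+2)
  Sa <- matrix(0, K, n1 * (n2 + 2))
  Sb <- matrix(0, K, K)
  for (j in 0:n2) for (i in 0:n1) {
    cc <- n1 * (j + 1) / (n2 + 1)
    if (i >= 1) Sa[idx(i, j), pidx(i - 1, j + 1)] <-
        Sa[idx(i, j), pidx(i - 1, j + 1)] + cc
    if (i <= n1 - 1) Sa[idx(i, j), pidx(i, j + 1)] <-
        Sa[idx(i, j), pidx(i, j + 1)] - cc
    Sb[idx(i, j), idx(i, j)] <- Sb[idx(i, j), idx(i, j)] - i
    if (i < n1) Sb[idx(i, j), idx(i + 1, j)] <-
        Sb[idx(i, j), idx(i + 1, j)] + (i + 1)
  }
  A12 <- Sa %*% kronecker(J2, P1) + Sb

  # migration into population 2 (rate M21), mirror image
  P2 <- proj_down(n2); J1 <- jack_up(n1)
  qidx <- function(a, b) a + (n1 + 2) * b + 1 # Psi' dims (n1+2) x n2
  Sa2 <- matrix(0, K, (n1 + 2) * n2)
  Sb2 <- matrix(0, K, K)
  for (j in 0:n2) for (i in 0:n1) {
    cc <- n2 * (i + 1) / (n1 + 1)
    if (j >= 1) Sa2[idx(i, j), qidx(i + 1, j - 1)] <-
        Sa2[idx(i, j), qidx(i + 1, j - 1)] + cc
    if (j <= n2 - 1) Sa2[idx(i, j), qidx(i + 1, j)] <-
        Sa2[idx(i, j), qidx(i + 1, j)] - cc
    Sb2[idx(i, j), idx(i, j)] <- Sb2[idx(i, j), idx(i, j)] - j
    if (j < n2) Sb2[idx(i, j), idx(i, j + 1)] <-
        Sb2[idx(i, j), idx(i, j + 1)] + (j + 1)
  }
  A21 <- Sa2 %*% kronecker(P2, J1) + Sb2

  B <- numeric(K)
  B[idx(1, 0)] <- n1 / 2
  B[idx(0, 1)] <- n2 / 2

  out <- list(D1 = D1, D2 = D2, A12 = A12, A21 = A21, B = B, K = K)
  .ps_cache[[key]] <- out
  out
}

#' Single-population equilibrium SFS
#'
#' Solves the steady state of the drift-mutation moment system for a
#' constant-size population: the balance of the closed tridiagonal drift
#' operator against the singleton mutation source.  For a constant size the
#' classical result is entries proportional to 1/i.
#'
#' @param n Haploid sample size.
#' @param nu Population size relative to the reference.
#' @return Numeric vector of expected entries at derived counts `0..n`
#'   (entries 0 and n are 0: monomorphic classes carry no expectation).
#' @export
equilibrium_sfs_single <- function(n, nu = 1) {
  T <- drift_tridiag(n)
  interior <- 2:n # derived counts 1..n-1
  A <- T[interior, interior, drop = FALSE] / (2 * nu)
  B <- numeric(n - 1)
  B[1] <- n / 2
  phi <- solve(A, -B)
  c(0, phi, 0)
}

# joint SFS right after the split from an ancestral equilibrium
split_joint <- function(n1, n2, nu_anc = 1) {
  n <- n1 + n2
  anc <- equilibrium_sfs_single(n, nu_anc)
  M <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    k <- i + j
    if (k == 0 || k == n) next
    M[i + 1, j + 1] <- anc[k + 1] * choose(n1, i) * choose(n2, j) / choose(n, k)
  }
  M
}

# propagate the affine system dPhi/dt = A Phi + B over duration d
propagate <- function(phi, A, B, d) {
  K <- length(phi)
  Atil <- rbind(cbind(A, B), 0)
  out <- as.matrix(Matrix::expm(Matrix::Matrix(Atil * d))) %*% c(phi, 1)
  out[seq_len(K)]
}

# integrate a ps_epochs schedule for sample sizes (n1, n2); the fixed
# corners are boundary atoms, not density, and are excluded from the
# dynamics (they would otherwise leak through the jackknife closure)
integrate_epochs <- function(epochs, n1, n2, growth_steps = 24) {
  ops <- sfs_operators(n1, n2)
  phi <- as.vector(split_joint(n1, n2, attr(epochs, "nu_anc")))
  corner <- c(1, (n1 + 1) * (n2 + 1))
  for (r in seq_len(nrow(epochs))) {
    e <- epochs[r, ]
    growing <- (e$nu1_start != e$nu1_end) || (e$nu2_start != e$nu2_end)
    steps <- if (growing) growth_steps else 1
    for (s in seq_len(steps)) {
      f <- (s - 0.5) / steps
      nu1 <- e$nu1_start * (e$nu1_end / e$nu1_start)^f
      nu2 <- e$nu2_start * (e$nu2_end / e$nu2_start)^f
      A <- ops$D1 / (2 * nu1) + ops$D2 / (2 * nu2) +
        e$M12 * ops$A12 + e$M21 * ops$A21
      A[, corner] <- 0
      A[corner, ] <- 0
      phi <- propagate(phi, A, ops$B, e$duration / steps)
    }
  }
  matrix(phi, n1 + 1, n2 + 1)
}

#' Hypergeometric projection of a joint SFS to smaller sample sizes
#'
#' Exact expected down-sampling: entry `(i, j)` at the smaller sizes is the
#' hypergeometric average over the original entries, per axis.
#'
#' @param sfs A [joint_sfs()] or plain matrix.
#' @param n1,n2 Target haploid sample sizes (at most the current ones).
#' @return Same type as the input, at the reduced sizes.
#' @export
sfs_project <- function(sfs, n1, n2) {
  M <- if (inherits(sfs, "ps_jsfs")) sfs$counts else as.matrix(sfs)
  N1 <- nrow(M) - 1; N2 <- ncol(M) - 1
  if (n1 > N1 || n2 > N2) stop("can only project to smaller sample sizes")
  P1 <- outer(0:n1, 0:N1, function(i, I) dhyper(i, I, N1 - I, n1))
  P2 <- outer(0:n2, 0:N2, function(j, J) dhyper(j, J, N2 - J, n2))
  out <- P1 %*% M %*% t(P2)
  if (inherits(sfs, "ps_jsfs"))
    joint_sfs(out, polarized = sfs$polarized, validate = FALSE)
  else out
}

#' Mis-polarization transform
#'
#' Mixes an unfolded expected (or observed) spectrum with its
#' derived/ancestral-reversed image: `M' = O * M + (1 - O) * reverse(M)`,
#' where `reverse` flips both axes (`i -> n1 - i`, `j -> n2 - j`).  `O` is
#' the fraction of sites whose ancestral state was correctly inferred.
#'
#' @param sfs A [joint_sfs()] object or a plain matrix.
#' @param O Fraction correctly polarized, in (0.5, 1].
#' @return Same type as the input.
#' @export
apply_misid <- function(sfs, O) {
  if (O <= 0.5 || O > 1) stop("O must be in (0.5, 1]")
  if (inherits(sfs, "ps_jsfs")) {
    if (!sfs$polarized) stop("mis-polarization applies to unfolded spectra only")
    sfs$counts <- O * sfs$counts + (1 - O) * sfs$counts[nrow(sfs$counts):1,
                                                        ncol(sfs$counts):1]
    return(sfs)
  }
  O * sfs + (1 - O) * sfs[nrow(sfs):1, ncol(sfs):1, drop = FALSE]
}

#' Expected joint SFS under a demographic model
#'
#' Computes the expected unfolded joint spectrum (up to a multiplicative
#' theta constant) for haploid sample sizes `n1`, `n2`.  Locus-class flags
#' expand into weighted mixtures: under `2M2P` the three classes
#' (`1-P1-P2`, `P1`, `P2`) with migration into population 1 (resp. 2)
#' zeroed; under `2N` the classes (`1-nr`, `nr`) with all sizes multiplied
#' by `bf`.  Mis-polarization (parameter `O`) is applied last.
#'
#' Two engines are available: `"exact"`, deterministic integration of the
#' moment system (recommended for `n <= 8` per population), and `"mc"`, a
#' Monte-Carlo coalescent average of branch lengths subtending each entry
#' (any sample size; returns a Monte-Carlo standard error as attribute
#' `"se"`).
#'
#' @param model A [demographic_model()].
#' @param n1,n2 Haploid sample sizes.
#' @param engine `"exact"` or `"mc"`.
#' @param mc_loci Number of genealogies for the Monte-Carlo engine.
#' @param seed Seed for the Monte-Carlo engine.
#' @param growth_steps Piecewise-constant steps per exponential epoch.
#' @param pad Internal oversampling of the exact engine: the moment system
#'   is integrated at sizes `(n1 + pad, n2 + pad)` and projected down
#'   exactly, which shrinks the jackknife closure error of the migration
#'   terms.  The default pads the larger sample size up to 12.
#' @return A [joint_sfs()] with real-valued expectation entries.
#' @export
expected_sfs <- function(model, n1, n2, engine = c("exact", "mc"),
                         mc_loci = 20000, seed = 1, growth_steps = 24,
                         pad = NULL) {
  engine <- match.arg(engine)
  if (is.null(pad)) pad <- max(0, 12 - max(n1, n2))
  if (engine == "exact" && (n1 > 8 || n2 > 8) )
    stop("exact engine supports up to 8 haploid samples per population; use engine = 'mc'")
  cls <- model_classes(model)
  M <- matrix(0, n1 + 1, n2 + 1)
  se2 <- matrix(0, n1 + 1, n2 + 1)
  for (ci in seq_along(cls)) {
    epochs <- build_epochs(model, cls[[ci]]$class)
    if (engine == "exact") {
      Mi <- integrate_epochs(epochs, n1 + pad, n2 + pad, growth_steps)
      Mi <- sfs_project(Mi, n1, n2)
    } else {
      Mi <- mc_expected_sfs(epochs, n1, n2, mc_loci,
                            seed = seed + 1000 * ci,
                            growth_steps = growth_steps)
      se2 <- se2 + (cls[[ci]]$weight * attr(Mi, "se"))^2
    }
    M <- M + cls[[ci]]$weight * unclass(Mi)
  }
  O <- unname(model$params["O"])
  M <- apply_misid(M, O)
  M <- pmax(M, 1e-12)
  out <- joint_sfs(M, polarized = TRUE, validate = FALSE)
  if (engine == "mc") {
    rev2 <- se2[nrow(se2):1, ncol(se2):1]
    attr(out, "se") <- sqrt(O^2 * se2 + (1 - O)^2 * rev2)
  }
  out
}
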