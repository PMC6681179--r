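#' Joint site frequency spectrum
#'
#' Container for a two-population (joint) SFS: an `(n1+1) x (n2+1)`
#' non-negative array indexed by derived-copy counts, a polarization flag,
#' and a boolean mask.  The fixed corners `(0, 0)` and `(n1, n2)` are masked
#' by default and excluded from totals and likelihoods.
#'
#' @param counts Numeric `(n1+1) x (n2+1)` matrix.
#' @param polarized Logical; `TRUE` for an unfolded spectrum.
#' @param mask Logical matrix of the same shape; `TRUE` entries are masked.
#'   Defaults to masking the two fixed corners.
#' @param validate Check non-negativity (disable for real-valued
#'   expectations that may carry rounding noise).
#' @return Object of class `ps_jsfs` with fields `counts`, `n1`, `n2`,
#'   `polarized`, `mask`.
#' @export
joint_sfs <- function(counts, polarized = TRUE, mask = NULL, validate = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n1 <- nrow(counts) - 1
  n2 <- ncol(counts) - 1
  if (validate && any(counts < 0)) stop("SFS counts must be non-negative")
  if (is.null(mask)) {
    mask <- matrix(FALSE, n1 + 1, n2 + 1)
    mask[1, 1] <- TRUE
    mask[n1 + 1, n2 + 1] <- TRUE
  }
  structure(list(counts = counts, n1 = n1, n2 = n2, polarized = polarized,
                 mask = mask),
            class = "ps_jsfs")
}

#' @export
print.ps_jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS (%d x %d haploid), %s, %g segregating\n",
              x$n1, x$n2, if (x$polarized) "unfolded" else "folded",
              sfs_total(x)))
  invisible(x)
}

#' Total unmasked count of a joint SFS
#' @param sfs A [joint_sfs()].
#' @return Sum of the unmasked entries.
#' @export
sfs_total <- function(sfs) sum(sfs$counts[!sfs$mask])

#' Build the joint SFS from polarized sites
#'
#' Entry `(i, j)` counts the sites with `i` derived copies in `pop1` and `j`
#' in `pop2`.  With `require_complete` (the default), sites with any missing
#' genotype in either population are skipped, so every tallied site carries
#' the full `n1` (resp. `n2`) allele copies.
#'
#' @param polarized_sites Data frame from [polarize_sites()].
#' @param pop1,pop2 Population labels (columns of the polarization table).
#' @param n1,n2 Haploid sample sizes of the two populations.
#' @param require_complete Skip sites with missing genotypes.
#' @return A [joint_sfs()].
#' @export
build_joint_sfs <- function(polarized_sites, pop1, pop2, n1, n2,
                            require_complete = TRUE) {
  ps <- polarized_sites[polarized_sites$usable, , drop = FALSE]
  d1 <- ps[[paste0("derived_", pop1)]]
  d2 <- ps[[paste0("derived_", pop2)]]
  c1 <- ps[[paste0("copies_", pop1)]]
  c2 <- ps[[paste0("copies_", pop2)]]
  if (is.null(d1) || is.null(d2))
    stop("polarization table lacks counts for the requested populations")
  if (require_complete) {
    keep <- c1 == n1 & c2 == n2
    ps <- ps[keep, , drop = FALSE]
    d1 <- d1[keep]; d2 <- d2[keep]
  }
  if (any(d1 > n1) || any(d2 > n2))
    stop("derived count exceeds haploid sample size")
  counts <- matrix(0, n1 + 1, n2 + 1)
  if (length(d1) > 0)
    for (k in seq_along(d1))
      counts[d1[k] + 1, d2[k] + 1] <- counts[d1[k] + 1, d2[k] + 1] + 1
  joint_sfs(counts, polarized = TRUE)
}

#' Fold a joint SFS
#'
#' Merges entry `(i, j)` with its derived/ancestral mirror
#' `(n1 - i, n2 - j)`; the merged mass is stored at the member of the pair
#' with the smaller minor-allele total (ties broken lexicographically) and
#' the mirror cell is masked.  The unmasked total is preserved.
#'
#' @param sfs An unfolded [joint_sfs()].
#' @return A folded [joint_sfs()] (`polarized = FALSE`).
#' @export
fold <- function(sfs) {
  if (!inherits(sfs, "ps_jsfs")) stop("expected a joint_sfs object")
  if (!sfs$polarized) stop("spectrum is already folded")
  n1 <- sfs$n1; n2 <- sfs$n2
  counts <- matrix(0, n1 + 1, n2 + 1)
  mask <- sfs$mask
  for (i in 0:n1) for (j in 0:n2) {
    ii <- n1 - i; jj <- n2 - j
    keep <- (i + j < ii + jj) || (i + j == ii + jj && (i < ii ||
              (i == ii && j <= jj)))
    if (!keep) { mask[i + 1, j + 1] <- TRUE; next }
    v <- sfs$counts[i + 1, j + 1]
    if (!(i == ii && j == jj)) v <- v + sfs$counts[ii + 1, jj + 1]
    counts[i + 1, j + 1] <- v
  }
  # both fixed corners fold onto (0,0); keep it masked
  mask[1, 1] <- TRUE
  joint_sfs(counts, polarized = FALSE, mask = mask)
}

#' Multinomial bootstrap of a joint SFS
#'
#' Each replicate redraws the `S` unmasked sites multinomially with
#' probabilities proportional to the observed entries, so every replicate
#' has the same total `S`.
#'
#' @param sfs A [joint_sfs()] with positive unmasked total.
#' @param n_replicates Number of pseudo-observed data sets.
#' @param seed Integer seed.
#' @return List of [joint_sfs()] replicates.
#' @export
bootstrap_sfs <- function(sfs, n_replicates = 100, seed = NULL) {
  S <- sfs_total(sfs)
  if (S <= 0) stop("cannot bootstrap an empty SFS")
  un <- !sfs$mask
  pr <- sfs$counts[un] / S
  with_seed(seed, {
    draws <- rmultinom(n_replicates, size = S, prob = pr)
  })
  lapply(seq_len(n_replicates), function(r) {
    m <- matrix(0, sfs$n1 + 1, sfs$n2 + 1)
    m[un] <- draws[, r]
    joint_sfs(m, polarized = sfs$polarized, mask = sfs$mask)
  })
}

#' Read and write a joint SFS as TSV
#'
#' The serialization is a tab-separated count matrix preceded by a two-line
#' header holding the haploid sample sizes, the polarization flag, and the
#' flattened mask; files round-trip exactly.
#'
#' @param sfs A [joint_sfs()].
#' @param path File path.
#' @return `write_sfs()` returns `path` invisibly; `read_sfs()` a
#'   [joint_sfs()].
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n1=%d\tn2=%d\tpolarized=%d", sfs$n1, sfs$n2,
                     as.integer(sfs$polarized)), con)
  writeLines(paste0("#mask=", paste(as.integer(sfs$mask), collapse = "")),
             con)
  write.table(sfs$counts, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  hdr <- readLines(path, n = 2)
  kv <- strsplit(sub("^#", "", hdr[1]), "\t")[[1]]
  vals <- setNames(vapply(strsplit(kv, "="), `[`, "", 2),
                   vapply(strsplit(kv, "="), `[`, "", 1))
  n1 <- as.integer(vals["n1"]); n2 <- as.integer(vals["n2"])
  pol <- as.integer(vals["polarized"]) == 1
  maskbits <- as.integer(strsplit(sub("^#mask=", "", hdr[2]), "")[[1]])
  mask <- matrix(maskbits == 1, n1 + 1, n2 + 1)
  counts <- as.matrix(read.table(path, sep = "\t", skip = 2))
  dimnames(counts) <- NULL
  joint_sfs(counts, polarized = pol, mask = mask)
}
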