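# Windowed population-genetic statistics for linked-selection scans.
# Windows are 0-based half-open; sites are assigned by (position - 1) in
# [start, end).  Windowed estimators use complete genotypes only.

#' Non-overlapping windows over chromosomes
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param size Window size (bp); a trailing partial window is kept.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, size) {
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, chrom_lengths[[ch]]))
  })
  do.call(rbind, out)
}

#' Remove windows overlapping mask intervals
#'
#' A window is dropped entirely when it intersects any mask interval on the
#' same chromosome (both in 0-based half-open coordinates).
#'
#' @param windows Window data frame.
#' @param mask Data frame `chrom`, `start`, `end` (e.g. from
#'   [read_mask_bed()]).
#' @return Filtered window data frame.
#' @export
apply_mask <- function(windows, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(windows)
  keep <- vapply(seq_len(nrow(windows)), function(i) {
    m <- mask[mask$chrom == windows$chrom[i], , drop = FALSE]
    !any(m$start < windows$end[i] & m$end > windows$start[i])
  }, TRUE)
  windows[keep, , drop = FALSE]
}

# indices of table sites falling in a window
sites_in_window <- function(table, w) {
  which(table$sites$chrom == w$chrom &
          table$sites$pos - 1 >= w$start & table$sites$pos - 1 < w$end)
}

# complete-genotype dosage matrix for a population (sites x samples)
pop_dosage <- function(table, population) {
  sm <- table$samples$sample[table$samples$population == population]
  table$gt[, sm, drop = FALSE]
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity and Tajima's D per window
#'
#' theta-pi is the mean number of pairwise differences per bp
#' (`sum over sites of 2 d (n - d) / (n (n - 1))`, divided by window
#' length); Tajima's D uses the classical constants with `S` the count of
#' segregating sites.  Only sites with complete genotypes in the focal
#' population enter (`n` = twice the population sample count).  Windows
#' without segregating sites have `theta_pi = 0` and `D = NA`.
#'
#' @param table A [genotype_table()].
#' @param windows Window data frame.
#' @param population Focal population label.
#' @return Data frame: windows plus `n_sites`, `S`, `theta_pi`, `tajima_d`.
#' @export
diversity_and_d <- function(table, windows, population) {
  g <- pop_dosage(table, population)
  n <- 2 * ncol(g)
  cst <- tajima_constants(n)
  complete <- rowSums(is.na(g)) == 0
  d <- rowSums(g)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- sites_in_window(table, w)
    idx <- idx[complete[idx]]
    dd <- d[idx]
    seg <- dd > 0 & dd < n
    S <- sum(seg)
    pi_sum <- sum(2 * dd * (n - dd) / (n * (n - 1)))
    L <- w$end - w$start
    D <- if (S == 0) NA_real_ else
      (pi_sum - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    data.frame(n_sites = length(idx), S = S, theta_pi = pi_sum / L,
               tajima_d = D)
  })
  cbind(windows, do.call(rbind, res))
}

# per-site within/between heterozygosity sums for a population pair
pair_site_terms <- function(table, popA, popB) {
  ga <- pop_dosage(table, popA)
  gb <- pop_dosage(table, popB)
  nA <- 2 * ncol(ga); nB <- 2 * ncol(gb)
  ok <- rowSums(is.na(ga)) == 0 & rowSums(is.na(gb)) == 0
  dA <- rowSums(ga); dB <- rowSums(gb)
  pA <- dA / nA; pB <- dB / nB
  hA <- 2 * dA * (nA - dA) / (nA * (nA - 1))
  hB <- 2 * dB * (nB - dB) / (nB * (nB - 1))
  list(ok = ok, hw = (hA + hB) / 2, hb = pA * (1 - pB) + pB * (1 - pA))
}

#' Hudson's F_ST per window
#'
#' `F_ST = 1 - Hw / Hb` with `Hw` the mean within-population
#' heterozygosity (unbiased, pairs without replacement) and `Hb` the
#' between-population heterozygosity, combined over windows as the ratio
#' of sums.  Windows with `Hb = 0` are `NA`.
#'
#' @param table A [genotype_table()].
#' @param windows Window data frame.
#' @param popA,popB Population labels.
#' @return Data frame: windows plus `n_sites` and `fst`.
#' @export
fst <- function(table, windows, popA, popB) {
  tm <- pair_site_terms(table, popA, popB)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- sites_in_window(table, windows[i, ])
    idx <- idx[tm$ok[idx]]
    hb <- sum(tm$hb[idx]); hw <- sum(tm$hw[idx])
    data.frame(n_sites = length(idx),
               fst = if (hb > 0) 1 - hw / hb else NA_real_)
  })
  cbind(windows, do.call(rbind, res))
}

#' Absolute divergence d_XY per window
#'
#' Mean between-population pairwise difference per bp:
#' `sum over sites of pA (1 - pB) + pB (1 - pA)`, divided by window
#' length.
#'
#' @inheritParams fst
#' @return Data frame: windows plus `n_sites` and `dxy`.
#' @export
dxy <- function(table, windows, popA, popB) {
  tm <- pair_site_terms(table, popA, popB)
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    idx <- sites_in_window(table, w)
    idx <- idx[tm$ok[idx]]
    data.frame(n_sites = length(idx),
               dxy = sum(tm$hb[idx]) / (w$end - w$start))
  })
  cbind(windows, do.call(rbind, res))
}

#' Genotype r-squared between two sites
#'
#' Squared Pearson correlation of alt-allele dosage vectors over samples
#' genotyped at both sites (the genotype-r2 convention for unphased data).
#'
#' @param table A [genotype_table()].
#' @param site_i,site_j Site row indices.
#' @return r-squared, or `NA` when either site is monomorphic among the
#'   complete pairs.
#' @export
geno_r2 <- function(table, site_i, site_j) {
  x <- table$gt[site_i, ]; y <- table$gt[site_j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y))^2
}

#' ZZ statistic of a window
#'
#' `ZZ = ZA - ZnS` where `ZA` is the mean genotype r-squared over adjacent
#' polymorphic site pairs and `ZnS` the mean over all pairs in the window.
#' Elevated values indicate intragenic recombination.  Requires at least 3
#' polymorphic sites.
#'
#' @param table A [genotype_table()].
#' @param window One-row window data frame (`chrom`, `start`, `end`).
#' @return `ZZ`, or `NA` with fewer than 3 polymorphic sites.
#' @export
zz <- function(table, window) {
  idx <- sites_in_window(table, window)
  poly <- idx[vapply(idx, function(s) {
    g <- table$gt[s, ]
    length(unique(g[!is.na(g)])) > 1
  }, TRUE)]
  k <- length(poly)
  if (k < 3) return(NA_real_)
  r2 <- matrix(NA_real_, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    r2[i, j] <- geno_r2(table, poly[i], poly[j])
  za <- mean(r2[cbind(1:(k - 1), 2:k)], na.rm = TRUE)
  zns <- mean(r2[upper.tri(r2)], na.rm = TRUE)
  za - zns
}

#' ZZ over a set of windows
#' @param table A [genotype_table()].
#' @param windows Window data frame.
#' @return Data frame: windows plus `zz`.
#' @export
windowed_zz <- function(table, windows) {
  v <- vapply(seq_len(nrow(windows)), function(i) zz(table, windows[i, ]), 0)
  cbind(windows, zz = v)
}

#' Mean derived allele frequency per window
#'
#' Averages per-site derived-allele frequencies over sites that are usable
#' (polarized), polymorphic within the focal population, and genotyped in
#' at least `min_genotyped` of the population's `total` individuals.
#'
#' @param table A [genotype_table()] (provides window coordinates only).
#' @param windows Window data frame.
#' @param polarized_sites Data frame from [polarize_sites()].
#' @param population Focal population.
#' @param min_genotyped,total Genotyped-individuals requirement.
#' @return Data frame: windows plus `n_daf_sites` and `mean_daf`.
#' @export
mean_daf <- function(table, windows, polarized_sites, population,
                     min_genotyped = 6, total = 8) {
  der <- polarized_sites[[paste0("derived_", population)]]
  cp <- polarized_sites[[paste0("copies_", population)]]
  if (is.null(der)) stop("no polarized counts for population ", population)
  qual <- polarized_sites$usable & !is.na(der) &
    cp / 2 >= min_genotyped & der > 0 & der < cp
  freq <- der / cp
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    in_w <- polarized_sites$chrom == w$chrom &
      polarized_sites$pos - 1 >= w$start & polarized_sites$pos - 1 < w$end
    f <- freq[in_w & qual]
    data.frame(n_daf_sites = length(f),
               mean_daf = if (length(f) > 0) mean(f) else NA_real_)
  })
  cbind(windows, do.call(rbind, res))
}

#' Ratio of recombination to diversity per window
#'
#' Joins a windowed recombination-rate table to windowed diversity and
#' forms `rho / theta_pi`, an approximation of `r / mu` less confounded by
#' local effective size.  Windows with `theta_pi = 0` get `NA`.
#'
#' @param window_rho_table Data frame `chrom`, `start`, `end`, `rho`.
#' @param window_theta Data frame with `chrom`, `start`, `end`,
#'   `theta_pi` (e.g. from [diversity_and_d()]).
#' @return Merged data frame with a `rho_over_theta` column.
#' @export
rho_over_theta <- function(window_rho_table, window_theta) {
  m <- merge(window_rho_table, window_theta,
             by = c("chrom", "start", "end"))
  m$rho_over_theta <- ifelse(m$theta_pi > 0, m$rho / m$theta_pi, NA_real_)
  m
}

#' Mean of a statistic across equal-count quantile bins
#'
#' Windows are ranked by the conditioning statistic and split into
#' `n_quantiles` equal-count bins; the mean of `stat` (and of the
#' conditioning statistic) is reported per bin.  Pairs with a missing
#' value in either statistic are excluded.
#'
#' @param stat Numeric vector (e.g. mean DAF per window).
#' @param conditioning_stat Numeric vector of the same length (e.g.
#'   rho/theta).
#' @param n_quantiles Number of bins.
#' @return Data frame `quantile`, `n`, `mean_conditioning`, `mean_stat`.
#' @export
quantile_profile <- function(stat, conditioning_stat, n_quantiles = 5) {
  ok <- !is.na(stat) & !is.na(conditioning_stat)
  stat <- stat[ok]; cond <- conditioning_stat[ok]
  if (length(stat) < n_quantiles)
    stop("fewer windows than quantiles")
  rk <- rank(cond, ties.method = "first")
  bin <- ceiling(rk * n_quantiles / length(rk))
  data.frame(quantile = seq_len(n_quantiles),
             n = as.vector(table(factor(bin, levels = 1:n_quantiles))),
             mean_conditioning = vapply(1:n_quantiles, function(b)
               mean(cond[bin == b]), 0),
             mean_stat = vapply(1:n_quantiles, function(b)
               mean(stat[bin == b]), 0))
}

#' Candidate islands of high relative and low absolute divergence
#'
#' Windows in the top `1 - fst_quantile` tail of F_ST and the bottom
#' `dxy_quantile` tail of d_XY (both inclusive), candidates for stronger
#' linked selection.
#'
#' @param window_table Data frame with `fst` and `dxy` columns.
#' @param fst_quantile Quantile above which F_ST qualifies (default 0.8,
#'   the top 20%).
#' @param dxy_quantile Quantile below which d_XY qualifies (default 0.2,
#'   the bottom 20%).
#' @return Subset of `window_table`.
#' @export
island_windows <- function(window_table, fst_quantile = 0.8,
                           dxy_quantile = 0.2) {
  f <- window_table$fst; d <- window_table$dxy
  qf <- quantile(f, fst_quantile, na.rm = TRUE)
  qd <- quantile(d, dxy_quantile, na.rm = TRUE)
  window_table[!is.na(f) & !is.na(d) & f >= qf & d <= qd, , drop = FALSE]
}

#' Spearman correlation between two windowed statistics
#'
#' Rank correlation with average ranks for ties; pairs with missing values
#' are dropped.
#'
#' @param statA,statB Numeric vectors of equal length.
#' @return List with `rho` and `p`.
#' @export
correlate_windows <- function(statA, statB) {
  ok <- !is.na(statA) & !is.na(statB)
  ct <- suppressWarnings(cor.test(statA[ok], statB[ok],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Assemble a window table of scan statistics
#'
#' Convenience wrapper combining [diversity_and_d()], [fst()], [dxy()],
#' [windowed_zz()], [mean_daf()] and [rho_over_theta()] into one table,
#' after removing masked windows.
#'
#' @param table A [genotype_table()].
#' @param windows Window data frame.
#' @param population Focal population for diversity, D and DAF.
#' @param pair Optional `c(popA, popB)` for F_ST and d_XY.
#' @param polarized_sites Optional polarization table enabling mean DAF.
#' @param rho Optional windowed rho table.
#' @param mask Optional mask intervals.
#' @param min_genotyped DAF genotyped-individuals requirement.
#' @return One row per window.
#' @export
window_table <- function(table, windows, population, pair = NULL,
                         polarized_sites = NULL, rho = NULL, mask = NULL,
                         min_genotyped = 6) {
  windows <- apply_mask(windows, mask)
  out <- diversity_and_d(table, windows, population)
  if (!is.null(pair)) {
    out$fst <- fst(table, windows, pair[1], pair[2])$fst
    out$dxy <- dxy(table, windows, pair[1], pair[2])$dxy
  }
  out$zz <- windowed_zz(table, windows)$zz
  if (!is.null(polarized_sites))
    out$mean_daf <- mean_daf(table, windows, polarized_sites, population,
                             min_genotyped = min_genotyped)$mean_daf
  if (!is.null(rho)) {
    m <- merge(out, rho[, c("chrom", "start", "end", "rho")],
               by = c("chrom", "start", "end"), all.x = TRUE, sort = FALSE)
    out <- m[order(match(paste(m$chrom, m$start),
                         paste(out$chrom, out$start))), ]
    out$rho_over_theta <- ifelse(out$theta_pi > 0, out$rho / out$theta_pi,
                                 NA_real_)
  }
  rownames(out) <- NULL
  out
}
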