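# Windowed statistics against brute-force oracles and constructed cases.

# independent oracles working directly on dosage matrices ------------------

oracle_pi <- function(g, L) {
  n <- 2 * ncol(g)
  tot <- 0
  for (s in seq_len(nrow(g))) {
    d <- sum(g[s, ])
    alleles <- c(rep(1, d), rep(0, n - d))
    pairs <- utils::combn(n, 2)
    tot <- tot + mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
  }
  tot / L
}

oracle_hudson <- function(ga, gb) {
  nA <- 2 * ncol(ga); nB <- 2 * ncol(gb)
  hw <- 0; hb <- 0
  for (s in seq_len(nrow(ga))) {
    aA <- c(rep(1, sum(ga[s, ])), rep(0, nA - sum(ga[s, ])))
    aB <- c(rep(1, sum(gb[s, ])), rep(0, nB - sum(gb[s, ])))
    pw <- utils::combn(nA, 2)
    hwA <- mean(aA[pw[1, ]] != aA[pw[2, ]])
    pw <- utils::combn(nB, 2)
    hwB <- mean(aB[pw[1, ]] != aB[pw[2, ]])
    hw <- hw + (hwA + hwB) / 2
    hb <- hb + mean(outer(aA, aB, "!="))
  }
  list(fst = 1 - hw / hb, dxy_sum = hb)
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  (num / den)^2
}

test_that("theta-pi matches brute-force pairwise differences", {
  # one site with 2 derived copies of n = 4, window of 10 bp
  g <- matrix(c(2L, 0L), 1, 2) # two diploids, dosages 2 and 0
  tab <- toy_table(g, pos = 5, pops = c("p", "p"))
  w <- data.frame(chrom = "chr1", start = 0, end = 10)
  out <- diversity_and_d(tab, w, "p")
  expect_equal(out$theta_pi, (2 * 2 * 2 / 12) / 10)
  expect_equal(out$theta_pi, oracle_pi(g, 10))
  expect_equal(out$S, 1)

  # monomorphic window: theta-pi 0, D missing
  tab0 <- toy_table(matrix(0L, 3, 2), pops = c("p", "p"))
  out0 <- diversity_and_d(tab0, data.frame(chrom = "chr1", start = 0,
                                           end = 50), "p")
  expect_equal(out0$theta_pi, 0)
  expect_true(is.na(out0$tajima_d))
})

test_that("Tajima's D for a single segregating site matches the constants", {
  g <- matrix(c(1L, 0L), 1, 2) # singleton among n = 4
  tab <- toy_table(g, pos = 3, pops = c("p", "p"))
  out <- diversity_and_d(tab, data.frame(chrom = "chr1", start = 0,
                                         end = 10), "p")
  n <- 4; S <- 1
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_sum <- 2 * 1 * 3 / (4 * 3)
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(out$tajima_d, D)
})

test_that("F_ST and d_XY on constructed cases", {
  w <- data.frame(chrom = "chr1", start = 0, end = 10)
  # fixed difference: F_ST = 1, per-site d_XY contribution = 1
  g <- matrix(c(0L, 0L, 2L, 2L), 1, 4)
  tab <- toy_table(g, pos = 5, pops = c("A", "A", "B", "B"))
  expect_equal(fst(tab, w, "A", "B")$fst, 1)
  expect_equal(dxy(tab, w, "A", "B")$dxy, 1 / 10)

  # identical frequencies: F_ST = 0 up to the finite-sample correction
  gbig <- matrix(rep(c(1L, 1L), 100), 1, 200)
  tabb <- toy_table(gbig, pos = 5, pops = rep(c("A", "B"), each = 100))
  expect_lt(abs(fst(tabb, w, "A", "B")$fst), 0.01)

  # random windows match the brute-force pair enumeration
  withr::with_seed(13, {
    for (r in 1:5) {
      g <- random_gt(6, 6)
      tab <- toy_table(g, pops = rep(c("A", "B"), each = 3))
      o <- oracle_hudson(g[, 1:3, drop = FALSE], g[, 4:6, drop = FALSE])
      w2 <- data.frame(chrom = "chr1", start = 0, end = 100)
      expect_equal(fst(tab, w2, "A", "B")$fst, o$fst, tolerance = 1e-12)
      expect_equal(dxy(tab, w2, "A", "B")$dxy, o$dxy_sum / 100,
                   tolerance = 1e-12)
    }
  })
})

test_that("genotype r2 and the ZZ statistic match exhaustive enumeration", {
  g <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L))
  tab <- toy_table(g, pops = rep("p", 4))
  expect_equal(geno_r2(tab, 1, 2), 1)

  # all pairwise r2 equal -> ZZ = 0
  g2 <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  tab2 <- toy_table(g2, pops = rep("p", 4))
  expect_equal(zz(tab2, data.frame(chrom = "chr1", start = 0, end = 100)),
               0)

  # 4 hand-listed sites: brute-force 6 pairs vs 3 adjacent
  withr::with_seed(19, {
    g4 <- random_gt(4, 8)
  })
  tab4 <- toy_table(g4, pops = rep("p", 8))
  r2 <- matrix(NA_real_, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) r2[i, j] <- oracle_r2(g4[i, ], g4[j, ])
  za <- mean(r2[cbind(1:3, 2:4)]); zns <- mean(r2[upper.tri(r2)])
  expect_equal(zz(tab4, data.frame(chrom = "chr1", start = 0, end = 100)),
               za - zns, tolerance = 1e-12)

  # fewer than 3 polymorphic sites: ZZ missing
  expect_true(is.na(zz(tab2, data.frame(chrom = "chr1", start = 0,
                                        end = 1))))
})

test_that("oracle equivalence holds on 100 random toy windows", {
  withr::with_seed(29, {
    ok <- TRUE
    for (r in 1:100) {
      S <- sample(3:6, 1)
      g <- random_gt(S, 6)
      tab <- toy_table(g, pops = rep(c("A", "B"), each = 3))
      w <- data.frame(chrom = "chr1", start = 0, end = 100)
      pi_a <- diversity_and_d(tab, w, "A")$theta_pi
      o_pi <- oracle_pi(g[, 1:3, drop = FALSE], 100)
      o <- oracle_hudson(g[, 1:3, drop = FALSE], g[, 4:6, drop = FALSE])
      f <- fst(tab, w, "A", "B")$fst
      d <- dxy(tab, w, "A", "B")$dxy
      ok <- ok && abs(pi_a - o_pi) < 1e-12 &&
        (is.na(f) || abs(f - o$fst) < 1e-12) &&
        abs(d - o$dxy_sum / 100) < 1e-12
    }
    expect_true(ok)
  })
})

test_that("count statistics are invariant to within-population genotype
           rearrangement, LD statistics are not", {
  withr::with_seed(37, {
    g <- random_gt(6, 8)
  })
  tab <- toy_table(g, pops = rep(c("A", "B"), each = 4))
  # redistribute dosages within population A at constant per-site counts
  g2 <- g
  for (s in 1:6) {
    d <- sum(g[s, 1:4])
    g2[s, 1:4] <- rev(c(rep(2L, d %/% 2), rep(1L, d %% 2),
                        rep(0L, 4 - d %/% 2 - d %% 2)))
  }
  tab2 <- toy_table(g2, pops = rep(c("A", "B"), each = 4))
  w <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_equal(dxy(tab, w, "A", "B")$dxy, dxy(tab2, w, "A", "B")$dxy)
  expect_equal(fst(tab, w, "A", "B")$fst, fst(tab2, w, "A", "B")$fst)
  # the LD structure does change
  expect_false(isTRUE(all.equal(zz(tab, w), zz(tab2, w))))
})

test_that("mean DAF averages qualifying sites only", {
  pol <- data.frame(chrom = "chr1", pos = c(5, 15, 25, 35, 45),
                    ancestral = "ref",
                    usable = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    derived_p = c(2, 8, 14, 16, 4),
                    copies_p = c(16, 16, 16, 16, 16))
  tab <- toy_table(matrix(0L, 5, 8), pos = pol$pos, pops = rep("p", 8))
  w <- data.frame(chrom = "chr1", start = 0, end = 50)
  out <- mean_daf(tab, w, pol, "p", min_genotyped = 6, total = 8)
  # fixed-derived site (16/16) and unusable site excluded
  expect_equal(out$mean_daf, mean(c(2, 8, 14) / 16))
  expect_equal(out$n_daf_sites, 3)

  # the example frequencies {0.125, 0.5, 0.875} average to 0.5
  expect_equal(mean(c(2, 8, 14) / 16), 0.5)

  # sites genotyped in fewer than 6 of 8 individuals are excluded
  pol$copies_p[2] <- 10
  out2 <- mean_daf(tab, w, pol, "p", min_genotyped = 6, total = 8)
  expect_equal(out2$n_daf_sites, 2)

  pol$usable <- FALSE
  expect_true(is.na(mean_daf(tab, w, pol, "p")$mean_daf))
})

test_that("rho/theta ratios and quantile profiles", {
  rho <- data.frame(chrom = "c", start = c(0, 10), end = c(10, 20),
                    rho = c(4, 6))
  th <- data.frame(chrom = "c", start = c(0, 10), end = c(10, 20),
                   theta_pi = c(2, 0))
  m <- rho_over_theta(rho, th)
  expect_equal(m$rho_over_theta, c(2, NA))

  prof <- quantile_profile(rep(0.3, 10), rep(1, 10), n_quantiles = 5)
  expect_equal(prof$mean_stat, rep(0.3, 5))
  expect_equal(prof$n, rep(2, 5))

  # hand-set values: sort by conditioning and average pairs
  stat <- c(5, 1, 3, 2, 4, 6, 8, 7, 10, 9)
  cond <- 10:1
  prof2 <- quantile_profile(stat, cond, n_quantiles = 5)
  o <- order(cond)
  man <- vapply(1:5, function(b) mean(stat[o][(2 * b - 1):(2 * b)]), 0)
  expect_equal(prof2$mean_stat, man)

  expect_error(quantile_profile(1:3, 1:3, n_quantiles = 5), "fewer")
})

test_that("island windows intersect the F_ST and d_XY quantile tails", {
  wt <- data.frame(fst = 1:100, dxy = 100:1)
  isl <- island_windows(wt)
  expect_equal(nrow(isl), 20)
  expect_true(all(isl$fst >= 81))

  expect_equal(correlate_windows(1:50, (1:50)^3)$rho, 1)
  expect_equal(correlate_windows(1:50, -(1:50))$rho, -1)
})

test_that("masked windows are removed from the window table", {
  sim <- simulate_neutral_windows(4, 6, 1000, mu = 1e-8, Nref = 2.5e4,
                                  seed = 8)
  mask <- data.frame(chrom = c("win00002", "win00005"),
                     start = c(500, 0), end = c(600, 50))
  wt <- window_table(sim$table, sim$windows, "pop", rho = sim$rho,
                     mask = mask)
  expect_equal(nrow(wt), 4)
  expect_false(any(wt$chrom %in% c("win00002", "win00005")))
  expect_true(all(c("theta_pi", "tajima_d", "zz", "rho") %in% names(wt)))
})

test_that("windowed ZZ tracks the true recombination rate", {
  withr::with_seed(51, {
    rho <- exp(runif(200, log(1e-4), log(3e-3)))
  })
  sim <- simulate_neutral_windows(8, 200, 2000, mu = 5e-8, Nref = 2.5e4,
                                  rho_per_bp = rho, seed = 52)
  wz <- windowed_zz(sim$table, sim$windows)
  m <- merge(wz, sim$rho, by = c("chrom", "start", "end"))
  ct <- correlate_windows(m$zz, m$rho)
  expect_gt(ct$rho, 0.3)
})
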