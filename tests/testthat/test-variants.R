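# VCF ingestion and site-level procedures.

test_that("load_vcf keeps biallelic SNPs and drops indels and triallelic sites", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP:GQ\t0/1:10:99\t1/1:12:99",
    "chr1\t200\t.\tC\tG\t50\tPASS\t.\tGT:DP:GQ\t0/0:9:99\t0/1:11:99",
    "chr1\t300\t.\tA\tAT\t50\tPASS\t.\tGT:DP:GQ\t0/1:10:99\t0/0:10:99",
    "chr1\t400\t.\tG\tA,C\t50\tPASS\t.\tGT:DP:GQ\t0/1:10:99\t0/2:10:99",
    "chr1\t500\t.\tT\tC\t50\tPASS\t.\tGT:DP:GQ\t./.:.:.\t0/1:8:77")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  st <- data.frame(sample = c("s1", "s2"), population = "p1")
  ct <- data.frame(chrom = "chr1", class = "autosome")
  expect_message(tab <- load_vcf(f, st, ct), "2 non-biallelic")
  expect_equal(nrow(tab$sites), 3)
  expect_equal(tab$sites$pos, c(100, 200, 500))
  expect_equal(tab$gt[1, ], c(s1 = 1L, s2 = 2L))
  expect_true(is.na(tab$gt[3, "s1"]))
  expect_equal(tab$dp[3, "s2"], 8)

  # unknown sample is a metadata error
  expect_error(load_vcf(f, data.frame(sample = "nope", population = "p"),
                        ct), "not present")

  # empty body: empty table, no error
  writeLines(vcf[1:5], f)
  tab0 <- load_vcf(f, st, ct)
  expect_equal(nrow(tab0$sites), 0)
})

test_that("VCF writing round-trips through load_vcf", {
  gt <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2)
  tab <- toy_table(gt, pops = c("p1", "p2"),
                   dp = matrix(10, 3, 2), gq = matrix(99, 3, 2))
  f <- tempfile(fileext = ".vcf")
  write_vcf(tab, f)
  back <- load_vcf(f, tab$samples,
                   data.frame(chrom = "chr1", class = "autosome"))
  expect_equal(unname(back$gt), unname(tab$gt))
  expect_equal(back$sites$pos, tab$sites$pos)
})

test_that("filter_sites masks genotypes first, then applies site filters", {
  # six sites crafted so exactly two survive all five thresholds
  gt <- matrix(1L, 6, 4)
  dp <- rbind(rep(10, 4),          # survives
              rep(10, 4),          # fails site quality
              rep(20, 4),          # mean depth 20 > 15
              c(5, 5, 5, 10),      # 3/4 masked -> 75% missing
              rep(10, 4),          # survives (one low-GQ genotype)
              c(5, 5, 10, 10))     # 2/4 masked -> 50% missing
  gq <- matrix(99, 6, 4)
  gq[5, 1] <- 10
  tab <- toy_table(gt, dp = dp, gq = gq, qual = c(50, 10, 50, 50, 50, 50))
  out <- filter_sites(tab)
  expect_equal(out$sites$pos, tab$sites$pos[c(1, 5)])
  expect_true(is.na(out$gt[2, 1])) # the low-GQ genotype was masked
  lg <- attr(out, "log")
  expect_equal(lg$sites_quality, 1)
  expect_equal(lg$sites_mean_depth, 1)
  expect_equal(lg$sites_missing, 2)
})

test_that("a site with mean depth 16 across genotyped samples is removed", {
  tab <- toy_table(matrix(1L, 1, 4), dp = matrix(16, 1, 4),
                   gq = matrix(99, 1, 4))
  expect_equal(nrow(filter_sites(tab)$sites), 0)
  # boundary: exactly 15 is kept
  tab15 <- toy_table(matrix(1L, 1, 4), dp = matrix(15, 1, 4),
                     gq = matrix(99, 1, 4))
  expect_equal(nrow(filter_sites(tab15)$sites), 1)
})

test_that("10 samples with 5 missing after depth masking exceed 40% and drop", {
  dp <- matrix(10, 1, 10); dp[1, 1:5] <- 3
  tab <- toy_table(matrix(1L, 1, 10), dp = dp, gq = matrix(99, 1, 10))
  expect_equal(nrow(filter_sites(tab)$sites), 0)
  # exactly 40% missing is kept ("no more than 40%")
  dp2 <- matrix(10, 1, 10); dp2[1, 1:4] <- 3
  tab2 <- toy_table(matrix(1L, 1, 10), dp = dp2, gq = matrix(99, 1, 10))
  expect_equal(nrow(filter_sites(tab2)$sites), 1)
})

test_that("filter_sites is idempotent", {
  withr::with_seed(7, {
    gt <- random_gt(40, 6, miss = 0.1)
    dp <- matrix(sample(3:20, 240, TRUE), 40)
    gq <- matrix(sample(10:99, 240, TRUE), 40)
  })
  tab <- toy_table(gt, dp = dp, gq = gq,
                   qual = sample(10:60, 40, TRUE))
  once <- filter_sites(tab)
  twice <- filter_sites(once)
  expect_equal(twice$sites, once$sites)
  expect_equal(twice$gt, once$gt)
})

test_that("thin_sites applies the greedy left-to-right rule", {
  tab <- toy_table(matrix(0L, 3, 2), pos = c(100, 5000, 12000))
  expect_equal(thin_sites(tab, 10000)$sites$pos, c(100, 12000))

  tab2 <- toy_table(matrix(0L, 4, 2), pos = c(1, 10001, 20001, 20002))
  expect_equal(thin_sites(tab2, 10000)$sites$pos, c(1, 10001, 20001))

  tab3 <- toy_table(matrix(0L, 1, 2), pos = 42)
  expect_equal(thin_sites(tab3, 10000)$sites$pos, 42)

  # gaps in the output are never below the threshold, per chromosome
  withr::with_seed(11, {
    pos <- sort(sample.int(1e5, 60))
  })
  tab4 <- toy_table(matrix(0L, 60, 2), pos = pos)
  out <- thin_sites(tab4, 5000)
  expect_true(all(diff(out$sites$pos) >= 5000))
})

test_that("depth-ratio sexing uses the 0.625 / 0.875 decision band", {
  gt <- matrix(0L, 4, 3)
  dp <- cbind(c(12, 12, 6, 6), c(12, 12, 12, 12), c(12, 12, 9, 9))
  tab <- toy_table(gt, chrom = c("a1", "a1", "x1", "x1"),
                   pos = c(10, 20, 10, 20), dp = dp,
                   cls = c(a1 = "autosome", x1 = "X"))
  sx <- infer_sex_from_depth(tab)
  expect_equal(sx$sex, c("XY", "XX", "unassigned"))
  expect_equal(sx$ratio, c(0.5, 1, 0.75))

  auto_only <- toy_table(matrix(0L, 2, 2), chrom = c("a1", "a1"),
                         pos = c(1, 2), dp = matrix(10, 2, 2),
                         cls = c(a1 = "autosome"))
  expect_error(infer_sex_from_depth(auto_only), "no X-linked sites")
})

test_that("sexing recovers all true sexes on simulated depth profiles", {
  sim <- simulate_sex_linked_dataset(
    "((A,B),C);", t_split = 4000, t_root = 10000,
    Ne = c(A = 1e4, B = 1e4, C = 1e4, inner = 1e4, anc = 1e4),
    xi = c(A = 0.5, B = 0.5, C = 0.5, inner = 0.5),
    n_per_leaf = 4, n_auto_loci = 160, n_x_loci = 160,
    locus_length = 500, mu = 2e-8, depth_cv = 0.2, seed = 5)
  cls <- sim$table$chrom_class[sim$table$sites$chrom]
  expect_gte(sum(cls == "X"), 200)        # sites per class
  expect_gte(sum(cls == "autosome"), 200)
  sx <- infer_sex_from_depth(sim$table)
  expect_equal(setNames(sx$sex, sx$sample),
               sim$truth$sex_assignments)
})

test_that("polarization follows the 75% outgroup rule", {
  gt <- rbind(c(0L, 1L, 0L, 0L),  # outgroups hom ref
              c(2L, 1L, NA, 2L),  # outgroup A missing, B fixed alt
              c(1L, 0L, 1L, 1L),  # outgroups both het: freq 0.5
              c(0L, 2L, 0L, 1L))  # outgroup copies 3/4 ref = 0.75
  tab <- toy_table(gt, pops = c("p1", "p1", "out", "out"))
  pol <- polarize_sites(tab, c("s03", "s04"))
  expect_equal(pol$ancestral, c("ref", "alt", NA, "ref"))
  expect_equal(pol$usable, c(TRUE, TRUE, FALSE, TRUE))
  # derived counts for p1 (2 samples, 4 copies)
  expect_equal(pol$derived_p1[1], 1)       # ancestral ref: count alt
  expect_equal(pol$derived_p1[2], 4 - 3)   # ancestral alt: copies - alt
  expect_error(polarize_sites(tab, "s03"), "exactly two")
})

test_that("polarization is error-free when outgroups are fixed ancestral", {
  m <- quick_sc_model()
  sim <- simulate_pair_dataset(m, 4, 4, n_loci = 60, locus_length = 500,
                               mu = 1e-8, Nref = 2e4, seed = 3,
                               outgroup = "fixed_ancestral")
  pol <- polarize_sites(sim$table, c("outgroup1", "outgroup2"))
  expect_true(all(pol$usable))
  # simulator writes REF as the true ancestral allele
  expect_true(all(pol$ancestral == "ref"))
})

test_that("male-adjusted X counts follow the one-copy-per-male rule", {
  # 3 XX + 2 XY, one X site and one autosomal site, all genotyped
  gt <- matrix(c(rep(1L, 5), rep(1L, 5)), 2, 5, byrow = TRUE)
  gt[1, 4] <- 0L; gt[1, 5] <- 2L # males hom on X
  tab <- toy_table(gt, chrom = c("x1", "a1"), pos = c(10, 10),
                   pops = rep("p1", 5),
                   cls = c(x1 = "X", a1 = "autosome"))
  sexes <- data.frame(sample = sprintf("s%02d", 1:5),
                      sex = c("XX", "XX", "XX", "XY", "XY"))
  ac <- adjust_x_counts(tab, sexes)
  expect_equal(unname(ac$copies[1, "p1"]), 8) # 3*2 + 2*1
  expect_equal(unname(ac$copies[2, "p1"]), 10)
  expect_equal(unname(ac$alt[1, "p1"]), 1 + 1 + 1 + 0 + 1)
  # an XY heterozygous X call is masked, dropping one copy
  gt[1, 4] <- 1L
  tab2 <- toy_table(gt, chrom = c("x1", "a1"), pos = c(10, 10),
                    pops = rep("p1", 5),
                    cls = c(x1 = "X", a1 = "autosome"))
  ac2 <- adjust_x_counts(tab2, sexes)
  expect_equal(unname(ac2$copies[1, "p1"]), 7)
  expect_equal(ac2$het_x_masked, 1)

  sexes$sex[1] <- "unassigned"
  expect_error(adjust_x_counts(tab, sexes), "assigned sex")
})
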