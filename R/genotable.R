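#' Genotype table
#'
#' In-memory container for a filtered SNP table: biallelic sites with
#' per-genotype alt-allele dosage in `{0, 1, 2, NA}`, depth and genotype
#' quality, a sample roster with population labels, and a per-chromosome
#' class (`"autosome"` or `"X"`).
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`.
#' @param gt Integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param dp,gq Numeric matrices of per-genotype depth and quality (may be
#'   `NA`).
#' @param samples Data frame with columns `sample`, `population`.
#' @param chrom_class Named character vector mapping chromosome ids to
#'   `"autosome"` or `"X"`.
#' @param ancestral Optional character vector (`"ref"`/`"alt"`) of true
#'   ancestral alleles (carried by simulated data).
#' @return Object of class `ps_geno`.
#' @export
genotype_table <- function(sites, gt, dp = NULL, gq = NULL, samples,
                           chrom_class, ancestral = NULL) {
  gt <- as.matrix(gt)
  stopifnot(nrow(sites) == nrow(gt), nrow(samples) == ncol(gt))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  bad <- !(gt %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype dosage must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  if (!all(unique(sites$chrom) %in% names(chrom_class)))
    stop("every chromosome needs a class (autosome or X)")
  colnames(gt) <- samples$sample
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = samples, chrom_class = chrom_class,
                 ancestral = ancestral),
            class = "ps_geno")
}

#' @export
print.ps_geno <- function(x, ...) {
  cat(sprintf("Genotype table: %d sites x %d samples (%d chromosomes)\n",
              nrow(x$sites), nrow(x$samples),
              length(unique(x$sites$chrom))))
  invisible(x)
}

# build a vcfR object from a genotype table
as_vcfR <- function(table) {
  S <- nrow(table$sites)
  gt_str <- matrix("./.", S, nrow(table$samples))
  g <- table$gt
  gt_str[!is.na(g) & g == 0] <- "0/0"
  gt_str[!is.na(g) & g == 1] <- "0/1"
  gt_str[!is.na(g) & g == 2] <- "1/1"
  dp <- ifelse(is.na(table$dp), ".", format(table$dp, trim = TRUE))
  gq <- ifelse(is.na(table$gq), ".", format(table$gq, trim = TRUE))
  cells <- matrix(paste(gt_str, dp, gq, sep = ":"), S,
                  nrow(table$samples))
  colnames(cells) <- table$samples$sample
  gtmat <- cbind(FORMAT = rep("GT:DP:GQ", S), cells)
  fix <- cbind(CHROM = as.character(table$sites$chrom),
               POS = as.character(table$sites$pos),
               ID = rep(".", S),
               REF = as.character(table$sites$ref),
               ALT = as.character(table$sites$alt),
               QUAL = ifelse(is.na(table$sites$qual), ".",
                             format(table$sites$qual, trim = TRUE)),
               FILTER = rep("PASS", S), INFO = rep(".", S))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">")
  v <- new("vcfR", meta = meta, fix = fix, gt = gtmat)
  v
}

#' Write a genotype table as VCF
#'
#' @param table A [genotype_table()].
#' @param path Output path; gzip-compressed when it ends in `.gz`,
#'   plain-text VCF otherwise.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  v <- as_vcfR(table)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(v, file = path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(v@meta, con)
    writeLines(paste0("#", paste(c(colnames(v@fix), colnames(v@gt)),
                                 collapse = "\t")), con)
    if (nrow(v@fix) > 0)
      writeLines(apply(cbind(v@fix, v@gt), 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a VCF into a genotype table
#'
#' Multi-allelic records and non-SNP records (indels, symbolic alleles) are
#' dropped with a logged count.  Samples are restricted to the sample table;
#' a sample-table entry absent from the VCF is a metadata error.
#'
#' @param path VCF (v4.x) file, optionally gzipped.
#' @param sample_table Data frame with columns `sample`, `population`.
#' @param chromosome_class_table Data frame with columns `chrom`, `class`
#'   (`"autosome"` or `"X"`).
#' @return A [genotype_table()].
#' @export
load_vcf <- function(path, sample_table, chromosome_class_table) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n0 <- nrow(v@fix)
  if (n0 > 0) {
    ref <- v@fix[, "REF"]; alt <- v@fix[, "ALT"]
    snp <- !is.na(alt) & grepl("^[ACGTacgt]$", ref) &
      grepl("^[ACGTacgt]$", alt)
    dropped <- sum(!snp)
    if (dropped > 0)
      message(sprintf("dropped %d non-biallelic-SNP record(s)", dropped))
    v <- v[snp, ]
  }
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(sample_table$sample, vcf_samples)
  if (length(missing) > 0)
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "))

  S <- nrow(v@fix)
  ns <- nrow(sample_table)
  if (S == 0) {
    return(genotype_table(
      sites = data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         qual = numeric()),
      gt = matrix(integer(), 0, ns),
      dp = matrix(numeric(), 0, ns), gq = matrix(numeric(), 0, ns),
      samples = sample_table,
      chrom_class = setNames(as.character(chromosome_class_table$class),
                             chromosome_class_table$chrom)))
  }

  gt_raw <- vcfR::extract.gt(v, "GT")[, sample_table$sample, drop = FALSE]
  a1 <- substr(gt_raw, 1, 1)
  a2 <- substr(gt_raw, 3, 3)
  num <- function(a) ifelse(a %in% c("0", "1"), as.integer(a), NA_integer_)
  d1 <- num(a1); d2 <- num(a2)
  # haploid records (single allele) are treated as homozygous
  d2 <- ifelse(a2 == "" & !is.na(d1), d1, d2)
  gt <- matrix(d1 + d2, S, ns)

  getfmt <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) matrix(NA_real_, S, ns)
    else m[, sample_table$sample, drop = FALSE]
  }
  dp <- getfmt("DP"); gq <- getfmt("GQ")

  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  sites <- data.frame(chrom = v@fix[, "CHROM"],
                      pos = as.integer(v@fix[, "POS"]),
                      ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                      qual = qual, stringsAsFactors = FALSE)
  cls <- setNames(as.character(chromosome_class_table$class),
                  chromosome_class_table$chrom)
  genotype_table(sites, gt, dp, gq, sample_table, cls)
}

#' Site and genotype filtering
#'
#' Genotype-level masking precedes site-level filters: genotypes below the
#' depth or genotype-quality threshold are set to missing first; sites are
#' then removed when the mean depth across still-genotyped samples exceeds
#' `max_mean_depth`, when the missing fraction exceeds
#' `max_missing_fraction`, or when site quality falls below
#' `min_site_quality`.  Site order is preserved and the operation is
#' idempotent.
#'
#' @param table A [genotype_table()].
#' @param min_gt_depth Minimum per-genotype depth.
#' @param max_mean_depth Maximum mean depth across genotyped samples.
#' @param max_missing_fraction Maximum fraction of missing genotypes.
#' @param min_site_quality Minimum site quality score.
#' @param min_gt_quality Minimum per-genotype quality.
#' @return Filtered [genotype_table()]; attribute `"log"` records the
#'   number of masked genotypes and of sites removed per criterion.
#' @export
filter_sites <- function(table, min_gt_depth = 6, max_mean_depth = 15,
                         max_missing_fraction = 0.4, min_site_quality = 20,
                         min_gt_quality = 20) {
  gt <- table$gt; dp <- table$dp; gq <- table$gq
  maskg <- (!is.na(dp) & dp < min_gt_depth) |
    (!is.na(gq) & gq < min_gt_quality)
  maskg <- maskg & !is.na(gt)
  gt[maskg] <- NA_integer_
  n_masked <- sum(maskg)

  genotyped <- !is.na(gt)
  mean_dp <- vapply(seq_len(nrow(gt)), function(s) {
    d <- dp[s, genotyped[s, ]]
    if (length(d) == 0) NA_real_ else mean(d, na.rm = TRUE)
  }, 0)
  miss_frac <- rowMeans(!genotyped)
  qual <- table$sites$qual

  bad_depth <- !is.na(mean_dp) & mean_dp > max_mean_depth
  bad_miss <- miss_frac > max_missing_fraction
  bad_qual <- !is.na(qual) & qual < min_site_quality
  keep <- !(bad_depth | bad_miss | bad_qual)

  out <- genotype_table(table$sites[keep, , drop = FALSE],
                        gt[keep, , drop = FALSE],
                        table$dp[keep, , drop = FALSE],
                        table$gq[keep, , drop = FALSE],
                        table$samples, table$chrom_class,
                        if (!is.null(table$ancestral))
                          table$ancestral[keep])
  attr(out, "log") <- list(genotypes_masked = n_masked,
                           sites_mean_depth = sum(bad_depth),
                           sites_missing = sum(bad_miss),
                           sites_quality = sum(bad_qual))
  out
}

#' Distance thinning of sites
#'
#' Greedy left-to-right scan per chromosome: a site is kept iff its position
#' is at least `min_distance_bp` beyond the last kept position (the first
#' site of each chromosome is always kept).
#'
#' @param table A [genotype_table()].
#' @param min_distance_bp Minimum distance between kept sites.
#' @return Thinned [genotype_table()].
#' @export
thin_sites <- function(table, min_distance_bp) {
  keep <- logical(nrow(table$sites))
  for (ch in unique(table$sites$chrom)) {
    idx <- which(table$sites$chrom == ch)
    last <- -Inf
    for (s in idx) {
      if (table$sites$pos[s] - last >= min_distance_bp) {
        keep[s] <- TRUE
        last <- table$sites$pos[s]
      }
    }
  }
  genotype_table(table$sites[keep, , drop = FALSE],
                 table$gt[keep, , drop = FALSE],
                 table$dp[keep, , drop = FALSE],
                 table$gq[keep, , drop = FALSE],
                 table$samples, table$chrom_class,
                 if (!is.null(table$ancestral)) table$ancestral[keep])
}

#' Depth-based sex inference
#'
#' XY individuals carry one X, so their coverage at X-linked sites is
#' expected to be half the autosomal coverage, while XX individuals show
#' equal coverage.  The per-sample ratio (mean X depth) / (mean autosomal
#' depth) is classified as XY below 0.625, XX above 0.875, and left
#' unassigned inside the guard band.
#'
#' @param table A [genotype_table()] containing both chromosome classes.
#' @param xy_threshold,xx_threshold Decision thresholds on the depth ratio.
#' @return Data frame with columns `sample`, `auto_depth`, `x_depth`,
#'   `ratio`, `sex` (`"XY"`, `"XX"` or `"unassigned"`).
#' @export
infer_sex_from_depth <- function(table, xy_threshold = 0.625,
                                 xx_threshold = 0.875) {
  cls <- table$chrom_class[table$sites$chrom]
  if (!any(cls == "X")) stop("no X-linked sites: cannot infer sex")
  if (!any(cls == "autosome")) stop("no autosomal sites: cannot infer sex")
  amean <- colMeans(table$dp[cls == "autosome", , drop = FALSE], na.rm = TRUE)
  xmean <- colMeans(table$dp[cls == "X", , drop = FALSE], na.rm = TRUE)
  ratio <- xmean / amean
  sex <- ifelse(ratio < xy_threshold, "XY",
                ifelse(ratio > xx_threshold, "XX", "unassigned"))
  data.frame(sample = table$samples$sample, auto_depth = unname(amean),
             x_depth = unname(xmean), ratio = unname(ratio),
             sex = unname(sex), stringsAsFactors = FALSE)
}

#' Outgroup polarization
#'
#' The ancestral allele is the allele at frequency at least 0.75 among the
#' (up to four) outgroup allele copies; if one outgroup individual is
#' missing, the allele fixed in the other is taken; otherwise the site is
#' flagged unusable.  Derived-allele counts are tallied for every non
#' outgroup population.
#'
#' @param table A [genotype_table()].
#' @param outgroup_samples Exactly two sample names.
#' @param min_freq Outgroup frequency threshold for calling the ancestral
#'   allele.
#' @return Data frame with columns `chrom`, `pos`, `ancestral`
#'   (`"ref"`/`"alt"`/`NA`), `usable`, and per population `derived_<pop>`
#'   and `copies_<pop>` (genotyped allele copies).
#' @export
polarize_sites <- function(table, outgroup_samples, min_freq = 0.75) {
  if (length(outgroup_samples) != 2)
    stop("exactly two outgroup samples are required")
  if (!all(outgroup_samples %in% table$samples$sample))
    stop("outgroup sample(s) not in table")
  og <- table$gt[, outgroup_samples, drop = FALSE]
  alt_cp <- rowSums(og, na.rm = TRUE)
  n_cp <- 2 * rowSums(!is.na(og))

  anc <- rep(NA_character_, nrow(og))
  both <- n_cp == 4
  one <- n_cp == 2
  f_alt <- ifelse(n_cp > 0, alt_cp / n_cp, NA)
  anc[both & (1 - f_alt) >= min_freq] <- "ref"
  anc[both & f_alt >= min_freq] <- "alt"
  anc[one & alt_cp == 0] <- "ref"
  anc[one & alt_cp == 2] <- "alt"
  usable <- !is.na(anc)

  focal <- setdiff(table$samples$sample, outgroup_samples)
  pops <- unique(table$samples$population[table$samples$sample %in% focal])
  out <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                    ancestral = anc, usable = usable,
                    stringsAsFactors = FALSE)
  for (p in pops) {
    ps <- table$samples$sample[table$samples$population == p &
                                 table$samples$sample %in% focal]
    g <- table$gt[, ps, drop = FALSE]
    alt <- rowSums(g, na.rm = TRUE)
    cp <- 2 * rowSums(!is.na(g))
    der <- ifelse(anc == "ref", alt, cp - alt)
    der[!usable] <- NA
    out[[paste0("derived_", p)]] <- der
    out[[paste0("copies_", p)]] <- cp
  }
  out
}

#' Male-adjusted allele counts
#'
#' On X-linked sites XY individuals contribute one allele copy (their
#' heterozygous X calls, which cannot be real, are set to missing and
#' counted in the log) and XX individuals two; autosomal sites are
#' unchanged (two copies per genotyped individual).
#'
#' @param table A [genotype_table()].
#' @param sexes Data frame from [infer_sex_from_depth()] (or any data frame
#'   with columns `sample` and `sex`).
#' @param samples Optional subset of samples to count (default: all).
#' @return List with matrices `alt` and `copies` (sites x populations),
#'   and `het_x_masked`, the number of masked heterozygous X calls in XY
#'   individuals.
#' @export
adjust_x_counts <- function(table, sexes, samples = NULL) {
  if (is.null(samples)) samples <- table$samples$sample
  sx <- setNames(sexes$sex, sexes$sample)[samples]
  if (any(is.na(sx) | sx == "unassigned"))
    stop("all counted samples need an assigned sex")
  isx <- table$chrom_class[table$sites$chrom] == "X"
  pops <- unique(table$samples$population[table$samples$sample %in% samples])
  S <- nrow(table$sites)
  alt <- matrix(0, S, length(pops), dimnames = list(NULL, pops))
  cps <- matrix(0, S, length(pops), dimnames = list(NULL, pops))
  n_het_masked <- 0
  for (p in pops) {
    ps <- table$samples$sample[table$samples$population == p &
                                 table$samples$sample %in% samples]
    g <- table$gt[, ps, drop = FALSE]
    male <- sx[ps] == "XY"
    if (any(male) && any(isx)) {
      gx <- g[isx, male, drop = FALSE]
      het <- !is.na(gx) & gx == 1
      n_het_masked <- n_het_masked + sum(het)
      gx[het] <- NA_integer_
      g[isx, male] <- gx
    }
    w <- matrix(2, S, length(ps))
    if (any(male)) w[isx, male] <- 1
    gn <- !is.na(g)
    cps[, p] <- rowSums(w * gn)
    # dosage 2 on X in males is one copy of the alt allele
    contrib <- g / 2 * w
    alt[, p] <- rowSums(contrib, na.rm = TRUE)
  }
  list(alt = alt, copies = cps, het_x_masked = n_het_masked)
}

#' Write a polarization table as TSV
#' @param polarized_sites Data frame from [polarize_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polarization_tsv <- function(polarized_sites, path) {
  write.table(polarized_sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
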