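test_that("genotype TSV and VCF round-trip through read/write", {
  cfg <- default_sim_config(seed = 2, n_individuals = c(SA = 15, Caucasian = 10))
  sim <- simulate_dataset(cfg)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_genotypes_tsv(sim$genotypes, tsv)
  write_genotypes_vcf(sim$genotypes, vcf)
  gt_tsv <- read_genotypes(tsv, "tsv")
  gt_vcf <- read_genotypes(vcf, "vcf")
  expect_identical(gt_tsv$geno, sim$genotypes$geno)
  expect_identical(gt_tsv$cohort, sim$genotypes$cohort)
  expect_identical(gt_vcf$geno, sim$genotypes$geno)
  expect_identical(gt_vcf$snps$pos, sim$genotypes$snps$pos)
})

test_that("small hand-written fixtures parse with the documented conventions", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("individual_id\trs1\trs2",
               "ind1\t0\t1", "ind2\t2\tNA", "ind3\t1\t2"), tsv)
  gt <- read_genotypes(tsv, "tsv")
  expect_equal(dim(gt$geno), c(3L, 2L))
  expect_identical(gt$geno["ind2", ], c(rs1 = 2L, rs2 = NA))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1\tind2",
               "9\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t./."), vcf)
  gt <- read_genotypes(vcf, "vcf")
  expect_identical(unname(gt$geno[, "rs1"]), c(1L, NA))

  writeLines(c("individual_id\trs1", "ind1\t5"), tsv)
  expect_error(read_genotypes(tsv, "tsv"), "line 2")

  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1",
               "9\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_genotypes(vcf, "vcf"), "triallelic")
})

test_that("replicate aggregation gives mean, SE and boundary flags", {
  meas <- data.frame(individual_id = "i1", gene = "g", marker_id = "m",
                     template = "cDNA", replicate = 1:4, ratio = c(2, 2, 2, 2))
  a <- aggregate_replicates(meas)$means
  expect_equal(a$mean_ratio, 2)
  expect_equal(a$se, 0)

  meas$ratio <- c(1, 3, NA, NA)
  a <- aggregate_replicates(meas)$means
  expect_equal(a$mean_ratio, 2)
  expect_equal(a$se, 1)
  expect_equal(a$n_replicates, 2L)

  meas$ratio <- c(1.5, NA, NA, NA)
  a <- aggregate_replicates(meas)$means
  expect_true(a$single_replicate)
  expect_true(is.na(a$se))

  meas$ratio <- rep(NA_real_, 4)
  res <- aggregate_replicates(meas)
  expect_null(res$means)
  expect_match(res$log, "all replicates missing")
})

test_that("gDNA normalization factors follow the strategy definitions", {
  g <- data.frame(individual_id = c("i1", "i2", "i3"), gene = "g",
                  marker_id = "m", template = "gDNA",
                  mean_ratio = c(1.25, 1.25, 1.25), se = 0, n_replicates = 4,
                  single_replicate = FALSE)
  nf <- compute_normalization(g)
  expect_equal(nf$nf, 1.25)

  # strategies coincide when every individual sits at the population mean
  nfi <- compute_normalization(g, "per-individual")
  expect_equal(unique(nfi$nf), 1.25)

  g2 <- g[0, ]
  expect_error(compute_normalization(g2), "gDNA")
})

test_that("normalization cancels assay bias and defines I on natural-log scale", {
  m <- data.frame(individual_id = "i1", gene = "g", marker_id = "m",
                  template = "cDNA", mean_ratio = 1.2, se = 0,
                  n_replicates = 4, single_replicate = FALSE)
  f <- data.frame(marker_id = "m", nf = 1.2)
  attr(f, "strategy") <- "population-mean"
  class(f) <- c("aer_normalization", class(f))
  out <- normalize_aer(m, f)
  expect_equal(out$norm_ratio, 1)
  expect_equal(out$I, 0)

  # noiseless mixing series at level 4: bias cancels exactly
  s <- simulate_mixing_series("m", levels = 4, bias = 1.3, cv = 0)
  agg <- aggregate_replicates(data.frame(
    individual_id = "mix", gene = "g", marker_id = "m", template = "cDNA",
    replicate = s$replicate, ratio = s$ratio))
  f4 <- data.frame(marker_id = "m", nf = 1.3)
  attr(f4, "strategy") <- "population-mean"
  class(f4) <- c("aer_normalization", class(f4))
  expect_equal(normalize_aer(agg$means, f4)$norm_ratio, 4)
})

test_that("population-mean normalization is scale equivariant and self-centring", {
  cfg <- cfg_marker_snp(0.25, 0.25, 0.25, 0.25, beta = log(1.4), n = 80,
                        marker_sd = c(m1 = 0.1), bias = c(m1 = 1.2),
                        replicate_cv = 0.05, n_replicates = 4, seed = 4)
  sim <- simulate_dataset(cfg)
  agg <- aggregate_replicates(sim$aer)$means
  nf <- compute_normalization(agg[agg$template == "gDNA", ])
  base <- normalize_aer(agg, nf)

  # gDNA normalized by its own population factor has mean exactly 1
  gd <- normalize_aer(agg, nf, template = "gDNA")
  expect_equal(mean(gd$norm_ratio), 1, tolerance = 1e-12)

  # multiplying all raw ratios of the assay by c leaves I unchanged
  scaled <- agg; scaled$mean_ratio <- scaled$mean_ratio * 3.7
  nf2 <- compute_normalization(scaled[scaled$template == "gDNA", ])
  expect_equal(nf2$nf, nf$nf * 3.7)
  expect_equal(normalize_aer(scaled, nf2)$I, base$I)
})

test_that("orientation flip negates I exactly", {
  cfg <- cfg_marker_snp(0.25, 0.25, 0.25, 0.25, beta = log(1.4), n = 40,
                        marker_sd = c(m1 = 0.1), seed = 6)
  pieces <- sim_to_aer(cfg)
  flipped <- flip_marker_orientation(pieces$aer, "m1")
  expect_equal(flipped$I, -pieces$aer$I)
})

test_that("delta-Ct arithmetic and its invariances", {
  ct <- data.frame(individual_id = "i1", gene = "g", ct_target = 25,
                   ct_b2m = 20, ct_gapd = 21, ct_hprt1 = 22)
  e <- delta_ct(ct)$expression
  expect_equal(e$delta_ct, 4)
  expect_equal(e$log_expr, -4 * log(2))

  ct$ct_target <- 21  # equals the reference mean
  expect_equal(delta_ct(ct)$expression$delta_ct, 0)

  # comparative-Ct identity: delta-Ct difference of 1 is a 2-fold change
  ct2 <- rbind(transform(ct, individual_id = "a", ct_target = 25),
               transform(ct, individual_id = "b", ct_target = 24))
  e2 <- delta_ct(ct2)$expression
  expect_equal(exp(diff(e2$log_expr)), 2)

  # adding a constant to every Ct of an individual changes nothing
  ct3 <- transform(ct, ct_target = ct_target + 3, ct_b2m = ct_b2m + 3,
                   ct_gapd = ct_gapd + 3, ct_hprt1 = ct_hprt1 + 3)
  expect_equal(delta_ct(ct3)$expression$delta_ct,
               delta_ct(ct)$expression$delta_ct)

  ct$ct_b2m <- NA
  res <- delta_ct(ct)
  expect_null(res$expression)
  expect_match(res$log, "missing reference")
})

test_that("QC excludes low call-rate individuals and flags HWE departures", {
  g <- matrix(0L, 10, 10,
              dimnames = list(paste0("i", 1:10), paste0("s", 1:10)))
  g[, 1:5] <- rep(c(0L, 1L, 2L), length.out = 50)
  g["i1", 1:3] <- NA  # 70% call rate
  gt <- genotype_table(g)
  res <- qc_filter(gt, min_call_rate = 0.8)
  expect_identical(res$excluded, "i1")
  expect_false("i1" %in% rownames(res$genotypes$geno))

  # perfect HWE: counts (25, 50, 25)
  calls <- rep(c(0L, 1L, 2L), times = c(25, 50, 25))
  expect_equal(hwe_chisq(calls)$chisq, 0)

  # no heterozygotes at all: flagged at any reasonable alpha
  calls <- rep(c(0L, 2L), times = c(50, 50))
  tst <- hwe_chisq(calls)
  expect_gt(tst$chisq, 50)
  expect_lt(tst$p, 1e-10)
})
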