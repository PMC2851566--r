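mk_post <- function(lst, snps) structure(lst, snps = snps,
                                         class = "phase_posterior")
cfg_df <- function(h1, h2, prob) data.frame(h1 = h1, h2 = h2, prob = prob,
                                            stringsAsFactors = FALSE)
mk_aer <- function(ids, marker, I, gene = "geneA")
  data.frame(individual_id = ids, gene = gene, marker_id = marker,
             template = "cDNA", norm_ratio = exp(I), I = I,
             stringsAsFactors = FALSE)

test_that("phase indicators implement the +1/0/-1 coding", {
  subset <- c("m1", "s1", "s2")
  # double het at s1 in coupling with the marker's coded allele
  x <- build_phase_indicators("000", "110", subset, c("s1", "s2"), "m1")
  expect_identical(unname(x), c(1L, 0L))       # s2 homozygous: 0
  # repulsion: coded allele of s1 on the non-numerator haplotype
  x <- build_phase_indicators("010", "100", subset, c("s1", "s2"), "m1")
  expect_identical(unname(x["s1"]), -1L)
  # flipping the marker numerator negates every indicator
  x1 <- build_phase_indicators("000", "111", subset, c("s1", "s2"), "m1")
  x2 <- build_phase_indicators("000", "111", subset, c("s1", "s2"), "m1",
                               numerator_allele = "noncoded")
  expect_identical(x2, -x1)
  expect_error(build_phase_indicators("000", "110", subset, "s1", "m1",
                                      numerator_allele = NULL),
               "orientation")
})

test_that("mixture log-likelihood matches the closed form on phase-certain data", {
  markers <- marker_table("m1", "geneA")
  post <- mk_post(list(i1 = cfg_df("0", "1", 1), i2 = cfg_df("0", "1", 1)),
                  snps = "m1")
  aer <- mk_aer(c("i1", "i2"), "m1", c(1, -1))
  prep <- prepare_aeqtl_data(aer, post, character(0), markers)
  # two unit-variance zero-mean normals at +-1
  expect_equal(aer_loglik(numeric(0), c(m1 = 1), prep),
               -log(2 * pi) - 1, tolerance = 1e-10)
})

test_that("degenerate posteriors collapse the mixture to a plain normal likelihood", {
  markers <- marker_table(c("m1", "m2"), c("geneA", "geneA"))
  subset <- c("m1", "m2", "s1")
  post <- mk_post(list(i1 = cfg_df("000", "111", 1),
                       i2 = cfg_df("010", "101", 1)),
                  snps = subset)
  aer <- rbind(mk_aer(c("i1", "i2"), "m1", c(0.61, -0.45)),
               mk_aer(c("i1", "i2"), "m2", c(0.52, 0.33)))
  prep <- prepare_aeqtl_data(aer, post, "s1", markers)
  beta <- c(s1 = 0.4); s2 <- c(m1 = 0.09, m2 = 0.16)
  # by hand: i1 couples s1 with both markers (X = +1, +1); i2 carries the
  # coded s1 allele on the haplotype bearing m1's coded allele (X = +1)
  # and opposite m2's (X = -1)
  manual <- sum(stats::dnorm(c(0.61, -0.45), c(0.4, 0.4), sqrt(0.09), log = TRUE)[1],
                stats::dnorm(-0.45, 0.4, sqrt(0.09), log = TRUE),
                stats::dnorm(0.52, 0.4, sqrt(0.16), log = TRUE),
                stats::dnorm(0.33, -0.4, sqrt(0.16), log = TRUE))
  expect_equal(aer_loglik(beta, s2, prep), manual, tolerance = 1e-10)
})

test_that("mixture likelihood equals exhaustive joint phase enumeration", {
  markers <- marker_table(c("m1", "m2"), c("geneA", "geneA"))
  subset <- c("m1", "m2", "s1")
  # three double heterozygotes with genuinely uncertain phase
  post <- mk_post(list(i1 = cfg_df(c("000", "010"), c("111", "101"), c(0.7, 0.3)),
                       i2 = cfg_df(c("000", "010"), c("111", "101"), c(0.55, 0.45)),
                       i3 = cfg_df(c("001", "011"), c("110", "100"), c(0.2, 0.8))),
                  snps = subset)
  aer <- rbind(mk_aer(c("i1", "i2", "i3"), "m1", c(0.4, -0.2, 0.15)),
               mk_aer(c("i1", "i2", "i3"), "m2", c(0.35, 0.05, -0.3)))
  prep <- prepare_aeqtl_data(aer, post, "s1", markers)
  beta <- c(s1 = 0.3); s2 <- c(m1 = 0.04, m2 = 0.07)

  # oracle: independent X definition + enumeration over all 2^3 joint
  # assignments of the three individuals' configurations
  x_of <- function(h1, h2, marker_pos, snp_pos) {
    num <- if (substring(h1, marker_pos, marker_pos) == "1") h1 else h2
    oth <- if (identical(num, h1)) h2 else h1
    bn <- substring(num, snp_pos, snp_pos); bo <- substring(oth, snp_pos, snp_pos)
    if (bn == bo) 0 else if (bn == "1") 1 else -1
  }
  dens_cfg <- function(id, row) {
    p <- post[[id]]
    mu1 <- beta * x_of(p$h1[row], p$h2[row], 1, 3)
    mu2 <- beta * x_of(p$h1[row], p$h2[row], 2, 3)
    I1 <- aer$I[aer$individual_id == id & aer$marker_id == "m1"]
    I2 <- aer$I[aer$individual_id == id & aer$marker_id == "m2"]
    stats::dnorm(I1, mu1, sqrt(s2[["m1"]])) * stats::dnorm(I2, mu2, sqrt(s2[["m2"]]))
  }
  total <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2)
    total <- total + post$i1$prob[a] * post$i2$prob[b] * post$i3$prob[cc] *
      dens_cfg("i1", a) * dens_cfg("i2", b) * dens_cfg("i3", cc)
  # joint factorizes over individuals, so log(total) must equal the
  # per-individual mixture sum
  expect_equal(aer_loglik(beta, s2, prep), log(total), tolerance = 1e-10)
})

test_that("adding a SNP with X identically zero changes nothing and is caught", {
  markers <- marker_table("m1", "geneA")
  subset <- c("m1", "s1", "s2")
  # every individual homozygous at s2
  post <- mk_post(list(i1 = cfg_df("000", "110", 1),
                       i2 = cfg_df("010", "100", 1)),
                  snps = subset)
  aer <- mk_aer(c("i1", "i2"), "m1", c(0.3, -0.1))
  prep1 <- prepare_aeqtl_data(aer, post, "s1", markers)
  prep2 <- prepare_aeqtl_data(aer, post, c("s1", "s2"), markers)
  s2v <- c(m1 = 0.05)
  expect_equal(aer_loglik(c(s1 = 0.2, s2 = 5), s2v, prep2),
               aer_loglik(c(s1 = 0.2), s2v, prep1), tolerance = 1e-12)
  expect_error(fit_aeqtl(prep2), "identifiable")
})

test_that("null-model fit recovers the closed-form variance MLE", {
  markers <- marker_table("m1", "geneA")
  I <- c(0.5, -0.2, 0.8, -0.4, 0.1)
  post <- mk_post(stats::setNames(
    replicate(5, cfg_df("0", "1", 1), simplify = FALSE),
    paste0("i", 1:5)), snps = "m1")
  aer <- mk_aer(paste0("i", 1:5), "m1", I)
  fit <- fit_aeqtl(prepare_aeqtl_data(aer, post, character(0), markers))
  expect_equal(unname(fit$sigma2["m1"]), mean(I^2), tolerance = 1e-12)
})

test_that("beta is recovered exactly on near-noiseless data", {
  cfg <- cfg_marker_snp(0.5, 0, 0, 0.5, beta = log(2), n = 60,
                        marker_sd = c(m1 = 0.01), seed = 8)
  pieces <- sim_to_aer(cfg)
  fit <- fit_sim(pieces$sim, pieces$aer, "s1")
  expect_equal(unname(fit$beta["s1"]), log(2), tolerance = 0.01)
})

test_that("orientation flip of the marker leaves the fitted effect unchanged", {
  cfg <- cfg_marker_snp(0.4, 0.1, 0.1, 0.4, beta = log(1.6), n = 150,
                        marker_sd = c(m1 = 0.1), seed = 12)
  pieces <- sim_to_aer(cfg)
  fit1 <- fit_sim(pieces$sim, pieces$aer, "s1")
  sim2 <- pieces$sim
  sim2$config$markers$numerator_allele <- "noncoded"
  fit2 <- fit_sim(sim2, flip_marker_orientation(pieces$aer, "m1"), "s1")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-5)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("permuting individual order leaves the fit unchanged", {
  cfg <- cfg_marker_snp(0.35, 0.15, 0.15, 0.35, beta = log(1.4), n = 80,
                        marker_sd = c(m1 = 0.12), seed = 13)
  pieces <- sim_to_aer(cfg)
  fit1 <- fit_sim(pieces$sim, pieces$aer, "s1")
  aer_rev <- pieces$aer[rev(seq_len(nrow(pieces$aer))), ]
  fit2 <- fit_sim(pieces$sim, aer_rev, "s1")
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-9)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
})

test_that("likelihood-ratio test arithmetic and nesting checks", {
  f <- structure(list(loglik = -10, beta = c(a = 1), n_params = 3,
                      individuals = c("i1", "i2")), class = "aeqtl_fit")
  n <- structure(list(loglik = -10, beta = stats::setNames(numeric(0), character(0)),
                      n_params = 2, individuals = c("i1", "i2")),
                 class = "aeqtl_fit")
  t0 <- lrt(f, f)
  expect_equal(t0$stat, 0); expect_equal(t0$p, 1)
  f$loglik <- -10 + 2.5  # stat = 5 on 1 df
  tst <- lrt(f, n)
  expect_equal(tst$stat, 5)
  expect_equal(tst$p, 0.02535, tolerance = 1e-3)
  n$individuals <- c("i1", "i3")
  expect_error(lrt(f, n), "identical individual set")
  n$individuals <- c("i1", "i2"); n$beta <- c(zzz = 1)
  expect_error(lrt(f, n), "nested")
})

test_that("fold-change convention follows exp(beta)", {
  expect_equal(effect_to_fold(0), 1)
  expect_equal(effect_to_fold(log(2)), 2)
  cfg <- cfg_marker_snp(0.5, 0, 0, 0.5, beta = log(1.5), n = 500,
                        marker_sd = c(m1 = 0.15), seed = 14)
  pieces <- sim_to_aer(cfg)
  fit <- fit_sim(pieces$sim, pieces$aer, "s1")
  expect_gt(effect_to_fold(unname(fit$beta["s1"])), 1.4)
  expect_lt(effect_to_fold(unname(fit$beta["s1"])), 1.6)
})

test_that("marker intercepts absorb residual assay bias", {
  cfg <- cfg_marker_snp(0.4, 0.1, 0.1, 0.4, beta = log(1.6), n = 250,
                        marker_sd = c(m1 = 0.1), bias = c(m1 = 1.25),
                        seed = 33)
  sim <- simulate_dataset(cfg)
  agg <- aggregate_replicates(sim$aer)$means
  # deliberately skip gDNA normalization: the assay bias stays in I
  raw <- agg[agg$template == "cDNA", ]
  raw$I <- log(raw$mean_ratio)
  markers <- sim$config$markers
  post <- phase_posteriors(
    em_haplotype_freqs(sim$genotypes, c("m1", "s1"), cohort = "pop"),
    sim$genotypes)
  dat <- prepare_aeqtl_data(raw, post, "s1", markers)
  fit <- fit_aeqtl(dat, marker_intercepts = TRUE)
  expect_equal(unname(fit$alpha["m1"]), log(1.25), tolerance = 0.05)
  expect_equal(unname(fit$beta["s1"]), log(1.6), tolerance = 0.1)
  # null closed form with intercepts: mean / central second moment
  dat0 <- prepare_aeqtl_data(raw, post, character(0), markers)
  fit0 <- fit_aeqtl(dat0, marker_intercepts = TRUE)
  keepI <- raw$I[raw$individual_id %in% fit0$individuals]
  expect_equal(unname(fit0$alpha["m1"]), mean(keepI), tolerance = 1e-9)
  expect_equal(unname(fit0$sigma2["m1"]), mean((keepI - mean(keepI))^2),
               tolerance = 1e-9)
})

test_that("scan excludes SNPs with too few informative heterozygotes", {
  cfg <- cfg_marker_snp(0.4, 0.1, 0.1, 0.4, beta = log(1.5), n = 60,
                        marker_sd = c(m1 = 0.1), seed = 15)
  pieces <- sim_to_aer(cfg)
  n_inf <- length(informative_heterozygotes(pieces$sim$genotypes, pieces$aer,
                                            "s1", "m1"))
  expect_gt(n_inf, 8)
  sc_hi <- scan_snps(pieces$aer, pieces$sim$genotypes, "geneA", "s1",
                     pieces$sim$config$markers, min_informative = n_inf + 1)
  expect_true(sc_hi$excluded)
  expect_match(sc_hi$reason, "informative heterozygotes")
  sc_lo <- scan_snps(pieces$aer, pieces$sim$genotypes, "geneA", "s1",
                     pieces$sim$config$markers, min_informative = 8)
  expect_false(sc_lo$excluded)
  expect_equal(sc_lo$n_informative, n_inf)
  # absent SNP flagged, scan continues
  sc <- scan_snps(pieces$aer, pieces$sim$genotypes, "geneA",
                  c("s1", "ghost"), pieces$sim$config$markers)
  expect_true(sc$excluded[sc$snp_id == "ghost"])
  expect_false(sc$excluded[sc$snp_id == "s1"])
})

test_that("combining two markers never loses informative heterozygotes", {
  cfg <- default_sim_config(seed = 19, n_individuals = c(SA = 80, Caucasian = 60))
  pieces <- sim_to_aer(cfg)
  gt <- pieces$sim$genotypes
  for (s in c("snp35", "snp45", "snp20")) {
    both <- length(informative_heterozygotes(gt, pieces$aer, s,
                                             c("g3_m1", "g3_m2")))
    m1 <- length(informative_heterozygotes(gt, pieces$aer, s, "g3_m1"))
    m2 <- length(informative_heterozygotes(gt, pieces$aer, s, "g3_m2"))
    expect_gte(both, max(m1, m2))
  }
})

test_that("stratified AER diagnostic separates one- from two-SNP heterozygotes", {
  # identical groups: no difference, P at 1
  aer_same <- mk_aer(paste0("i", 1:8), "m1",
                     rep(c(0.1, 0.2, 0.3, 0.4), 2))
  g <- matrix(c(rep(0L, 4), rep(1L, 4)), ncol = 1,
              dimnames = list(paste0("i", 1:8), "s1"))
  gt <- genotype_table(g)
  res <- stratified_aer(aer_same, NULL, "m1", "s1", gt)
  expect_gt(res$p, 0.95)

  # two causal SNPs in strong LD: the class heterozygous at the second
  # SNP carries both effects and shows the larger mean ratio
  haps <- c("111", "000", "110")
  cfg <- make_cfg(haplotypes = haps, freq = c(0.4, 0.4, 0.2),
                  site_ids = c("m1", "s1", "s2"),
                  markers = marker_table("m1", "geneA"),
                  cis = list(geneA = c(s1 = log(1.5), s2 = log(1.5))),
                  n = c(pop = 200), marker_sd = c(m1 = 0.05), seed = 21)
  pieces <- sim_to_aer(cfg)
  res <- stratified_aer(pieces$aer, pieces$gdna, "m1", "s2",
                        pieces$sim$genotypes)
  m_het <- res$groups$mean_ratio[res$groups$class == "heterozygous"]
  m_hom <- res$groups$mean_ratio[res$groups$class == "homozygous"]
  expect_gt(m_het, m_hom)
  expect_lt(res$p, 0.01)
  expect_equal(res$gdna_mean, 1, tolerance = 1e-9)
})
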