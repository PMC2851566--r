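# Builders for small, fully controlled simulation configurations used
# across the test files.  All fixtures are generated in code.

# Single-cohort configuration over an arbitrary site panel.
make_cfg <- function(haplotypes, freq, site_ids, markers,
                     cis = stats::setNames(
                       rep(list(numeric(0)), length(unique(markers$gene))),
                       unique(markers$gene)),
                     n = c(pop = 100), marker_sd = NULL, bias = NULL,
                     replicate_cv = 0, n_replicates = 1, resid_sd = 0,
                     age_coef = 0, sex_coef = 0, seed = 1,
                     geno_missing_rate = 0, ct_sd = 0) {
  if (is.null(marker_sd))
    marker_sd <- stats::setNames(rep(0, nrow(markers)), markers$marker_id)
  if (is.null(bias))
    bias <- stats::setNames(rep(1, nrow(markers)), markers$marker_id)
  pools <- lapply(names(n), function(co) list(haplotypes = haplotypes,
                                              freq = freq))
  names(pools) <- names(n)
  sim_config(
    n_individuals = n, haplotype_pool = pools, site_ids = site_ids,
    markers = markers, cis_effects = cis, marker_sd = marker_sd,
    trans_model = list(age = age_coef, sex = sex_coef,
                       ethnicity = c("Cape mixed-ancestry" = 0,
                                     "black African" = 0, "white" = 0,
                                     "Indian" = 0, "other" = 0),
                       resid_sd = resid_sd),
    assay_bias = bias, replicate_cv = replicate_cv,
    n_replicates = n_replicates, geno_missing_rate = geno_missing_rate,
    ct_sd = ct_sd, seed = seed)
}

# Two-site panel: one transcribed marker "m1" + one mapping SNP "s1",
# drawn from four haplotypes (order: m1 allele, s1 allele).
cfg_marker_snp <- function(f00, f10, f01, f11, beta, n = 100, ...) {
  make_cfg(haplotypes = c("00", "10", "01", "11"),
           freq = c(f00, f10, f01, f11),
           site_ids = c("m1", "s1"),
           markers = marker_table("m1", "geneA"),
           cis = list(geneA = c(s1 = beta)),
           n = c(pop = n), ...)
}

# End-to-end: simulate one cohort, aggregate, normalize, return the
# pieces the model fitters need.
sim_to_aer <- function(cfg) {
  sim <- simulate_dataset(cfg)
  agg <- aggregate_replicates(sim$aer)
  gdna <- agg$means[agg$means$template == "gDNA", , drop = FALSE]
  nf <- compute_normalization(gdna)
  list(sim = sim,
       aer = normalize_aer(agg$means, nf),
       gdna = normalize_aer(agg$means, nf, template = "gDNA"))
}

# Fit the mixture model for given SNPs on a simulated dataset.
fit_sim <- function(sim, aer, model_snps, gene = "geneA",
                    subset_extra = character(0), ...) {
  markers <- sim$config$markers[sim$config$markers$gene == gene, ]
  subset <- unique(c(markers$marker_id, model_snps, subset_extra))
  posts <- lapply(unique(sim$genotypes$cohort), function(co)
    phase_posteriors(em_haplotype_freqs(sim$genotypes, subset, cohort = co),
                     sim$genotypes))
  dat <- prepare_aeqtl_data(aer, posts, model_snps, markers)
  fit_aeqtl(dat, ...)
}

# Brute-force mixture likelihood by exhaustive enumeration of joint
# phase assignments across individuals (oracle for aer_loglik).
brute_force_loglik <- function(beta, sigma2, ind_list) {
  # ind_list: list per individual of list(configs = list of list(prob, mu
  # = named vector of marker means), I = named vector of observed ratios)
  total <- 0
  for (ind in ind_list) {
    s <- 0
    for (cf in ind$configs) {
      dens <- 1
      for (k in names(ind$I))
        dens <- dens * stats::dnorm(ind$I[[k]], cf$mu[[k]], sqrt(sigma2[[k]]))
      s <- s + cf$prob * dens
    }
    total <- total + log(s)
  }
  total
}

# Multinomial log-likelihood of 2-SNP genotype data under haplotype
# frequencies f (order 00, 10, 01, 11) assuming HWE.
geno2_loglik <- function(geno, f) {
  # geno: matrix n x 2 with 0/1/2 codes
  probs <- matrix(0, 3, 3)
  haps <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (i in 1:4) for (j in 1:4) {
    g1 <- haps[i, 1] + haps[j, 1]; g2 <- haps[i, 2] + haps[j, 2]
    probs[g1 + 1, g2 + 1] <- probs[g1 + 1, g2 + 1] + f[i] * f[j]
  }
  sum(log(probs[cbind(geno[, 1] + 1, geno[, 2] + 1)]))
}

# Grid-search oracle for 2-SNP haplotype frequencies: the MLE marginals
# equal the observed allele frequencies, so profile over f11 on a
# 0.001-step grid within its feasible interval.
grid_search_hapfreq <- function(geno, step = 0.001) {
  p1 <- mean(geno[, 1]) / 2
  p2 <- mean(geno[, 2]) / 2
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  grid <- seq(lo, hi, by = step)
  lls <- vapply(grid, function(f11) {
    f <- c(1 - p1 - p2 + f11, p1 - f11, p2 - f11, f11)
    if (any(f < -1e-12)) return(-Inf)
    geno2_loglik(geno, pmax(f, 0))
  }, numeric(1))
  f11 <- grid[which.max(lls)]
  c(`00` = 1 - p1 - p2 + f11, `10` = p1 - f11, `01` = p2 - f11, `11` = f11)
}
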