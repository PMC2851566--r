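# Two-cohort synthetic-data generator.  Emulates the study design the
# analysis assumes: unphased genotypes at a panel of mapping SNPs plus
# transcribed markers drawn from cohort-specific haplotype pools under
# random mating, lognormal allele-level expression with cis effects at
# chosen SNPs, trans covariate effects acting on both alleles equally,
# assay-specific multiplicative bias, replicate measurement noise, and
# real-time-PCR Ct readout of total expression against three reference
# genes.

#' Simulation configuration
#'
#' @param n_individuals named integer vector of cohort sizes.
#' @param haplotype_pool named list (by cohort) of `list(haplotypes =
#'   character vector of 0/1 strings over all sites, freq = numeric)`;
#'   frequencies must sum to 1 within 1e-9 per cohort.
#' @param site_ids site ids in haplotype-string order (mapping SNPs and
#'   transcribed markers).
#' @param markers a [marker_table()] whose `marker_id`s appear in
#'   `site_ids`.
#' @param cis_effects named list (by gene) of named numeric vectors:
#'   effect of each cis SNP on the natural-log expression of the allele
#'   carrying its coded allele.
#' @param marker_sd named numeric: per-marker dispersion (log scale) of
#'   the allelic-ratio readout beyond replicate noise.
#' @param trans_model list with `age`, `sex`, `ethnicity` (named numeric)
#'   coefficients and `resid_sd` (> 0): trans influences applied to both
#'   alleles equally.
#' @param assay_bias named numeric multiplicative bias per marker assay.
#' @param replicate_cv fractional (lognormal) noise per replicate
#'   measurement (>= 0).
#' @param n_replicates replicates per measurement (default 4).
#' @param baseline named numeric: per-gene baseline log allele expression.
#' @param geno_missing_rate per-call missingness of the genotyping assay.
#' @param ct_sd per-replicate Ct noise (cycles).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return validated object of class `aeqtl_sim_config`.
#' @export
sim_config <- function(n_individuals, haplotype_pool, site_ids, markers,
                       cis_effects, marker_sd, trans_model, assay_bias,
                       replicate_cv = 0.05, n_replicates = 4,
                       baseline = NULL, geno_missing_rate = 0,
                       ct_sd = 0.1, seed = 1L) {
  stopifnot(length(n_individuals) >= 1, all(n_individuals > 0))
  cohorts <- names(n_individuals)
  if (is.null(cohorts)) stop("n_individuals must be named by cohort")
  for (co in cohorts) {
    pool <- haplotype_pool[[co]]
    if (is.null(pool) || !length(pool$haplotypes))
      stop("empty haplotype pool for cohort ", co)
    if (abs(sum(pool$freq) - 1) > 1e-9)
      stop("haplotype frequencies for cohort ", co, " do not sum to 1")
    if (any(pool$freq < 0)) stop("negative haplotype frequency in cohort ", co)
    if (any(nchar(pool$haplotypes) != length(site_ids)))
      stop("haplotype length mismatch with site_ids in cohort ", co)
  }
  if (any(marker_sd < 0)) stop("marker_sd must be >= 0")
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (!all(markers$marker_id %in% site_ids))
    stop("markers must be among site_ids")
  genes <- unique(markers$gene)
  for (g in names(cis_effects))
    if (!all(names(cis_effects[[g]]) %in% site_ids))
      stop("cis-effect SNPs must be among site_ids (gene ", g, ")")
  if (is.null(baseline)) baseline <- stats::setNames(rep(2, length(genes)), genes)
  structure(list(n_individuals = n_individuals, haplotype_pool = haplotype_pool,
                 site_ids = site_ids, markers = markers,
                 cis_effects = cis_effects, marker_sd = marker_sd,
                 trans_model = trans_model, assay_bias = assay_bias,
                 replicate_cv = replicate_cv, n_replicates = n_replicates,
                 baseline = baseline, geno_missing_rate = geno_missing_rate,
                 ct_sd = ct_sd, seed = as.integer(seed)),
            class = "aeqtl_sim_config")
}

# deterministic founder-haplotype pools: the Caucasian-like cohort draws
# from few founder haplotypes (strong LD), the SA-like cohort from twice
# as many including recombinants (weaker LD, different frequencies).
make_default_pools <- function(site_ids, marker_pos_strong_ld = NULL,
                               n_founders_ca = 8, n_founders_sa = 16,
                               structure_seed = 20100408) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(structure_seed %% .Machine$integer.max)
  s <- length(site_ids)
  p_site <- stats::runif(s, 0.15, 0.5)
  founders_ca <- matrix(stats::rbinom(n_founders_ca * s, 1, rep(p_site, each = n_founders_ca)),
                        nrow = n_founders_ca)
  # SA founders: recombinants of the Caucasian founders plus fresh draws
  founders_sa <- matrix(0L, n_founders_sa, s)
  for (i in seq_len(n_founders_sa)) {
    if (i <= n_founders_ca) {
      a <- founders_ca[i, ]
      b <- founders_ca[sample(n_founders_ca, 1), ]
      xo <- sample(2:(s - 1), 1)
      founders_sa[i, ] <- c(a[1:xo], b[(xo + 1):s])
    } else {
      founders_sa[i, ] <- stats::rbinom(s, 1, p_site)
    }
  }
  if (!is.null(marker_pos_strong_ld) && length(marker_pos_strong_ld) == 2) {
    # make one marker pair co-inherited in all but one founder (high D')
    m1 <- marker_pos_strong_ld[1]; m2 <- marker_pos_strong_ld[2]
    founders_ca[, m2] <- founders_ca[, m1]
    founders_sa[, m2] <- founders_sa[, m1]
    founders_ca[n_founders_ca, m2] <- 1L - founders_ca[n_founders_ca, m1]
    founders_sa[n_founders_sa, m2] <- 1L - founders_sa[n_founders_sa, m1]
  }
  fix_monomorphic <- function(mat) {
    for (j in seq_len(ncol(mat)))
      if (length(unique(mat[, j])) == 1)
        mat[sample(nrow(mat), 1), j] <- 1L - mat[1, j]
    mat
  }
  founders_ca <- fix_monomorphic(founders_ca)
  founders_sa <- fix_monomorphic(founders_sa)
  freq_ca <- stats::rgamma(n_founders_ca, 2); freq_ca <- freq_ca / sum(freq_ca)
  freq_sa <- stats::rgamma(n_founders_sa, 2); freq_sa <- freq_sa / sum(freq_sa)
  to_str <- function(m) apply(m, 1, paste, collapse = "")
  list(SA = list(haplotypes = to_str(founders_sa), freq = freq_sa),
       Caucasian = list(haplotypes = to_str(founders_ca), freq = freq_ca))
}

#' Default simulation configuration
#'
#' The study conditions: a 310-individual SA-like cohort and a
#' 177-individual Caucasian-like cohort, 56 mapping SNPs plus 2
#' transcribed markers for each of 3 genes, cohort-specific founder
#' haplotype pools (the SA-like pool has more founders, hence lower LD),
#' cis effects sized like the observed gene effects (~1.4-, ~1.33- and
#' ~1.9-fold), per-marker ratio dispersions of 0.15/0.15/0.25 (the third
#' gene's assay is the noisiest), assay biases away from 1, 4 replicates
#' at 5% CV, and an age/sex/ethnicity trans model sized so cis effects
#' explain a minority (roughly 5-25%) of total log-expression variance.
#'
#' @param seed integer seed.
#' @param n_individuals named cohort sizes (default `c(SA = 310,
#'   Caucasian = 177)`).
#' @return an `aeqtl_sim_config`.
#' @export
default_sim_config <- function(seed = 1L,
                               n_individuals = c(SA = 310, Caucasian = 177)) {
  n_map <- 56
  snp_ids <- sprintf("snp%02d", seq_len(n_map))
  markers <- marker_table(
    marker_id = c("g1_m1", "g1_m2", "g2_m1", "g2_m2", "g3_m1", "g3_m2"),
    gene = c("gene1", "gene1", "gene2", "gene2", "gene3", "gene3"))
  # interleave markers at their genes' positions in the panel
  site_ids <- c(snp_ids[1:10], "g1_m1", "g1_m2", snp_ids[11:25],
                "g2_m1", "g2_m2", snp_ids[26:40], "g3_m1", "g3_m2",
                snp_ids[41:56])
  pools <- make_default_pools(site_ids,
                              marker_pos_strong_ld = match(c("g3_m1", "g3_m2"),
                                                           site_ids))
  sim_config(
    n_individuals = n_individuals,
    haplotype_pool = pools[names(n_individuals)],
    site_ids = site_ids, markers = markers,
    # gene2 and gene3 share a causal SNP with opposite signs, the
    # antisense-style pattern of a transcript pair regulated in cis by
    # the same site
    cis_effects = list(gene1 = c(snp08 = log(1.4)),
                       gene2 = c(snp20 = -log(1.33), snp35 = -log(1.25)),
                       gene3 = c(snp35 = log(1.9), snp45 = log(1.2))),
    marker_sd = c(g1_m1 = 0.15, g1_m2 = 0.15, g2_m1 = 0.15,
                  g2_m2 = 0.15, g3_m1 = 0.25, g3_m2 = 0.25),
    trans_model = list(age = 0.01, sex = 0.1,
                       ethnicity = c("Cape mixed-ancestry" = 0,
                                     "black African" = -0.1, "white" = 0.05,
                                     "Indian" = 0.1, "other" = 0),
                       resid_sd = 0.55),
    assay_bias = c(g1_m1 = 1.10, g1_m2 = 0.92, g2_m1 = 1.25,
                   g2_m2 = 0.85, g3_m1 = 1.18, g3_m2 = 1.05),
    replicate_cv = 0.05, n_replicates = 4,
    baseline = c(gene1 = 3, gene2 = 3.5, gene3 = 1.5),
    geno_missing_rate = 0.02, ct_sd = 0.1, seed = seed)
}

#' Draw paired haplotypes for one cohort
#'
#' Each individual receives two independent draws from the cohort's
#' haplotype frequency distribution (random mating, HWE at the
#' haplotype level).
#'
#' @param cfg an `aeqtl_sim_config`.
#' @param cohort cohort label.
#' @return character matrix `n x 2` of haplotype strings; rownames are
#'   individual ids (`<cohort>_<number>`).
#' @export
simulate_haplotypes <- function(cfg, cohort) {
  pool <- cfg$haplotype_pool[[cohort]]
  if (is.null(pool) || !length(pool$haplotypes))
    stop("empty haplotype pool for cohort ", cohort)
  if (abs(sum(pool$freq) - 1) > 1e-9)
    stop("haplotype frequencies do not sum to 1")
  n <- cfg$n_individuals[[cohort]]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((cfg$seed + 7L * match(cohort, names(cfg$n_individuals))) %%
             .Machine$integer.max)
  idx <- matrix(sample.int(length(pool$haplotypes), 2 * n, replace = TRUE,
                           prob = pool$freq), ncol = 2)
  out <- matrix(pool$haplotypes[idx], ncol = 2)
  rownames(out) <- sprintf("%s_%04d", cohort, seq_len(n))
  out
}

hap_allele <- function(haps, pos) as.integer(substring(haps, pos, pos))

# analytic per-allele cis contribution for every pool haplotype
pool_cis_values <- function(cfg, cohort, gene) {
  pool <- cfg$haplotype_pool[[cohort]]
  betas <- cfg$cis_effects[[gene]]
  if (is.null(betas) || !length(betas))
    return(list(c = rep(0, length(pool$haplotypes)), freq = pool$freq))
  pos <- match(names(betas), cfg$site_ids)
  c_vals <- rep(0, length(pool$haplotypes))
  for (t in seq_along(pos))
    c_vals <- c_vals + betas[t] * hap_allele(pool$haplotypes, pos[t])
  list(c = c_vals, freq = pool$freq)
}

# analytic variance of the trans contribution for one cohort
trans_variance <- function(cfg, cohort) {
  tm <- cfg$trans_model
  if (cohort == "SA") {
    age_var <- 4        # age = 17 + Poisson(4)
    sex_var <- 0.42 * (1 - 0.42)
    eth_p <- c(200, 67, 19, 10, 4) / 300
    eff <- tm$ethnicity[c("Cape mixed-ancestry", "black African", "Indian",
                          "white", "other")]
    eth_var <- sum(eth_p * eff^2) - sum(eth_p * eff)^2
  } else {
    age_var <- 14^2     # age ~ round(N(63, 14)), clipped
    sex_var <- 0.25
    eth_var <- 0
  }
  tm$age^2 * age_var + tm$sex^2 * sex_var + eth_var + tm$resid_sd^2
}

# exact Var(log(e^c1 + e^c2)) for c1, c2 iid over the pool cis values
logsum_variance <- function(cis) {
  K <- length(cis$c)
  w <- outer(cis$freq, cis$freq)
  u <- log(outer(exp(cis$c), exp(cis$c), "+"))
  mu <- sum(w * u)
  sum(w * (u - mu)^2)
}

pool_cis_variance <- function(cis) {
  mu <- sum(cis$freq * cis$c)
  sum(cis$freq * (cis$c - mu)^2)
}

simulate_covariates <- function(cfg, cohort, ids) {
  n <- length(ids)
  if (cohort == "SA") {
    age <- 17 + stats::rpois(n, 4)
    sex <- ifelse(stats::rbinom(n, 1, 0.42) == 1, "M", "F")
    ethnicity <- sample(c("Cape mixed-ancestry", "black African", "Indian",
                          "white", "other"), n, replace = TRUE,
                        prob = c(200, 67, 19, 10, 4) / 300)
  } else {
    age <- pmin(pmax(round(stats::rnorm(n, 63, 14)), 25), 101)
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
    ethnicity <- rep("white", n)
  }
  data.frame(individual_id = ids, age = age, sex = sex,
             ethnicity = ethnicity, stringsAsFactors = FALSE)
}

#' Simulate expression data for one cohort
#'
#' Per haplotype, log allele expression = gene baseline + sum of cis
#' effects of the alleles it carries + the individual's trans
#' contribution (covariates + residual, shared by both alleles, so the
#' allelic ratio is trans-free by construction).  Heterozygotes at a
#' transcribed marker yield cDNA ratio = (numerator-allele expression /
#' other-allele expression) x marker dispersion x assay bias x replicate
#' noise; gDNA ratio = assay bias x replicate noise.  Ct tables encode
#' the total expression of both alleles against three reference genes.
#'
#' @param haplotypes matrix from [simulate_haplotypes()].
#' @param cfg an `aeqtl_sim_config`.
#' @param cohort cohort label.
#' @return list with `genotypes` ([genotype_table()]), `aer` (replicate
#'   measurements), `ct`, `covariates`, `truth`, `flags` (e.g. markers
#'   monomorphic in the pool).
#' @export
simulate_expression <- function(haplotypes, cfg, cohort) {
  for (g in names(cfg$cis_effects))
    if (!all(names(cfg$cis_effects[[g]]) %in% cfg$site_ids))
      stop("cis-effect SNP absent from haplotypes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((cfg$seed + 1009L * match(cohort, names(cfg$n_individuals))) %%
             .Machine$integer.max)
  ids <- rownames(haplotypes)
  n <- length(ids)
  s <- length(cfg$site_ids)
  genes <- unique(cfg$markers$gene)
  flags <- character(0)

  # genotypes at every site (mapping SNPs + markers)
  a1 <- do.call(cbind, lapply(seq_len(s), function(p) hap_allele(haplotypes[, 1], p)))
  a2 <- do.call(cbind, lapply(seq_len(s), function(p) hap_allele(haplotypes[, 2], p)))
  geno <- a1 + a2
  dimnames(geno) <- list(ids, cfg$site_ids)
  if (cfg$geno_missing_rate > 0) {
    miss <- matrix(stats::runif(n * s) < cfg$geno_missing_rate, n, s)
    geno[miss] <- NA_integer_
  }
  snps <- data.frame(snp_id = cfg$site_ids, chrom = "9",
                     pos = 21958155L + 2800L * (seq_len(s) - 1L),
                     allele_ref = "A", allele_alt = "G",
                     stringsAsFactors = FALSE)
  gt <- genotype_table(geno, snps, cohort = rep(cohort, n))

  covariates <- simulate_covariates(cfg, cohort, ids)
  tm <- cfg$trans_model
  cov_part <- tm$age * (covariates$age - mean(covariates$age)) +
    tm$sex * (covariates$sex == "M") +
    unname(tm$ethnicity[covariates$ethnicity])

  aer_rows <- list(); ct_rows <- list()
  truth <- list(haplotypes = haplotypes, beta = cfg$cis_effects,
                v_cis = list(), var_log_total = list(), cis_fraction = list(),
                trans_variance = trans_variance(cfg, cohort))
  noise_sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  ref_base <- c(ct_b2m = 18, ct_gapd = 19, ct_hprt1 = 24)
  ct_gene_base <- stats::setNames(28 - cfg$baseline[genes] / log(2), genes)
  loading <- stats::rnorm(n, 0, 0.3)   # per-sample RNA amount, cancels in delta-Ct

  for (g in genes) {
    betas <- cfg$cis_effects[[g]]
    cis_of <- function(h) {
      v <- rep(0, length(h))
      for (b in names(betas))
        v <- v + betas[[b]] * hap_allele(h, match(b, cfg$site_ids))
      v
    }
    c1 <- cis_of(haplotypes[, 1]); c2 <- cis_of(haplotypes[, 2])
    trans <- cov_part + stats::rnorm(n, 0, tm$resid_sd)
    x1 <- cfg$baseline[[g]] + c1 + trans
    x2 <- cfg$baseline[[g]] + c2 + trans
    total <- exp(x1) + exp(x2)

    mk <- cfg$markers$marker_id[cfg$markers$gene == g]
    for (k in mk) {
      pos <- match(k, cfg$site_ids)
      al1 <- hap_allele(haplotypes[, 1], pos)
      al2 <- hap_allele(haplotypes[, 2], pos)
      pool_al <- hap_allele(cfg$haplotype_pool[[cohort]]$haplotypes, pos)
      if (length(unique(pool_al)) == 1) {
        flags <- c(flags, sprintf(
          "marker %s is monomorphic in the %s pool: no heterozygotes possible",
          k, cohort))
      }
      het <- which(al1 != al2)
      num <- if (cfg$markers$numerator_allele[match(k, cfg$markers$marker_id)] ==
                   "coded") 1L else 0L
      if (length(het)) {
        num_is_h1 <- al1[het] == num
        xn <- ifelse(num_is_h1, x1[het], x2[het])
        xd <- ifelse(num_is_h1, x2[het], x1[het])
        true_ratio <- exp(xn - xd +
                            stats::rnorm(length(het), 0, cfg$marker_sd[[k]]))
        nrep <- cfg$n_replicates
        for (tmpl in c("cDNA", "gDNA")) {
          base <- if (tmpl == "cDNA") true_ratio * cfg$assay_bias[[k]]
                  else rep(cfg$assay_bias[[k]], length(het))
          reps <- rep(base, each = nrep) *
            exp(stats::rnorm(nrep * length(het), 0, noise_sdlog))
          aer_rows[[length(aer_rows) + 1]] <- data.frame(
            individual_id = rep(ids[het], each = nrep), gene = g,
            marker_id = k, template = tmpl,
            replicate = rep(seq_len(nrep), times = length(het)),
            ratio = reps, stringsAsFactors = FALSE)
        }
      }
    }

    for (r in seq_len(cfg$n_replicates)) {
      ct_rows[[length(ct_rows) + 1]] <- data.frame(
        individual_id = ids, gene = g,
        ct_target = ct_gene_base[[g]] - log2(total) + loading +
          stats::rnorm(n, 0, cfg$ct_sd),
        ct_b2m = ref_base[["ct_b2m"]] + loading + stats::rnorm(n, 0, cfg$ct_sd),
        ct_gapd = ref_base[["ct_gapd"]] + loading + stats::rnorm(n, 0, cfg$ct_sd),
        ct_hprt1 = ref_base[["ct_hprt1"]] + loading + stats::rnorm(n, 0, cfg$ct_sd),
        stringsAsFactors = FALSE)
    }

    cis <- pool_cis_values(cfg, cohort, g)
    v_c <- pool_cis_variance(cis)
    v_tot <- truth$trans_variance + logsum_variance(cis)
    truth$v_cis[[g]] <- v_c
    truth$var_log_total[[g]] <- v_tot
    truth$cis_fraction[[g]] <- v_c / v_tot
  }

  list(genotypes = gt,
       aer = do.call(rbind, aer_rows),
       ct = do.call(rbind, ct_rows),
       covariates = covariates,
       truth = truth, flags = flags)
}

#' Simulate the full two-cohort dataset
#'
#' @param cfg an `aeqtl_sim_config` (default [default_sim_config()]).
#' @return object of class `aeqtl_sim`: `genotypes` (all cohorts),
#'   `aer`, `ct`, `covariates`, `truth` (per cohort), `flags`, `config`.
#' @export
simulate_dataset <- function(cfg = default_sim_config()) {
  per <- lapply(names(cfg$n_individuals), function(co) {
    haps <- simulate_haplotypes(cfg, co)
    simulate_expression(haps, cfg, co)
  })
  names(per) <- names(cfg$n_individuals)
  geno <- do.call(rbind, lapply(per, function(x) x$genotypes$geno))
  cohort <- unlist(lapply(names(per), function(co)
    rep(co, nrow(per[[co]]$genotypes$geno))))
  gt <- genotype_table(geno, per[[1]]$genotypes$snps, cohort)
  structure(list(
    genotypes = gt,
    aer = do.call(rbind, lapply(per, `[[`, "aer")),
    ct = do.call(rbind, lapply(per, `[[`, "ct")),
    covariates = do.call(rbind, lapply(per, `[[`, "covariates")),
    truth = lapply(per, `[[`, "truth"),
    flags = unlist(lapply(per, `[[`, "flags")),
    config = cfg), class = "aeqtl_sim")
}

#' @export
print.aeqtl_sim <- function(x, ...) {
  cat(sprintf("aeqtl_sim: %d individuals, %d sites, %d AER records, seed %d\n",
              nrow(x$genotypes$geno), ncol(x$genotypes$geno),
              if (is.null(x$aer)) 0L else nrow(x$aer), x$config$seed))
  invisible(x)
}

#' Simulate a PCR-product mixing series
#'
#' Emits assay measurements whose true allele-1:allele-2 content equals
#' each mixing level times the assay bias, for checking linearity of the
#' ratio readout (levels 8:1, 4:1, 1:1, 1:4, 1:8 by default).
#'
#' @param marker_id assay label.
#' @param levels positive true mixing ratios.
#' @param bias multiplicative assay bias.
#' @param cv fractional replicate noise.
#' @param n_replicates replicates per level.
#' @param seed integer seed.
#' @return data frame: `marker_id`, `level`, `replicate`, `ratio`.
#' @export
simulate_mixing_series <- function(marker_id, levels = c(8, 4, 1, 1 / 4, 1 / 8),
                                   bias = 1, cv = 0.05, n_replicates = 4,
                                   seed = 1L) {
  if (any(levels <= 0)) stop("mixing levels must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  do.call(rbind, lapply(levels, function(lv) data.frame(
    marker_id = marker_id, level = lv, replicate = seq_len(n_replicates),
    ratio = lv * bias * exp(stats::rnorm(n_replicates, 0, sdlog)),
    stringsAsFactors = FALSE)))
}

#' Write a simulated dataset to disk
#'
#' Genotypes as wide TSV and minimal VCF, AER and Ct tables as TSV,
#' covariates as TSV, truth record as JSON.
#'
#' @param sim an `aeqtl_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$aer, file.path(dir, "aer_measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ct, file.path(dir, "ct_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  for (co in names(truth)) truth[[co]]$haplotypes <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
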