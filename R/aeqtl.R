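# Core aeQTL machinery: phase indicators, mixture log-likelihood over
# phase configurations, maximum-likelihood fitting, likelihood-ratio
# tests, and the per-SNP scan.
#
# Model: for individual j heterozygous at transcribed markers k with log
# allelic ratios I_jk, and phase configuration g with posterior P(g|T_j),
#   log L = sum_j log sum_g P(g|T_j) prod_k N(I_jk; mu_gk, sigma2_k),
#   mu_gk = sum_i beta_i * X_ik(g),
# where X_ik(g) is +1 when the coded allele of mapping SNP i lies on the
# haplotype carrying the numerator allele of marker k, -1 when it lies on
# the other haplotype, and 0 when the individual is homozygous at i.

#' Phase indicators for one phase configuration
#'
#' @param h1,h2 haplotype strings (subset order) of the configuration.
#' @param subset_snps SNP ids in haplotype-string order.
#' @param model_snps mapping SNPs entering the model.
#' @param marker_id transcribed marker (must be heterozygous in the
#'   configuration).
#' @param numerator_allele `"coded"` (allele 1, default) or `"noncoded"`:
#'   which marker allele is the ratio numerator.
#' @return integer vector of X in `{-1, 0, +1}`, named by `model_snps`.
#' @export
build_phase_indicators <- function(h1, h2, subset_snps, model_snps,
                                   marker_id, numerator_allele = "coded") {
  if (is.null(numerator_allele) || !numerator_allele %in% c("coded", "noncoded"))
    stop("marker orientation metadata missing or invalid")
  mk <- match(marker_id, subset_snps)
  si <- match(model_snps, subset_snps)
  if (is.na(mk) || anyNA(si))
    stop("phase configuration does not cover all modelled SNPs and the marker")
  a1 <- substring(h1, mk, mk); a2 <- substring(h2, mk, mk)
  if (a1 == a2) stop("marker ", marker_id, " is homozygous in this configuration")
  num <- if (numerator_allele == "coded") "1" else "0"
  num_hap <- if (a1 == num) h1 else h2
  other <- if (a1 == num) h2 else h1
  x <- integer(length(model_snps))
  for (t in seq_along(si)) {
    bn <- substring(num_hap, si[t], si[t])
    bo <- substring(other, si[t], si[t])
    x[t] <- if (bn == bo) 0L else if (bn == "1") 1L else -1L
  }
  stats::setNames(x, model_snps)
}

#' Assemble the fitting structure for the mixture likelihood
#'
#' Joins normalized log allelic ratios with phase posteriors and expands
#' every (individual, configuration, marker) combination into a flat
#' design used by [aer_loglik()] and [fit_aeqtl()].  Only individuals
#' with a measured `I` at >= 1 marker at which they are heterozygous
#' enter; an individual's markers lacking measurements are simply absent.
#'
#' @param aer normalized AER data frame (needs `individual_id`,
#'   `marker_id`, `I`); rows must correspond to marker heterozygotes.
#' @param posteriors a `phase_posterior`, or a list of them (one per
#'   cohort) whose individuals are disjoint.
#' @param model_snps character vector (possibly empty) of mapping SNPs.
#' @param markers data frame with `marker_id` and `numerator_allele`
#'   (`"coded"`/`"noncoded"`); see [marker_table()].
#' @return object of class `aeqtl_data` (flat arrays + index vectors).
#' @export
prepare_aeqtl_data <- function(aer, posteriors, model_snps, markers) {
  if (inherits(posteriors, "phase_posterior")) posteriors <- list(posteriors)
  rows_I <- c(); rows_k <- c(); rows_jc <- c(); X_rows <- list()
  logp <- c(); jc_of_ind <- c(); ind_ids <- character(0)
  jc <- 0L
  for (post in posteriors) {
    subset_snps <- attr(post, "snps")
    mk_here <- intersect(markers$marker_id, subset_snps)
    for (id in names(post)) {
      a <- aer[aer$individual_id == id & aer$marker_id %in% mk_here &
                 is.finite(aer$I), , drop = FALSE]
      if (!nrow(a)) next
      cfgs <- post[[id]]
      # keep only markers heterozygous in the phase configurations (all
      # configurations of one individual share the genotype)
      het_mk <- a$marker_id[vapply(a$marker_id, function(m) {
        p <- match(m, subset_snps)
        substring(cfgs$h1[1], p, p) != substring(cfgs$h2[1], p, p)
      }, logical(1))]
      a <- a[a$marker_id %in% het_mk, , drop = FALSE]
      if (!nrow(a)) next
      ind_ids <- c(ind_ids, id)
      for (c_i in seq_len(nrow(cfgs))) {
        jc <- jc + 1L
        logp <- c(logp, log(cfgs$prob[c_i]))
        jc_of_ind <- c(jc_of_ind, length(ind_ids))
        for (r in seq_len(nrow(a))) {
          rows_I <- c(rows_I, a$I[r])
          rows_k <- c(rows_k, a$marker_id[r])
          rows_jc <- c(rows_jc, jc)
          X_rows[[length(X_rows) + 1]] <-
            if (length(model_snps))
              build_phase_indicators(
                cfgs$h1[c_i], cfgs$h2[c_i], subset_snps, model_snps,
                a$marker_id[r],
                markers$numerator_allele[match(a$marker_id[r], markers$marker_id)])
            else integer(0)
        }
      }
    }
  }
  if (!length(rows_I)) stop("no usable individuals: no heterozygous marker measurements")
  marker_ids <- sort(unique(rows_k))
  structure(list(
    I = rows_I,
    k_idx = match(rows_k, marker_ids),
    jc = rows_jc,
    logp = logp,
    jc_ind = jc_of_ind,
    X = if (length(model_snps))
      matrix(unlist(X_rows), ncol = length(model_snps), byrow = TRUE,
             dimnames = list(NULL, model_snps))
    else matrix(0, length(rows_I), 0),
    model_snps = model_snps, marker_ids = marker_ids,
    individuals = ind_ids, n = length(ind_ids)),
    class = "aeqtl_data")
}

#' Mixture log-likelihood of allelic expression ratios
#'
#' Evaluates the phase-uncertainty mixture likelihood: within each phase
#' configuration the marker ratios are conditionally independent normals
#' with genotype-dependent means and marker-specific variances; the
#' configurations are mixed with their posterior probabilities.
#' Computed with the log-sum-exp trick.
#'
#' @param beta named numeric vector of SNP effects (natural-log allelic
#'   fold per phase unit); may be empty.
#' @param sigma2 named numeric vector of per-marker variances (> 0).
#' @param data an `aeqtl_data` from [prepare_aeqtl_data()].
#' @return the log-likelihood (a single number).
#' @export
aer_loglik <- function(beta, sigma2, data) {
  stopifnot(inherits(data, "aeqtl_data"))
  if (length(beta) != length(data$model_snps))
    stop("beta must match the modelled SNPs")
  s2 <- sigma2[data$marker_ids]
  if (anyNA(s2) || any(s2 <= 0)) stop("sigma2 must be positive for every marker")
  mu <- if (length(beta)) drop(data$X %*% beta) else 0
  ld <- stats::dnorm(data$I, mean = mu, sd = sqrt(s2[data$k_idx]), log = TRUE)
  ll_jc <- drop(rowsum(ld, data$jc)) + data$logp
  grp <- data$jc_ind
  mx <- unname(tapply(ll_jc, grp, max))
  sum(mx + log(drop(rowsum(exp(ll_jc - mx[grp]), grp))))
}

#' Maximum-likelihood fit of the aeQTL model
#'
#' Maximizes the mixture likelihood over the SNP effects and the
#' per-marker variances (optimized on the log scale) with BFGS and
#' seeded multi-starts.  With no modelled SNPs the MLE is closed form
#' (`sigma2_k = mean(I_k^2)`).  Identifiability requires every modelled
#' SNP to have at least one informative phase indicator (`X != 0`).
#'
#' @param data an `aeqtl_data` from [prepare_aeqtl_data()].
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the random restarts.
#' @param se compute standard errors from the observed information
#'   (numerical Hessian) at the optimum.
#' @param marker_intercepts add a free intercept per marker to the mean
#'   (absorbs residual assay bias that gDNA normalization missed, at the
#'   cost of power; default off).
#' @return object of class `aeqtl_fit`: `loglik`, `beta`, `beta_se`,
#'   `sigma2`, `sigma2_se`, `alpha` (marker intercepts, if requested),
#'   `n`, `individuals`, `convergence`, `n_params`.
#' @export
fit_aeqtl <- function(data, n_starts = 5, seed = 1L, se = TRUE,
                      marker_intercepts = FALSE) {
  stopifnot(inherits(data, "aeqtl_data"))
  p <- length(data$model_snps)
  m <- length(data$marker_ids)
  if (p > 0) {
    informative <- colSums(data$X != 0) > 0
    if (!all(informative))
      stop("model not identifiable: no informative double heterozygote for SNP ",
           paste(data$model_snps[!informative], collapse = ", "))
  }
  if (p == 0) {
    # closed form: the configuration mixture is degenerate in the mean
    # (mu does not depend on phase), so the per-marker normal MLEs apply
    # to the unique (individual, marker) observations; observations
    # repeat once per configuration, so keep each individual's first
    # configuration only.
    keep <- data$jc %in% match(unique(data$jc_ind), data$jc_ind)
    nk <- vapply(seq_len(m), function(k)
      sum(keep & data$k_idx == k), numeric(1))
    alpha <- if (marker_intercepts)
      vapply(seq_len(m), function(k)
        mean(data$I[keep & data$k_idx == k]), numeric(1))
    else rep(0, m)
    s2 <- vapply(seq_len(m), function(k)
      mean((data$I[keep & data$k_idx == k] - alpha[k])^2), numeric(1))
    names(s2) <- data$marker_ids; names(alpha) <- data$marker_ids
    if (any(s2 < 1e-12))
      stop("variance estimate at zero boundary; data appear degenerate")
    ll_fun <- function() {
      ld <- stats::dnorm(data$I, alpha[data$k_idx], sqrt(s2[data$k_idx]),
                         log = TRUE)
      ll_jc <- drop(rowsum(ld, data$jc)) + data$logp
      grp <- data$jc_ind
      mx <- unname(tapply(ll_jc, grp, max))
      sum(mx + log(drop(rowsum(exp(ll_jc - mx[grp]), grp))))
    }
    ll <- if (marker_intercepts) ll_fun() else aer_loglik(numeric(0), s2, data)
    return(structure(list(loglik = ll,
                          beta = stats::setNames(numeric(0), character(0)),
                          beta_se = numeric(0), sigma2 = s2,
                          sigma2_se = if (se) s2 * sqrt(2 / nk) else NULL,
                          alpha = if (marker_intercepts) alpha else NULL,
                          n = data$n, individuals = data$individuals,
                          convergence = 0L,
                          n_params = m * (1 + marker_intercepts)),
                     class = "aeqtl_fit"))
  }
  n_alpha <- if (marker_intercepts) m else 0
  s2_at <- p + n_alpha + seq_len(m)
  negll <- function(par) {
    # keep the objective finite so line searches can back off from
    # extreme variance excursions
    if (any(!is.finite(par)) || any(par[s2_at] < -40) ||
        any(par[s2_at] > 40)) return(1e12)
    beta <- par[seq_len(p)]
    alpha <- if (n_alpha) par[p + seq_len(m)] else rep(0, m)
    s2 <- exp(par[s2_at])
    mu <- drop(data$X %*% beta) + alpha[data$k_idx]
    ld <- stats::dnorm(data$I, mu, sqrt(s2[data$k_idx]), log = TRUE)
    ll_jc <- drop(rowsum(ld, data$jc)) + data$logp
    grp <- data$jc_ind
    mx <- unname(tapply(ll_jc, grp, max))
    v <- -sum(mx + log(drop(rowsum(exp(ll_jc - mx[grp]), grp))))
    if (!is.finite(v)) 1e12 else v
  }
  keep <- data$jc %in% match(unique(data$jc_ind), data$jc_ind)
  v0 <- max(stats::var(data$I[keep]), 1e-4)
  start0 <- c(rep(0, p + n_alpha), rep(log(v0), m))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- list(start0)
  for (i in seq_len(max(0, n_starts - 1)))
    starts[[i + 1]] <- start0 + stats::rnorm(p + n_alpha + m, sd = 0.3)
  fits <- lapply(starts, function(s0)
    tryCatch(stats::optim(s0, negll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("optimization failed from every start")
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  if (best$convergence != 0)
    stop("optimizer did not converge (code ", best$convergence, ")")
  par <- best$par
  s2_hat <- exp(par[s2_at])
  if (any(s2_hat < 1e-12))
    stop("sigma^2 at zero boundary; data appear degenerate (no residual variation)")
  npar <- p + n_alpha + m
  beta_se <- rep(NA_real_, p); s2_se <- rep(NA_real_, m)
  if (se) {
    H <- stats::optimHess(par, negll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
    beta_se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
    s2_se <- sqrt(pmax(diag(V)[s2_at], 0)) * s2_hat  # delta method
  }
  structure(list(
    loglik = -best$value,
    beta = stats::setNames(par[seq_len(p)], data$model_snps),
    beta_se = stats::setNames(beta_se, data$model_snps),
    sigma2 = stats::setNames(s2_hat, data$marker_ids),
    sigma2_se = stats::setNames(s2_se, data$marker_ids),
    alpha = if (marker_intercepts)
      stats::setNames(par[p + seq_len(m)], data$marker_ids) else NULL,
    n = data$n, individuals = data$individuals,
    convergence = best$convergence, n_params = npar),
    class = "aeqtl_fit")
}

#' @export
print.aeqtl_fit <- function(x, ...) {
  cat(sprintf("aeqtl_fit: logL = %.4f, n = %d\n", x$loglik, x$n))
  if (length(x$beta)) {
    cat("effects (beta, natural-log fold):\n")
    print(round(rbind(beta = x$beta, se = x$beta_se, fold = exp(x$beta)), 4))
  }
  cat("marker variances:\n"); print(round(x$sigma2, 5))
  invisible(x)
}

#' Likelihood-ratio test between nested aeQTL fits
#'
#' @param full,null `aeqtl_fit` objects on the identical individual set,
#'   with the null model's SNPs a subset of the full model's.
#' @return data frame: `stat`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  if (!setequal(full$individuals, null$individuals) ||
      length(full$individuals) != length(null$individuals))
    stop("full and null fits must use the identical individual set")
  if (!all(names(null$beta) %in% names(full$beta)))
    stop("models are not nested")
  df <- full$n_params - null$n_params
  if (df < 0) stop("models are not nested (null has more parameters)")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  data.frame(stat = stat, df = df,
             p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fold change from an allelic effect
#'
#' Under the additive-on-log model a coded-allele copy multiplies its
#' allele's expression by `exp(beta)`, so both the heterozygote allelic
#' ratio and the coded-homozygote vs other-homozygote total expression
#' equal `exp(beta)`.
#'
#' @param beta effect on the natural-log scale.
#' @return fold change.
#' @export
effect_to_fold <- function(beta) exp(beta)

#' Marker metadata table
#'
#' @param marker_id transcribed marker ids.
#' @param gene gene of each marker.
#' @param numerator_allele `"coded"` or `"noncoded"` per marker.
#' @return data frame used by the fitting and scanning functions.
#' @export
marker_table <- function(marker_id, gene,
                         numerator_allele = rep("coded", length(marker_id))) {
  stopifnot(length(gene) == length(marker_id),
            all(numerator_allele %in% c("coded", "noncoded")))
  data.frame(marker_id = marker_id, gene = gene,
             numerator_allele = numerator_allele, stringsAsFactors = FALSE)
}

#' Count informative heterozygotes
#'
#' An informative heterozygote for a (SNP, gene) pair is an individual
#' heterozygous at the tested SNP and heterozygous (with a measured
#' ratio) at >= 1 transcribed marker of the gene.
#'
#' @param gt a [genotype_table()].
#' @param aer normalized AER data frame.
#' @param snp tested SNP id.
#' @param marker_ids transcribed markers of the gene.
#' @return character vector of informative individual ids.
#' @export
informative_heterozygotes <- function(gt, aer, snp, marker_ids) {
  het_snp <- rownames(gt$geno)[!is.na(gt$geno[, snp]) & gt$geno[, snp] == 1L]
  has_marker <- unique(aer$individual_id[aer$marker_id %in% marker_ids &
                                           is.finite(aer$I)])
  # marker heterozygosity is implied by the existence of a ratio, but
  # check against the genotype table where the marker is typed
  typed <- intersect(marker_ids, colnames(gt$geno))
  if (length(typed)) {
    het_any <- rownames(gt$geno)[rowSums(gt$geno[, typed, drop = FALSE] == 1L,
                                         na.rm = TRUE) > 0]
    has_marker <- intersect(has_marker, het_any)
  }
  intersect(het_snp, has_marker)
}

#' Per-SNP aeQTL scan with nested-model adjustment
#'
#' For each tested SNP, phases the subset (gene markers + adjustment SNPs
#' + tested SNP) separately per cohort, fits the full and null mixture
#' models on the identical individual set, and reports the 1-df
#' likelihood-ratio test with Bonferroni family-wise error rates.  SNPs
#' with fewer than `min_informative` informative heterozygotes are
#' excluded and flagged; SNPs absent from the genotype table are flagged
#' and the scan continues.
#'
#' @param aer normalized AER data frame for one gene's markers.
#' @param gt a [genotype_table()].
#' @param gene gene label.
#' @param snps SNPs to test.
#' @param markers [marker_table()] (restricted to this gene's markers).
#' @param adjust character vector of SNPs to condition on.
#' @param min_informative minimum informative heterozygotes (default 8).
#' @param m_tests Bonferroni multiplier (default: number of SNPs tested).
#' @param n_starts,seed optimizer options passed to [fit_aeqtl()].
#' @return data frame of class `aeqtl_scan`, one row per SNP:
#'   `snp_id, gene, beta, se, fold, lrt, df, p, neg_log10_p, fwer,
#'   neg_log10_fwer, n_informative, n_used, excluded, reason`.
#' @export
scan_snps <- function(aer, gt, gene, snps, markers, adjust = character(0),
                      min_informative = 8, m_tests = NULL,
                      n_starts = 3, seed = 1L) {
  markers <- markers[markers$gene == gene, , drop = FALSE]
  if (!nrow(markers)) stop("no markers for gene ", gene)
  snps <- setdiff(snps, c(adjust, markers$marker_id))
  if (is.null(m_tests)) m_tests <- length(snps)
  rows <- lapply(snps, function(s) {
    blank <- data.frame(snp_id = s, gene = gene, beta = NA_real_, se = NA_real_,
                        fold = NA_real_, lrt = NA_real_, df = NA_integer_,
                        p = NA_real_, neg_log10_p = NA_real_, fwer = NA_real_,
                        neg_log10_fwer = NA_real_, n_informative = NA_integer_,
                        n_used = NA_integer_, excluded = TRUE,
                        reason = "", stringsAsFactors = FALSE)
    if (!s %in% colnames(gt$geno)) {
      blank$reason <- "SNP absent from genotype table"
      return(blank)
    }
    inf_ids <- informative_heterozygotes(gt, aer, s, markers$marker_id)
    blank$n_informative <- length(inf_ids)
    if (length(inf_ids) < min_informative) {
      blank$reason <- sprintf("fewer than %d informative heterozygotes",
                              min_informative)
      return(blank)
    }
    subset_snps <- unique(c(markers$marker_id, adjust, s))
    res <- tryCatch({
      posts <- lapply(unique(gt$cohort), function(co)
        phase_posteriors(em_haplotype_freqs(gt, subset_snps, cohort = co), gt))
      dat_full <- prepare_aeqtl_data(aer, posts, c(adjust, s), markers)
      dat_null <- prepare_aeqtl_data(aer, posts, adjust, markers)
      # enforce identical individual sets for the nested comparison
      if (!setequal(dat_full$individuals, dat_null$individuals))
        stop("individual sets differ between nested models")
      full <- fit_aeqtl(dat_full, n_starts = n_starts, seed = seed, se = TRUE)
      null <- fit_aeqtl(dat_null, n_starts = n_starts, seed = seed, se = FALSE)
      tst <- lrt(full, null)
      data.frame(snp_id = s, gene = gene,
                 beta = unname(full$beta[s]), se = unname(full$beta_se[s]),
                 fold = effect_to_fold(unname(full$beta[s])),
                 lrt = tst$stat, df = tst$df, p = tst$p,
                 neg_log10_p = -log10(max(tst$p, .Machine$double.xmin)),
                 fwer = min(1, m_tests * tst$p),
                 neg_log10_fwer = -log10(max(min(1, m_tests * tst$p),
                                             .Machine$double.xmin)),
                 n_informative = length(inf_ids), n_used = full$n,
                 excluded = FALSE, reason = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      blank$reason <- conditionMessage(e)
      blank
    })
    res
  })
  out <- do.call(rbind, rows)
  # deterministic ordering: by genomic position (tie-break for equal P)
  pos <- gt$snps$pos[match(out$snp_id, gt$snps$snp_id)]
  out <- out[order(pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  attr(out, "adjust") <- adjust
  class(out) <- c("aeqtl_scan", class(out))
  out
}

#' Stratified allelic-ratio diagnostic
#'
#' Splits the normalized allelic expression ratios of one marker's
#' heterozygotes by genotype class (homozygous vs heterozygous) at a
#' conditioning SNP, reports group means, a two-sided Mann-Whitney test
#' between the classes, and the gDNA reference column (mean 1 under
#' population-mean normalization).
#'
#' @param aer normalized cDNA AER data frame.
#' @param gdna normalized gDNA AER data frame (same normalization), or
#'   `NULL`.
#' @param marker_id transcribed marker.
#' @param snp conditioning SNP.
#' @param gt a [genotype_table()].
#' @return list: `groups` (data frame of class, n, mean ratio), `p`
#'   (Mann-Whitney, `NA` when a class has < 2 individuals), `gdna_mean`.
#' @export
stratified_aer <- function(aer, gdna = NULL, marker_id, snp, gt) {
  a <- aer[aer$marker_id == marker_id & is.finite(aer$I), , drop = FALSE]
  gsnp <- gt$geno[match(a$individual_id, rownames(gt$geno)), snp]
  keep <- !is.na(gsnp)
  a <- a[keep, , drop = FALSE]; gsnp <- gsnp[keep]
  cls <- ifelse(gsnp == 1L, "heterozygous", "homozygous")
  groups <- do.call(rbind, lapply(c("homozygous", "heterozygous"), function(cl) {
    r <- a$norm_ratio[cls == cl]
    data.frame(class = cl, n = length(r),
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  p <- if (all(groups$n >= 2))
    stats::wilcox.test(a$norm_ratio[cls == "homozygous"],
                       a$norm_ratio[cls == "heterozygous"],
                       exact = FALSE)$p.value
  else NA_real_
  gdna_mean <- if (!is.null(gdna)) {
    g <- gdna[gdna$marker_id == marker_id & is.finite(gdna$norm_ratio), ]
    mean(g$norm_ratio)
  } else NA_real_
  list(groups = groups, p = p, gdna_mean = gdna_mean)
}
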