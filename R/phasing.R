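# Haplotypes over a SNP subset are encoded as strings of 0/1 in subset
# order ("0" = reference/non-coded allele, "1" = coded allele).

hap_strings <- function(n_snps) {
  if (n_snps == 1) return(c("0", "1"))
  # string position p is bit p of (index - 1): expand.grid varies the
  # first factor fastest, so columns are already in position order
  grid <- expand.grid(rep(list(c("0", "1")), n_snps))
  apply(grid, 1, paste, collapse = "")
}

# Enumerate unordered haplotype pairs (as indices into hap_strings order)
# compatible with one complete genotype vector.
compatible_pairs <- function(gvec) {
  s <- length(gvec)
  het <- which(gvec == 1L)
  base <- ifelse(gvec == 2L, 1L, 0L)
  pow <- 2L^(seq_len(s) - 1L)
  if (!length(het)) {
    idx <- sum(base * pow) + 1L
    return(matrix(idx, ncol = 2))
  }
  n_free <- length(het) - 1L
  n_cfg <- 2L^n_free
  h1 <- matrix(rep(base, n_cfg), nrow = n_cfg, byrow = TRUE)
  h2 <- h1
  if (n_free > 0) {
    bits <- t(vapply(0:(n_cfg - 1L),
                     function(v) as.integer(bitwAnd(bitwShiftR(v, 0:(n_free - 1L)), 1L)),
                     integer(n_free)))
    h1[, het[-1]] <- bits
    h2[, het[-1]] <- 1L - bits
  }
  h1[, het[1]] <- 0L
  h2[, het[1]] <- 1L
  cbind(h1 %*% pow + 1L, h2 %*% pow + 1L)
}

#' Haplotype-frequency estimation by EM under HWE
#'
#' Fits haplotype frequencies for a small SNP subset within one cohort by
#' expectation-maximisation, treating each individual's diplotype as
#' missing data.  Under Hardy-Weinberg equilibrium a diplotype `(h1, h2)`
#' has prior probability `f[h1] * f[h2]`, doubled when `h1 != h2`.
#' Individuals missing any subset genotype contribute no information and
#' are excluded (recorded in the result).  Initialisation is the uniform
#' frequency vector, so the fit is deterministic; optional random
#' multi-starts guard against the (rare, small-subset) local optima.
#'
#' @param gt a [genotype_table()].
#' @param snp_subset character vector of >= 1 SNP ids.
#' @param cohort optional cohort label (default: all individuals).
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter maximum EM iterations.
#' @param n_starts number of additional random restarts (0 = deterministic
#'   uniform start only).
#' @param seed RNG seed used only when `n_starts > 0`.
#' @return object of class `haplotype_model`: list with `snps`, `cohort`,
#'   `freq` (named by haplotype string), `loglik` (trace), `iterations`,
#'   `converged`, `n_used`, `excluded`.
#' @export
em_haplotype_freqs <- function(gt, snp_subset, cohort = NULL,
                               tol = 1e-8, max_iter = 10000,
                               n_starts = 0, seed = 1L) {
  stopifnot(length(snp_subset) >= 1)
  if (!all(snp_subset %in% colnames(gt$geno)))
    stop("SNPs absent from genotype table: ",
         paste(setdiff(snp_subset, colnames(gt$geno)), collapse = ", "))
  g <- gt$geno[, snp_subset, drop = FALSE]
  if (!is.null(cohort)) g <- g[gt$cohort == cohort, , drop = FALSE]
  complete <- stats::complete.cases(g)
  excluded <- rownames(g)[!complete]
  g <- g[complete, , drop = FALSE]
  n <- nrow(g)
  if (n == 0) stop("no individuals with complete genotypes on the subset")
  s <- length(snp_subset)
  haps <- hap_strings(s)

  # collapse to unique genotype patterns
  pat_key <- apply(g, 1, paste, collapse = ",")
  tab <- table(pat_key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  wts <- as.numeric(tab)
  pairs <- lapply(seq_len(nrow(pats)), function(i) compatible_pairs(pats[i, ]))

  run_em <- function(f) {
    ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      counts <- numeric(length(haps))
      ll <- 0
      for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        w <- f[pr[, 1]] * f[pr[, 2]] * ifelse(pr[, 1] != pr[, 2], 2, 1)
        tot <- sum(w)
        if (tot <= 0)
          stop(errorCondition(
            sprintf("genotype pattern %s incompatible with nonzero-frequency haplotypes",
                    paste(pats[i, ], collapse = "/")),
            class = c("aeqtl_phase_error", "error", "condition")))
        post <- w / tot
        ll <- ll + wts[i] * log(tot)
        for (r in seq_len(nrow(pr))) {
          counts[pr[r, 1]] <- counts[pr[r, 1]] + wts[i] * post[r]
          counts[pr[r, 2]] <- counts[pr[r, 2]] + wts[i] * post[r]
        }
      }
      ll_trace <- c(ll_trace, ll)
      f_new <- counts / (2 * n)
      if (length(ll_trace) > 1 && ll < ll_trace[length(ll_trace) - 1] - 1e-9)
        stop("EM log-likelihood decreased; this indicates a bug")
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol)
        return(list(freq = f, loglik = ll_trace, iterations = it, converged = TRUE))
    }
    stop(errorCondition(
      sprintf("EM did not converge in %d iterations (last max change %.3g)",
              max_iter, delta),
      trace = ll_trace, class = c("aeqtl_em_error", "error", "condition")))
  }

  starts <- list(rep(1 / length(haps), length(haps)))
  if (n_starts > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    for (i in seq_len(n_starts)) {
      f0 <- stats::rgamma(length(haps), 1)
      starts[[i + 1]] <- f0 / sum(f0)
    }
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, function(x) max(x$loglik), numeric(1)))]]
  structure(list(snps = snp_subset, cohort = cohort,
                 freq = stats::setNames(best$freq, haps),
                 loglik = best$loglik, iterations = best$iterations,
                 converged = best$converged, n_used = n, excluded = excluded),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("haplotype_model over %d SNPs (%s), %d individuals, %d EM iterations\n",
              length(x$snps), paste(x$snps, collapse = ", "),
              x$n_used, x$iterations))
  f <- sort(x$freq[x$freq > 1e-6], decreasing = TRUE)
  print(round(f, 4))
  invisible(x)
}

#' Posterior phase configurations given unphased genotypes
#'
#' For each individual, lists the diplotypes (ordered pairs of haplotype
#' strings with the first heterozygous subset SNP fixed to allele 0 on
#' haplotype 1, so each unordered configuration appears once) compatible
#' with the unphased genotype, with posterior probabilities proportional
#' to `f[h1] * f[h2]`.  Individuals heterozygous at at most one subset SNP
#' have a single configuration with probability 1.
#'
#' @param model a `haplotype_model` from [em_haplotype_freqs()].
#' @param gt a [genotype_table()] containing the model's SNPs.
#' @param individuals optional ids to restrict to (default: individuals of
#'   the model's cohort with complete subset genotypes).
#' @return object of class `phase_posterior`: named list (by individual)
#'   of data frames with columns `h1`, `h2`, `prob`; attribute `snps`.
#' @export
phase_posteriors <- function(model, gt, individuals = NULL) {
  g <- gt$geno[, model$snps, drop = FALSE]
  if (!is.null(model$cohort)) g <- g[gt$cohort == model$cohort, , drop = FALSE]
  if (!is.null(individuals)) g <- g[rownames(g) %in% individuals, , drop = FALSE]
  g <- g[stats::complete.cases(g), , drop = FALSE]
  haps <- names(model$freq)
  f <- unname(model$freq)
  out <- lapply(seq_len(nrow(g)), function(i) {
    pr <- compatible_pairs(g[i, ])
    w <- f[pr[, 1]] * f[pr[, 2]]
    if (sum(w) <= 0)
      stop(errorCondition(
        sprintf("genotype of individual '%s' has zero probability under the haplotype model",
                rownames(g)[i]),
        class = c("aeqtl_phase_error", "error", "condition")))
    keep <- w > 0
    data.frame(h1 = haps[pr[keep, 1]], h2 = haps[pr[keep, 2]],
               prob = w[keep] / sum(w), stringsAsFactors = FALSE)
  })
  names(out) <- rownames(g)
  structure(out, snps = model$snps, class = "phase_posterior")
}

#' Pairwise linkage-disequilibrium statistics
#'
#' Computes D, D' and r-squared for one SNP pair from 2-SNP haplotype
#' frequencies (estimated by [em_haplotype_freqs()] when a genotype table
#' is supplied).  `d_prime` is signed: `D / Dmax` with the usual
#' sign-dependent `Dmax`.  Monomorphic SNPs give `NA`.
#'
#' @param x either a `haplotype_model` over exactly 2 SNPs or a
#'   [genotype_table()].
#' @param snp_pair character vector of 2 SNP ids (required when `x` is a
#'   genotype table).
#' @param cohort optional cohort label.
#' @return one-row data frame: `snp_a`, `snp_b`, `d`, `d_prime`, `r2`.
#' @export
ld_stats <- function(x, snp_pair = NULL, cohort = NULL) {
  if (inherits(x, "genotype_table")) {
    stopifnot(length(snp_pair) == 2)
    x <- em_haplotype_freqs(x, snp_pair, cohort = cohort)
  }
  if (!inherits(x, "haplotype_model") || length(x$snps) != 2)
    stop("ld_stats needs a 2-SNP haplotype model or a genotype table + snp_pair")
  f <- x$freq  # order: 00, 10, 01, 11 (first SNP is the low bit)
  p_a <- f[["10"]] + f[["11"]]  # coded-allele freq at SNP 1
  p_b <- f[["01"]] + f[["11"]]  # coded-allele freq at SNP 2
  d <- f[["11"]] - p_a * p_b
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    dp <- NA_real_; r2 <- NA_real_
  } else {
    dmax <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
            else min(p_a * p_b, (1 - p_a) * (1 - p_b))
    dp <- if (dmax == 0) NA_real_ else d / dmax
    r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  }
  data.frame(snp_a = x$snps[1], snp_b = x$snps[2],
             d = unname(d), d_prime = unname(dp), r2 = unname(r2),
             stringsAsFactors = FALSE)
}

#' LD matrix over a SNP panel
#'
#' @param gt a [genotype_table()].
#' @param snps SNP ids (default: all).
#' @param cohort optional cohort label.
#' @return data frame with one row per unordered SNP pair.
#' @export
ld_matrix <- function(gt, snps = NULL, cohort = NULL) {
  if (is.null(snps)) snps <- colnames(gt$geno)
  pairs <- utils::combn(snps, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    tryCatch(ld_stats(gt, pairs[, j], cohort),
             error = function(e) data.frame(
               snp_a = pairs[1, j], snp_b = pairs[2, j],
               d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
               stringsAsFactors = FALSE))
  }))
}

# save/restore .Random.seed so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
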