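#' Outlier screen for total expression
#'
#' Algorithmic surrogate for by-eye exclusion of aberrant samples:
#' individuals whose per-gene log expression lies more than `threshold`
#' standard deviations from the gene mean are excluded, and every
#' exclusion is logged.
#'
#' @param expression data frame with `individual_id`, `gene`, `log_expr`.
#' @param threshold |z| cutoff (default 3).
#' @return list with `excluded` (data frame `individual_id`, `gene`, `z`)
#'   and `log`.
#' @export
detect_outliers <- function(expression, threshold = 3) {
  rows <- lapply(split(expression, expression$gene), function(d) {
    z <- (d$log_expr - mean(d$log_expr)) / stats::sd(d$log_expr)
    bad <- which(abs(z) > threshold)
    data.frame(individual_id = d$individual_id[bad], gene = d$gene[bad],
               z = z[bad], stringsAsFactors = FALSE)
  })
  excluded <- do.call(rbind, rows)
  rownames(excluded) <- NULL
  log <- if (nrow(excluded))
    sprintf("outlier excluded: %s (%s, z = %.2f)",
            excluded$individual_id, excluded$gene, excluded$z)
  else character(0)
  list(excluded = excluded, log = log)
}

#' Total-expression (eQTL) scan by linear regression
#'
#' Ordinary least squares of log-normalized expression on the additive
#' genotype (0/1/2 coded-allele copies), with optional age, sex and
#' ethnicity covariates.  Outliers are removed per gene before fitting.
#' Ethnicity categories with a single member are merged into `"other"` to
#' avoid a singular design.  Fold change is reported per two allele
#' copies (coded homozygote vs other homozygote), making it directly
#' comparable with the allelic-expression effect `exp(beta)`.
#'
#' @param expression data frame with `individual_id`, `gene`, `log_expr`
#'   (natural-log scale, e.g. from [delta_ct()]).
#' @param gt a [genotype_table()].
#' @param gene gene to scan.
#' @param snps SNPs to test.
#' @param covariates optional data frame with `individual_id`, `age`,
#'   `sex`, `ethnicity`.
#' @param outlier_threshold |z| cutoff passed to [detect_outliers()]
#'   (`Inf` disables the screen).
#' @param m_tests Bonferroni multiplier (default: number of SNPs tested).
#' @return data frame of class `eqtl_scan`: one row per SNP with
#'   `snp_id, gene, slope, se, t, p, neg_log10_p, fwer, neg_log10_fwer,
#'   fold, n_used, n_outliers, excluded, reason`.
#' @export
eqtl_scan <- function(expression, gt, gene, snps, covariates = NULL,
                      outlier_threshold = 3, m_tests = NULL) {
  d <- expression[expression$gene == gene, , drop = FALSE]
  if (nrow(d) < 3) stop("too few expression measurements for gene ", gene)
  out <- if (is.finite(outlier_threshold))
    detect_outliers(d, outlier_threshold) else list(excluded = d[0, ])
  n_out <- nrow(out$excluded)
  if (n_out) d <- d[!d$individual_id %in% out$excluded$individual_id, , drop = FALSE]
  if (!is.null(covariates)) {
    d <- merge(d, covariates, by = "individual_id")
    if ("ethnicity" %in% names(d)) {
      tab <- table(d$ethnicity)
      lone <- names(tab)[tab < 2]
      if (length(lone)) {
        warning("ethnicity categories merged into 'other': ",
                paste(lone, collapse = ", "))
        d$ethnicity[d$ethnicity %in% lone] <- "other"
      }
      d$ethnicity <- factor(d$ethnicity)
      if (nlevels(d$ethnicity) < 2) d$ethnicity <- NULL
    }
  }
  if (is.null(m_tests)) m_tests <- length(snps)
  cov_terms <- intersect(c("age", "sex", "ethnicity"), names(d))
  # constant covariates carry no information and would break the design
  cov_terms <- cov_terms[vapply(cov_terms, function(v)
    length(unique(d[[v]])) >= 2, logical(1))]
  rows <- lapply(snps, function(s) {
    blank <- data.frame(snp_id = s, gene = gene, slope = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        neg_log10_p = NA_real_, fwer = NA_real_,
                        neg_log10_fwer = NA_real_, fold = NA_real_,
                        n_used = NA_integer_, n_outliers = n_out,
                        excluded = TRUE, reason = "", stringsAsFactors = FALSE)
    if (!s %in% colnames(gt$geno)) {
      blank$reason <- "SNP absent from genotype table"
      return(blank)
    }
    g <- gt$geno[match(d$individual_id, rownames(gt$geno)), s]
    dd <- d[!is.na(g), , drop = FALSE]
    dd$genotype <- g[!is.na(g)]
    classes <- table(dd$genotype)
    if (length(classes) < 2) {
      blank$reason <- "fewer than 2 genotype classes"
      return(blank)
    }
    fml <- stats::reformulate(c("genotype", cov_terms), response = "log_expr")
    fit <- stats::lm(fml, data = dd)
    cf <- summary(fit)$coefficients
    if (!"genotype" %in% rownames(cf)) {
      blank$reason <- "genotype dropped from design"
      return(blank)
    }
    slope <- cf["genotype", "Estimate"]; se <- cf["genotype", "Std. Error"]
    p <- cf["genotype", "Pr(>|t|)"]
    data.frame(snp_id = s, gene = gene, slope = slope, se = se,
               t = cf["genotype", "t value"], p = p,
               neg_log10_p = -log10(max(p, .Machine$double.xmin)),
               fwer = min(1, m_tests * p),
               neg_log10_fwer = -log10(max(min(1, m_tests * p),
                                           .Machine$double.xmin)),
               fold = exp(2 * slope), n_used = nrow(dd), n_outliers = n_out,
               excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  pos <- gt$snps$pos[match(res$snp_id, gt$snps$snp_id)]
  res <- res[order(pos, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m_tests") <- m_tests
  class(res) <- c("eqtl_scan", class(res))
  res
}
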