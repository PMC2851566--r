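#' Bonferroni family-wise error rate
#'
#' @param p nominal P value(s) in `[0, 1]`.
#' @param m_tests number of tests (>= 1).
#' @param alpha FWER level for the threshold report.
#' @return list with `fwer` (`min(1, m_tests * p)`), `nominal_threshold`
#'   (`alpha / m_tests`), `neg_log10_nominal_threshold` and
#'   `neg_log10_fwer_threshold` (`-log10(alpha)`).
#' @export
bonferroni_fwer <- function(p, m_tests, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]")
  if (m_tests < 1) stop("m_tests must be >= 1")
  list(fwer = pmin(1, m_tests * p),
       nominal_threshold = alpha / m_tests,
       neg_log10_nominal_threshold = -log10(alpha / m_tests),
       neg_log10_fwer_threshold = -log10(alpha))
}

#' Cis-acting variance and its share of total expression variance
#'
#' The per-allele variance of cis-acting effects is estimated from the
#' log allelic ratios `I` of the marker's heterozygotes as
#' `sigma2_cis = (1 / (2 n)) * sum(I^2)` (the allelic ratio has mean
#' zero and variance twice the per-allele cis variance when the two
#' alleles' cis contributions are independent).  The total variance is
#' the sample variance of log total expression over all individuals, and
#' the cis fraction is their ratio.  `scale = "log-total"` applies the
#' alternative `1 / (4 n)` factor, expressing the cis variance on the
#' scale of the log of summed allelic expression.
#'
#' @param aer normalized AER data frame (cDNA).
#' @param marker_id transcribed marker used for the estimate.
#' @param expression data frame with `gene`, `log_expr` (natural-log
#'   scale) for the same gene.
#' @param gene gene label (rows of `expression` used).
#' @param scale `"per-allele"` (default, factor 1/(2n)) or `"log-total"`
#'   (factor 1/(4n)).
#' @return one-row data frame: `gene`, `marker_id`, `sigma2_cis`,
#'   `sigma2_total`, `cis_fraction`, `n`, `inconsistent` (fraction > 1).
#' @export
cis_variance_fraction <- function(aer, marker_id, expression, gene,
                                  scale = c("per-allele", "log-total")) {
  scale <- match.arg(scale)
  I <- aer$I[aer$marker_id == marker_id & is.finite(aer$I)]
  n <- length(I)
  if (n < 2) stop("need >= 2 marker heterozygotes with measured ratios")
  denom <- if (scale == "per-allele") 2 * n else 4 * n
  s2_cis <- sum(I^2) / denom
  le <- expression$log_expr[expression$gene == gene & is.finite(expression$log_expr)]
  if (length(le) < 2) stop("need >= 2 total-expression measurements")
  s2_tot <- stats::var(le)
  frac <- s2_cis / s2_tot
  data.frame(gene = gene, marker_id = marker_id, sigma2_cis = s2_cis,
             sigma2_total = s2_tot, cis_fraction = frac, n = n,
             inconsistent = frac > 1, stringsAsFactors = FALSE)
}

#' Compare two association scans
#'
#' Pearson correlations of the effect estimates and of the -log10 P
#' values over the SNPs shared by two scans (excluded SNPs dropped),
#' e.g. aeQTL vs eQTL on the same samples or the same scan in two
#' cohorts.
#'
#' @param scan_a,scan_b scan data frames carrying `snp_id`, an effect
#'   column (`beta` or `slope`) and `neg_log10_p`.
#' @return list: `r_effect`, `r_neg_log10_p`, `n_shared`, `table`
#'   (paired per-SNP values for plotting).
#' @export
compare_scans <- function(scan_a, scan_b) {
  eff <- function(s) if ("beta" %in% names(s)) s$beta else s$slope
  a <- data.frame(snp_id = scan_a$snp_id, effect_a = eff(scan_a),
                  nlp_a = scan_a$neg_log10_p,
                  stringsAsFactors = FALSE)[!scan_a$excluded, ]
  b <- data.frame(snp_id = scan_b$snp_id, effect_b = eff(scan_b),
                  nlp_b = scan_b$neg_log10_p,
                  stringsAsFactors = FALSE)[!scan_b$excluded, ]
  tab <- merge(a, b, by = "snp_id")
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3) stop("fewer than 3 shared, non-excluded SNPs")
  list(r_effect = stats::cor(tab$effect_a, tab$effect_b),
       r_neg_log10_p = stats::cor(tab$nlp_a, tab$nlp_b),
       n_shared = nrow(tab), table = tab)
}

#' Direction-of-effect concordance between gene scans
#'
#' For each pair of genes, counts the SNPs significant in both scans
#' (FWER below `threshold`) whose effects have the same vs opposite
#' sign.
#'
#' @param scans named list (by gene) of `aeqtl_scan` data frames.
#' @param threshold FWER significance threshold (default 0.05).
#' @return data frame: `gene_a`, `gene_b`, `same_direction`, `opposite`,
#'   `n_shared_significant`.
#' @export
direction_concordance <- function(scans, threshold = 0.05) {
  if (length(scans) < 2) stop("need scans for >= 2 genes")
  genes <- names(scans)
  pairs <- utils::combn(genes, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- scans[[pairs[1, j]]]; b <- scans[[pairs[2, j]]]
    a <- a[!a$excluded & a$fwer < threshold, c("snp_id", "beta")]
    b <- b[!b$excluded & b$fwer < threshold, c("snp_id", "beta")]
    tab <- merge(a, b, by = "snp_id", suffixes = c("_a", "_b"))
    same <- sum(sign(tab$beta_a) == sign(tab$beta_b))
    data.frame(gene_a = pairs[1, j], gene_b = pairs[2, j],
               same_direction = same, opposite = nrow(tab) - same,
               n_shared_significant = nrow(tab), stringsAsFactors = FALSE)
  }))
}

#' Round -log10 columns to reporting precision
#'
#' Output convention: -log10 P and -log10 FWER are reported to 2
#' decimals.
#'
#' @param scan a scan data frame.
#' @return the data frame with `neg_log10_p`/`neg_log10_fwer` rounded.
#' @export
format_scan <- function(scan) {
  for (col in c("neg_log10_p", "neg_log10_fwer"))
    if (col %in% names(scan)) scan[[col]] <- round(scan[[col]], 2)
  scan
}
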