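#' Genotype table
#'
#' Container for unphased genotypes of one or more cohorts: an individuals
#' x SNPs matrix of coded-allele counts (0/1/2, `NA` for missing) together
#' with SNP metadata.  The coded allele is the allele whose copies are
#' counted (the ALT allele when reading VCF); the convention is stored
#' explicitly so that orientation is never ambiguous downstream.
#'
#' @param geno integer matrix, individuals in rows (rownames = individual
#'   ids), SNPs in columns (colnames = SNP ids), entries in `{0, 1, 2, NA}`.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_ref`, `allele_alt`; one row per column of `geno`.  Extra
#'   columns are kept.
#' @param cohort character vector of cohort labels, one per individual.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `geno`, `snps`, `cohort` and `coded_allele = "alt"`.
#' @export
genotype_table <- function(geno, snps = NULL, cohort = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) stop("`geno` must have individual ids as rownames")
  if (is.null(colnames(geno))) stop("`geno` must have SNP ids as colnames")
  storage.mode(geno) <- "integer"
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf("invalid genotype code %s at individual '%s', SNP '%s'",
                 geno[idx],
                 rownames(geno)[(idx - 1) %% nrow(geno) + 1],
                 colnames(geno)[(idx - 1) %/% nrow(geno) + 1]))
  }
  if (is.null(snps)) {
    snps <- data.frame(snp_id = colnames(geno), chrom = "9",
                       pos = seq_len(ncol(geno)),
                       allele_ref = "A", allele_alt = "G",
                       stringsAsFactors = FALSE)
  }
  if (!all(colnames(geno) %in% snps$snp_id))
    stop("every SNP in `geno` needs a row in `snps`")
  snps <- snps[match(colnames(geno), snps$snp_id), , drop = FALSE]
  rownames(snps) <- NULL
  if (is.null(cohort)) cohort <- rep("cohort1", nrow(geno))
  if (length(cohort) != nrow(geno))
    stop("`cohort` must have one label per individual")
  structure(list(geno = geno, snps = snps,
                 cohort = stats::setNames(as.character(cohort), rownames(geno)),
                 coded_allele = "alt"),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d SNPs; cohorts: %s\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%s (n=%d)", names(table(x$cohort)),
                            as.integer(table(x$cohort))), collapse = ", ")))
  invisible(x)
}

#' Per-SNP allele frequency of the coded allele
#'
#' @param gt a [genotype_table()].
#' @param cohort optional cohort label; default uses all individuals.
#' @return named numeric vector of coded-allele frequencies.
#' @export
coded_allele_freq <- function(gt, cohort = NULL) {
  g <- gt$geno
  if (!is.null(cohort)) g <- g[gt$cohort == cohort, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @inheritParams coded_allele_freq
#' @return named numeric vector in `[0, 0.5]`.
#' @export
snp_maf <- function(gt, cohort = NULL) {
  p <- coded_allele_freq(gt, cohort)
  pmin(p, 1 - p)
}

#' Read genotypes from TSV or minimal VCF
#'
#' The TSV layout is wide: header `individual_id`, optionally `cohort`,
#' then one column per SNP holding coded-allele counts 0/1/2 (empty or
#' `NA` for missing).  The VCF reader handles the unphased GT-only dialect
#' this package writes (biallelic records; `./.` becomes missing); genotype
#' codes count copies of the ALT allele.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param snps optional SNP metadata data frame (TSV only; VCF carries its
#'   own).
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), snps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path, snps) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path, snps = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"individual_id" %in% names(df))
    stop("genotype TSV must have an 'individual_id' column")
  cohort <- if ("cohort" %in% names(df)) df$cohort else NULL
  snp_cols <- setdiff(names(df), c("individual_id", "cohort"))
  g <- as.matrix(df[snp_cols])
  suppressWarnings(storage.mode(g) <- "integer")
  bad_row <- which(apply(g, 1, function(r) any(!(r %in% c(0L, 1L, 2L, NA)))))
  if (length(bad_row))
    stop(sprintf("malformed genotype row at line %d of %s",
                 bad_row[1] + 1L, path))
  rownames(g) <- df$individual_id
  genotype_table(g, snps = snps, cohort = cohort)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                             drop = FALSE], stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("triallelic VCF records are not supported: ",
         paste(fix$ID[grepl(",", fix$ALT, fixed = TRUE)], collapse = ", "))
  gtc <- vcfR::extract.gt(v, element = "GT")
  code_one <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    bad <- !is.na(x) & !x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop("unsupported GT value: ", x[bad][1])
    out
  }
  g <- apply(gtc, 2, code_one)
  g <- t(matrix(g, nrow = nrow(gtc), dimnames = dimnames(gtc)))
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     allele_ref = fix$REF, allele_alt = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_table(g, snps = snps)
}

#' Write genotypes
#'
#' `write_genotypes_tsv()` writes the wide TSV layout read by
#' [read_genotypes()]; `write_genotypes_vcf()` writes a minimal unphased
#' GT-only VCF v4.2 (1-based positions, genotype = count of ALT copies).
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gt, path) {
  df <- data.frame(individual_id = rownames(gt$geno),
                   cohort = unname(gt$cohort),
                   as.data.frame(gt$geno, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gt$geno)), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gt$geno))) {
    calls <- gt$geno[, j]
    s <- ifelse(is.na(calls), "./.", gt_str[calls + 1L])
    writeLines(paste(c(gt$snps$chrom[j], gt$snps$pos[j], gt$snps$snp_id[j],
                       gt$snps$allele_ref[j], gt$snps$allele_alt[j],
                       ".", "PASS", ".", "GT", s), collapse = "\t"), con)
  }
  invisible(path)
}

#' Genotype quality control
#'
#' Removes individuals whose genotype call rate falls below
#' `min_call_rate` and flags (without removing) SNPs departing from
#' Hardy-Weinberg proportions within each cohort, using the 1-df
#' chi-squared goodness-of-fit test on genotype counts.
#'
#' @param gt a [genotype_table()].
#' @param min_call_rate minimum fraction of non-missing calls per
#'   individual (default 0.8).
#' @param hwe_alpha significance level for the per-cohort HWE flag.
#' @return list with `genotypes` (filtered [genotype_table()]), `excluded`
#'   (character vector of removed individual ids), `hwe` (data frame with
#'   per SNP x cohort chi-squared statistic, P value and flag) and `log`
#'   (character vector describing every action taken).
#' @export
qc_filter <- function(gt, min_call_rate = 0.8, hwe_alpha = 0.001) {
  call_rate <- rowMeans(!is.na(gt$geno))
  excluded <- rownames(gt$geno)[call_rate < min_call_rate]
  keep <- setdiff(rownames(gt$geno), excluded)
  log <- character(0)
  if (length(excluded))
    log <- c(log, sprintf("excluded individual %s: call rate %.2f < %.2f",
                          excluded, call_rate[excluded], min_call_rate))
  filtered <- genotype_table(gt$geno[keep, , drop = FALSE], gt$snps,
                             gt$cohort[keep])
  rows <- list()
  for (co in unique(filtered$cohort)) {
    g <- filtered$geno[filtered$cohort == co, , drop = FALSE]
    for (j in seq_len(ncol(g))) {
      tst <- hwe_chisq(g[, j])
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = colnames(g)[j], cohort = co,
        chisq = tst$chisq, p = tst$p,
        flagged = !is.na(tst$p) && tst$p < hwe_alpha,
        stringsAsFactors = FALSE)
    }
  }
  hwe <- do.call(rbind, rows)
  if (any(hwe$flagged))
    log <- c(log, sprintf("HWE flag: SNP %s in cohort %s (P = %.3g)",
                          hwe$snp_id[hwe$flagged], hwe$cohort[hwe$flagged],
                          hwe$p[hwe$flagged]))
  list(genotypes = filtered, excluded = excluded, hwe = hwe, log = log)
}

# 1-df chi-squared goodness of fit of genotype counts to HWE proportions.
hwe_chisq <- function(calls) {
  calls <- calls[!is.na(calls)]
  n <- length(calls)
  obs <- c(sum(calls == 0), sum(calls == 1), sum(calls == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (n == 0 || p <= 0 || p >= 1)
    return(list(chisq = NA_real_, p = NA_real_))
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((obs - exp)^2 / exp)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
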