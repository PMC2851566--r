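#' Aggregate replicate allelic-ratio measurements
#'
#' Replicate peak-area ratios are averaged on the ratio scale (the scale
#' of the assay readout) before any log transform; the standard error of
#' the mean and the replicate count are retained.  Records whose ratios
#' are all missing are dropped with a log entry; single-replicate records
#' get `se = NA` and are flagged.
#'
#' @param measurements data frame with columns `individual_id`, `gene`,
#'   `marker_id`, `template` (`"cDNA"` or `"gDNA"`), `replicate`, `ratio`.
#' @return list with `means` (one row per individual x marker x template:
#'   `mean_ratio`, `se`, `n_replicates`, `single_replicate` flag) and
#'   `log`.
#' @export
aggregate_replicates <- function(measurements) {
  req <- c("individual_id", "gene", "marker_id", "template", "replicate", "ratio")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  if (any(!is.na(measurements$ratio) & measurements$ratio <= 0))
    stop("raw ratios must be positive")
  key <- interaction(measurements$individual_id, measurements$gene,
                     measurements$marker_id, measurements$template,
                     drop = TRUE, sep = "\r")
  log <- character(0)
  rows <- lapply(split(measurements, key), function(d) {
    r <- d$ratio[!is.na(d$ratio)]
    if (!length(r)) {
      log <<- c(log, sprintf("dropped %s / %s / %s: all replicates missing",
                             d$individual_id[1], d$marker_id[1], d$template[1]))
      return(NULL)
    }
    data.frame(individual_id = d$individual_id[1], gene = d$gene[1],
               marker_id = d$marker_id[1], template = d$template[1],
               mean_ratio = mean(r),
               se = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
               n_replicates = length(r),
               single_replicate = length(r) == 1L,
               stringsAsFactors = FALSE)
  })
  means <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(means) <- NULL
  list(means = means, log = log)
}

#' Genomic-DNA normalization factors
#'
#' Genomic DNA from a heterozygote contains the two alleles in an exactly
#' 1:1 ratio, so the measured gDNA ratio of an assay is a direct estimate
#' of its multiplicative bias.  The population-mean strategy averages the
#' per-individual mean gDNA ratios of all gDNA heterozygotes of an assay;
#' the per-individual strategy keeps each individual's own gDNA ratio.
#'
#' @param gdna_means aggregated gDNA measurements (the `means` element of
#'   [aggregate_replicates()] restricted to `template == "gDNA"`).
#' @param strategy `"population-mean"` (default) or `"per-individual"`.
#' @return data frame of class `aer_normalization`: columns `marker_id`,
#'   `nf` and, for the per-individual strategy, `individual_id`.
#' @export
compute_normalization <- function(gdna_means,
                                  strategy = c("population-mean", "per-individual")) {
  strategy <- match.arg(strategy)
  g <- gdna_means[gdna_means$template == "gDNA", , drop = FALSE]
  if (!nrow(g)) stop("no gDNA measurements supplied")
  if (strategy == "population-mean") {
    nf <- vapply(split(g$mean_ratio, g$marker_id), mean, numeric(1))
    out <- data.frame(marker_id = names(nf), nf = unname(nf),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(marker_id = g$marker_id, individual_id = g$individual_id,
                      nf = g$mean_ratio, stringsAsFactors = FALSE)
  }
  if (any(!is.finite(out$nf) | out$nf <= 0))
    stop("non-positive normalization factor for assay: ",
         paste(out$marker_id[!is.finite(out$nf) | out$nf <= 0], collapse = ", "))
  attr(out, "strategy") <- strategy
  class(out) <- c("aer_normalization", class(out))
  out
}

#' Normalize allelic expression ratios against gDNA
#'
#' Divides each aggregated cDNA ratio by the assay's normalization factor
#' and takes the natural log, giving the per-individual, per-marker log
#' allelic expression ratio `I`.  Applying the population-mean strategy to
#' the gDNA measurements themselves yields mean normalized ratio 1 by
#' construction.
#'
#' @param means aggregated measurements (`means` from
#'   [aggregate_replicates()]); rows with `template == "cDNA"` are
#'   normalized (pass gDNA rows to check the reference).
#' @param factors an `aer_normalization` from [compute_normalization()].
#' @param template which template to normalize (default `"cDNA"`).
#' @return data frame with columns of `means` plus `norm_ratio` and `I`
#'   (natural-log normalized ratio).
#' @export
normalize_aer <- function(means, factors, template = "cDNA") {
  d <- means[means$template == template, , drop = FALSE]
  strategy <- attr(factors, "strategy")
  if (identical(strategy, "per-individual")) {
    idx <- match(paste(d$marker_id, d$individual_id),
                 paste(factors$marker_id, factors$individual_id))
  } else {
    idx <- match(d$marker_id, factors$marker_id)
  }
  if (anyNA(idx))
    stop("no normalization factor for assay: ",
         paste(unique(d$marker_id[is.na(idx)]), collapse = ", "))
  nf <- factors$nf[idx]
  if (any(d$mean_ratio <= 0)) stop("non-positive ratio cannot be normalized")
  d$norm_ratio <- d$mean_ratio / nf
  d$I <- log(d$norm_ratio)
  rownames(d) <- NULL
  d
}

#' Flip the numerator allele of a marker
#'
#' Reverses the orientation of the allelic ratio at one marker: ratios are
#' inverted and `I` is negated.  Used to express all markers of a gene on
#' a common numerator convention.
#'
#' @param aer normalized AER data frame from [normalize_aer()].
#' @param marker_id marker whose orientation to flip.
#' @return the data frame with the marker's `norm_ratio` inverted and `I`
#'   negated.
#' @export
flip_marker_orientation <- function(aer, marker_id) {
  i <- aer$marker_id == marker_id
  aer$norm_ratio[i] <- 1 / aer$norm_ratio[i]
  aer$I[i] <- -aer$I[i]
  if ("mean_ratio" %in% names(aer)) aer$mean_ratio[i] <- 1 / aer$mean_ratio[i]
  aer
}

#' Delta-Ct relative quantification of total expression
#'
#' Normalizes each target gene's mean Ct to the mean Ct of the three
#' reference genes and converts to log relative expression under the
#' comparative-Ct model with 100% amplification efficiency:
#' `log_expr = -delta_ct * log(2)` (natural-log scale), so a one-cycle
#' lower delta-Ct means two-fold higher expression.
#'
#' @param ct data frame with columns `individual_id`, `gene`, `ct_target`
#'   (replicates allowed: several rows per individual x gene) and the
#'   three reference-gene columns `ct_b2m`, `ct_gapd`, `ct_hprt1`.
#' @param efficiency amplification efficiency (1 = doubling per cycle);
#'   log relative expression is `-delta_ct * log(1 + efficiency)`.
#' @return list with `expression` (per individual x gene: `delta_ct`,
#'   `log_expr`) and `log` recording excluded records.
#' @export
delta_ct <- function(ct, efficiency = 1) {
  req <- c("individual_id", "gene", "ct_target", "ct_b2m", "ct_gapd", "ct_hprt1")
  if (!all(req %in% names(ct)))
    stop("ct table must have columns: ", paste(req, collapse = ", "))
  key <- interaction(ct$individual_id, ct$gene, drop = TRUE, sep = "\r")
  log <- character(0)
  rows <- lapply(split(ct, key), function(d) {
    refs <- unlist(d[c("ct_b2m", "ct_gapd", "ct_hprt1")])
    if (anyNA(refs) || all(is.na(d$ct_target))) {
      log <<- c(log, sprintf("excluded %s / %s: missing reference or target Ct",
                             d$individual_id[1], d$gene[1]))
      return(NULL)
    }
    dct <- mean(d$ct_target, na.rm = TRUE) - mean(refs)
    data.frame(individual_id = d$individual_id[1], gene = d$gene[1],
               delta_ct = dct, log_expr = -dct * log(1 + efficiency),
               stringsAsFactors = FALSE)
  })
  expression <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(expression) <- NULL
  list(expression = expression, log = log)
}
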