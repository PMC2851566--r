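#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> replicate aggregation and
#' gDNA normalization -> delta-Ct -> per-gene aeQTL scan -> sequential
#' adjustment for the top SNP -> eQTL scan -> cross-scan comparison and
#' concordance summaries.  Writes every intermediate table under
#' `out_dir` together with a provenance record (seed, configuration
#' hash, file inventory), so a rerun with the same configuration is
#' reproducible.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   entries: `seed`, `min_informative` (default 8), `fwer_alpha`
#'   (default 0.05), `m_tests` (default: number of mapping SNPs),
#'   `normalization` (`"population-mean"` or `"per-individual"`),
#'   `outlier_threshold` (default 3), `adjust_rounds` (default 1),
#'   `genes` (default: all simulated genes), `snps` (default: all
#'   mapping SNPs).
#' @param out_dir output directory.
#' @param sim optional pre-built `aeqtl_sim`; by default one is
#'   generated from [default_sim_config()] with the configured seed.
#' @return list with `scans` (per gene, per adjustment round), `eqtl`
#'   (per gene), `comparison`, `concordance`, `cis_variance`, `qc`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("aeqtl_run_"),
                         sim = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, min_informative = 8, fwer_alpha = 0.05,
                   m_tests = NULL, normalization = "population-mean",
                   outlier_threshold = 3, adjust_rounds = 1,
                   genes = NULL, snps = NULL)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown configuration entries: ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(sim)) sim <- simulate_dataset(default_sim_config(seed = cfg$seed))
  write_dataset(sim, file.path(out_dir, "data"))
  markers <- sim$config$markers
  genes <- if (is.null(cfg$genes)) unique(markers$gene) else cfg$genes
  snps <- if (is.null(cfg$snps))
    setdiff(colnames(sim$genotypes$geno), markers$marker_id) else cfg$snps
  m_tests <- if (is.null(cfg$m_tests)) length(snps) else cfg$m_tests

  qc <- qc_filter(sim$genotypes)
  say("qc: %d individuals excluded, %d HWE flags",
      length(qc$excluded), sum(qc$hwe$flagged))
  gt <- qc$genotypes

  agg <- aggregate_replicates(sim$aer)
  nf <- compute_normalization(agg$means[agg$means$template == "gDNA", ],
                              strategy = cfg$normalization)
  aer <- normalize_aer(agg$means, nf, template = "cDNA")
  aer <- aer[aer$individual_id %in% rownames(gt$geno), , drop = FALSE]
  gdna <- normalize_aer(agg$means, nf, template = "gDNA")
  expr <- delta_ct(sim$ct)$expression
  expr <- expr[expr$individual_id %in% rownames(gt$geno), , drop = FALSE]

  scans <- list(); eqtl <- list(); cisvar <- list()
  for (g in genes) {
    rounds <- list()
    adjust <- character(0)
    for (round in 0:cfg$adjust_rounds) {
      sc <- scan_snps(aer, gt, g, snps, markers, adjust = adjust,
                      min_informative = cfg$min_informative,
                      m_tests = m_tests)
      rounds[[paste0("adjust", round)]] <- sc
      ok <- sc[!sc$excluded, ]
      if (!nrow(ok) || min(ok$fwer) >= cfg$fwer_alpha) break
      top <- ok$snp_id[which.min(ok$p)]
      say("%s round %d: top SNP %s (P = %.3g); adjusting", g, round,
          top, min(ok$p))
      adjust <- c(adjust, top)
    }
    scans[[g]] <- rounds
    eqtl[[g]] <- eqtl_scan(expr, gt, g, snps, covariates = sim$covariates,
                           outlier_threshold = cfg$outlier_threshold,
                           m_tests = m_tests)
    cisvar[[g]] <- do.call(rbind, lapply(
      markers$marker_id[markers$gene == g], function(mk)
        cis_variance_fraction(aer, mk, expr, g)))
    utils::write.table(format_scan(rounds[[1]]),
                       file.path(out_dir, sprintf("scan_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_scan(eqtl[[g]]),
                       file.path(out_dir, sprintf("eqtl_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  comparison <- lapply(genes, function(g)
    tryCatch(compare_scans(scans[[g]][[1]], eqtl[[g]]),
             error = function(e) NULL))
  names(comparison) <- genes
  concordance <- tryCatch(
    direction_concordance(lapply(scans, `[[`, 1), threshold = cfg$fwer_alpha),
    error = function(e) NULL)
  if (!is.null(concordance))
    utils::write.table(concordance, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cisvar_tab <- do.call(rbind, cisvar)
  utils::write.table(cisvar_tab, file.path(out_dir, "cis_variance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  provenance <- list(
    package_version = as.character(utils::packageVersion("aeqtlmap")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "snps")],
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    files = data.frame(file = basename(files),
                       bytes = file.size(files), stringsAsFactors = FALSE),
    log = c(log_lines, qc$log))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  list(scans = scans, eqtl = eqtl, comparison = comparison,
       concordance = concordance, cis_variance = cisvar_tab, qc = qc,
       aer = aer, gdna = gdna, expression = expr, provenance = provenance,
       out_dir = out_dir)
}
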