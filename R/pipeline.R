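# End-to-end orchestration: QC -> modality screen (males) -> sex-stratified
# association scan -> FDR -> per-site twin analyses for the hits.

#' Run the full X chromosome-wide analysis
#'
#' Executes, in order: sample QC (detection-p masking and missing-rate
#' filter), probe QC (missing rate, SNP overlap, mapping), BMI outlier
#' exclusion, the male-stratum dip modality screen, the sex-stratified
#' association scan with BH-FDR, and — when twin columns are present — ACE
#' decomposition and the discordant-MZ paired test for every FDR hit.
#' When `config$outDir` is set, all result tables (TSV), a BED file of hits,
#' the resolved configuration (YAML) and a JSON run report are written
#' there.
#'
#' @param config a [pipelineConfig()].
#' @param mset a [MethylationSet-class] carrying the sample sheet and probe
#'   annotation.
#' @param spec optional [modelSpec()]; defaults to a male-stratum
#'   current-vs-noncurrent model on the configured outcome scale with the
#'   configured covariates and random terms.
#' @return a `PipelineReport` list: `qc` (exclusion counts per stage),
#'   `modality`, `association`, `hits`, `twins`, `config_hash`, `seed`,
#'   `n_input`, `n_retained`.
#' @export
runPipeline <- function(config, mset, spec = NULL) {
  stopifnot(inherits(config, "PipelineConfig"), is(mset, "MethylationSet"))
  nIn <- c(samples = ncol(mset), probes = nrow(mset))
  qc <- list()

  s1 <- qcFilterSamples(mset, config$detectionPCutoff, config$sampleMaxMissing)
  qc$samples_detection_missing <- nrow(s1$report$excluded_samples)
  s2 <- qcFilterProbes(s1$mset, config$probeMaxMissing)
  qc$probes_filtered <- table(factor(
    s2$report$excluded_probes$reason,
    levels = c("missing", "snp_overlap", "non_unique_mapping")))
  mset2 <- s2$mset
  sheet <- sampleSheet(mset2)
  if ("bmi" %in% names(sheet) && any(!is.na(sheet$bmi))) {
    s3 <- removePhenotypeOutliers(sheet, "bmi", config$bmiKSd)
    qc$samples_bmi_outlier <- nrow(s3$report$excluded_samples)
    keepIds <- s3$sheet$sample_id
    mset2 <- mset2[, keepIds]
    sheet <- s3$sheet
  } else qc$samples_bmi_outlier <- 0L
  if (ncol(mset2) == 0 || nrow(mset2) == 0)
    stop("no data left after quality control")

  male <- sheet$sex == "male"
  if (!any(male))
    stop("modality screen requires a male stratum")
  modality <- modalityScreen(mset2, stratum = male,
                             alpha = config$modalityAlpha,
                             correction = config$modalityCorrection,
                             nSim = config$modalityNSim, seed = config$seed)

  if (is.null(spec))
    spec <- modelSpec(outcomeScale = config$outcomeScale,
                      covariates = intersect(config$covariates,
                                             names(sheet)),
                      randomTerms = intersect(config$randomTerms,
                                              c(if ("batch_id" %in%
                                                      names(sheet)) "batch",
                                                if ("pair_id" %in%
                                                      names(sheet)) "pair")),
                      stratum = c(sex = "male"))
  assoc <- ewas(mset2, sheet, spec)
  hits <- assoc[!is.na(assoc$q) & assoc$q < config$fdrAlpha, , drop = FALSE]

  twins <- NULL
  hasTwins <- all(c("pair_id", "zygosity") %in% names(sheet)) &&
    any(!is.na(sheet$pair_id))
  if (hasTwins && nrow(hits)) {
    b <- betaValues(mset2)
    strat <- .applyStratum(sheet, spec$stratum)
    twins <- do.call(rbind, lapply(hits$probe_id, function(pb) {
      v <- b[pb, ]
      v[!strat] <- NA
      pt <- pairTable(v, sheet)
      ace <- tryCatch(aceDecompose(pt$mz, pt$dz, method = "ml"),
                      error = function(e) data.frame(
                        a2 = NA, c2 = NA, e2 = NA, loglik = NA,
                        n_mz_pairs = nrow(pt$mz), n_dz_pairs = nrow(pt$dz),
                        converged = FALSE, method = "ml"))
      dmz <- discordantMzPairs(v, sheet)
      dt <- if (length(dmz$exposed) >= 2)
        discordantMzTest(dmz$exposed, dmz$unexposed)
      else data.frame(n_pairs = length(dmz$exposed), mean_diff = NA,
                      t_stat = NA, p = NA, degenerate = NA)
      cbind(probe_id = pb, ace[, c("a2", "c2", "e2", "n_mz_pairs",
                                   "n_dz_pairs", "converged")],
            disc_n_pairs = dt$n_pairs, disc_mean_diff = dt$mean_diff,
            disc_t = dt$t_stat, disc_p = dt$p)
    }))
  }

  report <- list(
    qc = qc, modality = modality, association = assoc, hits = hits,
    twins = twins, seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "outDir")]),
    n_input = nIn,
    n_retained = c(samples = ncol(mset2), probes = nrow(mset2)))
  class(report) <- "PipelineReport"

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outDir, f)
    writeResultTable(assoc, out("association.tsv"))
    writeResultTable(modality, out("modality.tsv"))
    if (!is.null(twins)) writeResultTable(twins, out("twins.tsv"))
    ann <- probeAnnotation(mset2)
    if (nrow(hits)) {
      sites <- ann[match(hits$probe_id, ann$probe_id), ]
      sites$score <- round(-log10(hits$p))
      writeBed(sites, out("hits.bed"))
    }
    yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                             TRUE)],
                     out("config_resolved.yaml"))
    jsonlite::write_json(
      list(seed = config$seed, config_hash = report$config_hash,
           n_input = as.list(nIn),
           n_retained = as.list(report$n_retained),
           excluded = list(
             samples_detection_missing = qc$samples_detection_missing,
             samples_bmi_outlier = qc$samples_bmi_outlier,
             probes = as.list(qc$probes_filtered)),
           n_hits = nrow(hits)),
      out("run_report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  cat(sprintf("  input: %d samples x %d probes; retained: %d x %d\n",
              x$n_input["samples"], x$n_input["probes"],
              x$n_retained["samples"], x$n_retained["probes"]))
  cat(sprintf("  excluded samples: %d (detection/missing), %d (BMI)\n",
              x$qc$samples_detection_missing, x$qc$samples_bmi_outlier))
  cat("  excluded probes:",
      paste(names(x$qc$probes_filtered), as.integer(x$qc$probes_filtered),
            sep = "=", collapse = ", "), "\n")
  nm <- sum(!x$modality$unimodal_call, na.rm = TRUE)
  cat(sprintf("  modality screen: %d/%d sites called multimodal\n",
              nm, nrow(x$modality)))
  cat(sprintf("  association: %d sites, %d FDR hits\n",
              nrow(x$association), nrow(x$hits)))
  invisible(x)
}
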