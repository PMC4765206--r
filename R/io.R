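# Readers/writers for the tabular formats the pipeline touches, plus the
# run configuration. All tables are plain TSV; positions are 1-based
# (annotation convention) and only the BED export converts to 0-based
# half-open intervals.

.readTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), comment.char = "")
}

#' Read a probe-by-sample methylation matrix
#'
#' Expects a TSV with probe ids in the first column and sample ids in the
#' header; cells are beta-values in \[0, 1\] or the missing token (`NA` or an
#' empty cell). Anything else is a parse error naming the offending cell.
#'
#' @param path file path.
#' @param transpose set `TRUE` if the file has samples in rows.
#' @param sampleSheet,probeAnnotation,detectionP optional companions passed
#'   to [MethylationSet()]; `detectionP` may be a path to a matrix of the
#'   same layout.
#' @return a [MethylationSet-class].
#' @export
readMethylationMatrix <- function(path, transpose = FALSE, sampleSheet = NULL,
                                  probeAnnotation = NULL, detectionP = NULL) {
  raw <- .readTable(path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(raw)[-1]))
    stop("duplicate header ids in ", path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (is.character(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at probe '%s', sample '%s': '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]],
                   m[bad[1, 1], bad[1, 2]]))
    m <- num
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]))
  if (is.character(detectionP) && length(detectionP) == 1) {
    dp <- readMethylationMatrix(detectionP, transpose = transpose)
    detectionP <- betaValues(dp)[rownames(m), colnames(m)]
  }
  MethylationSet(m, sampleSheet = sampleSheet,
                 probeAnnotation = probeAnnotation, detectionP = detectionP)
}

#' Write a probe-by-sample matrix as TSV
#'
#' Full `%.17g` precision so a write/read round trip is lossless.
#'
#' @param m matrix with probe rownames and sample colnames (or a
#'   [MethylationSet-class], whose beta assay is written).
#' @param path output path.
#' @param idColumn name for the first (probe id) column.
#' @export
writeMethylationMatrix <- function(m, path, idColumn = "probe_id") {
  if (is(m, "MethylationSet")) m <- betaValues(m)
  df <- data.frame(rownames(m),
                   as.data.frame(format(m, digits = 17, trim = TRUE,
                                        scientific = NA)),
                   check.names = FALSE)
  names(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.smokingLevels <- c("never", "past", "current")

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `sex` (`male`/`female`), `age`,
#' `smoking_status` (`never`/`past`/`current`). Optional: `bmi`,
#' `years_smoked`, `cigarettes_per_day`, `pack_years`, `pair_id`, `zygosity`
#' (`MZ`/`DZ`), `batch_id`, `cohort_id`. When `years_smoked` and
#' `cigarettes_per_day` are present but `pack_years` is not, pack-years are
#' derived as years smoked times packs (cigarettes / 20) per day.
#'
#' Twin structure is validated: a `pair_id` must group exactly two samples,
#' with constant zygosity and sex within the pair.
#'
#' @param path file path (TSV or CSV by extension).
#' @return validated `data.frame`.
#' @export
readSampleSheet <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  sheet <- .readTable(path, sep = sep)
  validateSampleSheet(sheet)
}

#' Validate an in-memory sample sheet
#' @param sheet `data.frame` with the columns described in
#'   [readSampleSheet()].
#' @return the sheet, with `pack_years` derived when possible.
#' @export
validateSampleSheet <- function(sheet) {
  need <- c("sample_id", "sex", "age", "smoking_status")
  if (!all(need %in% names(sheet)))
    stop("sample sheet missing required columns: ",
         paste(setdiff(need, names(sheet)), collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  badSex <- setdiff(stats::na.omit(unique(sheet$sex)), c("male", "female"))
  if (length(badSex))
    stop("unknown sex categories: ", paste(badSex, collapse = ", "))
  badSmoke <- setdiff(stats::na.omit(unique(sheet$smoking_status)),
                      .smokingLevels)
  if (length(badSmoke))
    stop("unknown smoking categories: ", paste(badSmoke, collapse = ", "))
  if (!"pack_years" %in% names(sheet) &&
      all(c("years_smoked", "cigarettes_per_day") %in% names(sheet))) {
    sheet$pack_years <- sheet$years_smoked * sheet$cigarettes_per_day / 20
  }
  if ("pair_id" %in% names(sheet)) {
    pid <- sheet$pair_id[!is.na(sheet$pair_id)]
    sizes <- table(pid)
    if (any(sizes != 2))
      stop("pair_id must group exactly 2 samples; offending pairs: ",
           paste(names(sizes)[sizes != 2], collapse = ", "))
    for (col in intersect(c("zygosity", "sex"), names(sheet))) {
      byPair <- tapply(sheet[[col]][!is.na(sheet$pair_id)], pid,
                       function(v) length(unique(v)))
      if (any(byPair > 1))
        stop(col, " must be constant within a twin pair; offending pairs: ",
             paste(names(byPair)[byPair > 1], collapse = ", "))
    }
    if ("zygosity" %in% names(sheet)) {
      badZ <- setdiff(stats::na.omit(unique(sheet$zygosity)), c("MZ", "DZ"))
      if (length(badZ))
        stop("unknown zygosity categories: ", paste(badZ, collapse = ", "))
    }
  }
  sheet
}

#' Read probe annotation
#'
#' Columns: `probe_id`, `chromosome`, `position` (1-based), optional
#' `gene_symbol`, and logical `snp_overlap`, `unique_mapping`.
#' @param path file path.
#' @return validated `data.frame`.
#' @export
readProbeAnnotation <- function(path) {
  ann <- .readTable(path)
  need <- c("probe_id", "chromosome", "position")
  if (!all(need %in% names(ann)))
    stop("annotation missing required columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  if (anyDuplicated(ann$probe_id)) stop("duplicate probe_id in annotation")
  if (any(ann$position < 1, na.rm = TRUE))
    stop("positions must be 1-based (>= 1)")
  for (col in c("snp_overlap", "unique_mapping"))
    if (col %in% names(ann)) ann[[col]] <- as.logical(ann[[col]])
  ann
}

#' Write a result table as TSV (lossless numeric round trip)
#' @param df `data.frame`.
#' @param path output path.
#' @export
writeResultTable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#' @param path file path.
#' @export
readResultTable <- function(path) .readTable(path)

#' Export significant sites as BED
#'
#' Converts 1-based inclusive positions to BED's 0-based half-open intervals.
#' @param sites `data.frame` with `probe_id`, `chromosome`, `position` and
#'   optionally a score column `score`.
#' @param path output path.
#' @export
writeBed <- function(sites, path) {
  bed <- data.frame(chrom = sites$chromosome,
                    start = sites$position - 1L,
                    end = sites$position,
                    name = sites$probe_id,
                    score = if ("score" %in% names(sites)) sites$score else 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the quality-control thresholds, modality-screen settings, model
#' specification and output options of [runPipeline()] into a validated
#' list. `readPipelineConfig()` loads the same structure from YAML/JSON.
#'
#' @param detectionPCutoff,sampleMaxMissing,probeMaxMissing,bmiKSd QC
#'   thresholds (see [qcFilterSamples()], [qcFilterProbes()],
#'   [removePhenotypeOutliers()]).
#' @param modalityNSim,modalityAlpha,modalityCorrection dip-screen settings
#'   (see [modalityScreen()]); `modalityNSim` must be at least 1000.
#' @param outcomeScale `"beta"` or `"M"`.
#' @param covariates fixed-effect covariate names from the sample sheet (cell
#'   proportions are added separately by the pipeline when supplied).
#' @param randomTerms subset of `c("batch", "pair")`.
#' @param fdrAlpha Benjamini-Hochberg threshold for reporting hits.
#' @param seed integer seed used for the dip null tables.
#' @param outDir optional output directory; when set, [runPipeline()] writes
#'   result tables, a BED file of hits, the resolved configuration and a JSON
#'   run report there.
#' @return a `PipelineConfig` (validated named list).
#' @export
pipelineConfig <- function(detectionPCutoff = 0.001,
                           sampleMaxMissing = 0.05,
                           probeMaxMissing = 0.05,
                           bmiKSd = 3,
                           modalityNSim = 10000L,
                           modalityAlpha = 0.05,
                           modalityCorrection = "bonferroni",
                           outcomeScale = "beta",
                           covariates = c("age", "bmi"),
                           randomTerms = c("batch", "pair"),
                           fdrAlpha = 0.05,
                           seed = 1L,
                           outDir = NULL) {
  cfg <- list(detectionPCutoff = detectionPCutoff,
              sampleMaxMissing = sampleMaxMissing,
              probeMaxMissing = probeMaxMissing,
              bmiKSd = bmiKSd,
              modalityNSim = as.integer(modalityNSim),
              modalityAlpha = modalityAlpha,
              modalityCorrection = match.arg(modalityCorrection,
                                             c("bonferroni", "none")),
              outcomeScale = match.arg(outcomeScale, c("beta", "M")),
              covariates = covariates,
              randomTerms = randomTerms,
              fdrAlpha = fdrAlpha,
              seed = as.integer(seed),
              outDir = outDir)
  stopifnot(cfg$sampleMaxMissing >= 0, cfg$sampleMaxMissing <= 1,
            cfg$probeMaxMissing >= 0, cfg$probeMaxMissing <= 1,
            cfg$modalityNSim >= 1000L,
            cfg$modalityAlpha >= 0, cfg$modalityAlpha <= 1,
            cfg$fdrAlpha >= 0, cfg$fdrAlpha <= 1,
            all(cfg$randomTerms %in% c("batch", "pair")))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML (or JSON) file whose keys match the arguments of
#'   `pipelineConfig()`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k,
                if (is.null(v)) "<null>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
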