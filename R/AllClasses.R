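#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib xewas, .registration = TRUE
NULL

#' MethylationSet: probe-by-sample methylation container
#'
#' An S4 container for array methylation data, extending
#' [SummarizedExperiment::SummarizedExperiment]. The `"beta"` assay holds
#' methylation beta-values (methylated intensity over total intensity plus an
#' offset, so each value lies in \[0, 1\]); an optional `"detectionP"` assay
#' holds per-cell detection p-values. Probe annotation (chromosome, 1-based
#' position, gene symbol, SNP-overlap and unique-mapping flags) lives in
#' `rowData`; the sample sheet (sex, age, BMI, smoking variables, twin-pair
#' structure, batch, cohort) lives in `colData`.
#'
#' Missing measurements are `NA` in the beta assay.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    v <- b[!is.na(b)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if ("detectionP" %in% SummarizedExperiment::assayNames(object)) {
    p <- SummarizedExperiment::assay(object, "detectionP")
    v <- p[!is.na(p)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationSet
#'
#' @param beta numeric matrix of beta-values, probes in rows, samples in
#'   columns; `NA` marks missing measurements.
#' @param sampleSheet optional `data.frame` of per-sample phenotypes (one row
#'   per column of `beta`); see [readSampleSheet()] for the expected columns.
#' @param probeAnnotation optional `data.frame` of per-probe annotation (one
#'   row per row of `beta`) with columns such as `chromosome`, `position`,
#'   `gene_symbol`, `snp_overlap`, `unique_mapping`.
#' @param detectionP optional matrix of detection p-values, same shape as
#'   `beta`.
#' @return a validated [MethylationSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' MethylationSet(b)
#' @export
MethylationSet <- function(beta, sampleSheet = NULL, probeAnnotation = NULL,
                           detectionP = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    stop("beta matrix must have probe ids as rownames")
  if (is.null(colnames(beta)))
    stop("beta matrix must have sample ids as colnames")
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    stopifnot(identical(dim(detectionP), dim(beta)))
    dimnames(detectionP) <- dimnames(beta)
    assays$detectionP <- detectionP
  }
  cd <- if (is.null(sampleSheet)) {
    S4Vectors::DataFrame(row.names = colnames(beta))
  } else {
    stopifnot(nrow(sampleSheet) == ncol(beta))
    sampleSheet <- as.data.frame(sampleSheet)
    if ("sample_id" %in% names(sampleSheet)) {
      ord <- match(colnames(beta), sampleSheet$sample_id)
      if (anyNA(ord))
        stop("sample sheet does not cover all matrix samples: ",
             paste(colnames(beta)[is.na(ord)], collapse = ", "))
      sampleSheet <- sampleSheet[ord, , drop = FALSE]
    }
    S4Vectors::DataFrame(sampleSheet, row.names = colnames(beta))
  }
  rd <- if (is.null(probeAnnotation)) {
    S4Vectors::DataFrame(row.names = rownames(beta))
  } else {
    stopifnot(nrow(probeAnnotation) == nrow(beta))
    probeAnnotation <- as.data.frame(probeAnnotation)
    if ("probe_id" %in% names(probeAnnotation)) {
      ord <- match(rownames(beta), probeAnnotation$probe_id)
      if (anyNA(ord))
        stop("annotation does not cover all probes: ",
             paste(rownames(beta)[is.na(ord)], collapse = ", "))
      probeAnnotation <- probeAnnotation[ord, , drop = FALSE]
    }
    S4Vectors::DataFrame(probeAnnotation, row.names = rownames(beta))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = cd, rowData = rd)
  methods::new("MethylationSet", se)
}

#' @describeIn MethylationSet beta-value matrix (probes x samples)
#' @param object,x a `MethylationSet`
#' @export
betaValues <- function(object) SummarizedExperiment::assay(object, "beta")

#' @describeIn MethylationSet detection p-value matrix or `NULL`
#' @export
detectionP <- function(object) {
  if ("detectionP" %in% SummarizedExperiment::assayNames(object))
    SummarizedExperiment::assay(object, "detectionP") else NULL
}

#' @describeIn MethylationSet sample sheet as a plain `data.frame`
#' @export
sampleSheet <- function(object) {
  df <- as.data.frame(SummarizedExperiment::colData(object))
  df <- cbind(sample_id = colnames(object), df[setdiff(names(df), "sample_id")])
  rownames(df) <- NULL
  df
}

#' @describeIn MethylationSet probe annotation as a plain `data.frame`
#' @export
probeAnnotation <- function(object) {
  df <- as.data.frame(SummarizedExperiment::rowData(object))
  df <- cbind(probe_id = rownames(object), df[setdiff(names(df), "probe_id")])
  rownames(df) <- NULL
  df
}

#' @describeIn MethylationSet M-value matrix (logit2 of clipped beta)
#' @param eps clipping bound passed to [mFromBeta()]
#' @export
mValues <- function(object, eps = 1e-6) mFromBeta(betaValues(object), eps)

setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet with", nrow(object), "probes x", ncol(object),
      "samples\n")
  b <- betaValues(object)
  cat(sprintf("  beta: %.1f%% missing; detectionP: %s\n",
              100 * mean(is.na(b)),
              if (is.null(detectionP(object))) "absent" else "present"))
  sd_ <- SummarizedExperiment::colData(object)
  if ("sex" %in% names(sd_)) {
    tb <- table(sd_$sex)
    cat("  sex:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
})

#' Null distribution of the dip statistic at a fixed sample size
#'
#' Holds the sorted dip statistics of `nSim` samples of size `n` drawn from
#' the uniform distribution, the asymptotically least favourable unimodal
#' null. Empirical dip p-values are rank comparisons against this table.
#'
#' @slot n sample size simulated.
#' @slot nSim number of uniform null samples.
#' @slot dips sorted (ascending) null dip statistics, length `nSim`.
#' @slot seed integer seed the table was built under.
#' @seealso [buildNullTable()], [dipPvalue()]
#' @export
setClass("DipNullTable",
         representation(n = "integer", nSim = "integer",
                        dips = "numeric", seed = "integer"))

setValidity("DipNullTable", function(object) {
  msg <- character()
  if (length(object@dips) != object@nSim)
    msg <- c(msg, "length(dips) must equal nSim")
  if (is.unsorted(object@dips))
    msg <- c(msg, "dips must be sorted ascending")
  if (object@nSim < 1000L)
    msg <- c(msg, "nSim must be at least 1000 for a usable null table")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DipNullTable", function(object) {
  cat(sprintf(
    "DipNullTable: n = %d, nSim = %d (seed %d)\n  dip quantiles: 50%% %.4f, 95%% %.4f, 99%% %.4f\n",
    object@n, object@nSim, object@seed,
    stats::quantile(object@dips, 0.50), stats::quantile(object@dips, 0.95),
    stats::quantile(object@dips, 0.99)))
  invisible(object)
})
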