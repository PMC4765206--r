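# beta/M transforms, QC filters, phenotype outlier exclusion and
# reference-based cell-type deconvolution.

#' Beta-value from methylated/unmethylated intensities
#'
#' beta = max(I_meth, 0) / (|I_meth| + |I_unmeth| + alpha). The offset alpha
#' regularises low-intensity probes; the platform-customary default is 100.
#'
#' @param iMeth,iUnmeth numeric vectors of methylated / unmethylated
#'   fluorescence intensities.
#' @param alphaOffset nonnegative regularising offset.
#' @return beta-values in \[0, 1\]; `NA` where the denominator is zero.
#' @examples
#' betaFromIntensities(900, 0, 100)   # 0.9
#' @export
betaFromIntensities <- function(iMeth, iUnmeth, alphaOffset = 100) {
  if (any(alphaOffset < 0)) stop("alphaOffset must be nonnegative")
  den <- abs(iMeth) + abs(iUnmeth) + alphaOffset
  out <- pmax(iMeth, 0) / den
  out[den == 0] <- NA_real_
  out
}

#' M-value (logit2) transform of beta-values
#'
#' M = log2(beta / (1 - beta)), with beta clipped to \[eps, 1 - eps\] first so
#' the transform is finite. The M scale is approximately homoscedastic and is
#' the usual modelling scale for array methylation.
#'
#' @param beta beta-values in \[0, 1\] (vector or matrix).
#' @param eps clipping bound; the default 1e-6 caps |M| near 19.93.
#' @return M-values, same shape as `beta`.
#' @seealso [betaFromM()] for the inverse.
#' @export
mFromBeta <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Inverse of the M-value transform
#' @param m M-values.
#' @return beta-values in (0, 1).
#' @export
betaFromM <- function(m) 1 / (1 + 2^(-m))

newQCReport <- function() {
  list(excluded_samples = data.frame(sample_id = character(),
                                     reason = character()),
       excluded_probes = data.frame(probe_id = character(),
                                    reason = character()))
}

#' Sample-level quality control
#'
#' Cells whose detection p-value exceeds `detectionPCutoff` are set missing;
#' samples whose overall missing rate then exceeds `maxMissingRate` are
#' removed. Each removed sample is recorded with a single primary reason.
#'
#' @param mset a [MethylationSet-class].
#' @param detectionPCutoff per-cell detection p-value threshold (set `NA` to
#'   skip masking, e.g. when no detection p-values are available).
#' @param maxMissingRate maximum tolerated per-sample missing fraction.
#' @return `list(mset =, report =)` where `report$excluded_samples` names the
#'   removed samples.
#' @export
qcFilterSamples <- function(mset, detectionPCutoff = 0.001,
                            maxMissingRate = 0.05) {
  stopifnot(is(mset, "MethylationSet"))
  b <- betaValues(mset)
  dp <- detectionP(mset)
  if (!is.null(dp) && !is.na(detectionPCutoff)) {
    b[!is.na(dp) & dp > detectionPCutoff] <- NA_real_
  }
  missRate <- colMeans(is.na(b))
  drop <- missRate > maxMissingRate
  report <- newQCReport()
  if (any(drop)) {
    report$excluded_samples <- data.frame(
      sample_id = colnames(b)[drop],
      reason = sprintf("missing_rate_%.3f_above_%.3f",
                       missRate[drop], maxMissingRate))
  }
  out <- MethylationSet(
    beta = b[, !drop, drop = FALSE],
    sampleSheet = sampleSheet(mset)[!drop, , drop = FALSE],
    probeAnnotation = probeAnnotation(mset),
    detectionP = if (is.null(dp)) NULL else dp[, !drop, drop = FALSE])
  list(mset = out, report = report)
}

#' Probe-level quality control
#'
#' Removes probes that (in fixed precedence order, each probe counted once
#' under its first matching rule) have a missing rate above `maxMissingRate`,
#' overlap a SNP, or are not uniquely mapped. The SNP and mapping flags come
#' from the probe annotation (`snp_overlap`, `unique_mapping`).
#'
#' @inheritParams qcFilterSamples
#' @param maxMissingRate maximum tolerated per-probe missing fraction.
#' @return `list(mset =, report =)`; `report$excluded_probes$reason` is one of
#'   `"missing"`, `"snp_overlap"`, `"non_unique_mapping"`.
#' @export
qcFilterProbes <- function(mset, maxMissingRate = 0.05) {
  stopifnot(is(mset, "MethylationSet"))
  b <- betaValues(mset)
  ann <- probeAnnotation(mset)
  need <- c("snp_overlap", "unique_mapping")
  if (!all(need %in% names(ann)))
    stop("probe annotation must provide columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  missRate <- rowMeans(is.na(b))
  reason <- rep(NA_character_, nrow(b))
  reason[!as.logical(ann$unique_mapping)] <- "non_unique_mapping"
  reason[as.logical(ann$snp_overlap)] <- "snp_overlap"
  reason[missRate > maxMissingRate] <- "missing"   # highest precedence last
  drop <- !is.na(reason)
  report <- newQCReport()
  if (any(drop)) {
    report$excluded_probes <- data.frame(probe_id = rownames(b)[drop],
                                         reason = reason[drop])
  }
  dp <- detectionP(mset)
  out <- MethylationSet(
    beta = b[!drop, , drop = FALSE],
    sampleSheet = sampleSheet(mset),
    probeAnnotation = probeAnnotation(mset)[!drop, , drop = FALSE],
    detectionP = if (is.null(dp)) NULL else dp[!drop, , drop = FALSE])
  list(mset = out, report = report)
}

#' Remove phenotype outliers by a z-score rule
#'
#' Samples whose value of `variable` lies more than `kSd` standard deviations
#' from the mean are removed. Mean and SD are computed once on the full sheet
#' (no iteration); missing values are never flagged as outliers.
#'
#' @param sheet a sample-sheet `data.frame`.
#' @param variable name of a numeric column (default `"bmi"`).
#' @param kSd standard-deviation multiplier (default 3).
#' @return `list(sheet =, report =)`.
#' @export
removePhenotypeOutliers <- function(sheet, variable = "bmi", kSd = 3) {
  stopifnot(variable %in% names(sheet))
  x <- sheet[[variable]]
  if (!is.numeric(x)) stop("variable must be numeric: ", variable)
  report <- newQCReport()
  if (all(is.na(x))) {
    warning("all values of ", variable, " missing; no outlier screen applied")
    return(list(sheet = sheet, report = report))
  }
  mu <- mean(x, na.rm = TRUE)
  sdv <- stats::sd(x, na.rm = TRUE)
  drop <- if (is.na(sdv) || sdv == 0 || !is.finite(kSd)) {
    rep(FALSE, length(x))
  } else {
    !is.na(x) & abs(x - mu) > kSd * sdv
  }
  if (any(drop)) {
    report$excluded_samples <- data.frame(
      sample_id = sheet$sample_id[drop],
      reason = sprintf("%s_outlier_beyond_%g_sd", variable, kSd))
  }
  list(sheet = sheet[!drop, , drop = FALSE], report = report)
}

# Exhaustive active-set solver for min ||b - R w||^2, w >= 0, sum(w) = 1.
# k is small (six leukocyte types) so all 2^k - 1 supports are scanned;
# each equality-constrained subproblem is solved by Lagrange elimination.
simplexLsq <- function(R, b) {
  k <- ncol(R)
  best <- NULL; bestVal <- Inf
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    Rs <- R[, idx, drop = FALSE]
    G <- crossprod(Rs)
    a <- crossprod(Rs, b)
    one <- rep(1, length(idx))
    # KKT: [G 1; 1' 0] [w; lambda] = [a; 1]
    M <- rbind(cbind(G, one), c(one, 0))
    sol <- tryCatch(solve(M, c(a, 1)), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_along(idx)]
    if (any(w < -1e-9)) next
    w <- pmax(w, 0); w <- w / sum(w)
    val <- sum((b - Rs %*% w)^2)
    if (val < bestVal - 1e-12) { bestVal <- val; best <- list(idx = idx, w = w) }
  }
  if (is.null(best)) stop("constrained least squares failed (rank-deficient reference?)")
  out <- numeric(k)
  out[best$idx] <- best$w
  out
}

#' Reference-based cell-type proportion estimation
#'
#' Houseman-style constrained projection: for each sample, the beta-values at
#' cell-type marker sites are regressed on the reference profile under
#' nonnegativity and sum-to-one constraints, yielding interpretable mixing
#' proportions for the leukocyte subtypes.
#'
#' @param x a [MethylationSet-class] or a probe-by-sample beta matrix.
#' @param reference marker-by-cell-type matrix of reference beta profiles;
#'   rownames are marker probe ids present in `x`, colnames are cell types
#'   (e.g. granulocyte, monocyte, NK, B, CD4T, CD8T).
#' @return `data.frame` with `sample_id` and one proportion column per cell
#'   type; rows sum to one.
#' @export
estimateCellProportions <- function(x, reference) {
  b <- if (is(x, "MethylationSet")) betaValues(x) else as.matrix(x)
  reference <- as.matrix(reference)
  if (is.null(rownames(reference)))
    stop("reference must have marker probe ids as rownames")
  if (qr(reference)$rank < ncol(reference))
    stop("reference profile is rank deficient")
  markers <- intersect(rownames(reference), rownames(b))
  if (length(markers) < ncol(reference))
    stop("too few reference markers present in the matrix")
  R <- reference[markers, , drop = FALSE]
  B <- b[markers, , drop = FALSE]
  W <- matrix(NA_real_, ncol(B), ncol(R),
              dimnames = list(colnames(B), colnames(R)))
  for (j in seq_len(ncol(B))) {
    keep <- !is.na(B[, j])
    W[j, ] <- simplexLsq(R[keep, , drop = FALSE], B[keep, j])
  }
  data.frame(sample_id = rownames(W), as.data.frame(W), row.names = NULL,
             check.names = FALSE)
}
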