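# Sex-stratified site-wise association of methylation with smoking, with
# random effects for chip/batch and co-twin pair, BH-FDR control and
# genomic-control diagnostics.

#' Association model specification
#'
#' @param outcomeScale `"beta"` (direct biological interpretation) or `"M"`
#'   (approximately homoscedastic logit2 scale).
#' @param exposure `"current_vs_noncurrent"` (current smokers against past
#'   plus never) or `"pack_years"` (cumulative dose among smokers).
#' @param covariates fixed-effect covariate names from the sample sheet
#'   (e.g. `age`, `bmi`); cell-proportion columns may be included and are
#'   entered as k-1 compositional covariates via `dropCellType`.
#' @param randomTerms subset of `c("batch", "pair")`: independent random
#'   intercepts, crossed (twins share a chip only sometimes).
#' @param stratum named filter applied to the sheet, e.g.
#'   `c(sex = "male")`.
#' @param cellColumns names of cell-proportion columns in the sheet, if any.
#' @param dropCellType which cell-proportion column to drop (default the
#'   first, conventionally the granulocyte majority type).
#' @param packYearsSmokersOnly restrict the `pack_years` exposure to current
#'   and past smokers with positive pack-years (default `TRUE`).
#' @param extraCovariates optional additional exposure adjustment, e.g.
#'   `"smoking_current"` to condition a pack-years model on current status.
#' @return a `ModelSpec` (named list).
#' @export
modelSpec <- function(outcomeScale = c("beta", "M"),
                      exposure = c("current_vs_noncurrent", "pack_years"),
                      covariates = c("age", "bmi"),
                      randomTerms = character(),
                      stratum = c(sex = "male"),
                      cellColumns = character(),
                      dropCellType = NULL,
                      packYearsSmokersOnly = TRUE,
                      extraCovariates = character()) {
  spec <- list(outcomeScale = match.arg(outcomeScale),
               exposure = match.arg(exposure),
               covariates = covariates,
               randomTerms = intersect(randomTerms, c("batch", "pair")),
               stratum = stratum,
               cellColumns = cellColumns,
               dropCellType = if (is.null(dropCellType) &&
                                    length(cellColumns))
                 cellColumns[1] else dropCellType,
               packYearsSmokersOnly = packYearsSmokersOnly,
               extraCovariates = extraCovariates)
  class(spec) <- "ModelSpec"
  spec
}

.applyStratum <- function(sheet, stratum) {
  keep <- rep(TRUE, nrow(sheet))
  for (v in names(stratum)) keep <- keep & sheet[[v]] %in% stratum[[v]]
  keep
}

# Build the model frame for a spec: exposure column, covariates, random
# grouping factors. Returns NULL rows where the exposure is undefined.
.buildFrame <- function(sheet, spec) {
  keep <- if (length(spec$stratum)) .applyStratum(sheet, spec$stratum)
          else rep(TRUE, nrow(sheet))
  sh <- sheet[keep, , drop = FALSE]
  if (spec$exposure == "current_vs_noncurrent") {
    expo <- as.numeric(sh$smoking_status == "current")
  } else {
    if (!"pack_years" %in% names(sh))
      stop("pack_years exposure requires a pack_years column (or ",
           "years_smoked + cigarettes_per_day) in the sample sheet")
    expo <- sh$pack_years
    if (isTRUE(spec$packYearsSmokersOnly)) {
      inStr <- sh$smoking_status %in% c("current", "past") &
        !is.na(sh$pack_years) & sh$pack_years > 0
      expo[!inStr] <- NA
    }
  }
  fr <- data.frame(.exposure = expo)
  if ("smoking_current" %in% spec$extraCovariates)
    fr$smoking_current <- as.numeric(sh$smoking_status == "current")
  cells <- setdiff(spec$cellColumns, spec$dropCellType)
  for (v in c(spec$covariates, cells,
              setdiff(spec$extraCovariates, "smoking_current")))
    fr[[v]] <- sh[[v]]
  if ("batch" %in% spec$randomTerms) fr$.batch <- factor(sh$batch_id)
  if ("pair" %in% spec$randomTerms) {
    pid <- sh$pair_id
    pid[is.na(pid)] <- paste0(".single", seq_len(sum(is.na(pid))))
    fr$.pair <- factor(pid)
  }
  list(frame = fr, keep = keep)
}

.fitOne <- function(y, fr, spec, minN = 10L) {
  dat <- cbind(.y = y, fr)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  nUsed <- nrow(dat)
  fail <- function(msg) data.frame(estimate = NA_real_, se = NA_real_,
                                   t_stat = NA_real_, p = NA_real_,
                                   n_used = nUsed, note = msg)
  if (nUsed < minN) return(fail("too_few_complete_cases"))
  if (length(unique(dat$.exposure)) < 2) return(fail("constant_exposure"))
  fixed <- setdiff(names(dat), c(".y", ".batch", ".pair"))
  rhs <- paste(fixed, collapse = " + ")
  nFixed <- length(fixed) + 1L
  if (any(c(".batch", ".pair") %in% names(dat))) {
    rterms <- c(if (".batch" %in% names(dat)) "(1 | .batch)",
                if (".pair" %in% names(dat)) "(1 | .pair)")
    fml <- stats::as.formula(paste(".y ~", rhs, "+",
                                   paste(rterms, collapse = " + ")))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) return(fail("singular_fit"))
    cf <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    i <- which(names(cf) == ".exposure")
    est <- cf[i]; se <- sqrt(vc[i, i])
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- tryCatch(stats::lm(fml, data = dat), error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[".exposure"]))
      return(fail("singular_fit"))
    sm <- summary(fit)$coefficients
    est <- sm[".exposure", 1]; se <- sm[".exposure", 2]
  }
  df <- nUsed - nFixed
  tst <- est / se
  data.frame(estimate = unname(est), se = unname(se), t_stat = unname(tst),
             p = 2 * stats::pt(-abs(tst), df = max(df, 1)),
             n_used = nUsed, note = NA_character_)
}

#' Fit the association model at one site
#'
#' Linear model of a methylation outcome on the exposure with the spec's
#' covariates; with random terms, a linear mixed model with independent
#' random intercepts per grouping fitted by REML (Wald test on residual
#' degrees of freedom, n minus the fixed-effect count). Without random
#' terms, ordinary least squares.
#'
#' @param values outcome vector, one value per sheet row (on the beta scale;
#'   transformed internally when `spec$outcomeScale == "M"`).
#' @param sheet sample sheet.
#' @param spec a [modelSpec()].
#' @return one-row `data.frame`: `estimate`, `se`, `t_stat`, `p`, `n_used`,
#'   `note` (`NA` or the failure reason).
#' @export
fitSite <- function(values, sheet, spec = modelSpec()) {
  bf <- .buildFrame(sheet, spec)
  y <- values[bf$keep]
  if (spec$outcomeScale == "M") y <- mFromBeta(y)
  .fitOne(y, bf$frame, spec)
}

# Vectorised OLS over all probes sharing one design (no per-site missing).
.fastOls <- function(Y, X, iExposure) {
  qrX <- qr(X)
  cf <- qr.coef(qrX, t(Y))                # p x nsites
  res <- t(Y) - X %*% cf
  df <- nrow(X) - qrX$rank
  s2 <- colSums(res^2) / df
  XtXinv_ii <- chol2inv(qr.R(qrX))[iExposure, iExposure]
  est <- cf[iExposure, ]
  se <- sqrt(s2 * XtXinv_ii)
  tst <- est / se
  data.frame(estimate = est, se = se, t_stat = tst,
             p = 2 * stats::pt(-abs(tst), df = df),
             n_used = nrow(X), note = NA_character_)
}

#' X chromosome-wide association scan
#'
#' Runs [fitSite()] for every probe and attaches Benjamini-Hochberg
#' q-values. When no random terms are requested and no cell of the stratum
#' is missing, all sites share one design matrix and the scan is solved by a
#' single multi-response least-squares decomposition.
#'
#' @param x a [MethylationSet-class] or probe-by-sample beta matrix.
#' @param sheet sample sheet (taken from `x` when omitted).
#' @param spec a [modelSpec()].
#' @return `data.frame` with `probe_id`, `estimate`, `se`, `t_stat`, `p`,
#'   `q`, `n_used`, `note`, ordered as the input probes.
#' @export
ewas <- function(x, sheet = NULL, spec = modelSpec()) {
  b <- if (is(x, "MethylationSet")) betaValues(x) else as.matrix(x)
  if (is.null(sheet)) {
    if (!is(x, "MethylationSet"))
      stop("sheet required when x is a plain matrix")
    sheet <- sampleSheet(x)
  }
  bf <- .buildFrame(sheet, spec)
  Y <- b[, bf$keep, drop = FALSE]
  if (spec$outcomeScale == "M") Y <- mFromBeta(Y)
  fr <- bf$frame
  useFast <- !any(c(".batch", ".pair") %in% names(fr)) &&
    !anyNA(fr) && !anyNA(Y)
  if (useFast) {
    X <- stats::model.matrix(~ ., data = fr)
    res <- .fastOls(Y, X, which(colnames(X) == ".exposure"))
  } else {
    res <- do.call(rbind, lapply(seq_len(nrow(Y)), function(i)
      .fitOne(Y[i, ], fr, spec)))
  }
  out <- cbind(probe_id = rownames(b), res)
  out$q <- bhFdr(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with the usual cumulative-minimum monotonicity enforcement
#' (delegates to [stats::p.adjust()]). `NA` p-values give `NA` q-values.
#'
#' @param pvalues numeric p-values in (0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bhFdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Genomic-control inflation factor
#'
#' lambda = median observed chi-square(1) statistic / 0.4549 (the null
#' median), with statistics obtained by the quantile transform of the
#' two-sided p-values. Values near 1 indicate a calibrated scan.
#'
#' @param pvalues numeric p-values in (0, 1\].
#' @return lambda (double).
#' @export
genomicLambda <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Plot-ready QQ and Manhattan tables
#'
#' @param table an [ewas()] result.
#' @param annotation probe annotation with `probe_id`, `chromosome`,
#'   `position`.
#' @param fdrAlpha threshold used to place the Manhattan significance line.
#' @return `list(qq =, manhattan =, fdr_line =)`: the QQ table pairs sorted
#'   observed -log10 p with expected quantiles -log10((i - 0.5) / m); the
#'   Manhattan table maps position to -log10 p; `fdr_line` is the -log10 of
#'   the largest BH-significant p (or `NA` if none).
#' @export
qqManhattanData <- function(table, annotation, fdrAlpha = 0.05) {
  ok <- !is.na(table$p)
  p <- table$p[ok]
  m <- length(p)
  if (m == 0) stop("no usable p-values")
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sort(p)))
  ann <- annotation[match(table$probe_id, annotation$probe_id), ]
  manhattan <- data.frame(probe_id = table$probe_id,
                          chromosome = ann$chromosome,
                          position = ann$position,
                          neglog10_p = -log10(table$p),
                          q = table$q)
  sig <- !is.na(table$q) & table$q < fdrAlpha
  fdrLine <- if (any(sig)) -log10(max(table$p[sig])) else NA_real_
  list(qq = qq, manhattan = manhattan, fdr_line = fdrLine)
}
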