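# Fixed-effect inverse-variance meta-analysis with Cochran's Q and
# I-squared heterogeneity diagnostics, plus forest-plot data export.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights w_i = 1 / se_i^2; combined estimate sum(w b) / sum(w) with
#' standard error (sum w)^(-1/2); z = combined / se with a two-sided normal
#' p-value. Heterogeneity: Cochran's Q = sum w_i (b_i - combined)^2 on
#' k - 1 degrees of freedom, and I2 = max(0, (Q - df) / Q) * 100 (0 when
#' Q = 0). With a single study the estimate passes through and Q/I2 are
#' undefined.
#'
#' @param estimates per-study effect estimates.
#' @param ses per-study standard errors (> 0).
#' @param labels optional study labels.
#' @param probe_id,scale optional metadata carried into the result.
#' @return `list` of class `MetaResult`: `combined_estimate`, `combined_se`,
#'   `z`, `p`, `q_stat`, `q_df`, `q_p`, `i2`, and a `studies` data.frame.
#' @examples
#' fixedEffectMeta(c(0.058, 0.030, 0.028, 0.037),
#'                 c(0.009, 0.013, 0.016, 0.014))
#' @export
fixedEffectMeta <- function(estimates, ses, labels = NULL,
                            probe_id = NA_character_, scale = "beta") {
  k <- length(estimates)
  if (k < 1) stop("need at least one study")
  if (length(ses) != k) stop("estimates and ses must have equal length")
  if (any(is.na(estimates)) || any(is.na(ses)) || any(ses <= 0))
    stop("all studies need finite estimates and positive SEs")
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  w <- 1 / ses^2
  comb <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- comb / se
  p <- 2 * stats::pnorm(-abs(z))
  if (k >= 2) {
    q <- sum(w * (estimates - comb)^2)
    qdf <- k - 1L
    qp <- stats::pchisq(q, df = qdf, lower.tail = FALSE)
    i2 <- if (q > 0) max(0, (q - qdf) / q) * 100 else 0
  } else {
    q <- NA_real_; qdf <- NA_integer_; qp <- NA_real_; i2 <- NA_real_
  }
  out <- list(probe_id = probe_id, scale = scale,
              combined_estimate = comb, combined_se = se, z = z, p = p,
              q_stat = q, q_df = qdf, q_p = qp, i2 = i2,
              studies = data.frame(cohort_id = labels, estimate = estimates,
                                   se = ses, weight = w / sum(w)))
  class(out) <- "MetaResult"
  out
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis (%s scale%s)\n", x$scale,
              if (is.na(x$probe_id)) "" else paste0(", ", x$probe_id)))
  cat(sprintf("  combined: %.4g (se %.3g), z = %.3g, p = %.3g\n",
              x$combined_estimate, x$combined_se, x$z, x$p))
  if (!is.na(x$q_stat))
    cat(sprintf("  heterogeneity: Q = %.3g on %d df (p = %.3g), I2 = %.1f%%\n",
                x$q_stat, x$q_df, x$q_p, x$i2))
  invisible(x)
}

#' Forest-plot data for a meta-analysis
#'
#' @param result a [fixedEffectMeta()] result.
#' @param ciLevel normal-theory confidence level (default 0.95).
#' @return `data.frame` of per-study rows plus a `"combined"` row, each with
#'   `estimate`, `se`, `lower`, `upper`, `weight`.
#' @export
forestData <- function(result, ciLevel = 0.95) {
  stopifnot(inherits(result, "MetaResult"), ciLevel > 0, ciLevel < 1)
  zq <- stats::qnorm(1 - (1 - ciLevel) / 2)
  st <- result$studies
  rows <- data.frame(row = c(st$cohort_id, "combined"),
                     estimate = c(st$estimate, result$combined_estimate),
                     se = c(st$se, result$combined_se),
                     weight = c(st$weight, 1))
  rows$lower <- rows$estimate - zq * rows$se
  rows$upper <- rows$estimate + zq * rows$se
  rows
}

#' Meta-analyse selected sites across cohort association tables
#'
#' @param tables named list of [ewas()] result tables, one per cohort.
#' @param sites probe ids to combine (default: sites present in every
#'   table).
#' @param scale label recorded in each result.
#' @return named list of `MetaResult`, one per site.
#' @export
metaAcrossCohorts <- function(tables, sites = NULL, scale = "beta") {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (cohort ids)")
  if (is.null(sites))
    sites <- Reduce(intersect, lapply(tables, `[[`, "probe_id"))
  out <- lapply(sites, function(s) {
    est <- vapply(tables, function(tb)
      tb$estimate[match(s, tb$probe_id)], 0)
    se <- vapply(tables, function(tb) tb$se[match(s, tb$probe_id)], 0)
    ok <- !is.na(est) & !is.na(se) & se > 0
    fixedEffectMeta(est[ok], se[ok], labels = names(tables)[ok],
                    probe_id = s, scale = scale)
  })
  stats::setNames(out, sites)
}
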