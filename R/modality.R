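# Modality screening with the Hartigan-Hartigan dip statistic and a
# simulation-calibrated empirical null.

#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest possible value, over all unimodal
#' distribution functions G, of the maximum absolute difference between G and
#' the empirical distribution function of the sample. Large dips indicate
#' multimodality. The statistic is invariant under strictly increasing affine
#' transforms of the data, lies in \[0, 0.25\], and is at least 1/(2n) for
#' samples with at least two distinct values.
#'
#' The implementation solves the minimax problem exactly: for a candidate dip
#' value it tests whether a convex-then-concave distribution function (an
#' atom is allowed at the mode) can thread the band of half-width d around
#' the empirical CDF, and bisects on d. Ties contribute single jumps of mass
#' k/n, matching the distribution-function definition.
#'
#' @param x numeric vector, finite, length >= 1.
#' @return the dip statistic (double).
#' @examples
#' dipStatistic(c(0, 0, 0, 1, 1, 1))  # 0.25, two point masses
#' dipStatistic(rep(1, 10))           # 0, a point mass is unimodal
#' @export
dipStatistic <- function(x) {
  if (length(x) == 0) stop("empty input")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in input")
  .dipStatCpp(as.numeric(x))
}

# Independently coded pure-R reference implementation (vectorised band
# feasibility + bisection), used for cross-checks; O(K^2) per bisection step.
dipStatisticR <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  t <- unique(x); K <- length(t)
  if (K <= 1) return(0)
  cnt <- cumsum(tabulate(match(x, t), K))

  passDir <- function(t, l, u) {
    K <- length(t)
    # steepest forcing slope per j over earlier upper points, clipped at 0
    S <- outer(l, u, "-") / outer(t, t, "-")   # S[j,i] slope (t_i < t_j)
    S[!lower.tri(S)] <- -Inf
    s <- pmax(apply(S, 1, max), 0); s[1] <- 0
    # line_j evaluated at t_k (k >= j)
    E <- outer(l - s * t, rep(1, K)) + outer(s, t)   # E[j,k]
    E[!(row(E) <= col(E))] <- -Inf
    envIncl <- apply(E, 2, max)                        # lines j <= k at t_k
    envExcl <- vapply(seq_len(K), function(k)          # lines j <  k at t_k
      if (k == 1) -Inf else max(E[seq_len(k - 1), k]), 0)
    Afull <- pmax(envIncl, pmax(l, 0))
    prefixOK <- cumprod(Afull <= u + 1e-12) > 0
    Atil <- pmax(c(0, l[-K]), pmax(envExcl, 0))
    ok <- c(TRUE, prefixOK[-K]) & (Atil <= u + 1e-12)
    list(Atil = Atil, ok = ok)
  }
  feasible <- function(d) {
    l <- pmax(0, cnt / n - d)
    u <- pmin(1, c(0, cnt[-K]) / n + d)
    L <- passDir(t, l, u)
    R <- passDir(rev(-t), rev(1 - u), rev(1 - l))
    p <- K:1
    any(L$ok & R$ok[p] & (L$Atil <= 1 - R$Atil[p] + 1e-12))
  }
  lo <- 0; hi <- 0.25
  if (feasible(lo)) return(0)
  for (i in 1:44) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Build a dip null table by uniform simulation
#'
#' Simulates `nSim` samples of size `n` from the uniform distribution (the
#' asymptotically least favourable unimodal distribution), computes each dip,
#' and stores the sorted statistics. Empirical p-values for observed dips at
#' this sample size are rank comparisons against the table.
#'
#' @param n sample size (>= 4).
#' @param nSim number of simulations (>= 1000). The attainable p-value floor
#'   is 1/(nSim + 1).
#' @param seed integer seed; the table is reproducible under it.
#' @return a [DipNullTable-class].
#' @export
buildNullTable <- function(n, nSim = 1e5, seed = 1L) {
  n <- as.integer(n); nSim <- as.integer(nSim); seed <- as.integer(seed)
  if (n < 4L) stop("null tables require n >= 4")
  if (nSim < 1000L) stop("nSim must be at least 1000")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  dips <- .dipNullCpp(n, nSim)
  methods::new("DipNullTable", n = n, nSim = nSim, dips = dips, seed = seed)
}

#' Empirical dip p-value from a null table
#'
#' p = (1 + #\{null dips >= observed\}) / (nSim + 1). When the observed dip
#' exceeds every simulated null dip the p-value is reported as the floor
#' 1/(nSim + 1) with `p_is_bound = TRUE`, i.e. "p < floor" — the finite-
#' simulation analogue of capping extremely small empirical p-values.
#'
#' @param dip observed dip statistic.
#' @param table a [DipNullTable-class] for the matching sample size.
#' @return `list(empirical_p =, p_is_bound =)`.
#' @export
dipPvalue <- function(dip, table) {
  stopifnot(is(table, "DipNullTable"))
  nSim <- table@nSim
  nGe <- nSim - findInterval(dip, table@dips, left.open = TRUE)
  if (nGe == 0L) {
    list(empirical_p = 1 / (nSim + 1), p_is_bound = TRUE)
  } else {
    list(empirical_p = (1 + nGe) / (nSim + 1), p_is_bound = FALSE)
  }
}

# plain-TSV persistence for null tables (header line + sorted dips)
.writeNullTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d nSim=%d seed=%d", table@n, table@nSim,
                     table@seed), con)
  writeLines(format(table@dips, digits = 17, trim = TRUE), con)
  invisible(path)
}

.readNullTable <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  dips <- as.numeric(readLines(path)[-1])
  methods::new("DipNullTable", n = meta[1], nSim = meta[2], dips = dips,
               seed = meta[3])
}

#' Screen every probe for multimodality within a stratum
#'
#' Computes the dip of each probe's non-missing beta-values restricted to a
#' sample stratum (typically males only, since X inactivation makes many
#' female X-linked sites hemimethylated and hence pooled-sex distributions
#' bimodal), attaches empirical p-values from uniform null tables, and calls
#' each site unimodal or not at the configured corrected level.
#'
#' Null tables are simulated per distinct complete-case size; when the exact
#' size has no table (after `nearestN` consolidation) the nearest tabulated
#' size is used and recorded in `null_n`.
#'
#' @param x a [MethylationSet-class] or probe-by-sample beta matrix.
#' @param stratum logical/integer/character vector selecting samples
#'   (default: all).
#' @param alpha significance level for rejecting unimodality.
#' @param correction `"bonferroni"` (alpha divided by the number of screened
#'   sites) or `"none"`.
#' @param nSim simulations per null table.
#' @param seed integer seed for the null simulations.
#' @param nullTables optional pre-built list of [DipNullTable-class] objects
#'   (as returned by a previous run's `attr(, "nullTables")`) to reuse.
#' @param cacheDir optional directory; null tables are persisted there as
#'   plain TSV (one file per `(n, nSim, seed)`) and reloaded on later runs,
#'   so repeated screens at the same stratum sizes skip the simulation.
#' @param minN probes with fewer than `minN` non-missing values in the
#'   stratum are flagged (`NA` call) rather than tested.
#' @return `data.frame` with columns `probe_id`, `n`, `null_n`, `dip`,
#'   `empirical_p`, `p_is_bound`, `unimodal_call`; the null tables used are
#'   attached as `attr(, "nullTables")`.
#' @export
modalityScreen <- function(x, stratum = NULL, alpha = 0.05,
                           correction = c("bonferroni", "none"),
                           nSim = 1e4, seed = 1L, nullTables = NULL,
                           cacheDir = NULL, minN = 4L) {
  correction <- match.arg(correction)
  b <- if (is(x, "MethylationSet")) betaValues(x) else as.matrix(x)
  if (!is.null(stratum)) b <- b[, stratum, drop = FALSE]
  if (ncol(b) == 0) stop("empty stratum")
  nn <- nrow(b)
  ns <- rowSums(!is.na(b))
  testable <- ns >= minN
  threshold <- if (correction == "bonferroni") alpha / max(sum(testable), 1L)
               else alpha
  if (threshold > 0 && 1 / (nSim + 1) > threshold)
    warning(sprintf(paste0(
      "p-value floor 1/(nSim+1) = %.3g exceeds the corrected threshold ",
      "%.3g; no site can be called multimodal at this nSim"),
      1 / (nSim + 1), threshold))
  # one null table per distinct testable n
  sizes <- sort(unique(ns[testable]))
  if (is.null(nullTables)) nullTables <- list()
  for (sz in sizes) {
    key <- as.character(sz)
    if (!is.null(nullTables[[key]])) next
    cacheFile <- if (!is.null(cacheDir))
      file.path(cacheDir, sprintf("dipnull_n%d_sim%d_seed%d.tsv",
                                  sz, as.integer(nSim),
                                  as.integer(seed + sz)))
    if (!is.null(cacheFile) && file.exists(cacheFile)) {
      nullTables[[key]] <- .readNullTable(cacheFile)
    } else {
      nullTables[[key]] <- buildNullTable(sz, nSim = nSim,
                                          seed = seed + sz)
      if (!is.null(cacheFile)) {
        dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
        .writeNullTable(nullTables[[key]], cacheFile)
      }
    }
  }
  tabSizes <- as.integer(names(nullTables))
  out <- data.frame(probe_id = rownames(b), n = ns,
                    null_n = NA_integer_, dip = NA_real_,
                    empirical_p = NA_real_, p_is_bound = NA,
                    unimodal_call = NA, row.names = NULL)
  for (i in which(testable)) {
    v <- b[i, ]
    v <- v[!is.na(v)]
    d <- dipStatistic(v)
    key <- tabSizes[which.min(abs(tabSizes - length(v)))]
    pv <- dipPvalue(d, nullTables[[as.character(key)]])
    out$null_n[i] <- key
    out$dip[i] <- d
    out$empirical_p[i] <- pv$empirical_p
    out$p_is_bound[i] <- pv$p_is_bound
    out$unimodal_call[i] <- !(pv$empirical_p < threshold)
  }
  attr(out, "nullTables") <- nullTables
  attr(out, "threshold") <- threshold
  out
}
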