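# Twin analyses: ACE variance decomposition from MZ/DZ pair covariances and
# the exposure-discordant MZ paired test.

#' Assemble per-pair value tables from a sample sheet
#'
#' @param values outcome vector, one per sheet row.
#' @param sheet sample sheet with `pair_id` and `zygosity`.
#' @return `list(mz =, dz =)`: two-column matrices of co-twin values.
#' @export
pairTable <- function(values, sheet) {
  stopifnot(all(c("pair_id", "zygosity") %in% names(sheet)))
  keep <- !is.na(sheet$pair_id) & !is.na(values)
  pid <- sheet$pair_id[keep]
  complete <- names(which(table(pid) == 2))
  keep <- keep & sheet$pair_id %in% complete
  sp <- split(seq_len(nrow(sheet))[keep], sheet$pair_id[keep])
  m <- t(vapply(sp, function(ix) values[ix], numeric(2)))
  zyg <- vapply(sp, function(ix) sheet$zygosity[ix[1]], "")
  list(mz = m[zyg == "MZ", , drop = FALSE],
       dz = m[zyg == "DZ", , drop = FALSE])
}

.pairCor <- function(pairs) {
  # symmetrised intraclass-style correlation via double entry
  x <- c(pairs[, 1], pairs[, 2]); y <- c(pairs[, 2], pairs[, 1])
  stats::cor(x, y)
}

.falconer <- function(rMz, rDz) {
  a2 <- 2 * (rMz - rDz)
  c2 <- 2 * rDz - rMz
  e2 <- 1 - rMz
  w <- pmax(c(a2, c2, e2), 0)
  if (sum(w) == 0) w <- c(0, 0, 1)
  w / sum(w)
}

.acePairLoglik <- function(w, mzS, dzS) {
  # w = (a2, c2, e2); unit-variance bivariate normal pairs with
  # r_MZ = a2 + c2, r_DZ = a2/2 + c2. mzS/dzS are sufficient statistics
  # list(n, ss, cp): pair count, sum of squares, sum of cross products.
  ll <- 0
  for (i in 1:2) {
    s <- if (i == 1) mzS else dzS
    r <- if (i == 1) w[1] + w[2] else w[1] / 2 + w[2]
    r <- min(max(r, -1 + 1e-10), 1 - 1e-10)
    ll <- ll - s$n * log(2 * pi) - s$n / 2 * log(1 - r^2) -
      (s$ss - 2 * r * s$cp) / (2 * (1 - r^2))
  }
  ll
}

#' ACE variance decomposition from twin pairs
#'
#' Partitions trait variance into additive-genetic (a2), common-environment
#' (c2) and unique-environment (e2) fractions. The trait is standardised to
#' zero mean and unit variance first, so only fractions are estimated.
#'
#' `method = "ml"` maximises the Gaussian pair likelihood of the
#' unit-variance bivariate model with cov_MZ = a2 + c2 and
#' cov_DZ = a2/2 + c2 over the 2-simplex (boundary allowed), via softmax
#' coordinates with multiple starts (three fixed plus the Falconer point);
#' ties break by log-likelihood, then by smaller a2. `method = "falconer"`
#' uses the closed form a2 = 2(r_MZ - r_DZ), c2 = 2 r_DZ - r_MZ,
#' e2 = 1 - r_MZ, truncated to the simplex and renormalised.
#'
#' @param mzPairs,dzPairs two-column matrices of co-twin trait values.
#' @param method `"ml"` or `"falconer"`.
#' @param minPairs minimum pairs per zygosity for the ML fit.
#' @return `data.frame`: `a2`, `c2`, `e2`, `loglik` (`NA` for falconer),
#'   `n_mz_pairs`, `n_dz_pairs`, `converged`, `method`.
#' @export
aceDecompose <- function(mzPairs, dzPairs, method = c("ml", "falconer"),
                         minPairs = 5L) {
  method <- match.arg(method)
  mzPairs <- as.matrix(mzPairs); dzPairs <- as.matrix(dzPairs)
  nMz <- nrow(mzPairs); nDz <- nrow(dzPairs)
  if (method == "ml" && (nMz < minPairs || nDz < minPairs))
    stop("ML fit needs at least ", minPairs, " pairs per zygosity")
  if (nMz < 2 || nDz < 2) stop("need at least 2 pairs per zygosity")
  all_ <- c(mzPairs, dzPairs)
  mu <- mean(all_); sdv <- stats::sd(all_)
  if (sdv == 0) stop("trait has zero variance")
  mz <- (mzPairs - mu) / sdv
  dz <- (dzPairs - mu) / sdv
  rMz <- .pairCor(mz); rDz <- .pairCor(dz)
  fal <- .falconer(rMz, rDz)
  if (method == "falconer") {
    return(data.frame(a2 = fal[1], c2 = fal[2], e2 = fal[3],
                      loglik = NA_real_, n_mz_pairs = nMz, n_dz_pairs = nDz,
                      converged = TRUE, method = "falconer"))
  }
  mzS <- list(n = nMz, ss = sum(mz^2), cp = sum(mz[, 1] * mz[, 2]))
  dzS <- list(n = nDz, ss = sum(dz^2), cp = sum(dz[, 1] * dz[, 2]))
  softmax <- function(th) { e <- exp(c(th, 0)); e / sum(e) }
  negll <- function(th) -.acePairLoglik(softmax(th), mzS, dzS)
  starts <- list(c(0, 0), c(2, -2), c(-2, 2),
                 log(pmax(fal, 1e-6) / max(fal[3], 1e-6))[1:2])
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(stats::optim(st, negll, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    w <- softmax(opt$par)
    cand <- list(w = w, ll = -opt$value,
                 conv = opt$convergence == 0)
    if (is.null(best) || cand$ll > best$ll + 1e-9 ||
        (abs(cand$ll - best$ll) <= 1e-9 && cand$w[1] < best$w[1]))
      best <- cand
  }
  if (is.null(best)) stop("ACE optimisation failed")
  # snap near-boundary coordinates so exact-zero components are reported
  w <- best$w; w[w < 1e-6] <- 0; w <- w / sum(w)
  data.frame(a2 = w[1], c2 = w[2], e2 = w[3], loglik = best$ll,
             n_mz_pairs = nMz, n_dz_pairs = nDz, converged = best$conv,
             method = "ml")
}

#' Paired test in exposure-discordant MZ twins
#'
#' Within MZ pairs discordant for the exposure, genetic and shared
#' environmental influences cancel, so the within-pair difference isolates
#' the unique-environment (exposure) effect. A paired t-test on
#' exposed-minus-unexposed differences, two-sided on n_pairs - 1 degrees of
#' freedom.
#'
#' @param exposed,unexposed trait values of the exposed and unexposed
#'   co-twins, aligned by pair.
#' @return `data.frame`: `n_pairs`, `mean_diff` (exposed - unexposed),
#'   `t_stat`, `p`, `degenerate` (zero-variance differences give `NA` t/p).
#' @export
discordantMzTest <- function(exposed, unexposed) {
  stopifnot(length(exposed) == length(unexposed))
  ok <- !is.na(exposed) & !is.na(unexposed)
  d <- exposed[ok] - unexposed[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 discordant pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd <= 1e-10 * max(abs(md), 1)) {
    return(data.frame(n_pairs = n, mean_diff = md, t_stat = NA_real_,
                      p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(exposed[ok], unexposed[ok], paired = TRUE)
  data.frame(n_pairs = n, mean_diff = md,
             t_stat = unname(tt$statistic), p = tt$p.value,
             degenerate = FALSE)
}

#' Extract discordant MZ pairs for an exposure
#'
#' @param values outcome vector, one per sheet row.
#' @param sheet sample sheet with `pair_id`, `zygosity`, `smoking_status`.
#' @param exposedLevel smoking level counting as exposed (default
#'   `"current"`).
#' @return `list(exposed =, unexposed =)` aligned vectors, one entry per
#'   discordant MZ pair.
#' @export
discordantMzPairs <- function(values, sheet, exposedLevel = "current") {
  keep <- !is.na(sheet$pair_id) & sheet$zygosity %in% "MZ" & !is.na(values)
  sp <- split(seq_len(nrow(sheet))[keep], sheet$pair_id[keep])
  sp <- Filter(function(ix) length(ix) == 2, sp)
  expFlag <- sheet$smoking_status == exposedLevel
  disc <- Filter(function(ix) sum(expFlag[ix]) == 1, sp)
  list(exposed = vapply(disc, function(ix) values[ix[expFlag[ix]]], 0),
       unexposed = vapply(disc, function(ix) values[ix[!expFlag[ix]]], 0))
}
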