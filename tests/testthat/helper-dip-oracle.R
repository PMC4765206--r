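# LP brute-force oracle for the dip statistic: for every candidate mode
# location, minimise d over piecewise-linear unimodal CDFs (convex left of
# the mode, concave right, jump allowed at the mode) constrained to stay
# within d of the empirical CDF; take the minimum across modes.
# Independent of the package's solver: explicit constraint matrices fed to
# the two-phase simplex in helper-simplex.R.
dipLP <- function(x) {
  x <- sort(x); n <- length(x)
  t <- unique(x); K <- length(t)
  if (K <= 1) return(0)
  cc <- cumsum(tabulate(match(x, t), K)) / n
  cprev <- c(0, cc[-K])
  best <- Inf
  for (j in seq_len(K)) {
    m <- K + 2                       # vars: d, v_1..v_K, w (left limit)
    iv <- function(i) 1 + i
    iw <- m
    rows <- list(); rhs <- numeric()
    addrow <- function(coef, b) {
      rows[[length(rows) + 1]] <<- coef; rhs <<- c(rhs, b)
    }
    for (i in seq_len(K)) {
      lo <- cc[i]
      up <- if (i == j) cc[i] else cprev[i]
      r <- numeric(m); r[1] <- -1; r[iv(i)] <- -1; addrow(r, -lo)
      r <- numeric(m); r[1] <- -1; r[iv(i)] <-  1; addrow(r,  up)
      r <- numeric(m); r[iv(i)] <-  1; addrow(r, 1)
    }
    r <- numeric(m); r[1] <- -1; r[iw] <- -1; addrow(r, -cprev[j])
    r <- numeric(m); r[1] <- -1; r[iw] <-  1; addrow(r,  cprev[j])
    r <- numeric(m); r[iw] <- 1; addrow(r, 1)
    chain <- c(if (j > 1) iv(seq_len(j - 1)), iw, iv(j:K))
    for (q in seq_len(length(chain) - 1)) {
      r <- numeric(m); r[chain[q]] <- 1; r[chain[q + 1]] <- -1; addrow(r, 0)
    }
    la <- c(if (j > 1) t[seq_len(j - 1)], t[j])
    lv <- c(if (j > 1) iv(seq_len(j - 1)), iw)
    if (length(la) >= 3) for (q in seq_len(length(la) - 2)) {
      d1 <- la[q + 1] - la[q]; d2 <- la[q + 2] - la[q + 1]
      r <- numeric(m)
      r[lv[q]] <- r[lv[q]] - 1 / d1
      r[lv[q + 1]] <- r[lv[q + 1]] + 1 / d1 + 1 / d2
      r[lv[q + 2]] <- r[lv[q + 2]] - 1 / d2
      addrow(r, 0)
    }
    ra <- t[j:K]; rv <- iv(j:K)
    if (length(ra) >= 3) for (q in seq_len(length(ra) - 2)) {
      d1 <- ra[q + 1] - ra[q]; d2 <- ra[q + 2] - ra[q + 1]
      r <- numeric(m)
      r[rv[q]] <- r[rv[q]] + 1 / d1
      r[rv[q + 1]] <- r[rv[q + 1]] - 1 / d1 - 1 / d2
      r[rv[q + 2]] <- r[rv[q + 2]] + 1 / d2
      addrow(r, 0)
    }
    obj <- numeric(m); obj[1] <- 1
    sol <- simplexLP(obj, do.call(rbind, rows), rhs)
    if (sol$status == 0L) best <- min(best, sol$value)
  }
  best
}
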