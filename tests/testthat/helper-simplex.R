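# Minimal dense two-phase simplex with Bland's rule.
# Solves: min c'x  s.t.  A x <= b,  x >= 0.
# Returns list(value, x, status): status 0 ok, 1 infeasible, 2 unbounded.
simplexLP <- function(cvec, A, b, tol = 1e-9, maxit = 20000L) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  # equality form: for b_i >= 0:  a'x + s_i = b_i
  #                for b_i <  0: -a'x - s_i + r_i = -b_i
  Acon <- cbind(A, diag(m))
  Acon[neg, ] <- -Acon[neg, ]
  rhs <- abs(b) * 0 + ifelse(neg, -b, b)
  nart <- sum(neg)
  if (nart > 0) {
    Art <- matrix(0, m, nart)
    Art[cbind(which(neg), seq_len(nart))] <- 1
    Acon <- cbind(Acon, Art)
  }
  ntot <- ncol(Acon)
  basis <- integer(m)
  basis[!neg] <- n + which(!neg)
  if (nart > 0) basis[neg] <- n + m + seq_len(nart)

  pivot <- function(Tb, pr, pc) {
    Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
    for (i in seq_len(nrow(Tb))) if (i != pr && abs(Tb[i, pc]) > 0)
      Tb[i, ] <- Tb[i, ] - Tb[i, pc] * Tb[pr, ]
    Tb
  }
  # Tb has m constraint rows then one objective row; cols ntot + 1 (rhs last)
  solve_phase <- function(Tb, basis, ncols) {
    orow <- m + 1
    for (it in seq_len(maxit)) {
      enter <- 0L
      for (j in seq_len(ncols)) if (Tb[orow, j] < -tol) { enter <- j; break }
      if (enter == 0L) return(list(Tb = Tb, basis = basis, status = 0L))
      leave <- 0L; best <- Inf
      for (i in seq_len(m)) {
        a <- Tb[i, enter]
        if (a > tol) {
          r <- Tb[i, ncols + 1] / a
          if (r < best - tol ||
              (r <= best + tol && (leave == 0L || basis[i] < basis[leave]))) {
            best <- min(best, r); leave <- i
          }
        }
      }
      if (leave == 0L) return(list(status = 2L))
      Tb <- pivot(Tb, leave, enter)
      basis[leave] <- enter
    }
    list(status = 3L)
  }

  Tb <- rbind(cbind(Acon, rhs), 0)
  if (nart > 0) {
    # phase-1 objective: sum of artificials, reduced over initial basis
    Tb[m + 1, n + m + seq_len(nart)] <- 1
    for (i in which(neg)) Tb[m + 1, ] <- Tb[m + 1, ] - Tb[i, ]
    p1 <- solve_phase(Tb, basis, ntot)
    if (p1$status != 0L) return(list(status = 1L))
    if (p1$Tb[m + 1, ntot + 1] < -1e-7) return(list(status = 1L))
    Tb <- p1$Tb; basis <- p1$basis
    # pivot out artificials still basic (degenerate at zero)
    for (i in which(basis > n + m)) {
      j <- which(abs(Tb[i, seq_len(n + m)]) > tol)[1]
      if (!is.na(j)) { Tb <- pivot(Tb, i, j); basis[i] <- j }
    }
    keep <- c(seq_len(n + m), ntot + 1)
    Tb <- Tb[, keep, drop = FALSE]
    ntot <- n + m
  }
  # phase-2 objective
  Tb[m + 1, ] <- c(cvec, rep(0, ntot - n), 0)
  for (i in seq_len(m)) {
    if (basis[i] > ntot) next  # redundant zero row left from phase 1
    cb <- Tb[m + 1, basis[i]]
    if (abs(cb) > 0) Tb[m + 1, ] <- Tb[m + 1, ] - cb * Tb[i, ]
  }
  p2 <- solve_phase(Tb, basis, ntot)
  if (p2$status != 0L) return(list(status = p2$status))
  x <- numeric(ntot + 1)
  ok <- p2$basis <= ntot
  x[p2$basis[ok]] <- p2$Tb[seq_len(m), ntot + 1][ok]
  list(value = sum(cvec * x[seq_len(n)]), x = x[seq_len(n)], status = 0L)
}
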