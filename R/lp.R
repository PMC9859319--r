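## Dense two-phase primal simplex for equality-form linear programs
##
##   min c'x  subject to  A x = b,  x >= 0,
##
## with Bland's smallest-index rule throughout, so the method cannot cycle on
## the (heavily degenerate) SBM instances this package generates.  Problem
## sizes here are tiny (tens of variables, ~10 constraints), so a full
## tableau is the simplest reliable choice.

## one simplex phase on a tableau kept in canonical form; returns status
## 0 = optimal, 1 = unbounded, 2 = iteration limit
.lp_phase <- function(Ta, basis, cost, tol, max_iter) {
  m <- nrow(Ta); nc <- ncol(Ta) - 1L
  for (it in seq_len(max_iter)) {
    rc <- cost - as.vector(cost[basis] %*% Ta[, seq_len(nc), drop = FALSE])
    ent <- which(rc < -tol)
    if (!length(ent))
      return(list(Ta = Ta, basis = basis, status = 0L))
    j <- min(ent)                               # Bland: entering
    col <- Ta[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = 1L))
    ratio <- Ta[pos, nc + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol * max(1, abs(rmin))]
    i <- cand[which.min(basis[cand])]           # Bland: leaving
    Ta[i, ] <- Ta[i, ] / Ta[i, j]
    for (r in seq_len(m)) if (r != i && Ta[r, j] != 0)
      Ta[r, ] <- Ta[r, ] - Ta[r, j] * Ta[i, ]
    basis[i] <- j
  }
  list(status = 2L)
}

## Solve min c'x, A x = b, x >= 0.  Returns list(x, value, status) with
## status one of "optimal", "infeasible", "unbounded", "iteration_limit".
lp_solve_eq <- function(cc, A, b, tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A); cc <- as.numeric(cc); b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }
  ## scale rows to unit max magnitude for numerical balance
  rs <- apply(abs(cbind(A, b)), 1, max)
  rs[rs == 0] <- 1
  A <- A / rs; b <- b / rs

  ## phase 1: artificial basis
  Ta <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- .lp_phase(Ta, basis, cost1, tol, max_iter)
  if (p1$status != 0L)
    return(list(x = NULL, value = NA_real_, status = "iteration_limit"))
  Ta <- p1$Ta; basis <- p1$basis
  if (sum(Ta[basis > n, ncol(Ta)]) > 1e-7)
    return(list(x = NULL, value = NA_real_, status = "infeasible"))

  ## drive remaining artificials out of the basis (or drop redundant rows)
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    piv <- which(abs(Ta[i, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- piv[1]
      Ta[i, ] <- Ta[i, ] / Ta[i, j]
      for (r in seq_len(nrow(Ta))) if (r != i && Ta[r, j] != 0)
        Ta[r, ] <- Ta[r, ] - Ta[r, j] * Ta[i, ]
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)
  }
  if (length(drop_rows)) {
    Ta <- Ta[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  Ta <- Ta[, c(seq_len(n), n + m + 1L), drop = FALSE]

  ## phase 2
  p2 <- .lp_phase(Ta, basis, cc, tol, max_iter)
  if (p2$status == 1L)
    return(list(x = NULL, value = NA_real_, status = "unbounded"))
  if (p2$status == 2L)
    return(list(x = NULL, value = NA_real_, status = "iteration_limit"))
  x <- numeric(n)
  x[p2$basis] <- p2$Ta[, n + 1L]
  list(x = x, value = sum(cc * x), status = "optimal")
}
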