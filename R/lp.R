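# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   max/min  obj'x   s.t.  Aeq x = beq,  Ain x <= bin,  x >= 0.
#
# Written for the small, frequently degenerate linear programs of
# constraint-based metabolic models (tens of reactions): Bland's rule
# guarantees termination on degenerate bases, and full-tableau pivoting is
# plenty fast at this scale. Returns list(x, value, status) with status one
# of "optimal", "infeasible", "unbounded".

.simplexIterate <- function(tab, basis, cost, nCols, tol) {
  m <- nrow(tab)
  repeat {
    # reduced costs over the permitted columns
    cb <- cost[basis]
    red <- cost[seq_len(nCols)] -
      as.numeric(crossprod(cb, tab[, seq_len(nCols), drop = FALSE]))
    enter <- which(red < -tol)
    if (!length(enter)) return(list(tab = tab, basis = basis,
                                    status = "optimal"))
    j <- enter[1]  # Bland: smallest index enters
    col <- tab[, j]
    rows <- which(col > tol)
    if (!length(rows)) return(list(tab = tab, basis = basis,
                                   status = "unbounded"))
    ratio <- tab[rows, ncol(tab)] / col[rows]
    best <- rows[ratio <= min(ratio) + tol]
    i <- best[which.min(basis[best])]  # Bland: smallest basis index leaves
    # pivot on (i, j)
    tab[i, ] <- tab[i, ] / tab[i, j]
    other <- setdiff(seq_len(m), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
}

simplexSolve <- function(obj, Aeq, beq, Ain = NULL, bin = NULL,
                         maximize = TRUE, tol = 1e-9) {
  Aeq <- as.matrix(Aeq)
  n0 <- length(obj)
  A <- Aeq; b <- as.numeric(beq)
  nSlack <- 0L
  if (!is.null(Ain)) {
    Ain <- as.matrix(Ain)
    nSlack <- nrow(Ain)
    A <- rbind(cbind(A, matrix(0, nrow(A), nSlack)),
               cbind(Ain, diag(nSlack)))
    b <- c(b, as.numeric(bin))
  }
  n <- n0 + nSlack
  m <- nrow(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  ## phase 1: minimise the sum of artificial variables
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- .simplexIterate(tab, basis, cost1, nCols = n + m, tol = tol)
  val1 <- sum(p1$tab[, ncol(p1$tab)][p1$basis > n])
  if (val1 > 1e-7) return(list(x = NULL, value = NA_real_,
                               status = "infeasible"))
  tab <- p1$tab; basis <- p1$basis
  # drive remaining artificials out of the basis (or drop redundant rows)
  drop <- integer()
  for (i in which(basis > n)) {
    piv <- which(abs(tab[i, seq_len(n)]) > tol)
    if (!length(piv)) { drop <- c(drop, i); next }
    j <- piv[1]
    tab[i, ] <- tab[i, ] / tab[i, j]
    other <- setdiff(seq_len(nrow(tab)), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
  if (length(drop)) {
    tab <- tab[-drop, , drop = FALSE]
    basis <- basis[-drop]
  }
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  ## phase 2
  cost2 <- c(if (maximize) -obj else obj, rep(0, nSlack))
  p2 <- .simplexIterate(tab, basis, cost2, nCols = n, tol = tol)
  if (p2$status == "unbounded")
    return(list(x = NULL, value = NA_real_, status = "unbounded"))
  x <- numeric(n)
  x[p2$basis] <- p2$tab[, ncol(p2$tab)]
  x <- pmax(x, 0)  # clip pivot dust
  list(x = x[seq_len(n0)], value = sum(obj * x[seq_len(n0)]),
       status = "optimal")
}
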