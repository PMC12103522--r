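# Linear-programming backends.
#
# Feasibility at fixed mu is the hot path (bisection, grid oracles, gene
# knockouts run thousands of these), so it uses the compiled active-set
# solver in quadprog: minimizing ||v||^2 subject to the constraints either
# returns a (min-norm) feasible point or raises the solver's
# "constraints are inconsistent" error. quadprog's verdict is only
# trustworthy when the equality rows are linearly independent, and
# growth-rate couplings (mu/keff ~ 1e-6 at small mu) make a closed
# reaction's balance row numerically collinear with its fixed-variable
# row. Therefore fixed variables are substituted out of the system, rows
# are equilibrated, the equality block is QR-reduced to an independent
# subset, and the full original system is re-verified on any returned
# point (which also catches inconsistent dependent rows that the
# reduction dropped). Objective optimization (FVA min/max, parsimonious
# flux vectors) goes through boot::simplex, a true LP vertex solver.
# boot::simplex assumes x >= 0 and nonnegative right-hand sides, so
# variables are shifted by their lower bounds and equality rows are
# sign-normalized before the call (it silently returns wrong answers
# otherwise).

# Min-norm feasible point of {S v = 0, lb <= v <= ub}.
# Returns list(feasible, v, residual).
.lpFeasiblePoint <- function(S, lb, ub, tol = 1e-9) {
  n <- length(lb)
  stopifnot(ncol(S) == n)
  tol <- max(tol, 1e-12)
  fixed <- which((ub - lb) <= 1e-12)
  free <- setdiff(seq_len(n), fixed)
  vfix <- (lb[fixed] + ub[fixed]) / 2
  Sfull <- S[, free, drop = FALSE]
  rhs <- if (length(fixed)) {
    -as.numeric(S[, fixed, drop = FALSE] %*% vfix)
  } else {
    rep(0, nrow(S))
  }
  rowmax <- if (length(free)) apply(abs(Sfull), 1, max) else
    rep(0, nrow(S))
  live <- rowmax > 1e-14
  if (any(!live & abs(rhs) > tol)) {
    return(list(feasible = FALSE, v = NULL, residual = max(abs(rhs[!live]))))
  }
  if (!length(free)) {
    v <- numeric(n)
    v[fixed] <- vfix
    res <- max(abs(rhs), 0)
    return(list(feasible = res <= 10 * tol, v = if (res <= 10 * tol) v,
                residual = res))
  }
  # equilibrate: each live row is scaled by its largest remaining
  # coefficient, and residuals are judged on that scale. A balance row
  # whose only live coupling is ~ mu/keff (1e-6 at small mu) must not pass
  # on raw residual alone, or weakly coupled enzyme constraints silently
  # stop binding.
  scale <- pmax(rowmax, 1e-14)
  Sfull <- Sfull / scale
  rhs <- rhs / scale
  verify <- function(vfree) {
    r1 <- abs(as.numeric(Sfull %*% vfree) - rhs)[live]
    max(c(r1, lb[free] - vfree, vfree - ub[free], 0))
  }
  Sf <- Sfull[live, , drop = FALSE]
  rhs2 <- rhs[live]
  # keep an independent subset of equality rows (QR with column pivoting on
  # the transpose); dropped rows are re-checked by verify() below
  if (nrow(Sf) > 1L) {
    dec <- qr(t(Sf), tol = 1e-9)
    if (dec$rank < nrow(Sf)) {
      keep <- sort(dec$pivot[seq_len(dec$rank)])
      Sf <- Sf[keep, , drop = FALSE]
      rhs2 <- rhs2[keep]
    }
  }
  m <- length(free)
  ilo <- diag(m)
  ans <- tryCatch(
    quadprog::solve.QP(Dmat = diag(m), dvec = rep(0, m),
                       Amat = t(rbind(Sf, ilo, -ilo)),
                       bvec = c(rhs2, lb[free], -ub[free]),
                       meq = nrow(Sf)),
    error = function(e) e)
  if (inherits(ans, "error")) {
    if (grepl("inconsistent", conditionMessage(ans))) {
      return(list(feasible = FALSE, v = NULL, residual = NA_real_))
    }
    stop("LP backend failure (quadprog): ", conditionMessage(ans),
         call. = FALSE)
  }
  res <- verify(ans$solution)
  v <- numeric(n)
  v[free] <- ans$solution
  v[fixed] <- vfix
  list(feasible = res <= 10 * tol, v = if (res <= 10 * tol) v,
       residual = res)
}

# Optimize obj'v over {S v = 0, lb <= v <= ub} with boot::simplex.
# Fixed variables are substituted out (zero-width columns trip simplex1's
# basis bookkeeping) and rows are equilibrated: simplex pivoting degrades
# when row scales span many orders of magnitude.
# Returns list(status = "optimal"|"infeasible", value, v).
.lpOptimize <- function(obj, S, lb, ub, maximize = TRUE, eps = 1e-10) {
  n <- length(lb)
  stopifnot(length(obj) == n, ncol(S) == n)
  fixed <- which((ub - lb) <= 1e-12)
  free <- setdiff(seq_len(n), fixed)
  vfix <- (lb[fixed] + ub[fixed]) / 2
  rhs <- if (length(fixed)) {
    -as.numeric(S[, fixed, drop = FALSE] %*% vfix)
  } else {
    rep(0, nrow(S))
  }
  assemble <- function(vfree) {
    v <- numeric(n)
    v[free] <- vfree
    v[fixed] <- vfix
    v
  }
  if (!length(free)) {
    v <- assemble(numeric(0))
    feas <- max(c(abs(as.numeric(S %*% v)), lb - v, v - ub, 0)) <= 1e-8
    return(if (feas) list(status = "optimal", value = sum(obj * v), v = v)
           else list(status = "infeasible", value = NA_real_, v = NULL))
  }
  Sf <- S[, free, drop = FALSE]
  rmax <- apply(abs(Sf), 1, max)
  live <- rmax > 1e-14
  if (any(!live & abs(rhs) > 1e-9)) {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  Sf <- Sf[live, , drop = FALSE] / rmax[live]
  rhs <- rhs[live] / rmax[live]
  m <- length(free)
  # shift: x = v_free - lb_free >= 0, x <= ub - lb
  b3 <- rhs - as.numeric(Sf %*% lb[free])
  A3 <- Sf
  flip <- b3 < 0
  if (any(flip)) {
    A3[flip, ] <- -A3[flip, , drop = FALSE]
    b3[flip] <- -b3[flip]
  }
  ans <- boot::simplex(a = obj[free], A1 = diag(m), b1 = ub[free] - lb[free],
                       A3 = A3, b3 = b3, maxi = maximize,
                       n.iter = 50 * (2 * m + nrow(A3)), eps = eps)
  if (ans$solved == -1) {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  if (ans$solved != 1) {
    stop("LP backend failure (boot::simplex): iteration limit reached",
         call. = FALSE)
  }
  v <- assemble(as.numeric(ans$soln) + lb[free])
  list(status = "optimal", value = sum(obj * v), v = v)
}

# Parsimonious flux vector at a feasible point: minimize total absolute
# flux over sign-fixed reactions (lb >= 0 counts +v, ub <= 0 counts -v,
# genuinely reversible reactions are not penalized). Falls back to the
# given point if the LP fails.
.lpParsimonious <- function(S, lb, ub, fallback) {
  w <- ifelse(lb >= 0, 1, ifelse(ub <= 0, -1, 0))
  ans <- tryCatch(.lpOptimize(w, S, lb, ub, maximize = FALSE),
                  error = function(e) list(status = "failed"))
  if (ans$status == "optimal") ans$v else fallback
}
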