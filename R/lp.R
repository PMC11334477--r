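# Internal LP solver for FBA-sized problems.
#
# A dense two-phase primal simplex with Bland's anti-cycling rule. Flux
# problems are small (tens of variables) but routinely degenerate, so
# robustness is worth more than speed here; correctness is checked against
# brute-force vertex enumeration in the test suite.
#
# Interface: max/min c'v subject to S v = 0 (mass balance), lb <= v <= ub,
# and optional extra inequality rows A v <= b. Internally variables are
# shifted (x = v - lb >= 0) and upper bounds/inequalities become equality
# rows with slack variables.

LP_TOL <- 1e-9

# min c'x  s.t.  A x = b (b >= 0 after row scaling), x >= 0
simplex_core <- function(cc, A, b, tol = LP_TOL) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # tableau with artificial variables: columns = x (n) | artificial (m) | rhs
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  pivot <- function(Tb, r, j) {
    Tb[r, ] <- Tb[r, ] / Tb[r, j]
    other <- setdiff(seq_len(nrow(Tb)), r)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[r, ])
    Tb
  }
  # Bland's rule over allowed columns; returns updated tableau/basis or NULL
  # reduced costs computed from scratch for numerical safety (small problems)
  run_phase <- function(Tb, basis, costs, allowed) {
    repeat {
      cb <- costs[basis]
      red <- costs[allowed] - as.numeric(cb %*% Tb[, allowed, drop = FALSE])
      ent <- allowed[which(red < -tol)]
      if (!length(ent)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- min(ent)                               # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      r <- cand[which.min(basis[cand])]           # Bland: smallest basis index
      Tb <- pivot(Tb, r, j)
      basis[r] <- j
    }
  }

  # phase 1: drive artificials to zero
  ph1_cost <- c(rep(0, n), rep(1, m), 0)
  res <- run_phase(Tb, basis, ph1_cost, seq_len(n + m))
  Tb <- res$Tb; basis <- res$basis
  ph1_val <- sum(ph1_cost[basis] * Tb[, ncol(Tb)])
  if (ph1_val > 1e-7) return(list(status = "infeasible"))
  # pivot lingering artificials out of the basis where possible
  for (r in which(basis > n)) {
    j <- which(abs(Tb[r, seq_len(n)]) > tol)
    if (length(j)) { Tb <- pivot(Tb, r, j[1]); basis[r] <- j[1] }
    # else: redundant row; harmless to leave (rhs is ~0)
  }

  # phase 2 on the original columns
  ph2_cost <- c(cc, rep(0, m), 0)
  res <- run_phase(Tb, basis, ph2_cost, seq_len(n))
  if (res$status == "unbounded") return(list(status = "unbounded"))
  Tb <- res$Tb; basis <- res$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tb[keep, ncol(Tb)]
  list(status = "optimal", x = pmax(x, 0), objective = sum(cc * x))
}

solve_lp <- function(obj, S, lb, ub, A = NULL, b = NULL, maximize = TRUE,
                     tol = LP_TOL) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n, all(ub >= lb))
  u <- ub - lb
  n_extra <- if (is.null(A)) 0L else nrow(A)
  # variable layout: x (n) | ub slacks (n) | extra-ineq slacks
  ntot <- 2L * n + n_extra
  m_eq <- nrow(S)
  rows <- m_eq + n + n_extra
  M <- matrix(0, rows, ntot)
  M[seq_len(m_eq), seq_len(n)] <- S
  rhs <- c(as.numeric(-S %*% lb), u,
           if (n_extra) b - as.numeric(A %*% lb) else numeric())
  M[m_eq + seq_len(n), seq_len(n)] <- diag(n)
  M[m_eq + seq_len(n), n + seq_len(n)] <- diag(n)
  if (n_extra) {
    M[m_eq + n + seq_len(n_extra), seq_len(n)] <- A
    M[m_eq + n + seq_len(n_extra), 2L * n + seq_len(n_extra)] <- diag(n_extra)
  }
  cc <- c(if (maximize) -obj else obj, rep(0, n + n_extra))
  res <- simplex_core(cc, M, rhs)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, fluxes = NULL,
                message = res$status))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), fluxes = v,
       message = "optimal")
}
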