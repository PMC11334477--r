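# Shared fixtures: the study conditions used across modules.

table3_params <- function() {
  physio_params(
    X0 = 0.026, mu = 0.45,
    substrates = list(glycerol = list(S0 = 30, q = 14.7),
                      ethanolamine = list(S0 = 20, q = 7.8)),
    products = list(acetate = list(P0 = 0, q = 1.7),
                    ethanol = list(P0 = 0, q = 2.6)),
    k_evap = c(ethanol = 0.0379))
}

table3_roles <- c(glycerol = "substrate", ethanolamine = "substrate",
                  acetate = "product", ethanol = "product")

# constrained-FBA setting used throughout: measured exchange fluxes with
# growth fixed and ATP maintenance as the objective
measured_constraints <- function() {
  list(BIOMASS = 0.45, EX_ea_e = -7.8, EX_etoh_e = 2.6, EX_ac_e = 1.7,
       EX_glyc_e = -14.7)
}

# brute-force forward convolution of a CID with natural abundances by
# exhaustive enumeration over all heavy-isotope placements (oracle)
brute_force_cid <- function(true_cid, formula, abundances = natural_abundances()) {
  counts <- parse_formula(formula)
  nC <- counts[["C"]]
  out <- numeric(nC + 1)
  # per-atom shift distributions
  atom_dists <- list()
  for (el in names(counts)) {
    shifts <- abundances[[el]]
    atom_dists[[el]] <- c(1 - sum(shifts), shifts)
  }
  # enumerate shifts atom by atom, recursively
  add_atom <- function(dist, atom) {
    res <- numeric(length(dist) + length(atom) - 1)
    for (i in seq_along(dist)) for (j in seq_along(atom))
      res[i + j - 1] <- res[i + j - 1] + dist[i] * atom[j]
    res
  }
  for (j in 0:nC) {
    if (true_cid[j + 1] == 0) next
    dist <- 1
    for (el in names(counts)) {
      n_atoms <- counts[[el]] - if (el == "C") j else 0L
      if (n_atoms > 0) for (k in seq_len(n_atoms))
        dist <- add_atom(dist, atom_dists[[el]])
    }
    # the j labeled carbons are already 13C: shift baseline by j
    shifted <- c(rep(0, j), dist)
    n_keep <- min(length(shifted), nC + 1)
    out[1:n_keep] <- out[1:n_keep] + true_cid[j + 1] * shifted[1:n_keep]
  }
  out / sum(out)
}

# brute-force LP oracle: enumerate all basic feasible points of
# max c'v s.t. S v = 0, lb <= v <= ub by trying all ways to pin
# (n - rank) variables at a bound and solving for the rest
vertex_enum_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- ncol(S)
  r <- qr(S)$rank
  free_n <- n - r
  best <- NULL
  for (fix_idx in combn(n, free_n, simplify = FALSE)) {
    grid <- expand.grid(rep(list(c(1, 2)), free_n))
    for (g in seq_len(nrow(grid))) {
      v_fix <- ifelse(unlist(grid[g, ]) == 1, lb[fix_idx], ub[fix_idx])
      solve_idx <- setdiff(seq_len(n), fix_idx)
      A <- S[, solve_idx, drop = FALSE]
      b <- -as.numeric(S[, fix_idx, drop = FALSE] %*% v_fix)
      sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - b)) > 1e-8) next
      v <- numeric(n)
      v[fix_idx] <- v_fix; v[solve_idx] <- sol
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      val <- sum(obj * v)
      if (is.null(best) || (maximize && val > best) || (!maximize && val < best))
        best <- val
    }
  }
  best
}
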