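# Weighted-SSE objective and particle swarm optimization for the dynamic
# isotopic model.

# quantity/label_state -> state indices in the simulation output (sums over
# two indices express 'total' observables of split pools).
OBS_MAP <- list(
  "biomass.total" = 1L, "glycerol.total" = 2L,
  "ethanolamine.total" = c(3L, 4L),
  "ethanol.unlabeled" = 5L, "ethanol.U-13C" = 6L, "ethanol.total" = c(5L, 6L),
  "acetate.unlabeled" = 7L, "acetate.U-13C" = 8L, "acetate.total" = c(7L, 8L),
  "acetaldehyde.unlabeled" = 9L, "acetaldehyde.U-13C" = 10L,
  "acetaldehyde.total" = c(9L, 10L),
  "ammonium.total" = 11L)

MFA_FREE <- c("X0", "mu", "gly0", "ea0", "nh4_0", "v_gly_uptake",
              "v_glycolysis", "v_EutG", "v_AAL_release", "v_AceX", "v_NH4X",
              "v_cytEtOH", "pool_scale")

# Precompile data + network into a fast objective over the 13-vector of free
# parameters. Avoids per-call data frame construction: raw lsoda matrix
# indexing only.
make_mfa_objective <- function(data, network, tracer_purity = 1) {
  df <- as.data.frame(data)
  if (any(is.na(df$sd)))
    stop("objective requires sigma for every data point (sd column)")
  key <- paste(df$quantity, df$label_state, sep = ".")
  unknown <- setdiff(unique(key), names(OBS_MAP))
  if (length(unknown))
    stop("data series with no simulated observable: ",
         paste(unknown, collapse = ", "))
  times <- sort(unique(df$time_h))
  t0_added <- times[1] > 0
  tt <- if (t0_added) c(0, times) else times
  row_of <- match(df$time_h, times) + as.integer(t0_added)
  col1 <- vapply(key, function(k) OBS_MAP[[k]][1], 0L) + 1L
  col2 <- vapply(key, function(k) if (length(OBS_MAP[[k]]) > 1)
    OBS_MAP[[k]][2] else NA_integer_, 0L) + 1L
  has2 <- !is.na(col2)
  x <- df$value; sdv <- df$sd
  k_evap <- network$k_evap
  cyt_on <- network$cyt_ethanol

  function(v) {
    v <- setNames(as.numeric(v), MFA_FREE)
    v_eutd <- v["v_EutG"]
    v_ea <- 2 * v["v_EutG"] + v["v_AAL_release"]
    v_pta <- v["v_glycolysis"] + v_eutd - v["v_AceX"]
    if (v_pta < 0 || v["v_gly_uptake"] < v["v_glycolysis"] ||
        v_ea < v["v_NH4X"]) return(1e12)
    parms <- unname(c(v["mu"], k_evap, v["v_gly_uptake"], v["v_glycolysis"],
                      v_ea, v["v_EutG"], v_eutd, v["v_AAL_release"],
                      v["v_AceX"], v_pta, v["v_NH4X"],
                      if (cyt_on) v["v_cytEtOH"] else 0, 1e-3, 1e-6))
    pool <- v["pool_scale"]
    f_acp <- if (v["v_glycolysis"] + v_eutd > 0)
      v_eutd * tracer_purity / (v["v_glycolysis"] + v_eutd) else 0
    y0 <- unname(c(v["X0"], v["gly0"],
                   (1 - tracer_purity) * v["ea0"], tracer_purity * v["ea0"],
                   0, 0, 0, 0, 0, 0, v["nh4_0"],
                   pool * (1 - tracer_purity), pool * tracer_purity,
                   pool * (1 - f_acp), pool * f_acp, rep(0, 8)))
    out <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y0, tt, func = "eut_derivs", parms = parms,
                       dllname = "eutflux", initfunc = "eut_init",
                       rtol = 1e-7, atol = 1e-9, maxsteps = 20000)),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < length(tt) ||
        attr(out, "istate")[1] < 0) return(1e12)
    yhat <- out[cbind(row_of, col1)]
    yhat[has2] <- yhat[has2] + out[cbind(row_of[has2], col2[has2])]
    sum(((x - yhat) / sdv)^2)
  }
}

#' Weighted sum-of-squared-errors objective
#'
#' `f(p) = sum_i ((x_i - y_i(p)) / sigma_i)^2` over every data point, where
#' `y_i(p)` is the matching observable of [simulate_isotopic()]. Errors if any
#' point lacks a sigma: no silent weighting defaults.
#'
#' @param params a [flux_parameter_set()].
#' @param data a [culture_timeseries()] whose quantity/label combinations map
#'   onto simulated observables.
#' @param network an [build_eut_network()] object.
#' @param tracer_purity tracer purity applied at the EA source.
#' @return the objective value (single number).
#' @export
mfa_objective <- function(params, data, network, tracer_purity = 1) {
  stopifnot(inherits(params, "flux_parameter_set"))
  fn <- make_mfa_objective(data, network, tracer_purity)
  fn(unlist(params[MFA_FREE]))
}

#' Global-best particle swarm optimizer
#'
#' Constriction-factor PSO (chi = 0.729, c1 = c2 = 1.49445) with a global-best
#' topology and reflecting bounds. Deterministic under a fixed seed.
#'
#' @param fn objective function of a numeric vector; smaller is better.
#' @param lower,upper finite bound vectors (equal length).
#' @param iterations,swarm iteration count and swarm size.
#' @param seed integer seed.
#' @param quiet divert stdout during objective evaluation (silences numeric
#'   solver chatter from infeasible particles).
#' @return list with `par`, `value`, and `trace` (best objective per
#'   iteration, non-increasing).
#' @export
pso_optim <- function(fn, lower, upper, iterations = 2000, swarm = 50,
                      seed = 1L, quiet = TRUE) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  if (quiet) {
    zz <- file(nullfile(), open = "wt")
    sink(zz)
    on.exit({ sink(); close(zz) }, add = TRUE)
  }
  d <- length(lower)
  chi <- 0.729; c1 <- 1.49445; c2 <- 1.49445
  set.seed(derive_seed(seed, "pso"))
  span <- upper - lower
  X <- matrix(runif(swarm * d, lower, upper), d, swarm)
  V <- matrix(runif(swarm * d, -span, span), d, swarm) * 0.1
  fvals <- apply(X, 2, fn)
  if (all(!is.finite(fvals) | fvals >= 1e12))
    stop("all particles infeasible at initialization; widen the bounds")
  P <- X; pbest <- fvals
  g <- which.min(pbest)
  gbest <- P[, g]; gval <- pbest[g]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    R1 <- matrix(runif(swarm * d), d, swarm)
    R2 <- matrix(runif(swarm * d), d, swarm)
    V <- chi * (V + c1 * R1 * (P - X) + c2 * R2 * (gbest - X))
    X <- X + V
    # reflecting bounds
    for (k in seq_len(d)) {
      lo <- X[k, ] < lower[k]; hi <- X[k, ] > upper[k]
      X[k, lo] <- pmin(2 * lower[k] - X[k, lo], upper[k])
      X[k, hi] <- pmax(2 * upper[k] - X[k, hi], lower[k])
      V[k, lo | hi] <- -V[k, lo | hi]
    }
    fvals <- apply(X, 2, fn)
    imp <- fvals < pbest
    P[, imp] <- X[, imp]; pbest[imp] <- fvals[imp]
    g <- which.min(pbest)
    if (pbest[g] < gval) { gval <- pbest[g]; gbest <- P[, g] }
    trace[it] <- gval
  }
  list(par = gbest, value = gval, trace = trace)
}

#' Default parameter bounds for the isotopic fit
#'
#' Wide physiological boxes for the 13 free parameters of
#' [flux_parameter_set()], in model units.
#'
#' @return 2-row matrix (`lower`, `upper`) with one column per parameter.
#' @export
default_mfa_bounds <- function() {
  b <- rbind(
    lower = c(X0 = 0.005, mu = 0.1, gly0 = 10, ea0 = 5, nh4_0 = 0,
              v_gly_uptake = 0.1, v_glycolysis = 0, v_EutG = 0,
              v_AAL_release = 0, v_AceX = 0, v_NH4X = 0, v_cytEtOH = 0,
              pool_scale = 1e-4),
    upper = c(X0 = 0.2, mu = 1, gly0 = 50, ea0 = 40, nh4_0 = 2,
              v_gly_uptake = 30, v_glycolysis = 15, v_EutG = 8,
              v_AAL_release = 8, v_AceX = 8, v_NH4X = 5, v_cytEtOH = 2,
              pool_scale = 1e-2))
  b[, MFA_FREE]
}

#' Fit the dynamic isotopic model by particle swarm optimization
#'
#' Minimizes the weighted SSE of [mfa_objective()] over the 13 free
#' parameters with [pso_optim()] (defaults: 2000 iterations, swarm size 50).
#' Dependent fluxes (`v_EA_uptake`, `v_EutD`, `v_Pta`, `v_NH4_assim`) are
#' eliminated through the steady-state relations, so every candidate is
#' balance-consistent by construction. An optional Levenberg-style local
#' polish (`polish = TRUE`) refines the swarm optimum.
#'
#' @param data a [culture_timeseries()] of tracer observables with sigmas.
#' @param network an [build_eut_network()] object.
#' @param bounds bounds matrix as from [default_mfa_bounds()].
#' @param iterations,swarm,seed PSO settings.
#' @param tracer_purity tracer purity at the EA source.
#' @param polish run a local refinement after PSO.
#' @return object of class `mfa_fit`: `params` ([flux_parameter_set()]),
#'   `objective`, `trace`, `par` (free-parameter vector), `settings`, `bounds`.
#' @export
pso_fit <- function(data, network, bounds = default_mfa_bounds(),
                    iterations = 2000, swarm = 50, seed = 1L,
                    tracer_purity = 1, polish = FALSE) {
  fn <- make_mfa_objective(data, network, tracer_purity)
  opt <- pso_optim(fn, bounds["lower", ], bounds["upper", ],
                   iterations = iterations, swarm = swarm, seed = seed)
  par <- setNames(opt$par, MFA_FREE)
  value <- opt$value
  if (polish) {
    loc <- optim(par, fn, method = "L-BFGS-B", lower = bounds["lower", ],
                 upper = bounds["upper", ], control = list(maxit = 200))
    if (loc$value < value) { par <- setNames(loc$par, MFA_FREE); value <- loc$value }
  }
  params <- do.call(flux_parameter_set,
                    c(as.list(par), list(k_evap = network$k_evap)))
  structure(list(params = params, objective = value, trace = opt$trace,
                 par = par,
                 settings = list(iterations = iterations, swarm = swarm,
                                 seed = seed, tracer_purity = tracer_purity,
                                 polish = polish),
                 bounds = bounds),
            class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("Isotopic model fit (PSO,", x$settings$iterations, "iterations x swarm",
      x$settings$swarm, ")\n")
  cat("objective:", signif(x$objective, 6), "\n")
  fl <- unlist(x$params[c("v_EA_uptake", "v_EutG", "v_EutD", "v_AAL_release",
                          "v_glycolysis", "v_AceX", "v_Pta", "v_NH4X",
                          "v_cytEtOH")])
  print(round(fl, 3))
  invisible(x)
}
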