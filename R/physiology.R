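# Extracellular flux estimation from exponential-phase batch cultures.
#
# The model: constant biomass-specific fluxes during balanced exponential
# growth, so that
#   X(t) = X0 exp(mu t)
#   S(t) = S0 - (qS X0 / mu) (exp(mu t) - 1)              substrates
#   P(t) = P0 + (qP X0 / mu) (exp(mu t) - 1)              non-volatile products
#   dP/dt = qP X - k P  =>
#   P(t) = P0 exp(-k t) + qP X0 (exp(mu t) - exp(-k t)) / (mu + k)
# for volatile products subject to first-order evaporation (ethanol,
# k = 0.0379 1/h determined experimentally for shaken flasks).

#' Physiological parameter set for exponential batch growth
#'
#' @param X0 initial biomass (gDW/L), > 0.
#' @param mu exponential growth rate (1/h).
#' @param substrates named list; each element `list(S0 = , q = )` with the
#'   initial concentration (mM) and uptake flux (mmol/gDW/h, >= 0 means
#'   consumption).
#' @param products named list; each element `list(P0 = , q = )` with initial
#'   concentration (mM) and production flux (mmol/gDW/h, >= 0).
#' @param k_evap named numeric vector of first-order evaporation constants
#'   (1/h) for volatile products; products not named here do not evaporate.
#' @return an object of class `physio_params`.
#' @export
physio_params <- function(X0, mu, substrates = list(), products = list(),
                          k_evap = c(ethanol = 0.0379)) {
  stopifnot(is.numeric(X0), length(X0) == 1L, X0 > 0,
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  chk <- function(lst, what) {
    for (nm in names(lst)) {
      el <- lst[[nm]]
      if (!"q" %in% names(el) || !any(c("S0", "P0") %in% names(el)))
        stop(what, " '", nm, "' needs an initial concentration and a flux")
      if (el$q < 0) stop(what, " flux for '", nm, "' must be >= 0")
    }
  }
  chk(substrates, "substrate"); chk(products, "product")
  if (any(k_evap < 0)) stop("k_evap must be >= 0")
  structure(list(X0 = X0, mu = mu, substrates = substrates,
                 products = products, k_evap = k_evap),
            class = "physio_params")
}

# exp(mu t) - 1 over mu, with the analytic mu -> 0 limit (t).
expm1_over_mu <- function(mu, t) {
  if (abs(mu) < 1e-12) t else expm1(mu * t) / mu
}

#' Noiseless concentration trajectories of the exponential-growth model
#'
#' Evaluates the closed-form solutions of the constant-specific-flux batch
#' model at the requested times. Volatile products use the evaporation-aware
#' closed form; the `mu = 0` and `mu = -k` degeneracies are handled by their
#' analytic limits.
#'
#' @param params a [physio_params()].
#' @param times numeric vector of times (h), all >= 0.
#' @return data frame with one column per quantity (`biomass` plus each
#'   substrate/product name) and a `time_h` column.
#' @export
predict_concentrations <- function(params, times) {
  stopifnot(inherits(params, "physio_params"))
  if (any(times < 0)) stop("times must be >= 0")
  mu <- params$mu; X0 <- params$X0
  out <- data.frame(time_h = times, biomass = X0 * exp(mu * times))
  for (nm in names(params$substrates)) {
    el <- params$substrates[[nm]]
    out[[nm]] <- el$S0 - el$q * X0 * vapply(times, function(t) expm1_over_mu(mu, t), 0)
  }
  for (nm in names(params$products)) {
    el <- params$products[[nm]]
    k <- unname(params$k_evap[nm])
    if (is.na(k) || k == 0) {
      out[[nm]] <- el$P0 + el$q * X0 * vapply(times, function(t) expm1_over_mu(mu, t), 0)
    } else {
      # P(t) = P0 e^{-kt} + q X0 (e^{mu t} - e^{-k t})/(mu + k)
      denom <- mu + k
      out[[nm]] <- if (abs(denom) < 1e-12) {
        el$P0 * exp(-k * times) + el$q * X0 * times * exp(-k * times)
      } else {
        el$P0 * exp(-k * times) + el$q * X0 * (exp(mu * times) - exp(-k * times)) / denom
      }
    }
  }
  out
}

#' Truncate a time series to the exponential phase
#'
#' The constant-specific-flux model only holds while all substrates remain
#' available; concentration profiles flatten (and the generator clips at zero)
#' once a substrate is exhausted. This helper drops, for every series, all
#' time points at or beyond the first time any of the named substrates reaches
#' zero in any replicate, which is the window the closed-form fit is valid on.
#'
#' @param ts a [culture_timeseries()].
#' @param substrates quantities whose exhaustion ends the exponential phase.
#' @return the truncated [culture_timeseries()].
#' @export
truncate_exponential_phase <- function(ts, substrates = c("glycerol", "ethanolamine")) {
  substrates <- intersect(substrates, unique(ts$quantity))
  if (!length(substrates)) return(ts)
  sub <- ts[ts$quantity %in% substrates & ts$value <= 0, ]
  if (!nrow(sub)) return(ts)
  t_cut <- min(sub$time_h)
  culture_timeseries(as.data.frame(ts)[ts$time_h < t_cut, ])
}

# ---- fitting ---------------------------------------------------------------

# Flatten a physio_params-like parameter vector for the optimizer.
pp_to_vec <- function(X0, mu, subs, prods) {
  v <- c(X0 = X0, mu = mu)
  for (nm in names(subs)) v[paste0(c("S0_", "q_"), nm)] <- c(subs[[nm]]$S0, subs[[nm]]$q)
  for (nm in names(prods)) v[paste0(c("P0_", "q_"), nm)] <- c(prods[[nm]]$P0, prods[[nm]]$q)
  v
}

vec_to_pp <- function(v, sub_names, prod_names, k_evap) {
  subs <- setNames(lapply(sub_names, function(nm)
    list(S0 = unname(v[paste0("S0_", nm)]), q = max(0, unname(v[paste0("q_", nm)])))), sub_names)
  prods <- setNames(lapply(prod_names, function(nm)
    list(P0 = unname(v[paste0("P0_", nm)]), q = max(0, unname(v[paste0("q_", nm)])))), prod_names)
  physio_params(X0 = max(unname(v["X0"]), 1e-9), mu = unname(v["mu"]),
                substrates = subs, products = prods, k_evap = k_evap)
}

#' Fit growth rate and uptake/production fluxes to a culture time series
#'
#' Joint weighted least squares over all series: minimizes
#' sum(((x_i - y_i) / sigma_i)^2) with the closed-form trajectories of
#' [predict_concentrations()] as the model. Ethanol (or any quantity named in
#' `k_evap`) is corrected for first-order evaporation, with the evaporation
#' constant fixed by default (0.0379 1/h) or estimated when `fit_k_evap` is
#' `TRUE`. Optimization is multi-start Levenberg-Marquardt: starts are seeded
#' perturbations of initial guesses taken from a log-linear regression of
#' biomass (mu, X0) and two-point secants (fluxes).
#'
#' @param data a [culture_timeseries()] (label states are summed to totals).
#' @param roles named character vector mapping quantity -> `"substrate"` or
#'   `"product"`; `biomass` is implicit. Quantities absent from `roles` are
#'   ignored.
#' @param k_evap named numeric of evaporation constants (1/h).
#' @param fit_k_evap estimate the evaporation constant(s) instead of fixing.
#' @param n_starts number of optimizer starts (first start is unperturbed).
#' @param sigma_default relative sigma (fraction of the series maximum) used
#'   where the data carry no `sd` column.
#' @param mc_n number of Monte-Carlo residual-resampling replicates for
#'   standard errors (0 disables).
#' @param seed integer seed controlling the multi-start jitter and the
#'   Monte-Carlo resampling.
#' @return list with `params` ([physio_params()]), `objective`, `se` (named
#'   standard errors, present when `mc_n > 0`), `n_points`, and `settings`.
#' @export
fit_physiology <- function(data, roles, k_evap = c(ethanol = 0.0379),
                           fit_k_evap = FALSE, n_starts = 10,
                           sigma_default = 0.02, mc_n = 0, seed = 1L) {
  stopifnot(inherits(data, "culture_timeseries"))
  df <- as.data.frame(data)
  # collapse split label states to totals for physiology fitting
  agg <- stats::aggregate(value ~ replicate + time_h + quantity, df, sum)
  sda <- stats::aggregate(sd ~ replicate + time_h + quantity, df,
                          function(s) sqrt(sum(s^2)), na.action = stats::na.pass)
  df <- merge(agg, sda, by = c("replicate", "time_h", "quantity"))
  if (!"biomass" %in% df$quantity) stop("biomass series is required")
  sub_names <- names(roles)[roles == "substrate"]
  prod_names <- names(roles)[roles == "product"]
  keep <- c("biomass", sub_names, prod_names)
  df <- df[df$quantity %in% keep, ]
  cnt <- table(df$quantity[!duplicated(paste(df$quantity, df$time_h))])
  if (any(cnt < 3)) stop("need >= 3 time points per fitted quantity")

  # default sigmas: per-quantity fraction of the series maximum
  if (any(is.na(df$sd))) {
    mx <- tapply(df$value, df$quantity, max)
    df$sd <- ifelse(is.na(df$sd), pmax(sigma_default * mx[df$quantity], 1e-6), df$sd)
  }

  # initial guesses
  bio <- df[df$quantity == "biomass" & df$value > 0, ]
  fit0 <- lm(log(value) ~ time_h, data = bio)
  mu0 <- unname(coef(fit0)[2]); X00 <- exp(unname(coef(fit0)[1]))
  secant_q <- function(nm, sign) {
    d <- df[df$quantity == nm, ]
    d <- d[order(d$time_h), ]
    dX <- X00 * expm1_over_mu(mu0, max(d$time_h)) # integral of X dt approx
    q0 <- sign * (d$value[nrow(d)] - d$value[1]) / max(dX, 1e-9)
    max(q0, 0.01)
  }
  subs0 <- setNames(lapply(sub_names, function(nm) {
    d <- df[df$quantity == nm, ]
    list(S0 = max(d$value[d$time_h == min(d$time_h)]), q = secant_q(nm, -1))
  }), sub_names)
  prods0 <- setNames(lapply(prod_names, function(nm) {
    d <- df[df$quantity == nm, ]
    list(P0 = max(min(d$value), 0), q = secant_q(nm, +1))
  }), prod_names)
  v0 <- pp_to_vec(X00, mu0, subs0, prods0)
  if (fit_k_evap) v0 <- c(v0, k_evap = unname(k_evap[1]))
  nz <- vapply(prod_names, function(nm) any(df$value[df$quantity == nm] > 0), TRUE)
  if (fit_k_evap && length(prod_names) && !all(nz))
    warning("free k_evap with an all-zero product series is not identifiable; ",
            "k_evap will be bound to [0, 1]")

  resid_fun <- function(v) {
    if (fit_k_evap) {
      k_evap[1] <- min(max(unname(v["k_evap"]), 0), 1)
      v <- v[names(v) != "k_evap"]
    }
    pp <- tryCatch(vec_to_pp(v, sub_names, prod_names, k_evap),
                   error = function(e) NULL)
    if (is.null(pp)) return(rep(1e6, nrow(df)))
    pred <- predict_concentrations(pp, sort(unique(df$time_h)))
    yhat <- numeric(nrow(df))
    for (nm in keep) {
      i <- df$quantity == nm
      yhat[i] <- approx(pred$time_h, pred[[nm]], xout = df$time_h[i])$y
    }
    (df$value - yhat) / df$sd
  }

  run_start <- function(v) {
    f <- tryCatch(minpack.lm::nls.lm(par = v, fn = resid_fun,
                                     control = minpack.lm::nls.lm.control(maxiter = 200)),
                  error = function(e) NULL)
    if (is.null(f)) return(list(par = v, obj = Inf))
    list(par = coef(f), obj = sum(resid_fun(coef(f))^2))
  }

  set.seed(derive_seed(seed, "fit-physiology"))
  best <- run_start(v0)
  if (n_starts > 1) for (i in seq_len(n_starts - 1)) {
    vi <- v0 * exp(rnorm(length(v0), 0, 0.2))
    cand <- run_start(vi)
    if (cand$obj < best$obj) best <- cand
  }
  if (!is.finite(best$obj)) stop("physiology fit failed to converge from any start")

  k_fit <- k_evap
  par <- best$par
  if (fit_k_evap) {
    k_fit[1] <- min(max(unname(par["k_evap"]), 0), 1)
    par <- par[names(par) != "k_evap"]
  }
  params <- vec_to_pp(par, sub_names, prod_names, k_fit)

  se <- NULL
  if (mc_n > 0) {
    r <- resid_fun(best$par)
    draws <- matrix(NA_real_, mc_n, length(best$par),
                    dimnames = list(NULL, names(best$par)))
    base_pred <- df$value - r * df$sd
    for (b in seq_len(mc_n)) {
      df$value <- base_pred + sample(r, replace = TRUE) * df$sd
      draws[b, ] <- run_start(best$par)$par
    }
    df$value <- base_pred + r * df$sd
    se <- apply(draws, 2, sd)
  }

  list(params = params, objective = best$obj, se = se, n_points = nrow(df),
       settings = list(k_evap = k_fit, fit_k_evap = fit_k_evap,
                       n_starts = n_starts, mc_n = mc_n, seed = seed))
}
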