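# Synthetic culture time courses, tracer trajectories and raw isotopologue
# measurements with the statistical structure the downstream fits assume.
# Defaults emulate the study conditions: aerobic M9 glycerol + ethanolamine
# + B12 batch cultures sampled hourly (12 points, 0-11 h, 3 biological
# replicates), fully 13C2-labeled ethanolamine tracer, multiplicative Gaussian
# measurement noise with an additive floor, ethanol evaporation at 0.0379 1/h.

#' Convert optical density to biomass dry weight
#'
#' Uses the linear calibration gDW/L = 0.37 x OD600 established for
#' *E. coli* K-12 W3110 in shaken M9 cultures.
#'
#' @param od600 absorbance at 600 nm, >= 0.
#' @param factor calibration factor (gDW/L per OD unit).
#' @return biomass concentration in gDW/L.
#' @export
od_to_dryweight <- function(od600, factor = 0.37) {
  if (any(od600 < 0)) stop("od600 must be >= 0")
  factor * od600
}

#' Sampling design for synthetic experiments
#'
#' @param t_start,t_end sampling window (h).
#' @param n_points number of sampling times (>= 2, evenly spaced).
#' @param n_replicates biological replicates.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise (dimensionless fraction).
#' @param noise_floor additive noise floor (mM, standard deviation): the
#'   applied SD per point is `max(noise_cv * value, noise_floor)`.
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @return object of class `sampling_design`.
#' @export
sampling_design <- function(t_start = 0, t_end = 11, n_points = 12,
                            n_replicates = 3, noise_cv = 0.02,
                            noise_floor = 0.02, seed = 1L) {
  stopifnot(t_end > t_start, n_points >= 2, n_replicates >= 1,
            noise_cv >= 0, noise_floor >= 0)
  structure(list(t_start = t_start, t_end = t_end, n_points = n_points,
                 n_replicates = n_replicates, noise_cv = noise_cv,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "sampling_design")
}

design_times <- function(design) {
  seq(design$t_start, design$t_end, length.out = design$n_points)
}

# Perturb a noiseless long table with the design's noise model. Clipping of
# negative noisy concentrations to zero is applied after the noise and
# reported via message() so it is visible in run logs.
apply_noise_model <- function(long, design, stage) {
  sdv <- pmax(design$noise_cv * long$value, design$noise_floor)
  sdv[long$quantity == "biomass"] <-
    pmax(design$noise_cv * long$value[long$quantity == "biomass"], 1e-4)
  if (design$noise_cv > 0 || design$noise_floor > 0) {
    set.seed(derive_seed(design$seed, stage))
    long$value <- long$value + rnorm(nrow(long), 0, sdv)
  }
  n_clip <- sum(long$value < 0)
  if (n_clip > 0) {
    message("clipped ", n_clip, " negative noisy values to 0")
    long$value <- pmax(long$value, 0)
  }
  # noiseless designs still need a defined weighting: nominal 1e-6 floor
  long$sd <- pmax(sdv, 1e-6)
  long
}

#' Generate replicated physiology time courses
#'
#' Evaluates the closed-form exponential-growth trajectories of
#' [predict_concentrations()] on the design's sampling grid, then perturbs
#' every replicate with multiplicative Gaussian noise of SD
#' `max(noise_cv * value, noise_floor)`. The `sd` column records the applied
#' SD. With `noise_cv = noise_floor = 0` the table equals the noiseless model
#' exactly. Noiseless trajectories that fall below zero (substrate exhausted
#' after the exponential phase) are clipped at zero and reported; use
#' [truncate_exponential_phase()] before fitting.
#'
#' @param params a [physio_params()].
#' @param design a [sampling_design()].
#' @return a [culture_timeseries()] of `total` measurements.
#' @export
generate_physiology_timeseries <- function(params, design = sampling_design()) {
  stopifnot(inherits(params, "physio_params"), inherits(design, "sampling_design"))
  times <- design_times(design)
  pred <- predict_concentrations(params, times)
  quantities <- setdiff(names(pred), "time_h")
  long <- do.call(rbind, lapply(seq_len(design$n_replicates), function(r) {
    do.call(rbind, lapply(quantities, function(q)
      data.frame(replicate = r, time_h = times, quantity = q,
                 label_state = "total", value = pred[[q]])))
  }))
  n_neg <- sum(long$value < 0)
  if (n_neg > 0) {
    message("clipped ", n_neg,
            " negative noiseless values to 0 (substrate exhausted; ",
            "truncate to the exponential phase before fitting)")
    long$value <- pmax(long$value, 0)
  }
  long <- apply_noise_model(long, design, "physiology-noise")
  culture_timeseries(long)
}

#' Tracer specification
#'
#' @param element tracer element (only `"C"` is supported).
#' @param purity isotopic purity of the tracer substrate, in (0, 1].
#' @export
tracer_spec <- function(element = "C", purity = 1.0) {
  stopifnot(identical(element, "C"))
  if (purity <= 0 || purity > 1) stop("tracer purity must be in (0, 1]")
  structure(list(element = element, purity = purity), class = "tracer_spec")
}

#' Generate replicated tracer-experiment time courses
#'
#' Simulates the dynamic isotopic model ([simulate_isotopic()]) for a culture
#' grown on unlabeled glycerol plus uniformly 13C-labeled ethanolamine, then
#' applies the design's noise model. Ethanol and acetate are emitted split by
#' label state (`unlabeled` / `U-13C`); biomass, glycerol, ethanolamine and
#' ammonium as `total`. Acetaldehyde is a trace by-product and is excluded by
#' default.
#'
#' @param fluxes a [flux_parameter_set()]; must satisfy the steady-state flux
#'   balances (see [steady_state_flux_relations()]).
#' @param tracer a [tracer_spec()].
#' @param design a [sampling_design()].
#' @param network an [build_eut_network()] audit object (defaults to the
#'   standard reconstruction with the fluxes' cytosolic-ethanol setting).
#' @param include_acetaldehyde also emit the extracellular acetaldehyde trace
#'   series.
#' @return a [culture_timeseries()].
#' @export
generate_labeling_timeseries <- function(fluxes, tracer = tracer_spec(),
                                         design = sampling_design(),
                                         network = NULL,
                                         include_acetaldehyde = FALSE) {
  stopifnot(inherits(fluxes, "flux_parameter_set"),
            inherits(design, "sampling_design"))
  res <- steady_state_flux_relations(fluxes)
  if (any(abs(res) > 1e-6))
    stop("inconsistent flux set; violated balances: ",
         paste(sprintf("%s = %.4g", names(res)[abs(res) > 1e-6],
                       res[abs(res) > 1e-6]), collapse = ", "))
  if (is.null(network)) network <- build_eut_network(k_evap = fluxes$k_evap)
  times <- design_times(design)
  sim <- simulate_isotopic(network, fluxes, times, tracer_purity = tracer$purity)
  series <- list(
    list("biomass",      "total",     sim$biomass),
    list("glycerol",     "total",     sim$glycerol),
    list("ethanolamine", "total",     sim$ea_unlabeled + sim$ea_labeled),
    list("ammonium",     "total",     sim$ammonium),
    list("ethanol",      "unlabeled", sim$ethanol_unlabeled),
    list("ethanol",      "U-13C",     sim$ethanol_labeled),
    list("acetate",      "unlabeled", sim$acetate_unlabeled),
    list("acetate",      "U-13C",     sim$acetate_labeled))
  if (include_acetaldehyde)
    series <- c(series, list(
      list("acetaldehyde", "unlabeled", sim$acetaldehyde_unlabeled),
      list("acetaldehyde", "U-13C",     sim$acetaldehyde_labeled)))
  long <- do.call(rbind, lapply(seq_len(design$n_replicates), function(r)
    do.call(rbind, lapply(series, function(s)
      data.frame(replicate = r, time_h = sim$time_h, quantity = s[[1]],
                 label_state = s[[2]], value = pmax(s[[3]], 0))))))
  long <- apply_noise_model(long, design, "labeling-noise")
  culture_timeseries(long)
}

#' Generate a raw (uncorrected) carbon-isotopologue distribution
#'
#' Forward operation that the natural-abundance correction inverts: convolves
#' a true CID with the natural-abundance mass-shift distributions of all atoms
#' (heavy isotopes of H, N, O, S plus natural 13C on the unlabeled carbons),
#' optionally adds Gaussian noise, and renormalizes to sum one.
#'
#' @param true_cid numeric vector (M0..Mn, n = carbon count) summing to 1.
#' @param formula elemental formula string, e.g. `"C3H7NO2"`; must contain
#'   carbon.
#' @param abundances natural-abundance table, see [natural_abundances()].
#' @param noise_sd SD of additive Gaussian noise per isotopologue fraction.
#' @param seed integer seed for the noise.
#' @return numeric vector of measured fractions (sums to 1).
#' @export
generate_raw_cid <- function(true_cid, formula, abundances = natural_abundances(),
                             noise_sd = 0, seed = 1L) {
  if (abs(sum(true_cid) - 1) > 1e-9) stop("true_cid must sum to 1")
  counts <- parse_formula(formula)
  if (!"C" %in% names(counts) || counts[["C"]] < 1)
    stop("formula must contain carbon")
  if (length(true_cid) != counts[["C"]] + 1L)
    stop("true_cid length must be carbon count + 1")
  # forward convolution = correction matrix at tracer purity 1
  M <- build_correction_matrix(formula, tracer = list(element = "C", purity = 1),
                               abundances = abundances)
  raw <- as.numeric(M %*% true_cid)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "raw-cid-noise"))
    raw <- pmax(raw + rnorm(length(raw), 0, noise_sd), 0)
  }
  raw / sum(raw)
}
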