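# Synthetic-data generator: OD conversion, noise model, reproducibility,
# and the forward CID oracle.

test_that("OD600 to dry weight conversion is linear with the 0.37 calibration", {
  expect_equal(od_to_dryweight(1.0), 0.37)
  expect_equal(od_to_dryweight(0.0), 0.0)
  expect_equal(od_to_dryweight(2.0), 0.74)
  expect_equal(od_to_dryweight(1.0, factor = 0.4), 0.4)
  expect_error(od_to_dryweight(-0.1), "od600")
})

test_that("zero-noise generation equals the closed-form model exactly", {
  pp <- table3_params()
  des <- sampling_design(t_end = 7, n_points = 8, n_replicates = 2,
                         noise_cv = 0, noise_floor = 0)
  ts <- generate_physiology_timeseries(pp, des)
  pred <- predict_concentrations(pp, design_times <- seq(0, 7, 1))
  for (q in c("biomass", "glycerol", "ethanolamine", "acetate", "ethanol")) {
    for (r in 1:2) {
      got <- ts$value[ts$quantity == q & ts$replicate == r]
      expect_equal(got, pred[[q]], tolerance = 1e-12)
    }
  }
})

test_that("noiseless exponential-phase trajectories are monotone", {
  pp <- table3_params()
  des <- sampling_design(noise_cv = 0, noise_floor = 0, n_replicates = 1)
  ts <- suppressMessages(generate_physiology_timeseries(pp, des))
  ts <- truncate_exponential_phase(ts)
  gly <- ts$value[ts$quantity == "glycerol"]
  bio <- ts$value[ts$quantity == "biomass"]
  expect_true(all(diff(gly) < 0))
  expect_true(all(diff(bio) > 0))
})

test_that("identical seeds reproduce identical tables; different seeds differ", {
  pp <- table3_params()
  des <- sampling_design(t_end = 7, n_points = 8, seed = 11)
  t1 <- generate_physiology_timeseries(pp, des)
  t2 <- generate_physiology_timeseries(pp, des)
  expect_identical(t1, t2)
  des2 <- sampling_design(t_end = 7, n_points = 8, seed = 12)
  t3 <- generate_physiology_timeseries(pp, des2)
  expect_false(identical(t1$value, t3$value))
})

test_that("generated tables satisfy the container invariants and record sigmas", {
  pp <- table3_params()
  des <- sampling_design(t_end = 7, n_points = 8, noise_cv = 0.05,
                         noise_floor = 0.05, seed = 3)
  ts <- generate_physiology_timeseries(pp, des)
  expect_s3_class(ts, "culture_timeseries")
  expect_true(all(ts$value >= 0))
  expect_true(all(ts$sd > 0))
  big <- ts$value > 10
  expect_equal(ts$sd[big], pmax(0.05 * ts$value[big], 0.05) +
                 0 * ts$value[big], tolerance = 0.5)
})

test_that("labeling generator: null dynamics under zero fluxes and mu = 0", {
  fl <- flux_parameter_set(X0 = 0.03, mu = 0, gly0 = 30, ea0 = 20, nh4_0 = 0.4,
                           v_gly_uptake = 0, v_glycolysis = 0, v_EutG = 0,
                           v_AAL_release = 0, v_AceX = 0, v_NH4X = 0,
                           k_evap = 0)
  des <- sampling_design(t_end = 5, n_points = 6, n_replicates = 1,
                         noise_cv = 0, noise_floor = 0)
  ts <- generate_labeling_timeseries(fl, design = des)
  for (q in unique(ts$quantity)) {
    v <- ts$value[ts$quantity == q & ts$label_state != "U-13C"]
    expect_equal(diff(range(v)), 0, tolerance = 1e-8)
  }
})

test_that("labeling generator: no tracer entry means no labeled products", {
  fl <- flux_parameter_set(X0 = 0.026, mu = 0.45, gly0 = 30, ea0 = 20,
                           v_gly_uptake = 14.7, v_glycolysis = 2.5,
                           v_EutG = 0, v_AAL_release = 0, v_AceX = 1.6,
                           v_NH4X = 0)
  expect_equal(fl$v_EA_uptake, 0)
  des <- sampling_design(t_end = 7, n_points = 8, n_replicates = 1,
                         noise_cv = 0, noise_floor = 0)
  ts <- generate_labeling_timeseries(fl, design = des)
  lab <- ts$value[ts$label_state == "U-13C"]
  expect_true(all(lab < 1e-9))
})

test_that("labeling generator rejects inconsistent flux sets", {
  fl <- reference_flux_set()
  fl$v_EA_uptake <- fl$v_EA_uptake + 1   # break the EA branch balance
  des <- sampling_design(t_end = 5, n_points = 6)
  expect_error(generate_labeling_timeseries(fl, design = des),
               "violated balances")
})

test_that("at the study fluxes labeled and unlabeled acetate are nearly equal", {
  # glycerol and EA contribute equally to the cytosolic acetyl-P pool when
  # v_glycolysis ~ v_EutD, so acetate splits about 50/50
  fl <- reference_flux_set(v_glycolysis = 2.7)  # exactly equal inflows
  des <- sampling_design(t_end = 7, n_points = 8, n_replicates = 1,
                         noise_cv = 0, noise_floor = 0)
  ts <- generate_labeling_timeseries(fl, design = des)
  lab <- ts$value[ts$quantity == "acetate" & ts$label_state == "U-13C"]
  unl <- ts$value[ts$quantity == "acetate" & ts$label_state == "unlabeled"]
  keep <- lab + unl > 0.05
  expect_equal(lab[keep], unl[keep], tolerance = 0.02)
})

test_that("forward CID generation matches closed forms and the brute-force oracle", {
  # no heavy isotopes anywhere: identity
  ab0 <- natural_abundances(overrides = list(C = 0, H = 0, N = 0, O = 0))
  expect_equal(generate_raw_cid(c(0.3, 0.6, 0.1), "C2H4", abundances = ab0),
               c(0.3, 0.6, 0.1))
  # C2 fragment, pure M0, 13C fraction p: binomial expansion
  p <- 0.05
  ab <- natural_abundances(overrides = list(C = p, H = 0))
  raw <- generate_raw_cid(c(1, 0, 0), "C2H4", abundances = ab)
  expect_equal(raw, c((1 - p)^2, 2 * p * (1 - p), p^2) /
                 sum(c((1 - p)^2, 2 * p * (1 - p), p^2)), tolerance = 1e-12)
  # alanine with standard abundances vs exhaustive enumeration
  for (cid in list(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0.2, 0.3, 0.1, 0.4))) {
    raw <- generate_raw_cid(cid, "C3H7NO2")
    expect_equal(raw, brute_force_cid(cid, "C3H7NO2"), tolerance = 1e-10)
  }
  expect_error(generate_raw_cid(c(1), "H2O"), "carbon")
  expect_error(generate_raw_cid(c(0.5, 0.4), "C1H1"), "sum to 1")
})

test_that("forward convolution preserves normalization before noise", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cid <- runif(n + 1); cid <- cid / sum(cid)
    f <- paste0("C", n, "H", sample(3:10, 1), "N", sample(1:2, 1), "O2")
    M <- build_correction_matrix(f)
    expect_lt(abs(sum(M %*% cid) - sum(colSums(M) * cid)), 1e-12)
    raw <- generate_raw_cid(cid, f)
    expect_equal(sum(raw), 1, tolerance = 1e-12)
  }
})
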