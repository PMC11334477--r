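# Constraint-based modeling: LP correctness, core model audits, BMC
# installation with cofactor sequestration, FBA/FVA, EA partition.

test_that("LP solver agrees with brute-force vertex enumeration on toy problems", {
  set.seed(17)
  for (i in 1:15) {
    n <- 4
    S <- matrix(round(runif(2 * n, -2, 2)), 2, n)
    lb <- rep(0, n); ub <- runif(n, 1, 5)
    if (i %% 3 == 0) lb <- c(-2, 0, 0, 0)
    obj <- runif(n, -1, 1)
    mine <- eutflux:::solve_lp(obj, S, lb, ub, maximize = TRUE)
    oracle <- vertex_enum_lp(obj, S, lb, ub, maximize = TRUE)
    if (is.null(oracle)) {
      expect_identical(mine$status, "infeasible")
    } else {
      expect_identical(mine$status, "optimal")
      expect_equal(mine$objective, oracle, tolerance = 1e-7)
    }
  }
})

test_that("core model is viable on glycerol and starves without carbon", {
  m <- build_core_model()
  s <- fba(m)
  expect_identical(s$status, "optimal")
  expect_gt(s$objective, 0)
  s0 <- fba(m, constraints = list(EX_glyc_e = c(0, 0)))
  expect_identical(s0$status, "optimal")
  expect_equal(s0$objective, 0, tolerance = 1e-9)
})

test_that("core and BMC-augmented models pass the elemental balance audit", {
  expect_equal(nrow(element_balance(build_core_model())), 0)
  expect_equal(nrow(element_balance(add_eut_bmc(build_core_model()))), 0)
})

test_that("every FBA solution satisfies mass balance and bounds", {
  m <- add_eut_bmc(build_core_model())
  sol <- fba(m, objective = "ATPM", constraints = measured_constraints())
  expect_identical(sol$status, "optimal")
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  lb <- vapply(m$reactions, `[[`, 0, "lb")
  ub <- vapply(m$reactions, `[[`, 0, "ub")
  expect_true(all(sol$fluxes >= lb - 1e-9 & sol$fluxes <= ub + 1e-9))
})

test_that("cofactor sequestration forces v_EutE = v_EutG = v_EutD everywhere", {
  m <- add_eut_bmc(build_core_model())
  # FVA of the coupled reactions under a fixed EA influx: all three ranges
  # must coincide because BMC NAD(H) and CoA have no other producers/consumers
  fr <- fva(m, objective = "BIOMASS", fraction = 0.5,
            reactions = c("EUTE", "EUTG", "EUTD"),
            constraints = list(EX_ea_e = c(-7.8, 0)))
  expect_equal(fr$min[1], fr$min[2], tolerance = 1e-6)
  expect_equal(fr$min[1], fr$min[3], tolerance = 1e-6)
  expect_equal(fr$max[1], fr$max[2], tolerance = 1e-6)
  expect_equal(fr$max[1], fr$max[3], tolerance = 1e-6)
  # and at arbitrary solved vertices
  for (objective in c("ATPM", "BIOMASS", "EUTG")) {
    sol <- fba(m, objective = objective,
               constraints = list(EX_ea_e = c(-7.8, -7.8)))
    expect_equal(sol$fluxes[["EUTE"]], sol$fluxes[["EUTG"]], tolerance = 1e-6)
    expect_equal(sol$fluxes[["EUTE"]], sol$fluxes[["EUTD"]], tolerance = 1e-6)
  }
})

test_that("closed EA exchange zeroes all Eut reactions", {
  m <- add_eut_bmc(build_core_model(), ea_lb = 0)
  sol <- fba(m, objective = "ATPM", constraints = list(BIOMASS = c(0, 1000)))
  for (r in c("EUTBC", "EUTE", "EUTD", "EUTG", "ETOH_BMC_EGRESS"))
    expect_equal(sol$fluxes[[r]], 0, tolerance = 1e-9)
})

test_that("opening EA uptake cannot decrease the optimal objective", {
  m0 <- build_core_model()
  base <- fba(m0)
  m1 <- add_eut_bmc(m0, ea_lb = -7.8)
  aug <- fba(m1)
  expect_gte(aug$objective, base$objective - 1e-9)
})

test_that("installing the BMC twice raises a collision error", {
  m <- add_eut_bmc(build_core_model())
  expect_error(add_eut_bmc(m), "collision")
})

test_that("constrained FBA reproduces the equimolar BMC egress prediction", {
  m <- add_eut_bmc(build_core_model())
  sol <- fba(m, objective = "ATPM", constraints = measured_constraints())
  expect_identical(sol$status, "optimal")
  # 7.8 EA in, 2.6 ethanol out forces 2.6 acetyl-P and 2.6 acetaldehyde
  expect_equal(sol$fluxes[["EUTG"]], 2.6, tolerance = 1e-6)
  expect_equal(sol$fluxes[["EUTD"]], 2.6, tolerance = 1e-6)
  expect_equal(sol$fluxes[["ACALD_BMC_EGRESS"]], 2.6, tolerance = 1e-6)
  part <- ea_partition(sol, m)
  expect_equal(unname(round(part$carbon_pct["ethanol"])), 33)
  expect_equal(unname(round(part$carbon_pct["anabolic_acetyl_CoA"])), 12)
  expect_equal(unname(part$carbon_pct["acetate_excreted"]), 21.79, tolerance = 0.01)
  expect_equal(sum(part$carbon_pct[c("ethanol", "acetyl_P", "acetaldehyde")]),
               100, tolerance = 0.5)
})

test_that("EA partition arithmetic and degenerate cases", {
  m <- add_eut_bmc(build_core_model())
  # ethanol exactly one third of EA: 33.33% before rounding
  sol <- fba(m, objective = "ATPM",
             constraints = list(BIOMASS = 0.45, EX_ea_e = -7.5,
                                EX_etoh_e = 2.5, EX_ac_e = 1.7,
                                EX_glyc_e = -14.7))
  part <- ea_partition(sol, m)
  expect_equal(unname(part$carbon_pct["ethanol"]), 100 / 3, tolerance = 1e-6)
  # zero acetate: anabolic share equals the acetyl-P share
  sol0 <- fba(m, objective = "ATPM",
              constraints = list(BIOMASS = 0.45, EX_ea_e = -7.8,
                                 EX_etoh_e = 2.6, EX_ac_e = 0,
                                 EX_glyc_e = -14.7))
  part0 <- ea_partition(sol0, m)
  expect_equal(unname(part0$carbon_pct["anabolic_acetyl_CoA"]),
               unname(part0$carbon_pct["acetyl_P"]), tolerance = 1e-6)
  # zero EA uptake: partition undefined
  solz <- fba(m, objective = "ATPM", constraints = list(EX_ea_e = 0))
  expect_error(ea_partition(solz, m), "undefined")
})

test_that("infeasible constraint sets return a status, not an exception", {
  m <- build_core_model()
  sol <- fba(m, constraints = list(BIOMASS = 10, EX_glyc_e = c(0, 0)))
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective))
})

test_that("FVA ranges bracket the FBA flux and nest with the fraction", {
  m <- add_eut_bmc(build_core_model())
  cons <- measured_constraints()
  sol <- fba(m, objective = "ATPM", constraints = cons)
  rxns <- c("EUTG", "EUTD", "ACK", "PTA_ACCOA", "TCA", "EX_nh4_e")
  r99 <- fva(m, objective = "ATPM", fraction = 0.99, reactions = rxns,
             constraints = cons)
  r100 <- fva(m, objective = "ATPM", fraction = 1.0, reactions = rxns,
              constraints = cons)
  v <- sol$fluxes[rxns]
  expect_true(all(r99$min <= v + 1e-6 & r99$max >= v - 1e-6))
  expect_true(all(r99$min <= r100$min + 1e-6 & r99$max >= r100$max - 1e-6))
  expect_true(all(r100$min <= r100$max + 1e-9))
})

test_that("FVA against per-reaction LP oracle on a toy network", {
  # chain: EX_A (uptake) -> A -> split to B/C -> exports; check ranges
  sp <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                   compartment = "cytosol", C = c(1, 1, 1), N = 0)
  rx <- list(
    list(id = "IN", stoich = c(A = 1), lb = 0, ub = 10, type = "exchange", name = "IN"),
    list(id = "AB", stoich = c(A = -1, B = 1), lb = 0, ub = 1000, type = "internal", name = "AB"),
    list(id = "AC", stoich = c(A = -1, C = 1), lb = 0, ub = 4, type = "internal", name = "AC"),
    list(id = "OUTB", stoich = c(B = -1), lb = 0, ub = 1000, type = "exchange", name = "OUTB"),
    list(id = "OUTC", stoich = c(C = -1), lb = 0, ub = 1000, type = "exchange", name = "OUTC"))
  toy <- stoichiometric_model(sp, rx, objective = "OUTB")
  fr <- fva(toy, objective = "OUTB", fraction = 0.5)
  # optimum OUTB = 10 (all through B); at >= 5, AC can carry 0..4 but
  # limited by IN=10 minus the 5 needed for B: range [0, 4]
  expect_equal(fr$max[fr$reaction == "OUTB"], 10, tolerance = 1e-8)
  expect_equal(fr$min[fr$reaction == "OUTB"], 5, tolerance = 1e-8)
  expect_equal(fr$min[fr$reaction == "AC"], 0, tolerance = 1e-8)
  expect_equal(fr$max[fr$reaction == "AC"], 4, tolerance = 1e-8)
})

test_that("SBML round trip preserves the model; malformed input errors cleanly", {
  m <- add_eut_bmc(build_core_model())
  f1 <- tempfile(fileext = ".xml"); f2 <- tempfile(fileext = ".xml")
  write_sbml(m, f1)
  m2 <- read_sbml(f1)
  expect_equal(stoich_matrix(m), stoich_matrix(m2))
  expect_equal(vapply(m$reactions, `[[`, 0, "lb"),
               vapply(m2$reactions, `[[`, 0, "lb"))
  expect_identical(m$objective, m2$objective)
  write_sbml(m2, f2)
  expect_equal(stoich_matrix(read_sbml(f2)), stoich_matrix(m))
  # bundled fixture loads with its documented reaction count
  bundled <- read_sbml(system.file("extdata", "eut_core_model.xml",
                                   package = "eutflux"))
  expect_equal(length(bundled$reactions), length(build_core_model()$reactions))
  # malformed file: parse error, no partial model
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", bad)
  expect_error(read_sbml(bad), "parse error")
  # missing fbc package named explicitly
  nofbc <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               "<model/></sbml>"), nofbc)
  expect_error(read_sbml(nofbc), "fbc")
})
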