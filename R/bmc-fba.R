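# Compartmentalized FBA of EA catabolism: BMC installation with cofactor
# sequestration, LP-based FBA/FVA, and carbon/nitrogen partition reports.

#' Install the Eut BMC compartment into a stoichiometric model
#'
#' Adds a `bmc` compartment with its own NAD(H), CoA and acetyl-CoA pools and
#' the encapsulated reactions: EutBC (EA deamination to acetaldehyde, the
#' ammonium diffusing to the cytosol), EutE (acetaldehyde + NAD + CoA ->
#' acetyl-CoA + NADH), EutD (acetyl-CoA -> cytosolic acetyl-P + CoA), EutG
#' (acetaldehyde + NADH -> ethanol + NAD), plus EA entry through the shell
#' and acetaldehyde/ethanol egress. No transport reactions exist for NAD(H),
#' CoA or acetyl-CoA across the shell, so cofactor recycling forces
#' `v_EutE = v_EutG = v_EutD` at every feasible flux distribution. A
#' cytosolic acetate kinase (the EutQ/EutP role) already exists in the core
#' model (`ACK`); it is added here if absent. The EA exchange lower bound is
#' opened to `ea_lb`.
#'
#' @param model a `stoich_model` with cytosolic ammonium, acetyl-P, ethanol
#'   and acetaldehyde species (created if absent).
#' @param ea_lb lower bound opened on `EX_ea_e` (negative = uptake allowed).
#' @return the augmented `stoich_model`.
#' @export
add_eut_bmc <- function(model, ea_lb = -1000) {
  new_rxn_ids <- c("EAt_bmc", "EUTBC", "EUTE", "EUTD", "EUTG",
                   "ETOH_BMC_EGRESS", "ACALD_BMC_EGRESS")
  clash <- intersect(new_rxn_ids, reaction_ids(model))
  if (length(clash))
    stop("reaction id collisions (BMC already installed?): ",
         paste(clash, collapse = ", "))
  need <- list(
    c("nh4_c", "ammonium", "cytosol", 0, 1),
    c("acp_c", "acetyl phosphate", "cytosol", 2, 0),
    c("etoh_c", "ethanol", "cytosol", 2, 0),
    c("acald_c", "acetaldehyde", "cytosol", 2, 0))
  for (s in need) {
    if (!s[[1]] %in% model$species$id)
      model$species <- rbind(model$species,
                             mk_sp(s[[1]], s[[2]], s[[3]],
                                   as.numeric(s[[4]]), as.numeric(s[[5]])))
  }
  bmc_species <- rbind(
    mk_sp("ea_b", "ethanolamine", "bmc", 2, 1),
    mk_sp("acald_b", "acetaldehyde", "bmc", 2, 0),
    mk_sp("etoh_b", "ethanol", "bmc", 2, 0),
    mk_sp("accoa_b", "acetyl-CoA (acetyl moiety)", "bmc", 2, 0),
    mk_sp("nad_b", "NAD (BMC-internal)", "bmc", 0, 0),
    mk_sp("nadh_b", "NADH (BMC-internal)", "bmc", 0, 0),
    mk_sp("coa_b", "CoA (BMC-internal)", "bmc", 0, 0))
  model$species <- rbind(model$species, bmc_species)
  bmc_reactions <- list(
    mk_rxn("EAt_bmc", c(ea_e = -1, ea_b = 1), type = "transport",
           name = "EA entry through shell pores"),
    mk_rxn("EUTBC", c(ea_b = -1, acald_b = 1, nh4_c = 1),
           name = "ethanolamine ammonia-lyase"),
    mk_rxn("EUTE", c(acald_b = -1, nad_b = -1, coa_b = -1,
                     accoa_b = 1, nadh_b = 1),
           name = "acetaldehyde dehydrogenase (BMC)"),
    mk_rxn("EUTD", c(accoa_b = -1, acp_c = 1, coa_b = 1),
           name = "phosphotransacetylase: acetyl-P egress"),
    mk_rxn("EUTG", c(acald_b = -1, nadh_b = -1, etoh_b = 1, nad_b = 1),
           name = "alcohol dehydrogenase (BMC)"),
    mk_rxn("ETOH_BMC_EGRESS", c(etoh_b = -1, etoh_c = 1), type = "transport"),
    mk_rxn("ACALD_BMC_EGRESS", c(acald_b = -1, acald_c = 1), type = "transport"))
  if (!"ACK" %in% reaction_ids(model))
    bmc_reactions <- c(bmc_reactions, list(
      mk_rxn("ACK", c(acp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
             name = "acetate kinase (cytosolic, EutQ/P role)")))
  model$reactions <- c(model$reactions, bmc_reactions)
  i <- which(reaction_ids(model) == "EX_ea_e")
  if (length(i)) model$reactions[[i]]$lb <- ea_lb
  stoichiometric_model(model$species, model$reactions, model$objective)
}

apply_constraints <- function(model, constraints) {
  ids <- reaction_ids(model)
  for (nm in names(constraints)) {
    i <- which(ids == nm)
    if (!length(i)) stop("constraint references unknown reaction: ", nm)
    v <- constraints[[nm]]
    if (length(v) == 1L) {
      model$reactions[[i]]$lb <- model$reactions[[i]]$ub <- v
    } else {
      model$reactions[[i]]$lb <- v[1]; model$reactions[[i]]$ub <- v[2]
    }
  }
  model
}

#' Flux balance analysis
#'
#' Solves the LP `max c'v` (or `min`) subject to `S v = 0` and the model's
#' bounds, after applying `constraints` (named list: a single value fixes the
#' flux, a length-2 vector sets bounds). Uptake through `EX_` exchange
#' reactions is negative by convention.
#'
#' @param model a `stoich_model`.
#' @param objective reaction id to optimize (default: the model objective).
#' @param constraints named list of fixed values or `c(lb, ub)` pairs.
#' @param direction `"max"` or `"min"`.
#' @return object of class `flux_solution`: `status` (`"optimal"` or
#'   `"infeasible"` — infeasibility is a status, not an error), `objective`,
#'   and named `fluxes` (mmol/gDW/h).
#' @export
fba <- function(model, objective = model$objective, constraints = list(),
                direction = "max") {
  model <- apply_constraints(model, constraints)
  ids <- reaction_ids(model)
  if (!objective %in% ids) stop("unknown objective reaction: ", objective)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(ids == objective)
  sol <- solve_lp(obj, S, lb, ub, maximize = direction == "max")
  fluxes <- if (is.null(sol$fluxes)) NULL else setNames(sol$fluxes, ids)
  structure(list(status = sol$status, objective = sol$objective,
                 fluxes = fluxes, objective_id = objective,
                 direction = direction),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "| objective", x$objective_id, "=",
      signif(x$objective, 6), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to retaining at least
#' `fraction` of the FBA optimum of `objective`.
#'
#' @param model a `stoich_model`.
#' @param objective objective reaction id.
#' @param fraction fraction of the optimum to maintain, in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @param constraints as in [fba()].
#' @return data frame (`reaction`, `min`, `max`) with the base FBA solution
#'   attached as attribute `fba`.
#' @export
fva <- function(model, objective = model$objective, fraction = 0.99,
                reactions = NULL, constraints = list()) {
  stopifnot(fraction > 0, fraction <= 1)
  model <- apply_constraints(model, constraints)
  base <- fba(model, objective)
  if (base$status != "optimal")
    stop("FVA base problem is ", base$status)
  ids <- reaction_ids(model)
  reactions <- reactions %||% ids
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  cvec <- as.numeric(ids == objective)
  # keep c'v >= fraction * optimum as -c'v <= -fraction * optimum
  A <- matrix(-cvec, 1)
  b <- -fraction * base$objective
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    oo <- as.numeric(ids == reactions[k])
    lo <- solve_lp(oo, S, lb, ub, A = A, b = b, maximize = FALSE)
    hi <- solve_lp(oo, S, lb, ub, A = A, b = b, maximize = TRUE)
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  attr(out, "fba") <- base
  out
}

#' Carbon/nitrogen partition of ethanolamine in an FBA solution
#'
#' Expresses the fate of EA-derived carbon as percentages of the EA uptake
#' flux (EA, ethanol, acetyl-P, acetaldehyde and acetate are all C2, so mole
#' shares equal carbon shares): ethanol egress (EutG), acetyl-P egress
#' (EutD), acetaldehyde egress; excreted acetate is attributed to BMC-derived
#' acetyl-P (the model's accounting convention, since acetate and ethanol are
#' assumed to originate from the BMCs), and the remainder of the BMC acetyl-P
#' is the anabolic acetyl-CoA share. Nitrogen: excreted vs assimilated
#' ammonium as percentages of EA nitrogen.
#'
#' @param solution a [fba()] solution on a BMC-augmented model.
#' @param model the matching `stoich_model`.
#' @return list of percentage shares plus the absolute fluxes used.
#' @export
ea_partition <- function(solution, model) {
  if (solution$status != "optimal") stop("solution is not optimal")
  v <- solution$fluxes
  ea_uptake <- -v[["EX_ea_e"]]
  if (ea_uptake <= 0) stop("EA uptake is zero: partition undefined")
  ethanol <- v[["EUTG"]]
  acp <- v[["EUTD"]]
  acald <- v[["ACALD_BMC_EGRESS"]]
  acetate <- v[["EX_ac_e"]]
  anabolic <- acp - acetate   # acetate attributed to BMC acetyl-P
  nh4_excreted <- max(v[["EX_nh4_e"]], 0)
  pct <- function(x) 100 * x / ea_uptake
  shares <- c(ethanol = pct(ethanol), acetyl_P = pct(acp),
              acetaldehyde = pct(acald))
  if (abs(sum(shares) - 100) > 0.5)
    warning("BMC egress carbon accounts for ", round(sum(shares), 2),
            "% of EA carbon (expected 100)")
  list(carbon_pct = c(shares,
                      acetate_excreted = pct(acetate),
                      anabolic_acetyl_CoA = pct(anabolic)),
       nitrogen_pct = c(nh4_excreted = pct(nh4_excreted),
                        nh4_assimilated = 100 - pct(nh4_excreted)),
       fluxes = c(ea_uptake = ea_uptake, ethanol = ethanol, acetyl_P = acp,
                  acetaldehyde = acald, acetate = acetate,
                  anabolic = anabolic, nh4_excreted = nh4_excreted))
}
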