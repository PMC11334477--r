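# Stoichiometric model container and the bundled reduced core model of
# glycerol/ethanolamine co-metabolism. Species carry explicit carbon and
# nitrogen counts so elemental balance is auditable; cofactors (ATP, NAD(H),
# CoA) are lumped C0/N0 carriers. Identifiers follow BiGG-style conventions
# (EX_ prefixes, _e/_c/_b compartment suffixes) so a genome-scale model such
# as iML1515 can be substituted via SBML.

#' Construct a stoichiometric model
#'
#' @param species data frame with columns `id`, `name`, `compartment`,
#'   `C`, `N` (atom counts).
#' @param reactions list of reactions, each a list with `id`, `stoich`
#'   (named numeric: negative = consumed), `lb`, `ub`, `type` (one of
#'   `internal`, `transport`, `exchange`, `biomass`, `sink`, `maintenance`),
#'   and optional `name`.
#' @param objective reaction id of the default objective (maximized).
#' @return object of class `stoich_model`.
#' @export
stoichiometric_model <- function(species, reactions, objective) {
  stopifnot(all(c("id", "compartment", "C", "N") %in% names(species)))
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), species$id)
    if (length(unknown))
      stop("reaction ", r$id, " references unknown species: ",
           paste(unknown, collapse = ", "))
    if (r$lb > r$ub) stop("reaction ", r$id, ": lb > ub")
  }
  if (!objective %in% ids) stop("objective reaction not in model")
  m <- structure(list(species = species, reactions = reactions,
                      objective = objective), class = "stoich_model")
  bal <- element_balance(m)
  if (nrow(bal)) stop("elementally unbalanced reactions: ",
                      paste(bal$reaction, collapse = ", "))
  m
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' Stoichiometric matrix of a model
#'
#' @param model a `stoich_model`.
#' @return dense matrix, species x reactions.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$species), length(model$reactions),
              dimnames = list(model$species$id, reaction_ids(model)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Audit carbon/nitrogen balance of all internal reactions
#'
#' Checks that every reaction that is not an exchange, biomass, sink or
#' maintenance pseudo-reaction conserves carbon and nitrogen.
#'
#' @param model a `stoich_model`.
#' @param tol imbalance tolerance (atoms).
#' @return data frame of violations (`reaction`, `dC`, `dN`); zero rows when
#'   clean.
#' @export
element_balance <- function(model, tol = 1e-9) {
  C <- setNames(model$species$C, model$species$id)
  N <- setNames(model$species$N, model$species$id)
  out <- list()
  for (r in model$reactions) {
    if (r$type %in% c("exchange", "biomass", "sink", "maintenance")) next
    dC <- sum(r$stoich * C[names(r$stoich)])
    dN <- sum(r$stoich * N[names(r$stoich)])
    if (abs(dC) > tol || abs(dN) > tol)
      out[[r$id]] <- data.frame(reaction = r$id, dC = dC, dN = dN)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(reaction = character(), dC = numeric(), dN = numeric())
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model:", length(x$reactions), "reactions,",
      nrow(x$species), "species,",
      length(unique(x$species$compartment)), "compartments\n")
  cat("objective:", x$objective, "(maximize)\n")
  invisible(x)
}

mk_sp <- function(id, name, comp, C, N)
  data.frame(id = id, name = name, compartment = comp, C = C, N = N)

mk_rxn <- function(id, stoich, lb = 0, ub = 1000, type = "internal",
                   name = id)
  list(id = id, stoich = stoich, lb = lb, ub = ub, type = type, name = name)

#' Bundled reduced core model of glycerol metabolism
#'
#' A deliberately small, elementally balanced stand-in for a genome-scale
#' model: glycerol exchange and uptake, lumped glycolysis to acetyl-P (with
#' CO2 release and substrate-level ATP), lumped TCA oxidation of acetyl-CoA,
#' lumped oxidative phosphorylation, acetate kinase, an ATP-maintenance
#' reaction, and a biomass reaction with a 4:1 C:N composition drawing on
#' acetyl-CoA and ammonium. Ethanolamine, ethanol and acetaldehyde exchange
#' species exist but carry no producing pathway until [add_eut_bmc()] is
#' applied. Default exchange bounds describe the study medium: glycerol
#' available up to the measured uptake (14.7 mmol/gDW/h), ammonium unlimited,
#' ethanolamine closed.
#'
#' @return a `stoich_model` with objective `BIOMASS`.
#' @export
build_core_model <- function() {
  species <- rbind(
    mk_sp("glyc_e", "glycerol", "extracellular", 3, 0),
    mk_sp("glyc_c", "glycerol", "cytosol", 3, 0),
    mk_sp("ea_e", "ethanolamine", "extracellular", 2, 1),
    mk_sp("etoh_e", "ethanol", "extracellular", 2, 0),
    mk_sp("etoh_c", "ethanol", "cytosol", 2, 0),
    mk_sp("ac_e", "acetate", "extracellular", 2, 0),
    mk_sp("ac_c", "acetate", "cytosol", 2, 0),
    mk_sp("acald_e", "acetaldehyde", "extracellular", 2, 0),
    mk_sp("acald_c", "acetaldehyde", "cytosol", 2, 0),
    mk_sp("nh4_e", "ammonium", "extracellular", 0, 1),
    mk_sp("nh4_c", "ammonium", "cytosol", 0, 1),
    mk_sp("co2_e", "carbon dioxide", "extracellular", 1, 0),
    mk_sp("co2_c", "carbon dioxide", "cytosol", 1, 0),
    mk_sp("acp_c", "acetyl phosphate", "cytosol", 2, 0),
    mk_sp("accoa_c", "acetyl-CoA (acetyl moiety)", "cytosol", 2, 0),
    mk_sp("atp_c", "ATP (lumped carrier)", "cytosol", 0, 0),
    mk_sp("adp_c", "ADP (lumped carrier)", "cytosol", 0, 0),
    mk_sp("nad_c", "NAD (lumped carrier)", "cytosol", 0, 0),
    mk_sp("nadh_c", "NADH (lumped carrier)", "cytosol", 0, 0),
    mk_sp("coa_c", "CoA (lumped carrier)", "cytosol", 0, 0))
  reactions <- list(
    mk_rxn("EX_glyc_e", c(glyc_e = -1), lb = -14.7, type = "exchange"),
    mk_rxn("EX_ea_e", c(ea_e = -1), lb = 0, type = "exchange"),
    mk_rxn("EX_etoh_e", c(etoh_e = -1), type = "exchange"),
    mk_rxn("EX_ac_e", c(ac_e = -1), type = "exchange"),
    mk_rxn("EX_acald_e", c(acald_e = -1), type = "exchange"),
    mk_rxn("EX_nh4_e", c(nh4_e = -1), lb = -1000, type = "exchange"),
    mk_rxn("EX_co2_e", c(co2_e = -1), type = "exchange"),
    mk_rxn("GLYCt", c(glyc_e = -1, glyc_c = 1), type = "transport"),
    mk_rxn("ETOHt", c(etoh_c = -1, etoh_e = 1), type = "transport"),
    mk_rxn("ACt", c(ac_c = -1, ac_e = 1), type = "transport"),
    mk_rxn("ACALDt", c(acald_c = -1, acald_e = 1), type = "transport"),
    mk_rxn("NH4t", c(nh4_e = -1, nh4_c = 1), lb = -1000, type = "transport"),
    mk_rxn("CO2t", c(co2_c = -1, co2_e = 1), type = "transport"),
    mk_rxn("GLYCOLYSIS",
           c(glyc_c = -1, nad_c = -1, adp_c = -2,
             acp_c = 1, co2_c = 1, nadh_c = 1, atp_c = 2),
           name = "lumped glycolysis: glycerol to acetyl-P"),
    mk_rxn("PTA_ACCOA", c(acp_c = -1, coa_c = -1, accoa_c = 1),
           name = "acetyl-P to acetyl-CoA"),
    mk_rxn("ACK", c(acp_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
           name = "acetate kinase"),
    mk_rxn("TCA", c(accoa_c = -1, nad_c = -4, co2_c = 2, nadh_c = 4, coa_c = 1),
           name = "lumped TCA oxidation"),
    mk_rxn("NADHOX", c(nadh_c = -1, adp_c = -2, nad_c = 1, atp_c = 2),
           name = "lumped oxidative phosphorylation"),
    mk_rxn("ATPM", c(atp_c = -1, adp_c = 1), type = "maintenance",
           name = "ATP maintenance"),
    mk_rxn("BIOMASS",
           c(accoa_c = -2, nh4_c = -1, atp_c = -20, adp_c = 20, coa_c = 2),
           type = "biomass", name = "biomass synthesis (C:N = 4:1)"))
  stoichiometric_model(species, reactions, objective = "BIOMASS")
}
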