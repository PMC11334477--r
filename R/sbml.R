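# Minimal SBML Level 3 + fbc reader/writer for stoichiometric models.
# Covers the subset constraint-based tools exchange: compartments, species
# with chemical formulas, per-reaction flux-bound parameters, stoichiometry,
# and an fbc objective. Round trip (load -> write -> load) preserves the
# stoichiometric matrix, the bounds and the objective.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a stoichiometric model as SBML Level 3 with fbc
#'
#' @param model a `stoich_model`.
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  formula <- function(C, N) {
    f <- ""
    if (C > 0) f <- paste0(f, "C", C)
    if (N > 0) f <- paste0(f, "N", N)
    if (f == "") "X" else f   # carrier pseudo-species
  }
  ln <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
          sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
                  SBML_NS, FBC_NS),
          sprintf('  <model id="eutflux_model" fbc:strict="true">'))
  comps <- unique(model$species$compartment)
  ln <- c(ln, "    <listOfCompartments>",
          sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
          "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    ln <- c(ln, sprintf(paste0('      <species id="%s" name="%s" compartment="%s"',
                               ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                               ' constant="false" fbc:chemicalFormula="%s"/>'),
                        esc(s$id), esc(s$name), esc(s$compartment),
                        formula(s$C, s$N)))
  }
  ln <- c(ln, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions)
    ln <- c(ln, sprintf('      <parameter id="%s_lb" value="%.17g" constant="true"/>',
                        esc(r$id), r$lb),
            sprintf('      <parameter id="%s_ub" value="%.17g" constant="true"/>',
                    esc(r$id), r$ub))
  ln <- c(ln, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    ln <- c(ln, sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false"',
                               ' fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">'),
                        esc(r$id), esc(r$name %||% r$id),
                        if (r$lb < 0) "true" else "false", esc(r$id), esc(r$id)),
            sprintf('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>type: %s</p></body></notes>',
                    r$type))
    sub <- r$stoich[r$stoich < 0]; prod <- r$stoich[r$stoich > 0]
    if (length(sub)) ln <- c(ln, "        <listOfReactants>",
      sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
              esc(names(sub)), -unname(sub)), "        </listOfReactants>")
    if (length(prod)) ln <- c(ln, "        <listOfProducts>",
      sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
              esc(names(prod)), unname(prod)), "        </listOfProducts>")
    ln <- c(ln, "      </reaction>")
  }
  ln <- c(ln, "    </listOfReactions>",
          '    <fbc:listOfObjectives fbc:activeObjective="obj">',
          '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
          "        <fbc:listOfFluxObjectives>",
          sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                  esc(model$objective)),
          "        </fbc:listOfFluxObjectives>", "      </fbc:objective>",
          "    </fbc:listOfObjectives>", "  </model>", "</sbml>")
  writeLines(ln, path)
  invisible(path)
}

#' Read a stoichiometric model from SBML Level 3 with fbc
#'
#' Parses compartments, species (carbon/nitrogen counts from
#' `fbc:chemicalFormula` when present), reactions with fbc flux bounds, and
#' the active fbc objective. Fails with an explicit message when the fbc
#' package is absent; a malformed file raises a parse error and no partial
#' model is returned.
#'
#' @param path an SBML file.
#' @return a `stoich_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns_all <- xml2::xml_ns(doc)
  if (!any(grepl("sbml", ns_all, fixed = TRUE)))
    stop("not an SBML document: ", path)
  if (!any(grepl("/fbc/", ns_all, fixed = TRUE)))
    stop("SBML file lacks the fbc package (flux bounds/objective): ", path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  # tolerate other sbml level/version URIs by rewriting the prefix map
  s_uri <- grep("sbml.org/sbml/level", ns_all, value = TRUE)
  s_uri <- s_uri[!grepl("/fbc/", s_uri)][1]
  fbc_uri <- grep("/fbc/", ns_all, value = TRUE)[1]
  ns <- c(s = unname(s_uri), fbc = unname(fbc_uri))

  att <- xml2::xml_attr
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("no species found in ", path)
  count_el <- function(f, el) {
    if (is.na(f)) return(0)
    m <- regmatches(f, regexec(paste0(el, "(?![a-z])([0-9]*)"), f, perl = TRUE))[[1]]
    if (length(m) < 2 || !nzchar(m[1])) return(0)
    if (nzchar(m[2])) as.numeric(m[2]) else 1
  }
  forms <- att(sp_nodes, "chemicalFormula")
  species <- data.frame(
    id = att(sp_nodes, "id"),
    name = ifelse(is.na(att(sp_nodes, "name")), att(sp_nodes, "id"),
                  att(sp_nodes, "name")),
    compartment = att(sp_nodes, "compartment"),
    C = vapply(forms, count_el, 0, el = "C"),
    N = vapply(forms, count_el, 0, el = "N"))
  rownames(species) <- NULL

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pars <- setNames(as.numeric(att(par_nodes, "value")), att(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("no reactions found in ", path)
  reactions <- lapply(rx_nodes, function(nd) {
    id <- att(nd, "id")
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(nd, xp, ns)
      if (!length(refs)) return(numeric())
      setNames(sign * as.numeric(att(refs, "stoichiometry")),
               att(refs, "species"))
    }
    st_neg <- get_side("./s:listOfReactants/s:speciesReference", -1)
    st_pos <- get_side("./s:listOfProducts/s:speciesReference", +1)
    st <- c(st_neg, st_pos)
    lb_ref <- att(nd, "lowerFluxBound")
    ub_ref <- att(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pars)) pars[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pars)) pars[[ub_ref]] else 1000
    note <- xml2::xml_text(xml2::xml_find_first(nd, ".//s:notes", ns))
    type <- if (!is.na(note) && grepl("type:", note)) {
      trimws(sub(".*type:\\s*", "", note))
    } else if (startsWith(id, "EX_")) "exchange"
    else if (grepl("biomass", id, ignore.case = TRUE)) "biomass"
    else if (startsWith(id, "SK_") || startsWith(id, "DM_")) "sink"
    else if (grepl("^ATPM", id)) "maintenance"
    else "internal"
    nm <- att(nd, "name")
    list(id = id, stoich = st, lb = lb, ub = ub, type = type,
         name = if (is.na(nm)) id else nm)
  })

  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (inherits(obj_node, "xml_missing"))
    stop("SBML file lacks an fbc objective: ", path)
  objective <- xml2::xml_attr(obj_node, "reaction")

  stoichiometric_model(species, reactions, objective)
}
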