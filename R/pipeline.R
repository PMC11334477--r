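# Pipeline orchestration and result I/O: synthetic data -> physiology fit ->
# compartmentalized FBA -> isotopic fit, driven by a YAML configuration with
# one global seed fanned out per stage.

PIPELINE_KEYS <- list(
  top = c("seed", "output_dir", "stages", "design", "physiology", "fba",
          "isotopic"),
  design = c("t_start", "t_end", "n_points", "n_replicates", "noise_cv",
             "noise_floor"),
  physiology = c("n_starts", "mc_n"),
  fba = c("sbml_path", "constraints", "objective", "fva_fraction"),
  isotopic = c("iterations", "swarm", "tracer_purity", "cyt_ethanol",
               "fluxes"))

#' Read and validate a pipeline configuration
#'
#' YAML file with a global `seed`, an `output_dir`, the `stages` to run
#' (subset of `synthetic`, `physiology`, `fba`, `isotopic`), a sampling
#' `design` block and per-stage option blocks. Unknown keys are rejected
#' before any computation.
#'
#' @param path YAML file.
#' @return validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a configuration list (as from `yaml::read_yaml`).
#' @export
validate_pipeline_config <- function(cfg) {
  chk <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  chk(cfg, PIPELINE_KEYS$top, "top level")
  for (blk in c("design", "physiology", "fba", "isotopic"))
    if (!is.null(cfg[[blk]])) chk(cfg[[blk]], PIPELINE_KEYS[[blk]], blk)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% tempfile("eutflux_run_")
  cfg$stages <- cfg$stages %||% c("synthetic", "physiology", "fba", "isotopic")
  bad <- setdiff(cfg$stages, c("synthetic", "physiology", "fba", "isotopic"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$fba$sbml_path) && !file.exists(cfg$fba$sbml_path))
    stop("configured SBML model does not exist: ", cfg$fba$sbml_path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

result_meta <- function(cfg) {
  list(tool = "eutflux", version = as.character(packageVersion("eutflux")),
       seed = cfg$seed,
       config_hash = substr(jsonlite::base64_enc(
         serialize(unclass(cfg)[order(names(cfg))], NULL)), 1, 24),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write / read a JSON result object
#'
#' Every result file embeds the tool version, a configuration hash and the
#' seed under `meta`.
#'
#' @param obj list to serialize (a `meta` entry is added if absent).
#' @param path output path.
#' @param meta metadata list, e.g. from a pipeline configuration.
#' @export
write_result <- function(obj, path, meta = NULL) {
  if (is.null(obj$meta)) obj$meta <- meta %||%
      list(tool = "eutflux", version = as.character(packageVersion("eutflux")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

log_line <- function(con, stage, msg, ...) {
  rec <- list(stage = stage, message = msg, time = format(Sys.time()), ...)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  message("[", stage, "] ", msg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: synthetic data generation,
#' physiology fitting (with exponential-phase truncation), compartmentalized
#' FBA with EA partition, and the PSO isotopic fit. Each stage writes a
#' versioned JSON (and CSV for tables) into the output directory together
#' with a JSON-lines run log recording seeds and settings. A stage failure
#' aborts the run with the stage name in the error.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return invisible list of per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
    else validate_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$output_dir, "run_log.jsonl"), "a")
  on.exit(close(logf))
  meta <- result_meta(cfg)
  results <- list()
  stage <- "setup"
  run_stage <- function(name, fun) {
    stage <<- name
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  des_args <- cfg$design %||% list()
  design <- do.call(sampling_design, c(des_args, list(seed = cfg$seed)))

  if ("synthetic" %in% cfg$stages) {
    results$synthetic <- run_stage("synthetic", function() {
      pp <- physio_params(
        X0 = 0.026, mu = 0.45,
        substrates = list(glycerol = list(S0 = 30, q = 14.7),
                          ethanolamine = list(S0 = 20, q = 7.8)),
        products = list(acetate = list(P0 = 0, q = 1.7),
                        ethanol = list(P0 = 0, q = 2.6)))
      ts <- generate_physiology_timeseries(pp, design)
      write_timeseries(ts, file.path(cfg$output_dir, "physiology_timeseries.csv"))
      fl <- do.call(reference_flux_set, cfg$isotopic$fluxes %||% list())
      tr <- generate_labeling_timeseries(fl, design = design)
      write_timeseries(tr, file.path(cfg$output_dir, "labeling_timeseries.csv"))
      log_line(logf, "synthetic", "wrote synthetic tables", seed = cfg$seed)
      list(physiology = ts, labeling = tr)
    })
  }
  if ("physiology" %in% cfg$stages) {
    results$physiology <- run_stage("physiology", function() {
      ts <- results$synthetic$physiology %||%
        read_timeseries(file.path(cfg$output_dir, "physiology_timeseries.csv"))
      ts <- truncate_exponential_phase(ts)
      fit <- fit_physiology(
        ts, roles = c(glycerol = "substrate", ethanolamine = "substrate",
                      acetate = "product", ethanol = "product"),
        n_starts = cfg$physiology$n_starts %||% 10,
        mc_n = cfg$physiology$mc_n %||% 0, seed = cfg$seed)
      out <- list(mu = fit$params$mu, X0 = fit$params$X0,
                  q = c(glycerol = fit$params$substrates$glycerol$q,
                        ethanolamine = fit$params$substrates$ethanolamine$q,
                        acetate = fit$params$products$acetate$q,
                        ethanol = fit$params$products$ethanol$q),
                  objective = fit$objective, settings = fit$settings)
      write_result(out, file.path(cfg$output_dir, "physiology_fit.json"), meta)
      log_line(logf, "physiology", "fit complete",
               objective = fit$objective)
      fit
    })
  }
  if ("fba" %in% cfg$stages) {
    results$fba <- run_stage("fba", function() {
      model <- if (!is.null(cfg$fba$sbml_path)) read_sbml(cfg$fba$sbml_path)
        else add_eut_bmc(build_core_model())
      constraints <- cfg$fba$constraints %||% list(
        BIOMASS = 0.45, EX_ea_e = -7.8, EX_etoh_e = 2.6, EX_ac_e = 1.7,
        EX_glyc_e = -14.7)
      sol <- fba(model, objective = cfg$fba$objective %||% "ATPM",
                 constraints = constraints)
      part <- ea_partition(sol, model)
      out <- list(status = sol$status, objective = sol$objective,
                  partition = part)
      write_result(out, file.path(cfg$output_dir, "fba_partition.json"), meta)
      log_line(logf, "fba", paste("FBA", sol$status))
      out
    })
  }
  if ("isotopic" %in% cfg$stages) {
    results$isotopic <- run_stage("isotopic", function() {
      tr <- results$synthetic$labeling %||%
        read_timeseries(file.path(cfg$output_dir, "labeling_timeseries.csv"))
      net <- build_eut_network(
        cyt_ethanol = cfg$isotopic$cyt_ethanol %||% TRUE)
      fit <- pso_fit(tr, net,
                     iterations = cfg$isotopic$iterations %||% 2000,
                     swarm = cfg$isotopic$swarm %||% 50,
                     seed = cfg$seed,
                     tracer_purity = cfg$isotopic$tracer_purity %||% 1)
      out <- list(objective = fit$objective,
                  fluxes = unlist(fit$params[c("v_EA_uptake", "v_EutG",
                                               "v_EutD", "v_AAL_release",
                                               "v_glycolysis", "v_AceX",
                                               "v_Pta", "v_NH4X",
                                               "v_cytEtOH")]),
                  mu = fit$params$mu, settings = fit$settings)
      write_result(out, file.path(cfg$output_dir, "isotopic_fit.json"), meta)
      log_line(logf, "isotopic", "PSO fit complete", objective = fit$objective)
      fit
    })
  }
  log_line(logf, "done", "pipeline complete")
  invisible(results)
}
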