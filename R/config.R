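# YAML run-configuration loading and run provenance.

CONFIG_KEYS <- c("prescreen_cutoff", "quickopt_max_iter", "pd_c_max",
                 "threshold_pa", "threshold_sear", "temperature",
                 "gas_constant", "hartree_to_kcal", "report_fraction_min")

#' Read and validate a YAML predictor configuration
#'
#' Missing keys take the documented defaults (10 kcal/mol pre-screen, 5
#' quick-opt iterations, 2.4 A Pd-C cutoff, thresholds 0 and 5 kcal/mol,
#' 298.15 K); unknown keys are rejected rather than ignored.
#'
#' @param x YAML text, a YAML file path, or a named list.
#' @return A [predictor_config()].
#' @export
read_predictor_config <- function(x = NULL) {
  vals <- if (is.null(x)) {
    list()
  } else if (is.list(x)) {
    x
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(x)
  }
  vals <- vals %||% list()
  unknown <- setdiff(names(vals), CONFIG_KEYS)
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "pdregio_config_error")
  }
  do.call(predictor_config, vals)
}

#' Run a prediction and write report + manifest files
#'
#' The function behind the command-line `predict` entry point. Resolves the
#' backend, runs [predict_mechanism()], writes `report_<id>.json` /
#' `report_<id>.csv` and an append-only `manifest.json` capturing config,
#' backend, seeds and per-substrate outcome. Reports carry no timestamps, so
#' reruns with a deterministic backend are byte-identical; timestamps live in
#' the manifest only.
#'
#' @param smiles,substrate_id Input: a SMILES string (structure route) and/or
#'   the substrate id (required for the table route).
#' @param backend `"tabulated"` or `"synthetic"`.
#' @param table Energy-table CSV path (required for `backend = "tabulated"`;
#'   defaults to the bundled validation table when `substrate_id` matches a
#'   fixture).
#' @param deltas Optional per-substrate delta CSV/tibble for the tabulated
#'   backend.
#' @param seed Integer seed.
#' @param mech_offset,site_gap,noise_sd Synthetic-backend parameters.
#' @param config `NULL`, a YAML path/text or a [predictor_config()].
#' @param out Output directory.
#' @return The `ch_report`, invisibly.
#' @export
run_predict <- function(smiles = NULL, substrate_id = NULL,
                        backend = c("tabulated", "synthetic"), table = NULL,
                        deltas = NULL, seed = 1L, mech_offset = 0,
                        site_gap = 1, noise_sd = 0, config = NULL,
                        out = ".") {
  backend <- match.arg(backend)
  cfg <- if (inherits(config, "predictor_config")) config else
    read_predictor_config(config)
  be <- if (backend == "tabulated") {
    if (is.null(table)) {
      abort("backend 'tabulated' requires an energy table",
            class = "pdregio_config_error")
    }
    if (!is.data.frame(table) && !file.exists(table)) {
      abort(sprintf("energy table file '%s' not found", table),
            class = "pdregio_config_error")
    }
    tab <- read_energy_table(table)
    d <- deltas %||% attr(tab, "deltas")
    if (is.character(d)) d <- read.csv(d, stringsAsFactors = FALSE)
    tabulated_backend(tab, deltas = d)
  } else {
    synthetic_backend(seed = seed, site_gap = site_gap,
                      mech_offset = mech_offset, noise_sd = noise_sd)
  }
  x <- if (!is.null(smiles)) {
    parse_substrate(smiles, id = substrate_id %||% "query")
  } else if (!is.null(substrate_id)) {
    substrate_id
  } else {
    abort("either smiles or substrate_id is required",
          class = "pdregio_config_error")
  }
  report <- predict_mechanism(x, be, cfg, seed = seed)
  paths <- write_report(report, out)
  append_manifest(out, report, cfg, be, seed)
  invisible(report)
}

append_manifest <- function(dir, report, cfg, backend, seed) {
  path <- file.path(dir, "manifest.json")
  entry <- list(
    substrate_id = report$substrate_id,
    backend = backend$name,
    deterministic = backend$deterministic,
    seed = as.integer(seed),
    backend_seed = backend$seed %||% NA_integer_,
    config = unclass(cfg),
    call = report$call,
    basis = report$basis,
    delta_kcal = report$stability$delta,
    version = as.character(utils::packageVersion("pdregio")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  existing <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else list()
  jsonlite::write_json(c(existing, list(entry)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
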