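# Bundled validation fixtures (the published worked-example tables as
# machine-readable CSV) and synthetic-data generators for property tests.
#
# Substrate structures in the validation tables are depicted as drawings in
# the source; the SMILES shipped here (`smiles_synthetic` columns) are
# synthetic stand-ins with structure_confidence = "low", and every
# energy-level check keys off substrate ids, never structures. Likewise the
# per-site Pd-C distances in paper_tables.csv are synthetic placeholders in
# the stable range; only the stable/unstable status is source-derived.
# table2_meta.csv carries synthetic cross-mechanism delta offsets chosen to
# be consistent with the published per-substrate mechanism calls (the tables
# print only within-mechanism relative energies).

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "pdregio")
  if (!nzchar(p)) {
    # fall back for devtools::load_all() layouts
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) abort(sprintf("fixture file '%s' not found", file))
  p
}

#' Load the bundled validation fixtures
#'
#' Reads and validates the packaged worked-example tables: 12 literature
#' substrates with reaction conditions (`table1`), 8 heteroaromatic substrates
#' with per-mechanism site energies and mechanism calls (`table2_meta` plus
#' rows of `energies`), 6 further validation substrates (`table3`), and the 6
#' mechanism-threshold test records with Gibbs energies, Pd-C distances and
#' relative stabilities (`table4`; the entry-5 sign anomaly is stored verbatim
#' with `anomaly_flag = 1`).
#'
#' @return A `fixture_set` list: `table1`, `table2_meta`, `table3`, `table4`
#'   (tibbles) and `energies` (an `energy_table`).
#' @export
load_paper_fixtures <- function() {
  t1 <- as_tibble(read.csv(fixture_path("table1.csv"), stringsAsFactors = FALSE))
  t2 <- as_tibble(read.csv(fixture_path("table2_meta.csv"), stringsAsFactors = FALSE))
  t3 <- as_tibble(read.csv(fixture_path("table3.csv"), stringsAsFactors = FALSE))
  t4 <- as_tibble(read.csv(fixture_path("table4.csv"), stringsAsFactors = FALSE))
  en <- read_energy_table(fixture_path("paper_tables.csv"))
  if (nrow(t1) != 12) abort("fixture integrity: table1 must have 12 records")
  if (nrow(t2) != 8) abort("fixture integrity: table2 must have 8 records")
  if (nrow(t3) != 6) abort("fixture integrity: table3 must have 6 records")
  if (nrow(t4) != 6) abort("fixture integrity: table4 must have 6 records")
  if (!all(t2$substrate_id %in% en$substrate_id)) {
    abort("fixture integrity: every table2 substrate needs energy records")
  }
  structure(list(table1 = t1, table2_meta = t2, table3 = t3, table4 = t4,
                 energies = en),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> %d + %d + %d substrates, %d threshold records, %d energy rows\n",
              nrow(x$table1), nrow(x$table2_meta), nrow(x$table3),
              nrow(x$table4), nrow(x$energies)))
  invisible(x)
}

#' Generate a synthetic energy table with known ground truth
#'
#' Builds a deterministic [read_energy_table()]-conformant table whose true
#' per-substrate stability parameters (and the mechanism calls they imply) are
#' recorded in a ground-truth ledger, for parameter-recovery tests. Optional
#' Gaussian noise perturbs both the site energies and the cross-mechanism
#' delta actually written into the table, while the ledger keeps the noiseless
#' truth.
#'
#' @param n_substrates,n_sites Table dimensions (`n_sites` >= 1).
#' @param delta_distribution True stability parameters: a single number (point
#'   mass), a numeric vector of length `n_substrates`, or a `function(n)`
#'   drawing `n` values. Default: uniform on \[-10, 15\], spanning the PA /
#'   ambiguous / SEAr regimes.
#' @param decomposed_rate Probability, per substrate, that the
#'   `decomposed_mechanism` group is decomposed (all its records unstable).
#' @param seed Integer seed; same seed, same table.
#' @param noise_sd Gaussian noise sd in kcal/mol (0 = exact).
#' @param site_gap Spacing of consecutive site energies (kcal/mol).
#' @param decomposed_mechanism Which mechanism `decomposed_rate` applies to.
#' @param config Thresholds used to derive the true calls.
#' @return An `energy_table` with attributes `deltas` (tibble `substrate_id`,
#'   `delta_kcal` as realised in the table) and `ground_truth` (tibble
#'   `substrate_id`, `true_delta`, `decomposed`, `true_call`).
#' @export
make_synthetic_table <- function(n_substrates, n_sites,
                                 delta_distribution = function(n) runif(n, -10, 15),
                                 decomposed_rate = 0, seed = 1L, noise_sd = 0,
                                 site_gap = 1.5,
                                 decomposed_mechanism = "SEAR",
                                 config = predictor_config()) {
  stopifnot(n_sites >= 1, decomposed_rate >= 0, decomposed_rate <= 1)
  with_local_seed(as.integer(seed), {
    deltas <- if (is.function(delta_distribution)) {
      delta_distribution(n_substrates)
    } else if (length(delta_distribution) == 1) {
      rep(as.numeric(delta_distribution), n_substrates)
    } else {
      stopifnot(length(delta_distribution) == n_substrates)
      as.numeric(delta_distribution)
    }
    decomposed <- runif(n_substrates) < decomposed_rate
    ids <- sprintf("s%04d", seq_len(n_substrates))

    rows <- list(); realised <- numeric(n_substrates)
    for (i in seq_len(n_substrates)) {
      realised[i] <- deltas[i] + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
      for (m in c("PA", "SEAR")) {
        dec <- decomposed[i] && m == decomposed_mechanism
        raw <- (seq_len(n_sites) - 1) * site_gap +
          if (noise_sd > 0) rnorm(n_sites, 0, noise_sd) else 0
        rows[[length(rows) + 1]] <- tibble(
          substrate_id = ids[i], mechanism = m,
          h_label = paste0("H", seq_len(n_sites)),
          rel_gibbs_kcal = raw - min(raw),
          pd_c_angstrom = if (dec) 9.99 else round(runif(n_sites, 2.0, 2.3), 4),
          stable = as.integer(!dec)
        )
      }
    }
    tab <- read_energy_table(bind_rows(rows))

    true_call <- ifelse(
      decomposed & decomposed_mechanism == "SEAR", "PA",
      ifelse(decomposed & decomposed_mechanism == "PA", "SEAR",
        ifelse(deltas < config$threshold_pa, "PA",
          ifelse(deltas > config$threshold_sear, "SEAR", "AMBIGUOUS"))))
    attr(tab, "deltas") <- tibble(substrate_id = ids, delta_kcal = realised)
    attr(tab, "ground_truth") <- tibble(substrate_id = ids, true_delta = deltas,
                                        decomposed = decomposed,
                                        true_call = true_call)
    tab
  })
}

#' Generate NWChem-dialect fixture logs for an error-class scenario
#'
#' Produces one synthetic engine log per requested outcome, parsing back (via
#' [parse_result()] and [classify_failure()]) to exactly that error class.
#' Used to exercise the remediation state machine without an engine.
#'
#' @param scenario Character vector of error classes (`"NONE"`,
#'   `"SADDLE_POINT"`, `"HESSIAN_STALE"`, `"BAD_GUESS"`, `"DECOMPOSED"`,
#'   `"HARD_FAIL"`); must be non-empty.
#' @param geometry Optional geometry tibble for the logs; default is a small
#'   Pd-C-H model complex (Pd-C 2.10 A; 7.1781 A in decomposed logs).
#' @return A list of log strings, one per scenario element.
#' @export
make_fixture_logs <- function(scenario, geometry = NULL) {
  if (!length(scenario)) {
    abort("scenario must be non-empty", class = "pdregio_input_error")
  }
  bad <- setdiff(scenario, ERROR_CLASSES)
  if (length(bad)) {
    abort(sprintf("unknown scenario token(s): %s", paste(bad, collapse = ", ")),
          class = "pdregio_input_error")
  }
  geo_ok <- geometry %||% tibble(element = c("Pd", "C", "H"),
                                 x = c(0, 2.10, 2.75), y = 0, z = 0)
  geo_dec <- geo_ok
  geo_dec$x[geo_dec$element == "Pd"] <- geo_dec$x[geo_dec$element == "C"][1] - 7.1781
  n <- nrow(geo_ok)
  mode1 <- matrix(0, n, 3); mode1[1, 1] <- 1
  modes3 <- list(mode1, matrix(0, n, 3), matrix(0, n, 3))
  map(scenario, function(tok) {
    switch(tok,
      NONE = render_nwchem_log(geo_ok, energy = -355.5652,
                               frequencies = c(25.0, 45.1, 310.2),
                               modes = modes3, gibbs_correction = 0.011),
      SADDLE_POINT = render_nwchem_log(geo_ok, energy = -355.5601,
                                       frequencies = c(-152.0, 45.1, 310.2),
                                       modes = modes3, gibbs_correction = 0.011),
      DECOMPOSED = render_nwchem_log(geo_dec, energy = -355.5717,
                                     frequencies = c(25.0, 45.1, 310.2),
                                     modes = modes3, gibbs_correction = 0.011),
      HESSIAN_STALE = render_nwchem_log(
        geo_ok, energy = -355.41, converged = FALSE,
        failure_lines = c(
          " driver: step rejected, large geometry change detected",
          " Line search failed: the Hessian is out of date")),
      BAD_GUESS = render_nwchem_log(
        NULL, energy = NA, converged = FALSE, terminated = FALSE,
        failure_lines = " Fatal error: failure to perform initial guess"),
      HARD_FAIL = render_nwchem_log(
        NULL, energy = NA, converged = FALSE, terminated = FALSE,
        failure_lines = " received signal: segmentation violation")
    )
  })
}
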