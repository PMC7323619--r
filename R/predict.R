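# End-to-end prediction: sites -> intermediates -> quick-opt pre-screen ->
# full opt with remediation -> Pd-C filter -> relative energies -> stability
# parameter -> mechanism call -> Boltzmann fractions.

#' Predict mechanism and regioselectivity for one substrate
#'
#' Runs the full pipeline. Two input modes:
#'
#' * a `substrate` object (structure route): aromatic C-H sites are
#'   enumerated, conformers embedded and Pd(OAc)2 intermediates built for both
#'   mechanisms, then evaluated through `backend`;
#' * a substrate id string with a tabulated backend (table route): sites and
#'   final Gibbs energies are drawn directly from the backend's energy table,
#'   skipping 3D construction and the quick-opt pre-screen (the tabulated
#'   values are final Gibbs energies, already past pre-screening).
#'
#' @param x A `substrate` or a substrate id string.
#' @param backend A `pdregio_backend`.
#' @param config A [predictor_config()].
#' @param max_conformers Conformers per substrate on the structure route.
#' @param seed Seed recorded in provenance and used for conformer embedding.
#' @return A `ch_report` object; see [tidy.ch_report()], [glance.ch_report()],
#'   [autoplot.ch_report()].
#' @export
predict_mechanism <- function(x, backend, config = predictor_config(),
                              max_conformers = 3L, seed = 1L) {
  stopifnot(inherits(backend, "pdregio_backend"),
            inherits(config, "predictor_config"))
  if (inherits(x, "substrate")) {
    ints <- structure_route_intermediates(x, backend, config, max_conformers, seed)
    id <- x$id
  } else if (is.character(x) && length(x) == 1) {
    if (is.null(backend$table)) {
      abort("substrate-id input requires a tabulated backend",
            class = "pdregio_input_error")
    }
    ints <- table_route_intermediates(x, backend, config)
    id <- x
  } else {
    abort("x must be a substrate object or a substrate id string",
          class = "pdregio_input_error")
  }

  ints <- geometry_filter(ints, config$pd_c_max)

  site_tables <- list()
  mins <- list(PA = NA_real_, SEAR = NA_real_)
  for (m in c("PA", "SEAR")) {
    res <- relative_site_energies(ints[ints$mechanism == m, , drop = FALSE],
                                  hartree_to_kcal = config$hartree_to_kcal)
    if (!is.null(res)) {
      res$fraction <- unname(boltzmann_fractions(
        setNames(res$rel_gibbs_kcal, res$h_label),
        temperature = config$temperature, gas_constant = config$gas_constant))
      res$predicted <- res$fraction >= config$report_fraction_min
      res$mechanism <- m
      site_tables[[m]] <- res
      mins[[m]] <- min(res$gibbs_hartree)
    }
  }
  sp <- stability_parameter(mins$PA, mins$SEAR,
                            hartree_to_kcal = config$hartree_to_kcal)
  call <- classify_mechanism(sp, config)
  sites <- bind_rows(site_tables)
  predicted_sites <- sites |>
    group_by(.data$mechanism) |>
    filter(abs(.data$rel_gibbs_kcal) < 1e-9) |>
    slice_min(.data$h_label, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("mechanism", "h_label")

  structure(list(
    substrate_id = id,
    sites = sites[, c("mechanism", "h_label", "gibbs_hartree",
                      "rel_gibbs_kcal", "fraction", "predicted")],
    intermediates = ints,
    stability = sp,
    call = call$call,
    basis = call$basis,
    predicted_sites = predicted_sites,
    provenance = list(backend = backend$name,
                      deterministic = backend$deterministic,
                      seed = as.integer(seed),
                      backend_seed = backend$seed %||% NA_integer_,
                      config = unclass(config))
  ), class = "ch_report")
}

structure_route_intermediates <- function(s, backend, config, max_conformers,
                                          seed) {
  sites <- enumerate_ch_sites(s)
  confs <- generate_conformers(s, max_n = max_conformers, seed = seed)
  ints <- build_all_intermediates(s, confs, sites)

  # quick-opt energies for the pre-screen
  qtask <- qc_task("QUICK_OPT", max_iter = config$quickopt_max_iter)
  for (r in seq_len(nrow(ints))) {
    if (ints$status[r] == "DISCARDED") next
    key <- list(substrate_id = ints$substrate_id[r],
                mechanism = ints$mechanism[r], h_label = ints$h_label[r],
                geometry = ints$geometry[[r]])
    res <- backend$evaluate(key, qtask)
    if (res$converged) ints$electronic_energy[r] <- res$electronic_energy
    else { ints$status[r] <- "DISCARDED"; ints$discard_reason[r] <- "quick-opt failure" }
  }
  ints <- prescreen(ints, config$prescreen_cutoff, config$hartree_to_kcal)

  # full optimization + frequency job under the remediation state machine
  ftask <- qc_task("FULL_OPT_FREQ")
  for (r in seq_len(nrow(ints))) {
    if (ints$status[r] == "DISCARDED") next
    key <- list(substrate_id = ints$substrate_id[r],
                mechanism = ints$mechanism[r], h_label = ints$h_label[r])
    job <- run_job(ints$geometry[[r]],
                   evaluate = function(geo, attempt) {
                     backend$evaluate(c(key, list(geometry = geo)), ftask)
                   },
                   pd_c_max = config$pd_c_max)
    if (job$final == "ACCEPT") {
      res <- job$result
      ints$status[r] <- "OPTIMIZED"
      ints$electronic_energy[r] <- res$electronic_energy
      gc <- if (is.na(res$gibbs_correction)) 0 else res$gibbs_correction
      ints$gibbs_energy[r] <- res$electronic_energy + gc
      ints$geometry[[r]] <- res$final_geometry
      ints$pd_c_distance[r] <- min_pd_c_distance(res$final_geometry)
    } else {
      ints$status[r] <- "DISCARDED"
      ints$discard_reason[r] <- job$reason %||% "optimization failed"
    }
  }
  ints
}

table_route_intermediates <- function(id, backend, config) {
  tab <- backend$table
  keys <- tab[tab$substrate_id == id, c("mechanism", "h_label")]
  if (!nrow(keys)) {
    abort(sprintf("substrate id '%s' not present in the energy table", id),
          class = "pdregio_lookup_error")
  }
  ftask <- qc_task("FULL_OPT_FREQ")
  rows <- pmap(keys, function(mechanism, h_label) {
    res <- backend$evaluate(list(substrate_id = id, mechanism = mechanism,
                                 h_label = h_label), ftask)
    gc <- if (is.na(res$gibbs_correction)) 0 else res$gibbs_correction
    tibble(
      substrate_id = id, mechanism = mechanism, h_label = h_label,
      atom_index = NA_integer_, conformer_index = 1L,
      status = "OPTIMIZED", discard_reason = NA_character_,
      electronic_energy = res$electronic_energy,
      gibbs_energy = res$electronic_energy + gc,
      pd_c_distance = min_pd_c_distance(res$final_geometry),
      geometry = list(res$final_geometry)
    )
  })
  bind_rows(rows)
}
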