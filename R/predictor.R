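# The decision layer: energy pre-screen, Pd-C geometry filter, per-site
# relative Gibbs energies, the ipso-complex stability parameter with its
# thresholded mechanism call, and Boltzmann product fractions.

#' Predictor configuration
#'
#' Collects every tunable of the screening/classification pipeline:
#'
#' * `prescreen_cutoff` (kcal/mol, default 10): quick-opt intermediates more
#'   than this above their (substrate x mechanism) group minimum are dropped.
#' * `quickopt_max_iter` (default 5): iteration cap of the pre-screening
#'   optimization.
#' * `pd_c_max` (Angstrom, default 2.4): maximum Pd-C bond length for an
#'   intermediate to count as stable (inclusive).
#' * `threshold_pa` / `threshold_sear` (kcal/mol, defaults 0 and 5): the
#'   stability-parameter thresholds partitioning PA / ambiguous / SEAr;
#'   boundaries are read as a closed ambiguous interval.
#' * `temperature` (K, default 298.15) and `gas_constant`
#'   (kcal mol^-1 K^-1) for Boltzmann weighting.
#' * `hartree_to_kcal`: energy unit conversion.
#' * `report_fraction_min` (default 0.05): a site is flagged as a predicted
#'   product when its Boltzmann fraction reaches this value.
#'
#' @param prescreen_cutoff,quickopt_max_iter,pd_c_max,threshold_pa,threshold_sear,temperature,gas_constant,hartree_to_kcal,report_fraction_min
#'   See description.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(prescreen_cutoff = 10.0, quickopt_max_iter = 5L,
                             pd_c_max = 2.4, threshold_pa = 0.0,
                             threshold_sear = 5.0, temperature = 298.15,
                             gas_constant = GAS_CONSTANT_KCAL,
                             hartree_to_kcal = HARTREE_TO_KCAL,
                             report_fraction_min = 0.05) {
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("temperature must be > 0", class = "pdregio_config_error")
  }
  if (threshold_pa >= threshold_sear) {
    abort("threshold_pa must be < threshold_sear",
          class = "pdregio_config_error")
  }
  if (prescreen_cutoff <= 0) {
    abort("prescreen_cutoff must be > 0", class = "pdregio_config_error")
  }
  structure(list(
    prescreen_cutoff = prescreen_cutoff,
    quickopt_max_iter = as.integer(quickopt_max_iter),
    pd_c_max = pd_c_max,
    threshold_pa = threshold_pa,
    threshold_sear = threshold_sear,
    temperature = temperature,
    gas_constant = gas_constant,
    hartree_to_kcal = hartree_to_kcal,
    report_fraction_min = report_fraction_min
  ), class = "predictor_config")
}

#' Energy pre-screen of quick-optimized intermediates
#'
#' Keeps intermediates whose quick-opt energy lies within `cutoff` of the
#' minimum of their (substrate x mechanism) group; the rest are marked
#' `DISCARDED` with reason `"prescreen"`. The cutoff is group-relative and
#' the boundary is inclusive.
#'
#' @param intermediates Intermediate tibble with an `electronic_energy`
#'   column (Hartree).
#' @param cutoff Cut-off in kcal/mol (> 0).
#' @param hartree_to_kcal Unit conversion factor.
#' @return The tibble with updated `status`/`discard_reason`.
#' @export
prescreen <- function(intermediates, cutoff = 10.0,
                      hartree_to_kcal = HARTREE_TO_KCAL) {
  stopifnot(cutoff > 0)
  if (!nrow(intermediates)) return(intermediates)
  if (any(is.na(intermediates$electronic_energy) &
            intermediates$status != "DISCARDED")) {
    abort("prescreen requires quick-opt energies on all live intermediates",
          class = "pdregio_contract_error")
  }
  intermediates |>
    group_by(.data$substrate_id, .data$mechanism) |>
    mutate(
      rel = (.data$electronic_energy -
               min(.data$electronic_energy[.data$status != "DISCARDED"],
                   na.rm = TRUE)) * hartree_to_kcal,
      # 1e-9 guard keeps the boundary inclusive under Hartree<->kcal round-off
      drop = .data$status != "DISCARDED" & .data$rel - cutoff > 1e-9,
      status = ifelse(.data$drop, "DISCARDED",
                      ifelse(.data$status == "DISCARDED", "DISCARDED",
                             "PRESCREENED")),
      discard_reason = ifelse(.data$drop, "prescreen", .data$discard_reason)
    ) |>
    ungroup() |>
    select(-"rel", -"drop")
}

#' Pd-C geometry filter
#'
#' Keeps optimized intermediates whose Pd-C distance does not exceed
#' `pd_c_max` (inclusive); others are discarded with reason
#' `"no stable Pd-C bond"`.
#'
#' @param intermediates Intermediate tibble with `pd_c_distance` set on all
#'   live rows.
#' @param pd_c_max Maximum Pd-C bond length in Angstroms.
#' @return The tibble with updated `status`/`discard_reason`.
#' @export
geometry_filter <- function(intermediates, pd_c_max = 2.4) {
  if (!nrow(intermediates)) return(intermediates)
  live <- intermediates$status != "DISCARDED"
  if (any(is.na(intermediates$pd_c_distance[live]))) {
    abort("geometry_filter requires pd_c_distance on all live intermediates",
          class = "pdregio_contract_error")
  }
  drop <- live & intermediates$pd_c_distance > pd_c_max
  intermediates$status[drop] <- "DISCARDED"
  intermediates$discard_reason[drop] <- "no stable Pd-C bond"
  intermediates
}

#' Per-site relative Gibbs energies of one mechanism
#'
#' The energy of a site is the minimum Gibbs energy over that site's surviving
#' conformers (ties broken by lowest conformer index); relative energies are
#' referenced to the best site, so the minimum is exactly 0. Absolute shifts
#' of the input energies leave the result unchanged.
#'
#' @param intermediates Intermediate tibble rows of ONE substrate and ONE
#'   mechanism (discarded rows are ignored).
#' @param hartree_to_kcal Unit conversion factor.
#' @return A tibble `h_label`, `gibbs_hartree` (site minimum),
#'   `rel_gibbs_kcal`; or `NULL` when no intermediate survived (the caller
#'   records the mechanism as absent).
#' @export
relative_site_energies <- function(intermediates,
                                   hartree_to_kcal = HARTREE_TO_KCAL) {
  live <- intermediates[intermediates$status != "DISCARDED", , drop = FALSE]
  if (!nrow(live)) return(NULL)
  if (any(is.na(live$gibbs_energy))) {
    abort("relative_site_energies requires gibbs_energy on survivors",
          class = "pdregio_contract_error")
  }
  per_site <- live |>
    group_by(.data$h_label) |>
    arrange(.data$gibbs_energy, .data$conformer_index, .by_group = TRUE) |>
    summarise(gibbs_hartree = .data$gibbs_energy[1], .groups = "drop")
  per_site |>
    mutate(rel_gibbs_kcal =
             (.data$gibbs_hartree - min(.data$gibbs_hartree)) * hartree_to_kcal) |>
    arrange(.data$rel_gibbs_kcal, .data$h_label)
}

#' Ipso-complex stability parameter
#'
#' The energy difference between the most stable intermediates of the two
#' mechanisms, oriented as `delta = (G_min(PA) - G_min(SEAR)) * 627.5095`
#' kcal/mol: the more stable the SEAr ipso complex relative to the PA
#' intermediate, the larger `delta`.
#'
#' @param pa_min_G,sear_min_G Minimum Gibbs energies (Hartree) of the
#'   surviving intermediates of each mechanism; `NA`/`NULL` when the mechanism
#'   has no stable intermediate.
#' @param hartree_to_kcal Unit conversion factor.
#' @return A `stability_parameter` list: `delta` (kcal/mol or `NA`),
#'   `pa_min_G`, `sear_min_G`.
#' @export
stability_parameter <- function(pa_min_G, sear_min_G,
                                hartree_to_kcal = HARTREE_TO_KCAL) {
  pa <- if (is.null(pa_min_G)) NA_real_ else pa_min_G
  se <- if (is.null(sear_min_G)) NA_real_ else sear_min_G
  if (is.na(pa) && is.na(se)) {
    abort("no stable intermediates for either mechanism",
          class = "pdregio_domain_error")
  }
  delta <- if (!is.na(pa) && !is.na(se)) (pa - se) * hartree_to_kcal else NA_real_
  structure(list(delta = delta, pa_min_G = pa, sear_min_G = se),
            class = "stability_parameter")
}

#' Classify the operative mechanism from the stability parameter
#'
#' Threshold rules: `delta` below `threshold_pa` (0) calls proton abstraction;
#' above `threshold_sear` (5) calls electrophilic aromatic substitution;
#' within the closed interval both mechanisms are plausible (`AMBIGUOUS`). A
#' mechanism with no stable intermediate forfeits and the other is called
#' outright (`basis` `"SEAR_ABSENT"` / `"PA_ABSENT"`).
#'
#' @param sp A [stability_parameter()].
#' @param config A [predictor_config()].
#' @return A `mechanism_call` list: `call` (`"PA"`, `"SEAR"`, `"AMBIGUOUS"`)
#'   and `basis` (`"THRESHOLD"`, `"SEAR_ABSENT"`, `"PA_ABSENT"`).
#' @export
classify_mechanism <- function(sp, config = predictor_config()) {
  stopifnot(inherits(sp, "stability_parameter"))
  if (is.na(sp$sear_min_G)) {
    out <- list(call = "PA", basis = "SEAR_ABSENT")
  } else if (is.na(sp$pa_min_G)) {
    out <- list(call = "SEAR", basis = "PA_ABSENT")
  } else if (sp$delta < config$threshold_pa) {
    out <- list(call = "PA", basis = "THRESHOLD")
  } else if (sp$delta > config$threshold_sear) {
    out <- list(call = "SEAR", basis = "THRESHOLD")
  } else {
    out <- list(call = "AMBIGUOUS", basis = "THRESHOLD")
  }
  structure(out, class = "mechanism_call")
}

#' Boltzmann fractions from relative Gibbs energies
#'
#' `fraction_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)`, evaluated with the
#' max-shift trick so arbitrarily large energy gaps cannot overflow. Fractions
#' are invariant under a uniform shift of the energies and sum to 1.
#'
#' @param ddG Named numeric vector of relative Gibbs energies (kcal/mol), or a
#'   tibble with `h_label` and `rel_gibbs_kcal` columns.
#' @param temperature Temperature in Kelvin (> 0).
#' @param gas_constant Gas constant in kcal mol^-1 K^-1.
#' @return Named numeric vector of fractions summing to 1.
#' @export
#' @examples
#' boltzmann_fractions(c(H1 = 0, H2 = 0.5))  # 0.699 / 0.301 at 298.15 K
boltzmann_fractions <- function(ddG, temperature = 298.15,
                                gas_constant = GAS_CONSTANT_KCAL) {
  if (is.data.frame(ddG)) {
    ddG <- setNames(ddG$rel_gibbs_kcal, ddG$h_label)
  }
  if (!length(ddG)) abort("empty energy map", class = "pdregio_domain_error")
  if (any(!is.finite(ddG))) abort("non-finite energies")
  if (temperature <= 0) abort("temperature must be > 0")
  x <- -ddG / (gas_constant * temperature)
  x <- x - max(x)
  w <- exp(x)
  w / sum(w)
}
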