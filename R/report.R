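# The ch_report result object: printing, broom-style accessors, plotting and
# serialisation.

#' @export
print.ch_report <- function(x, ...) {
  cat(sprintf("<ch_report> substrate %s\n", x$substrate_id))
  d <- x$stability$delta
  cat(sprintf("  mechanism call: %s (%s)%s\n", x$call, x$basis,
              if (!is.na(d)) sprintf(", stability parameter %.4f kcal/mol", d)
              else ""))
  for (m in unique(x$sites$mechanism)) {
    st <- x$sites[x$sites$mechanism == m, ]
    cat(sprintf("  %s sites: %s\n", m,
                paste(sprintf("%s:%.1f (%.0f%%)", st$h_label,
                              st$rel_gibbs_kcal, 100 * st$fraction),
                      collapse = "  ")))
  }
  absent <- setdiff(c("PA", "SEAR"), unique(x$sites$mechanism))
  for (m in absent) cat(sprintf("  %s: no stable intermediate\n", m))
  invisible(x)
}

#' Tidy a mechanism report
#'
#' One row per (mechanism, site): relative Gibbs energy, Boltzmann fraction
#' and the predicted-product flag, mirroring the layout of published
#' site-energy tables.
#'
#' @param x A `ch_report`.
#' @param ... Unused.
#' @return A tibble with columns `substrate_id`, `mechanism`, `h_label`,
#'   `rel_gibbs_kcal`, `fraction`, `predicted`.
#' @export
tidy.ch_report <- function(x, ...) {
  out <- x$sites
  out$substrate_id <- x$substrate_id
  out[, c("substrate_id", "mechanism", "h_label", "rel_gibbs_kcal",
          "fraction", "predicted")]
}

#' One-row summary of a mechanism report
#'
#' @param x A `ch_report`.
#' @param ... Unused.
#' @return A one-row tibble: `substrate_id`, `delta_kcal`, `call`, `basis`,
#'   `n_sites_pa`, `n_sites_sear`, `top_site_pa`, `top_site_sear`.
#' @method glance ch_report
#' @export
glance.ch_report <- function(x, ...) {
  top <- function(m) {
    v <- x$predicted_sites$h_label[x$predicted_sites$mechanism == m]
    if (length(v)) v[[1]] else NA_character_
  }
  tibble(
    substrate_id = x$substrate_id,
    delta_kcal = x$stability$delta,
    call = x$call,
    basis = x$basis,
    n_sites_pa = sum(x$sites$mechanism == "PA"),
    n_sites_sear = sum(x$sites$mechanism == "SEAR"),
    top_site_pa = top("PA"),
    top_site_sear = top("SEAR")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the site-energy profile of a report
#'
#' Bar chart of relative Gibbs energies per site, faceted by mechanism, with
#' Boltzmann fractions annotated; predicted product sites are highlighted.
#'
#' @param object A `ch_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ch_report
#' @export
autoplot.ch_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h_label, y = .data$rel_gibbs_kcal,
                                  fill = .data$predicted)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$fraction)),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~mechanism, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(
      title = sprintf("Substrate %s - call: %s", object$substrate_id, object$call),
      x = "aromatic C-H site",
      y = expression(Delta * Delta * G ~ "(kcal/mol)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialise a report to JSON and CSV
#'
#' Writes `report.json` (full machine-readable report including provenance)
#' and `report.csv` (the tidy site table). Reports contain no timestamps so
#' deterministic backends regenerate them byte-identically.
#'
#' @param report A `ch_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, sprintf("report_%s.json", report$substrate_id))
  csv_path <- file.path(dir, sprintf("report_%s.csv", report$substrate_id))
  payload <- list(
    substrate_id = report$substrate_id,
    call = report$call,
    basis = report$basis,
    stability = list(delta_kcal = report$stability$delta,
                     pa_min_hartree = report$stability$pa_min_G,
                     sear_min_hartree = report$stability$sear_min_G),
    sites = tidy(report),
    predicted_sites = report$predicted_sites,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write.csv(tidy(report), csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
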