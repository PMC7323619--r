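# NWChem-dialect input-deck generation.

#' Describe a quantum-chemistry task
#'
#' Two task kinds drive the pipeline: a capped 5-iteration `QUICK_OPT` used to
#' pre-screen raw intermediates, and a `FULL_OPT_FREQ` geometry optimization
#' followed by a frequency/thermochemistry analysis. Electronic structure
#' defaults to B3LYP/6-31g(d,p); 6-31g(d,p) does not define palladium, so any
#' geometry containing Pd requires an explicit `basis_metal` (no silent
#' default).
#'
#' @param kind `"QUICK_OPT"` or `"FULL_OPT_FREQ"`.
#' @param functional Exchange-correlation functional keyword.
#' @param basis_main Basis set for main-group elements.
#' @param basis_metal Basis/ECP keyword applied to Pd; `NULL` means unset.
#' @param max_iter Optimizer iteration cap; defaults to 5 for `QUICK_OPT` and
#'   to the engine default (`NULL`) for `FULL_OPT_FREQ`.
#' @param charge,multiplicity Total charge and spin multiplicity.
#' @return A `qc_task` list.
#' @export
qc_task <- function(kind = c("QUICK_OPT", "FULL_OPT_FREQ"),
                    functional = "b3lyp", basis_main = "6-31g(d,p)",
                    basis_metal = NULL,
                    max_iter = if (kind == "QUICK_OPT") 5L else NULL,
                    charge = 0L, multiplicity = 1L) {
  kind <- match.arg(kind)
  if (multiplicity < 1) abort("multiplicity must be >= 1")
  structure(list(kind = kind, functional = functional, basis_main = basis_main,
                 basis_metal = basis_metal, max_iter = max_iter,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "qc_task")
}

#' Write an NWChem-dialect input deck
#'
#' Emits a complete input deck: geometry block in Angstroms, basis assignment
#' (with `basis_metal` applied to Pd), DFT block, iteration cap for quick
#' optimizations, and the task directive(s) (`optimize`, plus `freq` for
#' `FULL_OPT_FREQ`).
#'
#' @param geometry Tibble/data frame with `element`, `x`, `y`, `z` (Angstroms).
#' @param task A [qc_task()].
#' @param title Job title string.
#' @return The deck as a single string.
#' @export
write_deck <- function(geometry, task, title = "pdregio job") {
  stopifnot(inherits(task, "qc_task"))
  if (is.null(geometry) || nrow(geometry) == 0) {
    abort("geometry is empty", class = "pdregio_precondition_error")
  }
  elements <- unique(geometry$element)
  if ("Pd" %in% elements && is.null(task$basis_metal)) {
    abort(paste("No basis set assigned to Pd: 6-31g(d,p) does not define",
                "palladium; set basis_metal (e.g. an ECP basis) explicitly."),
          class = "pdregio_config_error")
  }
  geo <- sprintf("  %-2s %14.8f %14.8f %14.8f",
                 geometry$element, geometry$x, geometry$y, geometry$z)
  basis <- c("basis",
             if ("Pd" %in% elements)
               c(sprintf("  * library %s except Pd", task$basis_main),
                 sprintf("  Pd library %s", task$basis_metal))
             else sprintf("  * library %s", task$basis_main),
             "end")
  driver <- if (!is.null(task$max_iter)) {
    c("driver", sprintf("  maxiter %d", task$max_iter), "end")
  }
  tasks <- c("task dft optimize",
             if (task$kind == "FULL_OPT_FREQ") "task dft freq")
  paste(c(
    "start pdregio",
    sprintf("title \"%s\"", title),
    sprintf("charge %d", task$charge),
    "geometry units angstroms noautosym",
    geo,
    "end",
    basis,
    "dft",
    sprintf("  xc %s", task$functional),
    sprintf("  mult %d", task$multiplicity),
    "end",
    driver,
    tasks
  ), collapse = "\n")
}
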