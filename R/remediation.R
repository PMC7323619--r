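# Failure classification and the automated remediation state machine for
# geometry optimizations. Four recoverable/terminal failure modes are
# recognised, mirroring standard practice for unattended DFT screening:
#   (i)   optimization converged onto a saddle point -> displace the geometry
#         along the imaginary coordinate and resubmit;
#   (ii)  optimizer abort after a large geometry change (stale Hessian) ->
#         resubmit from the last coordinates;
#   (iii) SCF initial-guess failure (hopeless starting geometry) -> discard;
#   (iv)  decomposed intermediate (no Pd-C bond within the distance cutoff)
#         -> discard.

ERROR_CLASSES <- c("NONE", "SADDLE_POINT", "HESSIAN_STALE", "BAD_GUESS",
                   "DECOMPOSED", "HARD_FAIL")

#' Classify the outcome of a geometry optimization
#'
#' Maps a parsed engine result onto one failure class. Imaginary modes with
#' magnitude below `imag_tol` are treated as numerical noise rather than
#' saddle-point evidence. A pure function: the same result always yields the
#' same class.
#'
#' @param r A `qc_result`.
#' @param geometry_check `TRUE` when the final geometry retains a Pd-C bond
#'   within the distance cutoff (see [geometry_filter()]); `FALSE` signals a
#'   decomposed intermediate.
#' @param imag_tol Imaginary-mode magnitude (cm^-1) below which a negative
#'   frequency is ignored as noise.
#' @return One of `"NONE"`, `"SADDLE_POINT"`, `"HESSIAN_STALE"`,
#'   `"BAD_GUESS"`, `"DECOMPOSED"`, `"HARD_FAIL"`.
#' @export
classify_failure <- function(r, geometry_check = TRUE, imag_tol = 10) {
  stopifnot(inherits(r, "qc_result"))
  imag <- r$frequencies[r$frequencies < 0]
  if (r$converged && length(imag) && any(abs(imag) > imag_tol)) {
    return("SADDLE_POINT")
  }
  if (r$converged && !isTRUE(geometry_check)) return("DECOMPOSED")
  if (r$converged) return("NONE")
  if (grepl("initial guess", r$failure_text, ignore.case = TRUE)) {
    return("BAD_GUESS")
  }
  if (grepl("hessian", r$failure_text, ignore.case = TRUE)) {
    return("HESSIAN_STALE")
  }
  "HARD_FAIL"
}

#' Displace a geometry along a normal mode
#'
#' `new = old + amplitude * mode / ||mode||`; negating the amplitude inverts
#' the displacement exactly.
#'
#' @param geometry Geometry tibble (`element`, `x`, `y`, `z`).
#' @param mode Displacement matrix, one row (x, y, z) per atom.
#' @param amplitude Displacement amplitude in Angstroms.
#' @return The displaced geometry tibble.
#' @export
displace_along_mode <- function(geometry, mode, amplitude = 0.3) {
  mode <- as.matrix(mode)
  if (nrow(mode) != nrow(geometry) || ncol(mode) != 3) {
    abort("mode must supply one displacement vector per atom")
  }
  nrm <- sqrt(sum(mode^2))
  if (nrm < 1e-12) abort("zero-norm mode", class = "pdregio_numeric_error")
  out <- geometry
  out[c("x", "y", "z")] <- geometry[c("x", "y", "z")] + amplitude * mode / nrm
  out
}

#' Decide the remediation action for one attempt
#'
#' Pure mapping from failure class to action, with a retry budget: saddle
#' points are resubmitted from a geometry displaced along the
#' largest-magnitude imaginary mode, stale-Hessian aborts are resubmitted from
#' the last coordinates, initial-guess failures and decomposed intermediates
#' are discarded, and clean convergence is accepted. When `attempt` has
#' reached `max_retries`, any would-be resubmission becomes a discard with
#' reason `"max retries"`. Unrecognised hard failures are discarded: an
#' unknown failure is not safely retryable.
#'
#' @param attempt 1-based attempt counter.
#' @param r The `qc_result` of this attempt.
#' @param geometry_check As in [classify_failure()].
#' @param max_retries Maximum attempts per intermediate.
#' @param amplitude Displacement amplitude (Angstroms) for saddle-point
#'   remediation.
#' @param imag_tol Passed to [classify_failure()].
#' @return A list with `error_class`, `action` (`"ACCEPT"`,
#'   `"RESUBMIT_DISPLACED"`, `"RESUBMIT_LAST_GEOM"`, `"DISCARD"`),
#'   `next_geometry` (tibble or `NULL`) and `reason`.
#' @export
remediate <- function(attempt, r, geometry_check = TRUE, max_retries = 3,
                      amplitude = 0.3, imag_tol = 10) {
  cls <- classify_failure(r, geometry_check, imag_tol)
  act <- switch(cls,
    NONE = "ACCEPT",
    SADDLE_POINT = "RESUBMIT_DISPLACED",
    HESSIAN_STALE = "RESUBMIT_LAST_GEOM",
    BAD_GUESS = "DISCARD",
    DECOMPOSED = "DISCARD",
    HARD_FAIL = "DISCARD"
  )
  reason <- switch(cls,
    BAD_GUESS = "initial guess failure",
    DECOMPOSED = "no stable Pd-C bond",
    HARD_FAIL = "unrecoverable failure",
    NA_character_
  )
  if (act %in% c("RESUBMIT_DISPLACED", "RESUBMIT_LAST_GEOM") &&
      attempt >= max_retries) {
    return(list(error_class = cls, action = "DISCARD", next_geometry = NULL,
                reason = "max retries"))
  }
  next_geometry <- NULL
  if (act == "RESUBMIT_DISPLACED") {
    imag <- which(r$frequencies < 0)
    k <- imag[which.max(abs(r$frequencies[imag]))]
    mode <- if (length(r$normal_modes) >= k) r$normal_modes[[k]] else NULL
    if (is.null(mode) || is.null(r$final_geometry)) {
      return(list(error_class = cls, action = "DISCARD", next_geometry = NULL,
                  reason = "saddle point without usable mode"))
    }
    next_geometry <- displace_along_mode(r$final_geometry, mode, amplitude)
  }
  if (act == "RESUBMIT_LAST_GEOM") {
    if (is.null(r$final_geometry)) {
      return(list(error_class = cls, action = "DISCARD", next_geometry = NULL,
                  reason = "no coordinates to restart from"))
    }
    next_geometry <- r$final_geometry
  }
  list(error_class = cls, action = act, next_geometry = next_geometry,
       reason = reason)
}

#' Drive one job through the remediation state machine
#'
#' Repeatedly evaluates a geometry with `evaluate`, classifies the outcome and
#' applies [remediate()] until the job ends in `ACCEPT` or `DISCARD` or the
#' retry budget is exhausted. Guaranteed to terminate within `max_retries`
#' attempts.
#'
#' @param geometry Starting geometry tibble.
#' @param evaluate `function(geometry, attempt) -> qc_result`.
#' @param pd_c_max Pd-C distance cutoff (Angstroms) for the decomposition
#'   check; geometries without Pd are exempt from the check.
#' @param max_retries,amplitude,imag_tol See [remediate()].
#' @return A list with `final` (`"ACCEPT"` or `"DISCARD"`), `result` (last
#'   `qc_result`), `reason`, and `ledger`: a tibble of per-attempt records
#'   (`attempt`, `error_class`, `action`).
#' @export
run_job <- function(geometry, evaluate, pd_c_max = 2.4, max_retries = 3,
                    amplitude = 0.3, imag_tol = 10) {
  ledger <- list()
  geo <- geometry
  for (attempt in seq_len(max_retries)) {
    r <- evaluate(geo, attempt)
    gcheck <- TRUE
    g <- r$final_geometry
    if (!is.null(g) && "Pd" %in% g$element) {
      gcheck <- min_pd_c_distance(g) <= pd_c_max
    }
    dec <- remediate(attempt, r, geometry_check = gcheck,
                     max_retries = max_retries, amplitude = amplitude,
                     imag_tol = imag_tol)
    ledger[[attempt]] <- tibble(attempt = attempt,
                                error_class = dec$error_class,
                                action = dec$action)
    if (dec$action %in% c("ACCEPT", "DISCARD")) {
      return(list(final = dec$action, result = r, reason = dec$reason,
                  ledger = bind_rows(ledger)))
    }
    geo <- dec$next_geometry
  }
  list(final = "DISCARD", result = r, reason = "max retries",
       ledger = bind_rows(ledger))
}
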