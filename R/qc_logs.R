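# NWChem-dialect output-log parsing. Total by contract: malformed or truncated
# logs never raise; they come back as terminated_normally = FALSE with the
# offending text preserved in failure_text.

#' Parse an NWChem-dialect output log
#'
#' Extracts termination status, convergence, the last printed geometry, the
#' final electronic energy, the thermal Gibbs correction and the frequency
#' block (negative values encode imaginary modes) together with per-mode
#' Cartesian displacement vectors. Never raises on malformed input.
#'
#' @param log_text The log as a single string or character vector of lines.
#' @return A `qc_result` list: `terminated_normally`, `converged`,
#'   `final_geometry` (tibble or `NULL`), `electronic_energy` (Hartree),
#'   `gibbs_correction` (Hartree, `NA` unless a frequency job),
#'   `frequencies` (cm^-1), `normal_modes` (list of n_atoms x 3 matrices),
#'   `failure_text`.
#' @export
parse_result <- function(log_text) {
  lines <- if (length(log_text) == 1) strsplit(log_text, "\n")[[1]] else log_text
  if (!length(lines) || !any(nzchar(lines))) {
    return(qc_result(terminated_normally = FALSE, failure_text = "empty log"))
  }
  terminated <- any(grepl("^ *Total times", lines))
  converged <- any(grepl("Optimization converged", lines, fixed = TRUE))

  energy <- NA_real_
  e_lines <- grep("Total DFT energy", lines, value = TRUE)
  if (length(e_lines)) {
    energy <- suppressWarnings(
      as.numeric(sub(".*=\\s*([-0-9.eEdD+]+).*", "\\1", tail(e_lines, 1))))
  }

  gibbs <- NA_real_
  g_lines <- grep("Thermal correction to Gibbs", lines, value = TRUE)
  if (length(g_lines)) {
    m <- regmatches(tail(g_lines, 1),
                    regexpr("[-0-9.eE+]+\\s*au", tail(g_lines, 1)))
    if (length(m)) gibbs <- suppressWarnings(as.numeric(sub("\\s*au", "", m)))
  }

  geometry <- NULL
  g_idx <- grep("Output coordinates in angstroms", lines)
  if (length(g_idx)) {
    i <- tail(g_idx, 1) + 4L  # header, blank, column names, ruler
    rows <- list()
    ok <- TRUE
    while (i <= length(lines)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 6) break
      xyz <- suppressWarnings(as.numeric(f[4:6]))
      if (any(is.na(xyz))) { ok <- length(rows) > 0; break }
      rows[[length(rows) + 1]] <- tibble(element = f[2],
                                         x = xyz[1], y = xyz[2], z = xyz[3])
      i <- i + 1L
    }
    if (length(rows) && ok) geometry <- bind_rows(rows)
  }

  freqs <- numeric(0); modes <- list()
  f_idx <- grep("^ P\\.Frequency", lines)
  for (fi in f_idx) {
    fv <- suppressWarnings(as.numeric(strsplit(trimws(lines[fi]), "\\s+")[[1]][-1]))
    fv <- fv[!is.na(fv)]
    if (!length(fv)) next
    block <- list()
    i <- fi + 2L  # blank line then displacement rows
    while (i <= length(lines)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != length(fv) + 1 || any(is.na(v))) break
      block[[length(block) + 1]] <- v[-1]
      i <- i + 1L
    }
    if (length(block) %% 3 == 0 && length(block) > 0) {
      disp <- do.call(rbind, block)   # 3N rows x n_modes
      for (k in seq_along(fv)) {
        modes[[length(modes) + 1]] <- matrix(disp[, k], ncol = 3, byrow = TRUE)
      }
    } else {
      modes <- c(modes, rep(list(NULL), length(fv)))
    }
    freqs <- c(freqs, fv)
  }

  failure <- ""
  if (!terminated || !converged) {
    bad <- grep("error|Error|ERROR|fail|Fail|FAIL", lines, value = TRUE)
    failure <- paste(utils::head(bad, 5), collapse = "\n")
    if (!nzchar(failure) && !terminated) failure <- "log truncated"
  }

  qc_result(
    terminated_normally = terminated,
    converged = converged && terminated,
    final_geometry = geometry,
    electronic_energy = energy,
    gibbs_correction = gibbs,
    frequencies = freqs,
    normal_modes = modes,
    failure_text = failure
  )
}

#' Construct a QC result object
#'
#' Mostly used internally (by [parse_result()] and the desk-scale backends);
#' exposed so scripted backends in tests and user code can fabricate results.
#'
#' @param terminated_normally,converged Logical status flags.
#' @param final_geometry Geometry tibble or `NULL`.
#' @param electronic_energy,gibbs_correction Energies in Hartree.
#' @param frequencies Numeric vector in cm^-1 (negative = imaginary).
#' @param normal_modes List of per-mode displacement matrices (n_atoms x 3).
#' @param failure_text Diagnostic text for failed jobs.
#' @return A `qc_result` list.
#' @export
qc_result <- function(terminated_normally = FALSE, converged = FALSE,
                      final_geometry = NULL, electronic_energy = NA_real_,
                      gibbs_correction = NA_real_, frequencies = numeric(0),
                      normal_modes = list(), failure_text = "") {
  if (isTRUE(converged) &&
      (is.null(final_geometry) || is.na(electronic_energy))) {
    abort("a converged qc_result requires final_geometry and electronic_energy")
  }
  structure(list(
    terminated_normally = isTRUE(terminated_normally),
    converged = isTRUE(converged),
    final_geometry = final_geometry,
    electronic_energy = electronic_energy,
    gibbs_correction = gibbs_correction,
    frequencies = frequencies,
    normal_modes = normal_modes,
    failure_text = failure_text
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> terminated=%s converged=%s E=%s nfreq=%d\n",
              x$terminated_normally, x$converged,
              format(x$electronic_energy), length(x$frequencies)))
  invisible(x)
}

# Simulated engine echo: renders a deck's geometry back as a normally
# terminated, converged NWChem-dialect log. Supports the deck->log->parse
# round-trip property and the scripted backends.
simulate_engine_echo <- function(deck, energy = -1.0) {
  lines <- strsplit(deck, "\n")[[1]]
  g0 <- grep("^geometry", lines)
  g1 <- grep("^end$", lines)
  g1 <- min(g1[g1 > g0])
  atoms <- lines[(g0 + 1):(g1 - 1)]
  f <- strsplit(trimws(atoms), "\\s+")
  geo <- tibble(element = map_chr(f, 1),
                x = as.numeric(map_chr(f, 2)),
                y = as.numeric(map_chr(f, 3)),
                z = as.numeric(map_chr(f, 4)))
  render_nwchem_log(geo, energy = energy)
}

# Render an NWChem-dialect log from parts; the fixture-log generator and the
# desk-scale backends all speak through this one writer.
render_nwchem_log <- function(geometry, energy = -1.0, converged = TRUE,
                              frequencies = NULL, modes = NULL,
                              gibbs_correction = NULL, terminated = TRUE,
                              failure_lines = character(0)) {
  out <- c("          Job information", "")
  if (!is.null(geometry)) {
    out <- c(out,
      " Output coordinates in angstroms (scale by  1.889725989 to convert to a.u.)",
      "",
      "  No.       Tag          Charge          X              Y              Z",
      " ---- ---------------- ---------- -------------- -------------- --------------",
      sprintf(" %4d %-16s %10.4f %14.8f %14.8f %14.8f",
              seq_len(nrow(geometry)), geometry$element, 0,
              geometry$x, geometry$y, geometry$z),
      "")
  }
  if (converged) out <- c(out, "      Optimization converged", "")
  if (!is.na(energy) && !is.null(energy)) {
    out <- c(out, sprintf("         Total DFT energy = %20.9f", energy), "")
  }
  if (!is.null(frequencies)) {
    n_atoms <- nrow(geometry)
    if (is.null(modes)) {
      modes <- rep(list(matrix(0, n_atoms, 3)), length(frequencies))
      if (length(modes)) modes[[1]][1, 1] <- 1
    }
    out <- c(out, "", "        NORMAL MODE EIGENVECTORS IN CARTESIAN COORDINATES", "")
    disp <- vapply(modes, function(m) as.numeric(t(m)), numeric(3 * n_atoms))
    disp <- matrix(disp, nrow = 3 * n_atoms)
    out <- c(out,
      paste(" P.Frequency", paste(sprintf("%10.2f", frequencies), collapse = "")),
      "",
      sprintf("  %4d   %s", seq_len(3 * n_atoms),
              apply(disp, 1, function(r) paste(sprintf("%10.5f", r), collapse = ""))),
      "")
  }
  if (!is.null(gibbs_correction)) {
    out <- c(out, sprintf(
      " Thermal correction to Gibbs free energy  = %10.3f kcal/mol  (%10.6f au)",
      gibbs_correction * 627.5095, gibbs_correction), "")
  }
  out <- c(out, failure_lines)
  if (terminated) {
    out <- c(out, "", " Total times  cpu:        1.0s     wall:        1.0s")
  }
  paste(out, collapse = "\n")
}
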