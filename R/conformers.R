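# 3D embedding and conformer generation via OpenBabel: --gen3d builds an
# initial 3D structure, --confab runs a systematic (hence deterministic) rotor
# search, and obenergy ranks the resulting conformers with MMFF94.

obenergy_path <- function() {
  p <- Sys.which("obenergy")
  if (!nzchar(p)) abort("OpenBabel executable 'obenergy' not found on PATH.")
  unname(p)
}

substrate_to_mol <- function(s) {
  # write the substrate back through OpenBabel from its source text so atom
  # ordering matches the parsed connection table (heavy atoms first, then H)
  is_mol <- looks_like_mol(s$source_text)
  args <- if (is_mol) c("-imol", "-omol", "-h") else
    c(paste0("-:", shQuote(s$source_text)), "-omol", "-h")
  res <- run_obabel(args, input = if (is_mol) s$source_text else NULL)
  paste(res$text, collapse = "\n")
}

read_sdf_conformers <- function(lines) {
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (r in recs) {
    if (length(r) < 5) next
    counts <- r[[4]]
    na <- as.integer(substr(counts, 1, 3))
    if (is.na(na) || na < 1) next
    at <- r[5:(4 + na)]
    out[[length(out) + 1]] <- tibble(
      element = trimws(substr(at, 32, 34)),
      x = as.numeric(substr(at, 1, 10)),
      y = as.numeric(substr(at, 11, 20)),
      z = as.numeric(substr(at, 21, 30))
    )
  }
  out
}

#' Generate ranked 3D conformers for a substrate
#'
#' Embeds the substrate in 3D and enumerates low-energy conformers with a
#' systematic rotor search, ranked ascending by MMFF94 energy. The search is
#' systematic, so results are reproducible by construction; `seed` is part of
#' the calling contract and recorded in provenance, but does not alter the
#' search.
#'
#' @param s A `substrate`.
#' @param max_n Maximum number of conformers to keep (>= 1).
#' @param seed Integer seed recorded for provenance.
#' @return A list of conformers, each a tibble (`element`, `x`, `y`, `z` in
#'   Angstroms) with attribute `ff_energy` (kcal/mol); sorted ascending by
#'   `ff_energy`. Atom count and order match the parent substrate.
#' @export
generate_conformers <- function(s, max_n = 5L, seed = 1L) {
  stopifnot(inherits(s, "substrate"))
  if (!is.numeric(max_n) || max_n < 1) {
    abort("max_n must be >= 1", class = "pdregio_precondition_error")
  }
  tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(c(tmp, tmp2)), add = TRUE)
  tmp2 <- tempfile(fileext = ".sdf")
  is_mol <- looks_like_mol(s$source_text)
  args <- if (is_mol) c("-imol", "-O", tmp, "--gen3d", "-h") else
    c(paste0("-:", shQuote(s$source_text)), "-O", tmp, "--gen3d", "-h")
  res <- run_obabel(args, input = if (is_mol) s$source_text else NULL)
  if (!file.exists(tmp) || !file.size(tmp)) {
    abort(sprintf("3D embedding failed for substrate '%s'", s$id),
          class = "pdregio_domain_error")
  }
  res2 <- run_obabel(c(tmp, "-O", tmp2, "--confab", "--conf", "1000000"))
  use <- if (file.exists(tmp2) && file.size(tmp2) > 0) tmp2 else tmp
  geoms <- read_sdf_conformers(readLines(use, warn = FALSE))
  if (!length(geoms)) {
    abort(sprintf("3D embedding failed for substrate '%s'", s$id),
          class = "pdregio_domain_error")
  }
  en <- suppressWarnings(system2(obenergy_path(), c("-ff", "MMFF94", use),
                                 stdout = TRUE, stderr = FALSE))
  ff <- as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1",
                       grep("TOTAL ENERGY", en, value = TRUE)))
  if (length(ff) != length(geoms)) ff <- rep(NA_real_, length(geoms))
  ord <- order(ff)
  geoms <- geoms[ord][seq_len(min(max_n, length(geoms)))]
  ff <- ff[ord][seq_len(length(geoms))]
  nat <- nrow(s$atoms)
  for (k in seq_along(geoms)) {
    if (nrow(geoms[[k]]) != nat) {
      abort(sprintf("Conformer atom count mismatch for substrate '%s'", s$id),
            class = "pdregio_domain_error")
    }
    geoms[[k]][c("x", "y", "z")] <- round(geoms[[k]][c("x", "y", "z")], 4)
    attr(geoms[[k]], "ff_energy") <- ff[[k]]
    attr(geoms[[k]], "seed") <- as.integer(seed)
  }
  geoms
}
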