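# Substrate parsing and aromatic C-H site enumeration.
#
# OpenBabel (obabel) does the chemistry-format heavy lifting: SMILES/MOL input,
# aromaticity perception and explicit hydrogens. Sybyl MOL2 is the interchange
# format because it carries aromatic atom types (C.ar, N.ar) and aromatic bond
# records explicitly, where MOL V2000 output is kekulized.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) abort("OpenBabel executable 'obabel' not found on PATH.")
  unname(p)
}

run_obabel <- function(args, input = NULL) {
  err_file <- tempfile(); on.exit(unlink(err_file))
  out <- suppressWarnings(system2(
    obabel_path(), args,
    input = input, stdout = TRUE, stderr = err_file
  ))
  status <- attr(out, "status") %||% 0L
  err <- if (file.exists(err_file)) readLines(err_file, warn = FALSE) else character()
  list(text = out, status = status, err = err)
}

looks_like_mol <- function(text) {
  grepl("V2000|V3000|\\$\\$\\$\\$", text) || length(strsplit(text, "\n")[[1]]) > 3
}

# Minimal Sybyl MOL2 reader: atom and bond blocks only. No installed R package
# reads MOL2 (ChemmineR is SDF-only), and only these two blocks are needed.
parse_mol2 <- function(lines) {
  sec <- grep("^@<TRIPOS>", lines)
  names(sec) <- sub("^@<TRIPOS>", "", lines[sec])
  grab <- function(name) {
    i <- sec[names(sec) == name][1]
    if (is.na(i)) return(character())
    nxt <- sec[sec > i]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    lines[(i + 1L):end]
  }
  atom_lines <- grab("ATOM")
  bond_lines <- grab("BOND")
  atom_lines <- grep("^\\s*[0-9]+\\s", atom_lines, value = TRUE)
  bond_lines <- grep("^\\s*[0-9]+\\s+[0-9]+\\s+[0-9]+\\s", bond_lines, value = TRUE)
  af <- strsplit(trimws(atom_lines), "\\s+")
  atoms <- tibble(
    idx = seq_along(af),
    element = map_chr(af, function(x) sub("\\..*$", "", x[6])),
    type = map_chr(af, function(x) x[6]),
    x = map_dbl(af, function(x) as.numeric(x[3])),
    y = map_dbl(af, function(x) as.numeric(x[4])),
    z = map_dbl(af, function(x) as.numeric(x[5])),
    charge = map_dbl(af, function(x) if (length(x) >= 9) as.numeric(x[9]) else 0)
  )
  bf <- strsplit(trimws(bond_lines), "\\s+")
  bonds <- tibble(
    a1 = map_dbl(bf, function(x) as.numeric(x[2])),
    a2 = map_dbl(bf, function(x) as.numeric(x[3])),
    type = map_chr(bf, function(x) x[4])
  )
  bonds$aromatic <- bonds$type == "ar"
  bonds$order <- suppressWarnings(as.numeric(bonds$type))
  bonds$order[bonds$type == "ar"] <- 1.5
  bonds$order[bonds$type == "am"] <- 1
  atoms$aromatic <- grepl("\\.ar$", atoms$type)
  # atoms on aromatic bonds count as aromatic even when typed otherwise
  # (e.g., furan oxygen is O.2 in Sybyl typing but sits on two "ar" bonds)
  on_ar <- unique(c(bonds$a1[bonds$aromatic], bonds$a2[bonds$aromatic]))
  atoms$aromatic[atoms$idx %in% on_ar] <- TRUE
  list(atoms = atoms, bonds = bonds)
}

#' Parse a substrate from SMILES or MOL text
#'
#' Reads a SMILES string or a MOL/SDF (V2000) block, perceives aromaticity,
#' adds explicit hydrogens and returns a `substrate` object holding the full
#' connection table. Parsing and perception are delegated to OpenBabel.
#'
#' @param text A SMILES string or the text of a MOL/SDF block.
#' @param id Substrate identifier, unique within a run.
#' @param name Optional human-readable name (defaults to `id`).
#'
#' @return A `substrate` object: a list with `id`, `name`, `atoms` (tibble with
#'   1-based `idx`, `element`, `aromatic`, `charge`), `bonds` (tibble with
#'   `a1`, `a2`, `order`, `aromatic`) and `source_text`.
#' @export
#' @examples
#' \dontrun{
#' benzene <- parse_substrate("c1ccccc1", id = "benzene")
#' }
parse_substrate <- function(text, id, name = id) {
  stopifnot(is.character(text), length(text) == 1, nzchar(id))
  is_mol <- looks_like_mol(text)
  args <- if (is_mol) {
    c("-imol", "-omol2", "-h")
  } else {
    c(paste0("-:", shQuote(text)), "-omol2", "-h")
  }
  res <- run_obabel(args, input = if (is_mol) text else NULL)
  if (res$status != 0 || !any(grepl("@<TRIPOS>ATOM", res$text))) {
    err <- paste(grep("error|Error|Warning", res$err, value = TRUE), collapse = "; ")
    abort(sprintf("Failed to parse substrate '%s': %s", id,
                  if (nzchar(err)) err else "no structure produced"),
          class = "pdregio_input_error")
  }
  ct <- parse_mol2(res$text)
  if (!any(ct$atoms$aromatic & ct$atoms$element == "C")) {
    abort(sprintf("Substrate '%s' has no aromatic C-H sites.", id),
          class = "pdregio_domain_error")
  }
  structure(
    list(id = id, name = name, atoms = ct$atoms, bonds = ct$bonds,
         source_text = text),
    class = "substrate"
  )
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate> %s (%d atoms, %d aromatic)\n",
              x$id, nrow(x$atoms), sum(x$atoms$aromatic)))
  invisible(x)
}

neighbours_of <- function(s, i) {
  b <- s$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# Order-independent symmetry classes by colour refinement (Morgan-style).
# Initial invariant: element, aromatic flag, formal-ish charge sign, degree and
# hydrogen count. Each round a vertex colour becomes the lexicographic rank of
# (own colour, sorted neighbour colours), so the final classes do not depend on
# input atom order.
canonical_ranks <- function(s) {
  n <- nrow(s$atoms)
  adj <- map(seq_len(n), function(i) neighbours_of(s, i))
  h_count <- map_dbl(seq_len(n), function(i) {
    sum(s$atoms$element[adj[[i]]] == "H")
  })
  key <- paste(s$atoms$element, s$atoms$aromatic, sign(round(s$atoms$charge)),
               lengths(adj), h_count)
  col <- match(key, sort(unique(key)))
  repeat {
    key2 <- map_chr(seq_len(n), function(i) {
      paste(col[i], paste(sort(col[adj[[i]]]), collapse = ","))
    })
    col2 <- match(key2, sort(unique(key2)))
    if (length(unique(col2)) == length(unique(col))) return(col2)
    col <- col2
  }
}

aromatic_ring_ids <- function(s) {
  # connected components of the aromatic-bond subgraph; fused systems share an id
  n <- nrow(s$atoms)
  comp <- rep(NA_integer_, n)
  ab <- s$bonds[s$bonds$aromatic, , drop = FALSE]
  cur <- 0L
  for (seed in unique(c(ab$a1, ab$a2))) {
    if (!is.na(comp[seed])) next
    cur <- cur + 1L
    queue <- seed
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- c(ab$a2[ab$a1 == v], ab$a1[ab$a2 == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

#' Enumerate symmetry-unique aromatic C-H sites
#'
#' Lists aromatic carbons bearing exactly one hydrogen. Symmetry-equivalent
#' positions (identical colour-refinement canonical rank, e.g. the six CH of
#' benzene) are collapsed to one representative, and labels `H1`, `H2`, ... are
#' assigned in canonical-rank order so they are stable under any reordering of
#' the input atoms.
#'
#' @param s A `substrate`.
#' @return A tibble with one row per unique site: `atom_index` (1-based),
#'   `h_label`, `ring_id`, `h_index` (index of the attached hydrogen) and
#'   `n_equivalent` (size of the symmetry class).
#' @export
enumerate_ch_sites <- function(s) {
  stopifnot(inherits(s, "substrate"))
  ranks <- canonical_ranks(s)
  rings <- aromatic_ring_ids(s)
  n <- nrow(s$atoms)
  cand <- which(s$atoms$aromatic & s$atoms$element == "C")
  rows <- list()
  for (i in cand) {
    nb <- neighbours_of(s, i)
    hs <- nb[s$atoms$element[nb] == "H"]
    if (length(hs) != 1) next
    rows[[length(rows) + 1]] <- tibble(
      atom_index = i, rank = ranks[i], ring_id = rings[i], h_index = hs[[1]]
    )
  }
  if (!length(rows)) {
    abort(sprintf("Substrate '%s' has no aromatic C-H sites.", s$id),
          class = "pdregio_domain_error")
  }
  sites <- bind_rows(rows)
  sites <- sites |>
    group_by(.data$rank) |>
    mutate(n_equivalent = n()) |>
    slice_min(.data$atom_index, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$rank)
  sites$h_label <- paste0("H", seq_len(nrow(sites)))
  sites[, c("atom_index", "h_label", "ring_id", "h_index", "n_equivalent")]
}
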