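# Construction of seed geometries for the Pd(OAc)2-substrate intermediates of
# the two mechanisms. These are idealized starting structures intended for a
# subsequent quick optimization, not optimized geometries:
#   SEAR - Wheland-type ipso complex: Pd bound to the site carbon (2.1 A) on
#          one ring face, the carbon pyramidalised, its H retained and bent to
#          the opposite face.
#   PA   - proton-abstraction (CMD-like) arrangement: Pd at 2.1 A from the
#          site carbon with one acetate oxygen directed at the site H
#          (O...H <= 2.0 A).
# Template Pd-C/Pd-O/O...H distances are seed values chosen near typical
# optimized Pd(II) aryl complexes so a short optimization converges.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("zero-length vector in geometry construction")
  v / n
}

geom_matrix <- function(g) as.matrix(g[, c("x", "y", "z")])

# Build one acetate (CH3COO-) given the coordinating oxygen position, the
# in-fragment outward direction f1 (away from the metal) and a perpendicular
# f2 fixing the carboxylate plane. Idealized bond lengths/angles.
acetate_fragment <- function(o1, f1, f2) {
  f1 <- unitv(f1); f2 <- unitv(f2 - sum(f2 * f1) * f1)
  ang <- function(deg) cos(deg * pi / 180) * f1 + sin(deg * pi / 180) * f2
  cc <- o1 + 1.28 * ang(25)          # carboxylate carbon
  # directions from cc: back to O1 is at angle 25+180; O2 and CH3 fan out
  o2 <- cc + 1.25 * ang(25 + 115)    # ~115 deg O1-C-O2
  cm <- cc + 1.50 * ang(25 - 122)    # methyl carbon opposite the O-C-O fan
  u <- unitv(cm - cc)
  q1 <- f2 - sum(f2 * u) * u
  if (vnorm(q1) < 1e-6) q1 <- f1 - sum(f1 * u) * u
  q1 <- unitv(q1); q2 <- pracma_cross(u, q1)
  hs <- map(c(0, 120, 240), function(phi) {
    d <- cos(70.5 * pi / 180) * u +
      sin(70.5 * pi / 180) * (cos(phi * pi / 180) * q1 + sin(phi * pi / 180) * q2)
    cm + 1.09 * d
  })
  coords <- rbind(o1, cc, o2, cm, hs[[1]], hs[[2]], hs[[3]])
  tibble(element = c("O", "C", "O", "C", "H", "H", "H"),
         x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

site_frame <- function(s, conf, site) {
  i <- site$atom_index
  nb <- neighbours_of(s, i)
  ring_nb <- nb[s$atoms$element[nb] != "H"]
  h_i <- site$h_index
  if (length(ring_nb) < 2) abort("site carbon lacks two ring neighbours")
  M <- geom_matrix(conf)
  C <- M[i, ]; H <- M[h_i, ]
  u1 <- unitv(M[ring_nb[1], ] - C); u2 <- unitv(M[ring_nb[2], ] - C)
  n <- unitv(pracma_cross(u1, u2))
  eh <- M[h_i, ] - C
  eh <- unitv(eh - sum(eh * n) * n)   # in-plane C->H direction
  e3 <- unitv(pracma_cross(n, eh))
  list(C = C, H = H, n = n, eh = eh, e3 = e3, h_i = h_i, c_i = i)
}

#' Build a raw Pd(OAc)2 intermediate for one site and mechanism
#'
#' Places a palladium diacetate template onto a substrate conformer at an
#' aromatic C-H site, in the geometry characteristic of the requested
#' mechanism (`"SEAR"` Wheland-type ipso complex, or `"PA"` proton-abstraction
#' arrangement with an acetate oxygen directed at the site hydrogen).
#'
#' @param s The parent `substrate`.
#' @param conf One conformer tibble from [generate_conformers()].
#' @param site One-row tibble from [enumerate_ch_sites()].
#' @param mechanism `"PA"` or `"SEAR"`.
#' @param conformer_index Index of `conf` in its conformer list (provenance).
#' @return A one-row intermediate tibble with columns `substrate_id`,
#'   `mechanism`, `h_label`, `atom_index`, `conformer_index`, `status`
#'   (`"RAW"`, or `"DISCARDED"` on steric clash), `discard_reason`, and a
#'   `geometry` list-column (element/x/y/z, substrate atoms first, then Pd,
#'   then the two acetates; 15 added atoms).
#' @export
build_intermediate <- function(s, conf, site, mechanism = c("PA", "SEAR"),
                               conformer_index = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(s, "substrate"), nrow(site) == 1)
  i <- site$atom_index
  if (i > nrow(s$atoms) || s$atoms$element[i] != "C" || !s$atoms$aromatic[i]) {
    abort("site does not point at an aromatic carbon",
          class = "pdregio_precondition_error")
  }
  if (nrow(conf) != nrow(s$atoms)) {
    abort("conformer does not belong to this substrate",
          class = "pdregio_precondition_error")
  }
  fr <- site_frame(s, conf, site)
  geom <- conf[, c("element", "x", "y", "z")]
  pd <- fr$C + 2.1 * fr$n

  if (mechanism == "SEAR") {
    # pyramidalise the site carbon: bend its H below the ring plane, away from Pd
    h_new <- fr$C + 1.09 * unitv(fr$eh - 0.8 * fr$n)
    geom[fr$h_i, c("x", "y", "z")] <- as.list(h_new)
    d1 <- unitv(fr$e3 + 0.45 * fr$n)
    d2 <- unitv(-fr$e3 + 0.45 * fr$n)
    ac1 <- acetate_fragment(pd + 2.0 * d1, d1, fr$n)
    ac2 <- acetate_fragment(pd + 2.0 * d2, d2, fr$n)
  } else {
    # abstracting acetate: coordinating O trans-ish over the ring edge, second
    # O placed on the extended C-H axis ~1.9 A from the retained hydrogen
    o1 <- fr$C + 1.99 * fr$eh + 1.90 * fr$n
    o2 <- fr$C + (1.09 + 1.90) * fr$eh
    mid <- (o1 + o2) / 2
    axis <- unitv(o2 - o1)
    half <- vnorm(o2 - o1) / 2
    off <- sqrt(max(1.28^2 - half^2, 0.15))
    away <- (mid - pd); away <- away - sum(away * axis) * axis
    cc <- mid + off * unitv(away)
    cm <- cc + 1.50 * unitv(cc - mid)
    u <- unitv(cm - cc)
    q1 <- unitv(fr$e3 - sum(fr$e3 * u) * u); q2 <- pracma_cross(u, q1)
    hs <- map(c(0, 120, 240), function(phi) {
      d <- cos(70.5 * pi / 180) * u +
        sin(70.5 * pi / 180) * (cos(phi * pi / 180) * q1 + sin(phi * pi / 180) * q2)
      cm + 1.09 * d
    })
    co1 <- rbind(o1, cc, o2, cm, hs[[1]], hs[[2]], hs[[3]])
    ac1 <- tibble(element = c("O", "C", "O", "C", "H", "H", "H"),
                  x = co1[, 1], y = co1[, 2], z = co1[, 3])
    d2 <- unitv(-fr$eh + 0.45 * fr$n)
    ac2 <- acetate_fragment(pd + 2.0 * d2, d2, fr$n)
  }

  full <- bind_rows(
    geom,
    tibble(element = "Pd", x = pd[1], y = pd[2], z = pd[3]),
    ac1, ac2
  )
  full[c("x", "y", "z")] <- round(full[c("x", "y", "z")], 4)

  status <- "RAW"; reason <- NA_character_
  D <- as.matrix(stats::dist(geom_matrix(full)))
  diag(D) <- Inf
  if (min(D) < 0.7) { status <- "DISCARDED"; reason <- "clash" }

  tibble(
    substrate_id = s$id,
    mechanism = mechanism,
    h_label = site$h_label,
    atom_index = i,
    conformer_index = as.integer(conformer_index),
    status = status,
    discard_reason = reason,
    electronic_energy = NA_real_,
    gibbs_energy = NA_real_,
    pd_c_distance = NA_real_,
    geometry = list(full)
  )
}

#' Build all raw intermediates for a substrate
#'
#' Enumerates unique aromatic C-H sites, and for every (conformer, site) pair
#' builds one intermediate per mechanism.
#'
#' @inheritParams build_intermediate
#' @param conformers List of conformers from [generate_conformers()].
#' @param sites Optional site table; computed with [enumerate_ch_sites()] if
#'   omitted.
#' @return An intermediate tibble, two rows (PA + SEAR) per (conformer, site)
#'   pair unless discarded for steric clash.
#' @export
build_all_intermediates <- function(s, conformers, sites = NULL) {
  sites <- sites %||% enumerate_ch_sites(s)
  out <- list()
  for (k in seq_along(conformers)) {
    for (r in seq_len(nrow(sites))) {
      for (m in c("PA", "SEAR")) {
        out[[length(out) + 1]] <-
          build_intermediate(s, conformers[[k]], sites[r, ], m, conformer_index = k)
      }
    }
  }
  bind_rows(out)
}

#' Write intermediates to a multi-record XYZ file
#'
#' One XYZ record per intermediate; the comment line encodes
#' `substrate_id mechanism h_label conformer=k status`.
#'
#' @param intermediates An intermediate tibble with a `geometry` list-column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intermediates_xyz <- function(intermediates, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in seq_len(nrow(intermediates))) {
    g <- intermediates$geometry[[r]]
    writeLines(as.character(nrow(g)), con)
    writeLines(sprintf("%s %s %s conformer=%d status=%s",
                       intermediates$substrate_id[r], intermediates$mechanism[r],
                       intermediates$h_label[r], intermediates$conformer_index[r],
                       intermediates$status[r]), con)
    writeLines(sprintf("%-2s %12.4f %12.4f %12.4f", g$element, g$x, g$y, g$z), con)
  }
  invisible(path)
}

# minimum Pd-C distance of a geometry tibble (Inf when no Pd or no C)
min_pd_c_distance <- function(g) {
  M <- geom_matrix(g)
  pd <- which(g$element == "Pd"); cc <- which(g$element == "C")
  if (!length(pd) || !length(cc)) return(Inf)
  min(apply(M[cc, , drop = FALSE], 1, function(v) vnorm(v - M[pd[1], ])))
}
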