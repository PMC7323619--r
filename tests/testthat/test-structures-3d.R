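test_that("rigid aromatics give one conformer; generation is deterministic", {
  b <- parse_substrate("c1ccccc1", "benzene")
  c1 <- generate_conformers(b, max_n = 5, seed = 7)
  expect_length(c1, 1)
  expect_true(all(is.finite(as.matrix(c1[[1]][, c("x", "y", "z")]))))
  expect_equal(nrow(c1[[1]]), nrow(b$atoms))
  c2 <- generate_conformers(b, max_n = 5, seed = 7)
  expect_equal(c1[[1]], c2[[1]])
  expect_error(generate_conformers(b, max_n = 0),
               class = "pdregio_precondition_error")
})

test_that("flexible substrates yield multiple conformers sorted by energy", {
  s <- parse_substrate("c1ccc(cc1)C(=O)Nc1ccccc1", "benzanilide")
  cs <- generate_conformers(s, max_n = 5, seed = 1)
  expect_gt(length(cs), 1)
  ff <- vapply(cs, attr, numeric(1), "ff_energy")
  expect_false(is.unsorted(ff))
  cs2 <- generate_conformers(s, max_n = 5, seed = 1)
  expect_identical(lapply(cs, as.data.frame), lapply(cs2, as.data.frame))
})

test_that("intermediate templates satisfy the mechanism geometry contracts", {
  b <- parse_substrate("c1ccccc1", "benzene")
  cf <- generate_conformers(b, 1)[[1]]
  sites <- enumerate_ch_sites(b)

  for (m in c("PA", "SEAR")) {
    i <- build_intermediate(b, cf, sites[1, ], m)
    g <- i$geometry[[1]]
    expect_equal(i$status, "RAW")
    expect_equal(sum(g$element == "Pd"), 1)           # exactly one Pd
    expect_equal(nrow(g), nrow(b$atoms) + 15)         # Pd + 2 acetates
    M <- as.matrix(g[, c("x", "y", "z")])
    pd <- which(g$element == "Pd")
    d_pdc <- sqrt(sum((M[pd, ] - M[sites$atom_index[1], ])^2))
    expect_equal(d_pdc, 2.1, tolerance = 0.01)
    D <- as.matrix(stats::dist(M)); diag(D) <- Inf
    expect_gt(min(D), 0.7)                            # no steric clash
  }

  pa <- build_intermediate(b, cf, sites[1, ], "PA")
  g <- pa$geometry[[1]]
  M <- as.matrix(g[, c("x", "y", "z")])
  h <- sites$h_index[1]
  o_min <- min(apply(M[g$element == "O", , drop = FALSE], 1,
                     function(v) sqrt(sum((v - M[h, ])^2))))
  expect_lte(o_min, 2.0)  # abstracting oxygen reaches the site hydrogen
})

test_that("two intermediates per (conformer, site) pair; bad sites rejected", {
  p <- parse_substrate("c1ccncc1", "pyridine")
  cfs <- generate_conformers(p, 1)
  sites <- enumerate_ch_sites(p)
  ints <- build_all_intermediates(p, cfs, sites)
  expect_equal(nrow(ints), 2 * nrow(sites) * length(cfs))
  expect_equal(ints |> dplyr::count(h_label, mechanism) |> nrow(),
               2 * nrow(sites))

  n_idx <- which(p$atoms$element == "N")[1]
  bad <- sites[1, ]; bad$atom_index <- n_idx
  expect_error(build_intermediate(p, cfs[[1]], bad, "SEAR"),
               class = "pdregio_precondition_error")
})

test_that("XYZ export writes one labelled record per intermediate", {
  b <- parse_substrate("c1ccccc1", "benzene")
  cfs <- generate_conformers(b, 1)
  ints <- build_all_intermediates(b, cfs)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_intermediates_xyz(ints, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "27"), nrow(ints))
  expect_true(any(grepl("benzene SEAR H1", lines)))
})
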