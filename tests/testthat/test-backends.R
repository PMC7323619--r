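test_that("tabulated backend reproduces table records and flags decomposition", {
  fx <- paper_fixtures()
  task <- qc_task("FULL_OPT_FREQ")
  r <- tabulated_evaluate(fx$energies, "t2e4", "PA", "H6", task)
  expect_true(r$converged)
  # H6 is the 0.0 site of this group: energy equals the group offset exactly
  expect_equal(r$electronic_energy, -355.5, tolerance = 1e-12)
  r2 <- tabulated_evaluate(fx$energies, "t2e4", "PA", "H1", task)
  expect_equal((r2$electronic_energy - r$electronic_energy) * 627.5095, 1.9,
               tolerance = 1e-9)

  dec <- tabulated_evaluate(fx$energies, "t2e5", "SEAR", "H1", task)
  expect_gt(pdregio:::min_pd_c_distance(dec$final_geometry), 2.4)
  expect_equal(classify_failure(dec, geometry_check = FALSE), "DECOMPOSED")

  expect_error(tabulated_evaluate(fx$energies, "nope", "PA", "H1", task),
               class = "pdregio_lookup_error")
})

test_that("energy-table validation enforces the zero-minimum invariant", {
  bad <- tibble::tibble(substrate_id = "x", mechanism = "PA", h_label = "H1",
                        rel_gibbs_kcal = 1.0, pd_c_angstrom = 2.1, stable = 1)
  expect_error(read_energy_table(bad), "minimum")
  bad2 <- bad; bad2$rel_gibbs_kcal <- 0; bad2$pd_c_angstrom <- -1
  expect_error(read_energy_table(bad2), "positive")
})

test_that("synthetic backend is deterministic and analytically exact at zero noise", {
  task <- qc_task("FULL_OPT_FREQ")
  key <- function(m, h) list(substrate_id = "s1", mechanism = m, h_label = h)

  b <- synthetic_backend(seed = 11, site_gap = 1.0, mech_offset = 6.0)
  b2 <- synthetic_backend(seed = 11, site_gap = 1.0, mech_offset = 6.0)
  r1 <- b$evaluate(key("PA", "H2"), task)
  expect_equal(r1$electronic_energy, b2$evaluate(key("PA", "H2"), task)$electronic_energy)

  # site spacing and mechanism offset are exact with noise_sd = 0
  e <- function(m, h) b$evaluate(key(m, h), task)$electronic_energy
  expect_equal((e("PA", "H3") - e("PA", "H1")) * 627.5095, 2.0, tolerance = 1e-9)
  delta <- (e("PA", "H1") - e("SEAR", "H1")) * 627.5095
  expect_equal(delta, 6.0, tolerance = 1e-9)

  # with noise, same seed still reproduces; different seed differs
  bn <- synthetic_backend(seed = 5, noise_sd = 1)
  bn2 <- synthetic_backend(seed = 5, noise_sd = 1)
  bn3 <- synthetic_backend(seed = 6, noise_sd = 1)
  expect_equal(bn$evaluate(key("PA", "H1"), task)$electronic_energy,
               bn2$evaluate(key("PA", "H1"), task)$electronic_energy)
  expect_false(isTRUE(all.equal(
    bn$evaluate(key("PA", "H1"), task)$electronic_energy,
    bn3$evaluate(key("PA", "H1"), task)$electronic_energy)))
})

test_that("synthetic offsets steer the classifier exactly at zero noise", {
  cfg <- predictor_config()
  for (off in c(6.0, -3.0, 2.5)) {
    tab <- make_synthetic_table(1, 3, delta_distribution = off, seed = 1)
    be <- tabulated_backend(tab, deltas = attr(tab, "deltas"))
    rep <- predict_mechanism("s0001", be, cfg)
    expected <- if (off < 0) "PA" else if (off > 5) "SEAR" else "AMBIGUOUS"
    expect_equal(rep$call, expected)
    expect_equal(rep$stability$delta, off, tolerance = 1e-9)
  }
})
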