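test_that("prescreen keeps intermediates within the group-relative cutoff", {
  out <- prescreen(mk_ints(c(0, 4, 11)), cutoff = 10)
  expect_equal(out$status, c("PRESCREENED", "PRESCREENED", "DISCARDED"))
  expect_equal(out$discard_reason[3], "prescreen")

  # boundary inclusive
  out2 <- prescreen(mk_ints(c(0, 10)), cutoff = 10)
  expect_equal(out2$status, rep("PRESCREENED", 2))

  # cutoff is group-relative: a uniform shift changes nothing
  out3 <- prescreen(mk_ints(c(100, 104, 111)), cutoff = 10)
  expect_equal(out3$status, c("PRESCREENED", "PRESCREENED", "DISCARDED"))

  # groups are substrate x mechanism
  two <- dplyr::bind_rows(mk_ints(c(0, 4), "PA"), mk_ints(c(20, 25), "SEAR"))
  expect_true(all(prescreen(two, 10)$status == "PRESCREENED"))

  expect_equal(nrow(prescreen(mk_ints(numeric(0)), 10)), 0)
})

test_that("geometry filter applies the Pd-C cutoff inclusively", {
  ints <- mk_ints(c(0, 1, 2), status = "OPTIMIZED")
  ints$pd_c_distance <- c(2.3005, 7.1781, 2.4)
  out <- geometry_filter(ints, pd_c_max = 2.4)
  expect_equal(out$status, c("OPTIMIZED", "DISCARDED", "OPTIMIZED"))
  expect_equal(out$discard_reason[2], "no stable Pd-C bond")
  ints$pd_c_distance[1] <- NA
  expect_error(geometry_filter(ints, 2.4), class = "pdregio_contract_error")
})

test_that("relative site energies are shift-invariant with an exact zero minimum", {
  ints <- mk_ints(c(1.9, 9.8, 0.0), status = "OPTIMIZED")
  r <- relative_site_energies(ints)
  expect_equal(min(r$rel_gibbs_kcal), 0)
  expect_equal(setNames(r$rel_gibbs_kcal, r$h_label)[c("H1", "H2", "H3")],
               c(H1 = 1.9, H2 = 9.8, H3 = 0), tolerance = 1e-9)

  shifted <- ints; shifted$gibbs_energy <- shifted$gibbs_energy + 42
  r2 <- relative_site_energies(shifted)
  expect_equal(r$rel_gibbs_kcal, r2$rel_gibbs_kcal, tolerance = 1e-9)

  single <- relative_site_energies(mk_ints(3.3, status = "OPTIMIZED"))
  expect_equal(single$rel_gibbs_kcal, 0)

  none <- mk_ints(c(0, 1), status = "DISCARDED")
  expect_null(relative_site_energies(none))

  # per-site minimum over conformers
  multi <- dplyr::bind_rows(mk_ints(c(0, 5), status = "OPTIMIZED"),
                            mk_ints(c(2, 1), status = "OPTIMIZED"))
  multi$conformer_index <- c(1L, 1L, 2L, 2L)
  rm <- relative_site_energies(multi)
  expect_equal(setNames(rm$rel_gibbs_kcal, rm$h_label)[c("H1", "H2")],
               c(H1 = 0, H2 = 1), tolerance = 1e-9)
})

test_that("stability parameter converts Hartree gaps with the right orientation", {
  sp0 <- stability_parameter(-355.5, -355.5)
  expect_equal(sp0$delta, 0)
  sp <- stability_parameter(-355.5 + 2.0 / 627.5095, -355.5)
  expect_equal(sp$delta, 2.0, tolerance = 1e-9)
  spa <- stability_parameter(-355.5, NA)
  expect_true(is.na(spa$delta))
  expect_error(stability_parameter(NA, NA), class = "pdregio_domain_error")
})

test_that("mechanism classification matches a brute-force rule table on a dense grid", {
  cfg <- predictor_config()
  oracle <- function(d) if (d < 0) "PA" else if (d > 5) "SEAR" else "AMBIGUOUS"
  grid <- seq(-30, 30, by = 0.01)
  calls <- vapply(grid, function(d) {
    classify_mechanism(stability_parameter(d / 627.5095, 0), cfg)$call
  }, character(1))
  expect_equal(calls, vapply(grid, oracle, character(1)))
  # absence rules
  expect_equal(classify_mechanism(stability_parameter(-355.5, NA), cfg)$call, "PA")
  expect_equal(classify_mechanism(stability_parameter(-355.5, NA), cfg)$basis,
               "SEAR_ABSENT")
  expect_equal(classify_mechanism(stability_parameter(NA, -355.5), cfg)$call, "SEAR")
  # closed ambiguous interval at both boundaries
  expect_equal(classify_mechanism(stability_parameter(0, 0), cfg)$call, "AMBIGUOUS")
  expect_equal(classify_mechanism(stability_parameter(5 / 627.5095, 0), cfg)$call,
               "AMBIGUOUS")
})

test_that("Boltzmann fractions obey the distribution's limit properties", {
  expect_equal(boltzmann_fractions(c(H1 = 0)), c(H1 = 1))
  expect_equal(unname(boltzmann_fractions(c(A = 0, B = 0, C = 0))),
               rep(1 / 3, 3), tolerance = 1e-12)

  set.seed(41)
  for (k in 1:20) {
    dd <- setNames(c(0, sort(runif(4, 0, 20))), paste0("H", 1:5))
    f <- boltzmann_fractions(dd)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(diff(f[order(dd)]) <= 1e-15))      # monotone in energy
    expect_equal(f, boltzmann_fractions(dd + 7.7), tolerance = 1e-12)  # shift
  }
  hot <- boltzmann_fractions(c(H1 = 0, H2 = 1, H3 = 3), temperature = 1e9)
  expect_equal(unname(hot), rep(1 / 3, 3), tolerance = 1e-6)
  cold <- boltzmann_fractions(c(H1 = 0, H2 = 3, H3 = 12), temperature = 1e-3)
  expect_gt(cold[["H1"]], 1 - 1e-9)
  expect_error(boltzmann_fractions(numeric(0)), class = "pdregio_domain_error")
})

test_that("Boltzmann fractions match the independent direct-formula oracle", {
  dd <- c(H1 = 0, H2 = 0.5)
  f <- boltzmann_fractions(dd, temperature = 298.15)
  expect_equal(unname(f), unname(boltzmann_oracle(dd)), tolerance = 1e-12)
  expect_equal(f[["H1"]], 0.699, tolerance = 1e-3)
  expect_equal(f[["H2"]], 0.301, tolerance = 1e-3)
})

test_that("predict on the table route equals the direct short-path oracle", {
  fx <- paper_fixtures()
  be <- paper_backend()
  for (id in fx$table2_meta$substrate_id) {
    rep <- predict_mechanism(id, be)
    # oracle: work straight from the table, bypassing the pipeline
    t <- fx$energies[fx$energies$substrate_id == id & fx$energies$stable, ]
    d <- fx$table2_meta$delta_kcal[fx$table2_meta$substrate_id == id]
    for (m in intersect(c("PA", "SEAR"), unique(t$mechanism))) {
      tm <- t[t$mechanism == m, ]
      got <- rep$sites[rep$sites$mechanism == m, ]
      expect_equal(setNames(got$rel_gibbs_kcal, got$h_label)[tm$h_label],
                   setNames(tm$rel_gibbs_kcal, tm$h_label), tolerance = 1e-9)
      fr <- boltzmann_oracle(setNames(tm$rel_gibbs_kcal, tm$h_label))
      expect_equal(setNames(got$fraction, got$h_label)[tm$h_label], fr,
                   tolerance = 1e-9)
    }
    both <- all(c("PA", "SEAR") %in% t$mechanism)
    if (both && !is.na(d)) expect_equal(rep$stability$delta, d, tolerance = 1e-9)
    oracle_call <- if (!"SEAR" %in% t$mechanism) "PA"
      else if (!"PA" %in% t$mechanism) "SEAR"
      else if (d < 0) "PA" else if (d > 5) "SEAR" else "AMBIGUOUS"
    expect_equal(rep$call, oracle_call)
  }
})

test_that("the structure route runs end-to-end on a real heteroarene", {
  fu <- parse_substrate("c1ccoc1", "furan")
  be <- synthetic_backend(seed = 3, mech_offset = -3.0, site_gap = 1.0)
  rep <- predict_mechanism(fu, be, max_conformers = 1)
  expect_equal(rep$call, "PA")
  expect_equal(rep$stability$delta, -3.0, tolerance = 1e-9)
  # furan has two unique sites (alpha/beta); both mechanisms reported
  expect_equal(nrow(rep$sites), 4)
  expect_equal(sum(rep$sites$mechanism == "PA"), 2)
  td <- generics::tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- generics::glance(rep)
  expect_equal(gl$call, "PA")
  expect_equal(gl$top_site_pa, "H1")
  plt <- ggplot2::autoplot(rep)
  expect_s3_class(plt, "ggplot")
})

test_that("prediction propagates absence of all stable intermediates", {
  tab <- tibble::tibble(
    substrate_id = "dead", mechanism = c("PA", "SEAR"), h_label = "H1",
    rel_gibbs_kcal = 0, pd_c_angstrom = 9.99, stable = 0L)
  be <- tabulated_backend(tab)
  expect_error(predict_mechanism("dead", be), class = "pdregio_domain_error")
})
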