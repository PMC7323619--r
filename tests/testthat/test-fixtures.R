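test_that("the bundled fixture set validates and matches its cardinalities", {
  fx <- paper_fixtures()
  expect_equal(nrow(fx$table1), 12)
  expect_equal(nrow(fx$table2_meta), 8)
  expect_equal(nrow(fx$table3), 6)
  expect_equal(nrow(fx$table4), 6)
  expect_s3_class(fx$energies, "energy_table")

  # threshold-test record 2: Gibbs value, distance, relative stability, calls
  e2 <- fx$table4[fx$table4$entry == 2, ]
  expect_equal(e2$gibbs_hartree, -355.5577)
  expect_equal(e2$pd_c_angstrom, 2.3778)
  expect_equal(e2$relative_stability, -1.6369)
  expect_equal(e2$predicted_mechanism, "PA")
  expect_equal(e2$reported_mechanism, "PA")

  # the entry-5 sign anomaly is stored verbatim and flagged, not corrected
  e5 <- fx$table4[fx$table4$entry == 5, ]
  expect_equal(e5$gibbs_hartree, 355.5717)
  expect_equal(e5$anomaly_flag, 1L)

  # per-mechanism site energies of validation entry 3
  t3 <- fx$energies[fx$energies$substrate_id == "t2e3" &
                      fx$energies$mechanism == "PA", ]
  expect_equal(setNames(t3$rel_gibbs_kcal, t3$h_label),
               c(H1 = 0.0, H2 = 0.7))
})

test_that("synthetic tables are deterministic with a faithful ground-truth ledger", {
  t1 <- make_synthetic_table(10, 3, seed = 9)
  t2 <- make_synthetic_table(10, 3, seed = 9)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "ground_truth"), attr(t2, "ground_truth"))

  # point mass above the upper threshold: every substrate is SEAr
  tse <- make_synthetic_table(6, 2, delta_distribution = 7, seed = 2)
  be <- tabulated_backend(tse, deltas = attr(tse, "deltas"))
  calls <- vapply(attr(tse, "ground_truth")$substrate_id,
                  function(id) predict_mechanism(id, be)$call, character(1))
  expect_true(all(calls == "SEAR"))
  expect_true(all(attr(tse, "ground_truth")$true_call == "SEAR"))

  # full decomposition of the SEAr branch forces PA via absence
  tpa <- make_synthetic_table(6, 2, delta_distribution = 7,
                              decomposed_rate = 1, seed = 3)
  bpa <- tabulated_backend(tpa, deltas = attr(tpa, "deltas"))
  reps <- lapply(attr(tpa, "ground_truth")$substrate_id,
                 function(id) predict_mechanism(id, bpa))
  expect_true(all(vapply(reps, `[[`, character(1), "call") == "PA"))
  expect_true(all(vapply(reps, `[[`, character(1), "basis") == "SEAR_ABSENT"))
})

test_that("fixture-log generation rejects bad scenarios", {
  expect_error(make_fixture_logs(character(0)), class = "pdregio_input_error")
  expect_error(make_fixture_logs(c("NONE", "NOT_A_CLASS")),
               class = "pdregio_input_error")
  logs <- make_fixture_logs(c("SADDLE_POINT", "NONE"))
  expect_length(logs, 2)
  expect_true(any(parse_result(logs[[1]])$frequencies < 0))
  expect_false(any(parse_result(logs[[2]])$frequencies < 0))
})
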