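test_that("failure classification maps fixture outcomes to the handler classes", {
  logs <- make_fixture_logs(c("NONE", "SADDLE_POINT", "HESSIAN_STALE",
                              "BAD_GUESS", "DECOMPOSED", "HARD_FAIL"))
  cls <- vapply(logs, function(l) {
    r <- parse_result(l)
    gc <- TRUE
    if (!is.null(r$final_geometry) && "Pd" %in% r$final_geometry$element) {
      gc <- pdregio:::min_pd_c_distance(r$final_geometry) <= 2.4
    }
    classify_failure(r, gc)
  }, character(1))
  expect_equal(cls, c("NONE", "SADDLE_POINT", "HESSIAN_STALE",
                      "BAD_GUESS", "DECOMPOSED", "HARD_FAIL"))
  # purity: same result, same class
  r <- parse_result(logs[[2]])
  expect_identical(classify_failure(r, TRUE), classify_failure(r, TRUE))
  # small imaginary modes are numerical noise, not saddle evidence
  r_noise <- qc_result(TRUE, TRUE,
                       final_geometry = tibble::tibble(element = "H", x = 0, y = 0, z = 0),
                       electronic_energy = -1, frequencies = c(-4, 30))
  expect_equal(classify_failure(r_noise, TRUE), "NONE")
})

test_that("mode displacement is linear, exact and reversible", {
  g <- tibble::tibble(element = c("C", "H"), x = c(0, 1.09), y = 0, z = 0)
  mode <- rbind(c(0, 0, 1), c(0, 0, 0))
  expect_equal(displace_along_mode(g, mode, 0), g)
  d <- displace_along_mode(g, mode, 0.3)
  expect_equal(d$z, c(0.3, 0))  # unit mode on one atom moves it exactly 0.3 A
  back <- displace_along_mode(d, mode, -0.3)
  expect_lt(max(abs(as.matrix(back[, 2:4]) - as.matrix(g[, 2:4]))), 1e-12)
  expect_error(displace_along_mode(g, matrix(0, 2, 3), 0.3),
               class = "pdregio_numeric_error")
})

test_that("remediation actions follow the handler table", {
  saddle <- parse_result(make_fixture_logs("SADDLE_POINT")[[1]])
  dec <- remediate(1, saddle, geometry_check = TRUE)
  expect_equal(dec$action, "RESUBMIT_DISPLACED")
  # displaced geometry differs from the last geometry only along the mode
  diff <- as.matrix(dec$next_geometry[, 2:4]) -
    as.matrix(saddle$final_geometry[, 2:4])
  expect_equal(sqrt(sum(diff^2)), 0.3, tolerance = 1e-9)
  expect_equal(abs(diff[1, 1]), 0.3, tolerance = 1e-9,
               ignore_attr = TRUE)  # mode lives on atom 1 x
  expect_equal(max(abs(diff[-1, ])), 0)

  stale <- parse_result(make_fixture_logs("HESSIAN_STALE")[[1]])
  dec2 <- remediate(1, stale)
  expect_equal(dec2$action, "RESUBMIT_LAST_GEOM")
  expect_equal(dec2$next_geometry, stale$final_geometry)

  badg <- parse_result(make_fixture_logs("BAD_GUESS")[[1]])
  expect_equal(remediate(1, badg)$action, "DISCARD")
  okr <- parse_result(make_fixture_logs("NONE")[[1]])
  expect_equal(remediate(1, okr)$action, "ACCEPT")
  expect_equal(remediate(1, okr, geometry_check = FALSE)$action, "DISCARD")
  # retry exhaustion converts resubmissions into discards
  out <- remediate(3, stale, max_retries = 3)
  expect_equal(out$action, "DISCARD")
  expect_equal(out$reason, "max retries")
})

test_that("the state machine terminates every scenario within the retry budget", {
  # exhaustive over all error-class sequences of length <= 4
  classes <- c("NONE", "SADDLE_POINT", "HESSIAN_STALE", "BAD_GUESS",
               "DECOMPOSED", "HARD_FAIL")
  base_logs <- setNames(make_fixture_logs(classes), classes)
  geo0 <- tibble::tibble(element = c("Pd", "C", "H"), x = c(0, 2.1, 2.75),
                         y = 0, z = 0)
  seqs <- unlist(lapply(1:4, function(k) {
    m <- as.matrix(expand.grid(rep(list(classes), k), stringsAsFactors = FALSE))
    split(m, row(m))
  }), recursive = FALSE)
  finals <- character(0)
  for (sc in seqs) {
    job <- run_job(geo0, scripted_evaluate(sc, logs = base_logs[sc]),
                   max_retries = 3)
    expect_true(job$final %in% c("ACCEPT", "DISCARD"))
    expect_lte(nrow(job$ledger), 3)
    finals <- c(finals, job$final)
  }
  expect_length(finals, 6 + 36 + 216 + 1296)
  # immediate clean convergence is accepted on attempt one
  job1 <- run_job(geo0, scripted_evaluate("NONE", logs = base_logs["NONE"]))
  expect_equal(job1$final, "ACCEPT")
  expect_equal(nrow(job1$ledger), 1)
})
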