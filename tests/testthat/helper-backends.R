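# Shared helpers: fixture access, scripted engine backends and small oracles.

paper_fixtures <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- load_paper_fixtures()
    fx
  }
})

paper_backend <- function() {
  fx <- paper_fixtures()
  tabulated_backend(fx$energies,
                    deltas = fx$table2_meta[, c("substrate_id", "delta_kcal")])
}

# evaluate() closure that replays a fixed error-class scenario (attempt i ->
# i-th log), padding with clean convergence beyond the scripted length
scripted_evaluate <- function(scenario, logs = NULL) {
  logs <- logs %||% make_fixture_logs(scenario)
  pad <- make_fixture_logs("NONE")[[1]]
  function(geometry, attempt) {
    parse_result(if (attempt <= length(logs)) logs[[attempt]] else pad)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent Boltzmann oracle: literal formula, no shift trick
boltzmann_oracle <- function(ddG, temperature = 298.15, R = 1.987204e-3) {
  w <- exp(-ddG / (R * temperature))
  w / sum(w)
}

# graph distance from an atom to the nearest atom of a given element
graph_dist_to_element <- function(s, from, element) {
  n <- nrow(s$atoms)
  d <- rep(Inf, n); d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- c(s$bonds$a2[s$bonds$a1 == v], s$bonds$a1[s$bonds$a2 == v])
    for (w in nb) if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
  }
  min(d[s$atoms$element == element])
}
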