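# minimal intermediate-table builder used across predictor tests
mk_ints <- function(energies_kcal, mechanism = "PA", status = "RAW",
                    pd_c = 2.1, substrate = "s") {
  n <- length(energies_kcal)
  tibble::tibble(
    substrate_id = substrate, mechanism = mechanism,
    h_label = paste0("H", seq_len(n)), atom_index = seq_len(n),
    conformer_index = 1L, status = status, discard_reason = NA_character_,
    electronic_energy = -355.5 + energies_kcal / 627.5095,
    gibbs_energy = -355.5 + energies_kcal / 627.5095,
    pd_c_distance = rep_len(pd_c, n), geometry = vector("list", n)
  )
}
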