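# In-code builders for small thermochemistry fixtures.

# minimal reference-enthalpy table for one or more phases
refs_for <- function(phases = "gas", h_h = -0.5, h_p = 1.0, h_e = 0.1) {
  data.frame(phase = phases,
             h_hydrogen_atom = rep_len(h_h, length(phases)),
             h_proton = rep_len(h_p, length(phases)),
             h_electron = rep_len(h_e, length(phases)),
             provenance = "test", stringsAsFactors = FALSE)
}

# one compound with parent + site radical/anion + cation in one phase
toy_species <- function(compound = "X", phase = "gas", site = "4'-OH",
                        parent = -100, radical = -14.3, anion = -80,
                        cation = 138) {
  species_set(data.frame(
    compound = compound,
    role = c("parent", "radical", "anion", "radical_cation"),
    site = c(NA, site, site, NA),
    phase = phase,
    enthalpy = c(parent, radical, anion, cation),
    stringsAsFactors = FALSE))
}

pick <- function(set, role, site = NA) {
  df <- as.data.frame(set)
  species_lookup(set, df$compound[1], role, site, df$phase[1])
}
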