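#!/usr/bin/env Rscript
# Stage 3 — PES profiles and TST kinetics for Pt-3-O-glc + .OH.
# Rebuilds the four H-abstraction PES profiles from the bundled reference
# energetics (barriers and reaction free energies relative to the
# pre-reaction complex), evaluates conventional TST rate constants at
# sigma = kappa = 1, and compares the computed ranking with the published
# reference rate-constant ordering.

library(radscav)
dir.create("results", showWarnings = FALSE)

t2 <- table2_kinetics()
rt <- rate_table(table2_profiles())
rt$k_ref <- t2$k_ref[match(rt$reaction, t2$reaction)]
radscav:::write_delim_utf8(as.data.frame(rt), "results/rate_table.tsv")

message("TST rate table (RC-referenced, 298.15 K, sigma = kappa = 1):")
for (i in seq_len(nrow(rt))) {
  message(sprintf("  %-26s dG# %s  dG %s  k(TST) %s   [k_ref %s]",
                  rt$reaction[i], format_energy(rt$delta_g_activation[i]),
                  format_energy(rt$delta_g_reaction[i]),
                  format_rate(rt$rate_constant[i]), format_rate(rt$k_ref[i])))
}
stopifnot(identical(rt$reaction, t2$reaction[order(-t2$k_ref)]))
message("Computed TST ranking matches the reference rate-constant ordering ",
        "(4'-OH fastest, 3'-OH slowest), and the fastest channel is also ",
        "the most exergonic (dG = ", format_energy(min(rt$delta_g_reaction)),
        " kcal/mol).")
message("Note: absolute reference k values embed unstated degeneracy/",
        "tunnelling settings, so only orderings are compared; recomputed k ",
        "is reported under the explicit sigma = kappa = 1 convention.")
message(sprintf("Checks: kB*T/h = %s s^-1 at 298.15 K; Wigner kappa(1500 cm^-1) = %.3f",
                format_rate(tst_rate(0)), wigner_kappa(1500)))
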