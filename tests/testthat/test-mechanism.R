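t1 <- table1_descriptors()

test_that("most active site selection matches the published blocks and tie-breaks canonically", {
  expect_equal(min_site(t1, "Pt-3-O-glc", "gas", "bde"),
               list(site = "4′-OH", value = 86.2))
  expect_equal(min_site(t1, "Pt-3-O-glc", "water", "pa"),
               list(site = "7-OH", value = 22.2))
  # exact tie resolves to the canonically earlier site
  tied <- descriptor_table(data.frame(
    compound = "A", site = c("7-OH", "5-OH"), phase = "gas",
    bde = c(90, 90)))
  expect_equal(min_site(tied, "A", "gas", "bde")$site, "5-OH")
  # min value is a lower bound on all inputs
  ms <- min_site(t1, "Cy-3-O-glc", "gas", "bde")
  expect_true(all(ms$value <= t1$bde[t1$compound == "Cy-3-O-glc" &
                                       t1$phase == "gas"]))
  only_ip <- descriptor_table(data.frame(compound = "A", site = "5-OH",
                                         phase = "gas", ip = 240))
  expect_error(min_site(only_ip, "A", "gas", "bde"), "not computable")
})

test_that("compound ranking reproduces the published 4'-OH gas BDE sequence", {
  # the text-quoted variant: Pt < Dp < Mv < Cy < Pn
  r <- rank_compounds(quoted_bde_ranking(), "bde", "4'-OH", "gas")
  expect_equal(r$compound, c("Pt-3-O-glc", "Dp-3-O-glc", "Mv-3-O-glc",
                             "Cy-3-O-glc", "Pn-3-O-glc"))
  expect_equal(r$value, c(86.2, 86.7, 87.4, 89.8, 93.4))
  # on the table as printed, Cy's 4'-OH value is 94.0 and Cy ranks last
  rp <- rank_compounds(t1, "bde", "4'-OH", "gas")
  expect_equal(rp$compound[1], "Pt-3-O-glc")
  expect_equal(rp$compound[5], "Cy-3-O-glc")
  # output is a permutation of input compounds, values ascending
  expect_setequal(rp$compound, unique(t1$compound))
  expect_true(all(diff(rp$value) >= 0))
  # missing rows are dropped with a warning, singleton ranks trivially
  expect_warning(
    one <- rank_compounds(t1, "bde", "3'-OH", "gas"),
    "no bde row")
  expect_equal(nrow(one), 2)  # only Dp and Pt carry a 3'-OH
  # lowest gas-phase ETE compound is Pt
  ete_r <- rank_compounds(t1, "ete", "3'-OH", "gas",
                          compounds = c("Dp-3-O-glc", "Pt-3-O-glc"))
  expect_equal(ete_r$compound[1], "Pt-3-O-glc")
  expect_equal(ete_r$value[1], 130.0)
})

test_that("mechanism classification is the argmin of {min BDE, IP, min PA}", {
  v <- classify_mechanism(t1, "Pt-3-O-glc", "gas")
  expect_equal(v$mechanism, "HAT")
  expect_equal(v$evidence$min_bde$value, 86.2)
  expect_equal(v$evidence$ip, 239.6)
  expect_equal(v$evidence$min_pa$value, 247.3)
  w <- classify_mechanism(t1, "Pt-3-O-glc", "water")
  expect_equal(w$mechanism, "SPLET")
  expect_equal(w$evidence$min_pa, list(site = "7-OH", value = 22.2))
  # forced SET-PT when IP undercuts both minima
  syn <- descriptor_table(data.frame(
    compound = "A", site = c("4'-OH", "5-OH"), phase = "gas",
    bde = c(80, 85), ip = 60, pa = c(90, 70)))
  expect_equal(classify_mechanism(syn, "A", "gas")$mechanism, "SET-PT")
  # exact tie flags and resolves by the fixed HAT > SET-PT > SPLET priority
  tie <- descriptor_table(data.frame(
    compound = "A", site = "4'-OH", phase = "gas",
    bde = 50, ip = 50, pa = 50))
  vt <- classify_mechanism(tie, "A", "gas")
  expect_true(vt$tie)
  expect_equal(vt$mechanism, "HAT")
  # a missing leg is an explicit not-computable error
  noip <- descriptor_table(data.frame(
    compound = "A", site = "4'-OH", phase = "gas", bde = 80, pa = 90))
  expect_error(classify_mechanism(noip, "A", "gas"), "not computable.*ip")
})

test_that("the full fixture classifies HAT in gas and SPLET in both solvents", {
  all_v <- classify_all(t1)
  expect_equal(nrow(all_v), 15)
  expect_true(all(all_v$mechanism[all_v$phase == "gas"] == "HAT"))
  expect_true(all(all_v$mechanism[all_v$phase %in% c("water", "ethanol")] ==
                    "SPLET"))
  expect_false(any(all_v$tie))
})

test_that("solvent shifts reproduce the published mean IP drops", {
  gw <- solvent_shift_summary(t1, "ip", "gas", "water")
  expect_equal(nrow(gw$per_compound), 5)
  expect_equal(format_energy(gw$mean), "101.5")
  ge <- solvent_shift_summary(t1, "ip", "gas", "ethanol")
  expect_equal(format_energy(ge$mean), "105.6")
  # identical phases shift by zero
  gg <- solvent_shift_summary(t1, "ip", "gas", "gas")
  expect_true(all(gg$per_compound$shift == 0))
})

test_that("substituent contrast reproduces the published 6.6 kcal/mol average", {
  d <- substituent_contrast(t1, "bde", "4'-OH", "gas", "Pn-3-O-glc",
                            c("Mv-3-O-glc", "Pt-3-O-glc"))
  expect_equal(d, mean(c(93.4 - 87.4, 93.4 - 86.2)))
  expect_equal(format_energy(d), "6.6")
  expect_equal(substituent_contrast(t1, "bde", "4'-OH", "gas",
                                    "Pn-3-O-glc", "Pn-3-O-glc"), 0)
  expect_equal(substituent_contrast(t1, "bde", "4'-OH", "gas",
                                    "Pn-3-O-glc", "Pt-3-O-glc"), 7.2)
  expect_error(substituent_contrast(t1, "bde", "4'-OH", "gas",
                                    "Pn-3-O-glc", "Zz-3-O-glc"), "Zz-3-O-glc")
})

test_that("double-HAT analysis favours the cheapest channel, independent of ordering and spin bookkeeping", {
  refs <- refs_for("gas", h_h = -0.5)
  parent <- species_set(data.frame(compound = "Pt-3-O-glc", role = "parent",
                                   site = NA, phase = "gas", enthalpy = -1000,
                                   stringsAsFactors = FALSE))
  radical <- species_set(rbind(
    as.data.frame(parent)[, c("compound", "role", "site", "phase", "enthalpy")],
    data.frame(compound = "Pt-3-O-glc", role = "radical", site = "4'-OH",
               phase = "gas", enthalpy = -1000 + 86.2 + 0.5)))
  rad <- pick(radical, "radical", "4'-OH")
  # products placed so second-step costs are the published 44.4 / 80.8
  prods <- data.frame(
    compound = c("benzodioxole", "o-quinone", "o-quinone"),
    role = "product", site = NA, phase = "gas",
    enthalpy = c(rad$enthalpy + 0.5 + 44.4,
                 rad$enthalpy + 0.5 + 80.8,    # singlet
                 rad$enthalpy + 0.5 + 95.0),   # higher-lying triplet
    spin = c(NA, "singlet", "triplet"), stringsAsFactors = FALSE)
  res <- second_hat_analysis(pick(parent, "parent"), rad, prods, refs)
  expect_equal(res$favored, "benzodioxole")
  expect_equal(res$channels$cost, c(44.4, 80.8), tolerance = 1e-12)
  expect_equal(res$channels$spin[res$channels$product == "o-quinone"],
               "singlet")  # lowest-enthalpy spin state selected
  # channel order invariance
  res2 <- second_hat_analysis(pick(parent, "parent"), rad,
                              prods[rev(seq_len(nrow(prods))), ], refs)
  expect_equal(res2$channels, res$channels)
  # synthetic case with the quinone cheaper flips the verdict
  cheap <- prods; cheap$enthalpy[2] <- rad$enthalpy + 0.5 + 30
  expect_equal(second_hat_analysis(pick(parent, "parent"), rad, cheap,
                                   refs)$favored, "o-quinone")
  expect_error(second_hat_analysis(pick(parent, "parent"), rad,
                                   prods[0, ], refs), "no channel")
})

test_that("bundled double-HAT costs favour benzodioxole in every phase", {
  dh <- second_hat_from_costs(fig2_double_hat())
  expect_true(all(dh$favored == "benzodioxole"))
  expect_equal(sort(dh$cost), c(44.4, 47.4, 48.3))
  expect_true(all(dh$margin > 0))
})
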