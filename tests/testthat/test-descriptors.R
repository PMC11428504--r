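refs <- refs_for("gas", h_h = -0.5, h_p = 1.0, h_e = 0.1)

test_that("descriptor equations evaluate their defining arithmetic", {
  set <- toy_species()
  parent <- pick(set, "parent"); radical <- pick(set, "radical", "4'-OH")
  anion <- pick(set, "anion", "4'-OH"); cation <- pick(set, "radical_cation")
  expect_equal(bde(parent, radical, refs), 85.2)     # -14.3 - 0.5 + 100
  expect_equal(ip(parent, cation, refs), 238.1)      # 138 + 0.1 + 100
  expect_equal(pa(parent, anion, refs), 21.0)        # -80 + 1 + 100
  an2 <- anion; an2$enthalpy <- -128.1
  expect_equal(ete(an2, radical, refs), 113.9)       # -14.3 + 0.1 + 128.1
  # negative PDE is legal
  cat2 <- cation; cat2$enthalpy <- 15
  rad2 <- radical; rad2$enthalpy <- 10
  expect_equal(pde(cat2, rad2, refs), -4.0)
  # degenerate identity: equal enthalpies and zero H-atom reference
  refs0 <- refs_for("gas", h_h = 0)
  rad0 <- radical; rad0$enthalpy <- parent$enthalpy
  expect_equal(bde(parent, rad0, refs0), 0.0)
})

test_that("mismatched phase, compound or role is rejected", {
  set <- toy_species()
  parent <- pick(set, "parent"); radical <- pick(set, "radical", "4'-OH")
  other <- toy_species("Y", phase = "water")
  refs2 <- refs_for(c("gas", "water"))
  expect_error(bde(parent, pick(other, "radical", "4'-OH"), refs2),
               "mismatch")
  expect_error(bde(radical, radical, refs), "role mismatch")
  expect_error(ip(parent, radical, refs), "role mismatch")
})

test_that("Hess identities hold exactly on any complete species set", {
  set.seed(3)
  for (i in 1:20) {
    set <- toy_species(parent = runif(1, -1100, -900),
                       radical = runif(1, -1000, -800),
                       anion = runif(1, -1050, -850),
                       cation = runif(1, -900, -700))
    parent <- pick(set, "parent"); radical <- pick(set, "radical", "4'-OH")
    anion <- pick(set, "anion", "4'-OH"); cation <- pick(set, "radical_cation")
    lhs <- ip(parent, cation, refs) + pde(cation, radical, refs)
    rhs <- pa(parent, anion, refs) + ete(anion, radical, refs)
    C <- unname(reference_constant(refs, "gas"))
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(lhs, bde(parent, radical, refs) + C, tolerance = 1e-12)
    # translation invariance: shifting every enthalpy leaves all five fixed
    shift <- runif(1, -50, 50)
    sset <- as.data.frame(set); sset$enthalpy <- sset$enthalpy + shift
    sset <- species_set(sset)
    expect_equal(bde(pick(sset, "parent"), pick(sset, "radical", "4'-OH"), refs),
                 bde(parent, radical, refs), tolerance = 1e-9)
    expect_equal(pa(pick(sset, "parent"), pick(sset, "anion", "4'-OH"), refs),
                 pa(parent, anion, refs), tolerance = 1e-9)
  }
})

test_that("descriptor tables assemble per compound-site-phase with absent (not zero) gaps", {
  base_cols <- c("compound", "role", "site", "phase", "enthalpy")
  df <- rbind(as.data.frame(toy_species("A"))[, base_cols],
              data.frame(compound = "A", role = c("radical", "anion"),
                         site = "7-OH", phase = "gas",
                         enthalpy = c(-10, -75), stringsAsFactors = FALSE))
  tab <- build_descriptor_table(species_set(df), refs)
  expect_equal(nrow(tab), 2)
  expect_true(all(!is.na(as.matrix(tab[, c("bde", "ip", "pde", "pa", "ete")]))))
  expect_equal(tab$ip[1], tab$ip[2])  # IP broadcast across site rows

  # drop the anions: pa/ete absent, the rest intact
  no_anion <- species_set(df[df$role != "anion", ])
  tab2 <- build_descriptor_table(no_anion, refs)
  expect_true(all(is.na(tab2$pa)) && all(is.na(tab2$ete)))
  expect_true(all(!is.na(tab2$bde)))

  # glycoside sites are excluded from the default enumeration
  glc <- rbind(df, data.frame(compound = "A", role = "radical",
                              site = "glc-2-OH", phase = "gas",
                              enthalpy = -12, stringsAsFactors = FALSE))
  expect_equal(nrow(build_descriptor_table(species_set(glc), refs)), 2)
  expect_equal(nrow(build_descriptor_table(species_set(glc), refs,
                                           exclude_pattern = "^$")), 3)
})

test_that("descriptor table validation enforces site-constant IP and non-empty rows", {
  bad <- data.frame(compound = "A", site = c("4'-OH", "5-OH"), phase = "gas",
                    bde = c(86, 94), ip = c(240, 241))
  expect_error(descriptor_table(bad), "IP varies")
  empty_row <- data.frame(compound = "A", site = "4'-OH", phase = "gas",
                          bde = NA_real_)
  expect_error(descriptor_table(empty_row), "no descriptor")
})

test_that("bundled descriptor fixture has the published shape and closes its Hess cycles", {
  t1 <- table1_descriptors()
  expect_equal(nrow(t1), 57)  # 19 site rows x 3 phases
  expect_equal(length(unique(t1$compound)), 5)
  expect_equal(sum(t1$phase == "gas"), 19)
  rep <- check_hess_closure(t1, refs = default_reference_enthalpies(),
                            tolerance = 0.3)
  expect_true(all(!rep$flagged))
  expect_true(all(abs(rep$pair_gap) <= 0.3))
  # synthetic tables close to machine precision
  tg <- random_descriptor_targets(25, seed = 5)
  tab <- build_descriptor_table(make_species_set(tg), default_reference_enthalpies())
  rep2 <- check_hess_closure(tab, refs = default_reference_enthalpies(),
                             tolerance = 1e-9)
  expect_true(all(!rep2$flagged))
})

test_that("descriptor tables round-trip through delimited text", {
  t1 <- table1_descriptors()
  tf <- tempfile(fileext = ".tsv")
  write_descriptor_table(t1, tf)
  expect_equal(as.data.frame(read_descriptor_table(tf)), as.data.frame(t1))
})
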