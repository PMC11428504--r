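test_that("PES profiles re-reference to the pre-complex and flag missing or inverted stationary points", {
  sp <- make_pes(data.frame(reaction = "r1", barrier = 7.6,
                            reaction_energy = -31.1, rc_complexation = 2))
  p <- build_pes(sp)
  expect_s3_class(p, "pes_profile")
  expect_equal(profileval <- p$levels$gibbs_rel[p$levels$role == "pre_complex"], 0)
  expect_equal(activation_free_energy(p), 7.6)
  expect_equal(reaction_free_energy(p), -31.1)
  expect_equal(reaction_free_energy(p, endpoint = "pre_complex"), 0)
  expect_false(p$barrierless)
  # separated reactants sit above the RC by the complexation energy
  expect_equal(activation_free_energy(p, reference = "reactants"), 7.6 - 2)

  expect_error(build_pes(sp[sp$role != "transition_state", ]),
               "missing transition state")
  expect_error(build_pes(sp[sp$role != "pre_complex", ]), "missing pre")
  two_phase <- sp; two_phase$phase[1] <- "water"
  expect_error(build_pes(two_phase), "phase")

  # TS below RC: flagged barrierless, not an error
  bl <- build_pes(make_pes(data.frame(reaction = "r2", barrier = -1,
                                      reaction_energy = -20)))
  expect_true(bl$barrierless)
})

test_that("Wigner correction has the right limit, value and quadratic scaling", {
  # kappa -> 1 as the wavenumber vanishes
  expect_equal(wigner_kappa(1e-8, 298.15), 1, tolerance = 1e-12)
  # frozen high-precision oracle value at 1500 cm^-1, 298.15 K
  expect_equal(wigner_kappa(1500, 298.15), 3.18317499451376,
               tolerance = 1e-10)
  # quadratic growth: kappa(2v) - 1 = 4 (kappa(v) - 1)
  for (v in c(200, 900, 1712.5)) {
    expect_equal(wigner_kappa(2 * v) - 1, 4 * (wigner_kappa(v) - 1),
                 tolerance = 1e-12)
  }
  expect_error(wigner_kappa(-10), "positive")
  expect_error(wigner_kappa(1500, 0), "temperature")
})

test_that("TST rate matches the frozen constants oracle and scales linearly in sigma", {
  # kB*T/h at 298.15 K, computed independently with CODATA constants
  expect_equal(tst_rate(0), 6212437991620.12, tolerance = 1e-10)
  expect_equal(tst_rate(7.6), 16688734.609, tolerance = 1e-8)
  expect_equal(tst_rate(7.6, sigma = 2), 2 * tst_rate(7.6))
  expect_equal(tst_rate(7.6, kappa = 3.5), 3.5 * tst_rate(7.6))
  expect_error(tst_rate(7.6, sigma = 1.5), "sigma")
  expect_error(tst_rate(7.6, kappa = 0.5), "kappa")
  expect_error(tst_rate(7.6, temperature = -1), "temperature")
})

test_that("TST rate is monotone decreasing in the barrier and increasing in T", {
  set.seed(19)
  for (i in 1:20) {
    T0 <- runif(1, 250, 400)
    dg <- sort(runif(6, 0.5, 25))
    k <- tst_rate(dg, temperature = T0)
    expect_true(all(diff(k) < 0))
    temps <- sort(runif(6, 200, 500))
    k2 <- vapply(temps, function(tt) tst_rate(dg[3], tt), numeric(1))
    expect_true(all(diff(k2) > 0))
  }
})

test_that("ln k is affine in 1/T and agrees with an independent Eyring-form evaluation", {
  # fixed activation enthalpy/entropy; dG(T) = dH - T dS
  dH <- 8.0       # kcal/mol
  dS <- -0.004    # kcal/mol/K
  temps <- seq(250, 450, by = 25)
  k_tst <- vapply(temps, function(tt) tst_rate(dH - tt * dS, tt), numeric(1))
  # independent Eyring form with separately typed constants
  kB <- 1.380649e-23; h <- 6.62607015e-34; Rk <- 8.31446261815324 / 4184
  k_eyr <- (kB * temps / h) * exp(dS / Rk) * exp(-dH / (Rk * temps))
  expect_equal(k_tst, k_eyr, tolerance = 1e-12)
  # affine in 1/T after removing the prefactor's T dependence
  y <- log(k_tst / temps)
  fit <- stats::lm(y ~ I(1 / temps))
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
})

test_that("the rate table ranks the published reactions by barrier and flags the 4'-OH channel", {
  rt <- rate_table(table2_profiles())
  expect_equal(nrow(rt), 4)
  expect_match(rt$reaction[1], "4'-OH", fixed = TRUE)
  expect_true(rt$fastest[1] && rt$min_barrier[1])
  expect_equal(rt$delta_g_activation, c(7.6, 8.1, 8.3, 9.8))
  expect_equal(rt$delta_g_reaction, c(-31.1, -24.0, -21.2, -22.7))
  # ordering by computed k matches ordering by ascending barrier
  expect_true(all(diff(rt$rate_constant) < 0))
  # and matches the ordering of the published reference rate constants
  t2 <- table2_kinetics()
  expect_equal(rt$reaction,
               t2$reaction[order(-t2$k_ref)])
  # sigma map and Wigner-from-imaginary-frequency pathways
  sp <- make_pes(data.frame(reaction = "rw", barrier = 5,
                            reaction_energy = -10, imag_wavenumber = 1500))
  rw <- rate_table(list(build_pes(sp)))
  expect_equal(rw$kappa, wigner_kappa(1500, 298.15))
  single <- rate_table(build_pes(make_pes(data.frame(
    reaction = "solo", barrier = 3, reaction_energy = -5))))
  expect_equal(nrow(single), 1)
  expect_true(single$fastest)
})
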