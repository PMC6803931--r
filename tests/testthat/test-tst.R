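kc <- kin_constants()

test_that("partition functions match textbook closed forms", {
  a <- species("H", mass_amu = 1.008, geometry = "atom", degeneracy = 2)
  qa <- partition_functions(a, 298.15)
  expect_equal(qa$q_rot, 1)
  expect_equal(qa$q_vib, 1)
  expect_equal(qa$g_elec, 2)
  # translational density of states, direct formula
  m <- 1.008e-3 / kc$N_A
  expect_equal(qa$q_trans_per_V, (2 * pi * m * kc$kB * 298.15 / kc$h^2)^1.5)

  co <- species("CO", mass_amu = 28.01, geometry = "linear",
                rotational_constants_cm1 = 1.9313, sigma = 1,
                frequencies_cm1 = 2143)
  q <- partition_functions(co, 298.15)
  expect_equal(q$q_rot, 107.3, tolerance = 1e-3)     # T/(c2*B)
  expect_equal(q$q_vib, 1.0000323, tolerance = 1e-6) # ZPE-referenced
})

test_that("closed-form q_vib equals a brute-force sum over harmonic levels", {
  # lowest mode kept above ~200 1/cm so 200 harmonic levels exhaust the
  # geometric series to better than 1e-10 of the total at 2000 K
  freqs <- c(220.5, 800, 1500.25, 3100)
  sp <- species("toy", mass_amu = 20, geometry = "nonlinear",
                rotational_constants_cm1 = c(1, 1, 1),
                frequencies_cm1 = freqs)
  for (T in c(150, 298.15, 1000, 2000)) {
    brute <- prod(vapply(freqs, function(f)
      sum(exp(-(0:200) * kc$c2 * f / T)), numeric(1)))
    expect_equal(partition_functions(sp, T)$q_vib, brute,
                 tolerance = 1e-10)
  }
})

test_that("species invariants are enforced", {
  expect_error(species("bad", 10, "atom", frequencies_cm1 = 100),
               "atom")
  expect_error(species("bad", 10, "linear",
                       rotational_constants_cm1 = c(1, 2, 3)),
               "exactly one")
  expect_error(species("bad", 10, "nonlinear",
                       rotational_constants_cm1 = c(1, 2)), "three")
  expect_error(species("bad", 10, "nonlinear",
                       rotational_constants_cm1 = c(1, 2, 3),
                       frequencies_cm1 = -5), "positive real")
})

test_that("TST reduces to the universal frequency factor when the Q-ratio is forced", {
  sys <- synth_reaction_system("toy_unimolecular")
  sys$ts$electronic_energy <- 0  # eps = 0 with ZPE disabled
  k0 <- tst_rate(sys, 298.15, zpe_corrected = FALSE, force_q_ratio = 1)
  expect_equal(k0, kc$kB * 298.15 / kc$h, tolerance = 1e-9)
  expect_equal(k0, 6.2124e12, tolerance = 1e-4)
  # one decade forced by eps = RT ln 10
  sys$ts$electronic_energy <- kc$R_J * 298.15 * log(10)
  k1 <- tst_rate(sys, 298.15, zpe_corrected = FALSE, force_q_ratio = 1)
  expect_equal(k1, k0 / 10, tolerance = 1e-9)
})

test_that("the rate is linear in the transition-state degeneracy", {
  sys <- synth_reaction_system("toy_bimolecular")
  k1 <- tst_rate(sys, 400)
  sys$ts$degeneracy <- sys$ts$degeneracy * 2
  expect_equal(tst_rate(sys, 400), 2 * k1, tolerance = 1e-12)
})

test_that("bimolecular units: molar rate is N_A times the per-molecule rate", {
  sys <- synth_reaction_system("toy_bimolecular")
  k_molec <- tst_rate(sys, c(300, 600), units = "molecule")
  k_molar <- tst_rate(sys, c(300, 600), units = "molar")
  expect_equal(k_molar, k_molec * kc$N_A, tolerance = 1e-12)
})

test_that("d-TST deformation and deformed factor match direct arithmetic", {
  sys <- synth_reaction_system("toy_unimolecular")
  # force h*nu = eps so d = -1/12 exactly
  eps_cal <- barrier_height(sys, zpe_corrected = FALSE)
  sys$nu_imag_cm1 <- eps_cal / kc$cm1_to_cal_mol
  d <- dtst_rate(sys, 300, zpe_corrected = FALSE)$d
  expect_equal(d, -1 / 12, tolerance = 1e-12)
  # deformed factor vs classical at eps/(R T) = 1: (1 + 1/12)^(-12)
  Tstar <- eps_cal / kc$R_cal
  kd <- dtst_rate(sys, Tstar, zpe_corrected = FALSE, force_q_ratio = 1)$k
  ktst <- tst_rate(sys, Tstar, zpe_corrected = FALSE, force_q_ratio = 1)
  expect_equal(kd / (kc$kB * Tstar / kc$h), (1 + 1 / 12)^(-12),
               tolerance = 1e-10)
  expect_equal(ktst / (kc$kB * Tstar / kc$h), exp(-1), tolerance = 1e-10)
  expect_equal(kd / ktst, 1.040, tolerance = 1e-3)  # mild tunneling boost
})

test_that("d-TST collapses onto TST as the imaginary frequency vanishes", {
  sys <- synth_reaction_system("toy_unimolecular")
  sys$nu_imag_cm1 <- 1e-6
  T <- c(250, 400, 800)
  expect_equal(dtst_rate(sys, T)$k, tst_rate(sys, T), tolerance = 1e-9)
})

test_that("d-TST is sub-Arrhenius: concave ln k vs beta", {
  sys <- synth_reaction_system("deep_tunnel")
  T <- seq(250, 800, length.out = 9)
  beta <- 1 / (kc$R_cal * T)
  lnk <- log(dtst_rate(sys, T)$k)
  # discrete second derivative along a strictly monotone beta grid
  curv <- diff(diff(lnk) / diff(beta)) / diff(beta[-1])
  expect_true(all(curv > 0))
})

test_that("d-TST refuses a nonpositive barrier", {
  sys <- synth_reaction_system("toy_unimolecular")
  sys$ts$electronic_energy <- -1000
  expect_error(dtst_rate(sys, 300, zpe_corrected = FALSE),
               "positive barrier")
})

test_that("thermochemistry from species energies matches the declared enthalpy", {
  sys <- synth_reaction_system("toy_bimolecular")
  dH <- reaction_enthalpy(sys, zpe_corrected = FALSE)
  expect_equal(dH, sys$dH_cal_mol, tolerance = 1e-6)
})

test_that("energy overrides replace electronic energies only", {
  sys <- synth_reaction_system("toy_unimolecular")
  eps0 <- barrier_height(sys, zpe_corrected = FALSE)
  sys$energy_override <- list(
    ts = list(value = 50000, units = "J/mol"))
  expect_equal(barrier_height(sys, zpe_corrected = FALSE),
               50000 / kc$cal_to_J, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(eps0, barrier_height(sys, FALSE))))
})
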