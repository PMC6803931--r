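kc <- kin_constants()

test_that("crossover temperature and regime windows partition the axis", {
  cr <- crossover_and_regime(1000, 300)
  expect_equal(cr$Tc, kc$c2 * 1000 / pi, tolerance = 1e-12)
  expect_equal(cr$Tc, 458.0, tolerance = 1e-3)
  Tc <- cr$Tc
  expect_equal(as.character(crossover_and_regime(1000, 3 * Tc)$regime),
               "negligible")
  expect_equal(as.character(crossover_and_regime(1000, 1.5 * Tc)$regime),
               "small")
  expect_equal(as.character(crossover_and_regime(1000, 0.75 * Tc)$regime),
               "moderate")
  expect_equal(as.character(crossover_and_regime(1000, 0.4 * Tc)$regime),
               "deep")
  # exact partition of (0, 10 Tc]: every temperature in exactly one window
  Tgrid <- seq(1e-3, 10 * Tc, length.out = 2000)
  reg <- crossover_and_regime(1000, Tgrid)$regime
  expect_false(anyNA(reg))
  expect_setequal(levels(reg), c("deep", "moderate", "small", "negligible"))
  # boundaries: deep window is T <= Tc/2
  eps <- 1e-9
  expect_equal(as.character(crossover_and_regime(1000, Tc / 2)$regime),
               "deep")
  expect_equal(as.character(crossover_and_regime(1000, Tc / 2 + eps)$regime),
               "moderate")
  expect_equal(as.character(crossover_and_regime(1000, Tc)$regime),
               "moderate")
  expect_equal(as.character(crossover_and_regime(1000, 2 * Tc)$regime),
               "small")
})

test_that("the Bell-1958 leading term matches its closed form at the regime boundary", {
  Tc <- crossover_and_regime(1000, 300)$Tc
  # at T = 2 Tc the argument is pi/4
  expect_equal(tunneling_kappa("bell58_1t", 1000, 5000, 2 * Tc),
               (pi / 4) / sin(pi / 4), tolerance = 1e-9)
  expect_equal(tunneling_kappa("bell58_1t", 1000, 5000, 2 * Tc),
               1.1107, tolerance = 1e-4)
})

test_that("all tunneling corrections approach unity at high temperature", {
  nu <- 1200; eps <- 8000
  Thot <- 1e6
  for (m in c("bell35", "bell58_1t", "bell58_2t"))
    expect_equal(tunneling_kappa(m, nu, eps, Thot), 1, tolerance = 1e-3,
                 label = m)
  expect_equal(tunneling_kappa("st", nu, eps, Thot, dH_cal_mol = -3000), 1,
               tolerance = 1e-3)
})

test_that("kappa >= 1 below 2 Tc for the Bell-1958 leading term", {
  nu <- 1000
  Tc <- crossover_and_regime(nu, 300)$Tc
  T <- seq(0.55 * Tc, 2 * Tc, length.out = 20)
  kap <- tunneling_kappa("bell58_1t", nu, 5000, T)
  expect_true(all(kap >= 1))
  # corrected rate therefore exceeds plain TST there
  sys <- synth_reaction_system("deep_tunnel")
  Tc2 <- crossover_and_regime(sys$nu_imag_cm1, 300)$Tc
  Tw <- seq(0.6 * Tc2, 1.9 * Tc2, length.out = 5)
  expect_true(all(corrected_rate(sys, Tw, "bell58_1t") >=
                  tst_rate(sys, Tw)))
})

test_that("the Bell-1958 pole at Tc/2 is detected and refused, naming Tc", {
  nu <- 1000
  Tc <- crossover_and_regime(nu, 300)$Tc
  expect_error(tunneling_kappa("bell58_1t", nu, 5000, Tc / 2),
               "crossover temperature")
  expect_error(tunneling_kappa("bell58_1t", nu, 5000, 0.3 * Tc), "Tc")
  # the error names the computed crossover temperature
  err <- tryCatch(tunneling_kappa("bell58_1t", nu, 5000, Tc / 2),
                  error = conditionMessage)
  expect_match(err, sprintf("%.4g", Tc))
})

test_that("Bell-1935 stays finite through its removable point and exceeds 1 at moderate T", {
  nu <- 1000; eps <- 5000
  # removable point: kB T = hbar nu
  Trem <- kc$cm1_to_cal_mol * nu / (2 * pi) / kc$R_cal
  kap_rem <- tunneling_kappa("bell35", nu, eps, Trem)
  expect_true(is.finite(kap_rem))
  near <- tunneling_kappa("bell35", nu, eps, Trem * (1 + 1e-5))
  expect_equal(kap_rem, near, tolerance = 1e-3)
  expect_gt(tunneling_kappa("bell35", nu, eps, 2 * Trem), 1)
})

test_that("Skodje-Truhlar is pole-free with a finite branch mismatch at Tc", {
  nu <- 1500; eps <- 6000; dH <- -2000
  Tc <- crossover_and_regime(nu, 300)$Tc
  # dense sweep through Tc/2 and Tc: no divergence anywhere
  T <- seq(0.2 * Tc, 3 * Tc, length.out = 400)
  kap <- tunneling_kappa("st", nu, eps, T, dH)
  expect_true(all(is.finite(kap)))
  expect_true(all(kap > 0))
  # branch mismatch at T = Tc is finite and modest
  k_lo <- tunneling_kappa("st", nu, eps, Tc * (1 - 1e-9), dH)
  k_hi <- tunneling_kappa("st", nu, eps, Tc * (1 + 1e-9), dH)
  expect_true(is.finite(k_lo) && is.finite(k_hi))
  expect_lt(abs(k_lo / k_hi - 1), 0.5)
  expect_error(tunneling_kappa("st", nu, eps, 300), "dH")
  # deep branch grows with cooling (tunneling-dominated)
  expect_gt(tunneling_kappa("st", nu, eps, 0.3 * Tc, dH),
            tunneling_kappa("st", nu, eps, 0.9 * Tc, dH))
})

test_that("corrected_rate dispatches to its components", {
  sys <- synth_reaction_system("toy_bimolecular")
  T <- c(400, 800)
  expect_equal(corrected_rate(sys, T, "none"), tst_rate(sys, T))
  expect_equal(corrected_rate(sys, T, "dtst"), dtst_rate(sys, T)$k)
  eps <- barrier_height(sys)
  expect_equal(corrected_rate(sys, T, "bell35"),
               tunneling_kappa("bell35", sys$nu_imag_cm1, eps, T) *
                 tst_rate(sys, T))
  # far above Tc the corrections decay to 1: the Bell-1958/ST family like
  # (h nu / kB T)^2, Bell-1935 only like h nu/(2 pi kB T), so the latter
  # needs a larger temperature multiple for the same 2% closeness
  Tc <- crossover_and_regime(sys$nu_imag_cm1, 300)$Tc
  for (m in c("bell58_1t", "bell58_2t", "st"))
    expect_equal(corrected_rate(sys, 10 * Tc, m) / tst_rate(sys, 10 * Tc),
                 1, tolerance = 0.02, label = m)
  expect_equal(corrected_rate(sys, 30 * Tc, "bell35") /
                 tst_rate(sys, 30 * Tc), 1, tolerance = 0.02)
  # and the documented first-order tail of Bell-1935: kappa - 1 ~ b/a
  kcl <- kin_constants()
  eps_b <- barrier_height(sys)
  for (Tbig in c(20, 40) * Tc) {
    ba <- kcl$cm1_to_cal_mol * sys$nu_imag_cm1 / (2 * pi) /
      (kcl$R_cal * Tbig)
    expect_equal(tunneling_kappa("bell35", sys$nu_imag_cm1, eps_b, Tbig) - 1,
                 ba, tolerance = 0.05)
  }
})
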