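kc <- kin_constants()

test_that("the water viscosity law evaluates and bounds its domain", {
  w <- solvent_model()
  expect_equal(am_viscosity(w, 298.15), 8.5635e-3, tolerance = 1e-4)
  # T -> infinity: eta -> eta0
  expect_equal(am_viscosity(w, 1e9), 2.7024e-4, tolerance = 1e-5)
  expect_error(am_viscosity(w, 213), "T\\*")
  expect_error(am_viscosity(w, 150), "T\\*")
  # deformed-exponential parametrization agrees with a direct power law
  # built to mimic it at one temperature
  am <- solvent_model("generic", eta0 = 1e-3, parametrization = "am",
                      eps_J_mol = 12000, d_visc = -0.5)
  x <- 12000 / (kc$R_J * 300)
  expect_equal(am_viscosity(am, 300), 1e-3 * (1 + 0.5 * x)^(-2),
               tolerance = 1e-12)
})

test_that("Stokes-Einstein diffusion and the Smoluchowski limit match cgs arithmetic", {
  w <- solvent_model()
  T <- 298.15
  eta <- am_viscosity(w, T)
  # radius chosen so the reference D ~ 1.7e-5 cm^2/s
  r <- 1.5e-8
  D_ref <- (kc$kB * 1e7) * T / (6 * pi * eta * r)
  expect_equal(D_ref, 1.70e-5, tolerance = 5e-3)
  # volumes that produce that radius: V = 4/3 pi r^3 N_A
  V <- 4 / 3 * pi * r^3 * kc$N_A
  ck <- collins_kimball_rate(1e11, V, V, w, T)
  expect_equal(ck$r_A, r, tolerance = 1e-12)
  expect_equal(ck$D_A, D_ref, tolerance = 1e-12)
  expect_equal(ck$D_AB, ck$D_A + ck$D_B, tolerance = 1e-15)
  expect_equal(ck$r_AB, ck$r_A + ck$r_B, tolerance = 1e-15)
  # k_D = 4 pi r_AB D_AB N_A; frozen from hand cgs arithmetic
  expect_equal(4 * pi * 3e-8 * 3.4e-5 * kc$N_A, 7.72e12, tolerance = 1e-3)
  expect_equal(ck$k_D, 4 * pi * ck$r_AB * ck$D_AB * kc$N_A,
               tolerance = 1e-12)
})

test_that("Collins-Kimball is the harmonic combination with the right limits", {
  w <- solvent_model()
  V <- 30
  ck <- collins_kimball_rate(1e11, V, V, w, 298.15)
  expect_equal(1 / ck$k_obs, 1 / ck$k_tst + 1 / ck$k_D, tolerance = 1e-12)
  expect_lte(ck$k_obs, min(ck$k_tst, ck$k_D))
  # k_tst = k_D gives exactly half
  ck2 <- collins_kimball_rate(ck$k_D, V, V, w, 298.15)
  expect_equal(ck2$k_obs, ck$k_D / 2, tolerance = 1e-12)
  # activation control: k_obs -> k_tst when k_tst << k_D
  ck3 <- collins_kimball_rate(ck$k_D * 1e-8, V, V, w, 298.15)
  expect_equal(ck3$k_obs / ck3$k_tst, 1, tolerance = 1e-6)
  # diffusion control: k_obs -> k_D when k_tst >> k_D
  ck4 <- collins_kimball_rate(ck$k_D * 1e8, V, V, w, 298.15)
  expect_equal(ck4$k_obs / ck$k_D, 1, tolerance = 1e-6)
  expect_error(collins_kimball_rate(1e11, NULL, V, w, 298.15), "volume")
})

test_that("per-molecule and molar routes to the diffusion limit agree", {
  w <- solvent_model()
  ck <- collins_kimball_rate(1e11, 25, 40, w, 298.15)
  k_per_molecule <- 4 * pi * ck$r_AB * ck$D_AB  # cm^3 molecule^-1 s^-1
  expect_equal(k_per_molecule * kc$N_A, ck$k_D, tolerance = 1e-12)
})

test_that("Kramers transmission matches closed-form checkpoints", {
  # mu = 0: frictionless limit is exact TST
  w0 <- solvent_model("inviscid", eta0 = 1e-300, parametrization = "direct",
                      T_star = 1e-6, exponent = 0)
  kr0 <- kramers_rate(1e11, 2e-8, 30, 1500, w0, 298.15)
  expect_equal(kr0$kappa_kr, 1, tolerance = 1e-12)
  # mu = 1.5 omega: kappa = sqrt(9/16 + 1) - 3/4 = 1/2 (3-4-5 triangle)
  mu_over_omega <- function(kr) kr$mu / kr$omega_imag
  # choose r so that mu = 1.5 omega at water viscosity
  omega <- 2 * pi * kc$c_cm * 1000
  eta <- am_viscosity(solvent_model(), 298.15)
  m_g <- 30 / kc$N_A
  r_target <- 1.5 * omega * m_g / (6 * pi * eta)
  kr <- kramers_rate(1e11, r_target, 30, 1000, solvent_model(), 298.15)
  expect_equal(mu_over_omega(kr), 1.5, tolerance = 1e-12)
  expect_equal(kr$kappa_kr, 0.5, tolerance = 1e-12)
  expect_equal(kr$k_obs, 0.5e11, tolerance = 1e-3)
  # high friction: kappa -> omega/mu
  kr_h <- kramers_rate(1e11, 100 * r_target, 30, 1000, solvent_model(),
                       298.15)
  expect_equal(kr_h$kappa_kr * mu_over_omega(kr_h), 1, tolerance = 1e-2)
  expect_error(kramers_rate(1e11, 2e-8, 30, -5, solvent_model(), 298.15),
               "positive")
})

test_that("Kramers transmission is strictly decreasing in friction and within (0, 1]", {
  omega_nu <- 1200
  radii <- 10^seq(-9, -6, length.out = 12)
  kaps <- vapply(radii, function(r)
    kramers_rate(1, r, 40, omega_nu, solvent_model(), 298.15)$kappa_kr,
    numeric(1))
  expect_true(all(diff(kaps) < 0))
  expect_true(all(kaps > 0 & kaps <= 1))
})

test_that("both solvent formulations agree when far from diffusion control", {
  # toy bimolecular reaction in water at 298.15 K with a stiff barrier
  # frequency and small cage radii: friction and diffusion corrections are
  # both mild, so the two observed rates sit within a few percent
  w <- solvent_model()
  T <- 298.15
  k_act <- 1e11  # cm^3 mol^-1 s^-1, well below the ~7e12 diffusion limit
  ck <- collins_kimball_rate(k_act, 20, 25, w, T)
  kr <- kramers_rate(k_act, 1.5e-8, 35, 2500, w, T)
  expect_gt(kr$kappa_kr, 0.94)
  expect_gt(ck$k_obs / k_act, 0.94)
  ratio <- ck$k_obs / kr$k_obs
  expect_lt(abs(log(ratio)), log(1.10))
})
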