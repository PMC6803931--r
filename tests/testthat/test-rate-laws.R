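test_that("rate laws reproduce directly evaluated reference values", {
  # frozen from direct evaluation with R = 1.98720... cal/(mol K)
  arr <- rate_law_params("arrhenius", A = 1.52e11, Ea = 14600)
  expect_equal(eval_rate_law(arr, 298.15), 3.019738, tolerance = 1e-6)

  am_anti <- rate_law_params("am", A = 7.43e-14, eps_dd = -324.61, d = 1.24)
  expect_equal(eval_rate_law(am_anti, 298.15), 1.128648e-13,
               tolerance = 1e-6)
  # negative apparent activation energy: anti-Arrhenius
  expect_equal(apparent_ea(am_anti, 298.15), -193.2927, tolerance = 1e-6)
  expect_lt(apparent_ea(am_anti, 298.15), 0)

  expect_equal(ascc_d(2441, 429), -2.573936e-3, tolerance = 1e-6)
  expect_equal(ascc_d(1000, 0), 0)
  expect_equal(ascc_d(500, 500), -1 / 12)  # E_nu = eps forces -(1/2)^2/3
})

test_that("the deformed exponential reduces to Arrhenius as d -> 0", {
  arr <- rate_law_params("arrhenius", A = 2.5e7, Ea = 3100)
  am <- rate_law_params("am", A = 2.5e7, eps_dd = 3100, d = 1e-10)
  T <- seq(220, 800, length.out = 11)
  expect_equal(eval_rate_law(am, T), eval_rate_law(arr, T),
               tolerance = 1e-6)
})

test_that("closed-form apparent Ea matches the finite-difference oracle for every law", {
  cases <- list(
    rate_law_params("arrhenius", A = 1e12, Ea = 5000),
    am_ref_params(),
    rate_law_params("am", A = 1.91e4, eps_dd = 2391, d = 0.207),
    rate_law_params("ascc", A = 2.33e4, eps_dd = 2441, E_nu = 429),
    rate_law_params("nts", A = 3.12e4, E0 = 1655, T0 = 168),
    rate_law_params("vft", A = 1.25e5, B = -1298, T0 = 175))
  grids <- list(c(250, 500), c(200, 1000), c(278, 338), c(100, 300),
                c(100, 300), c(278, 338))
  for (i in seq_along(cases)) {
    T <- seq(grids[[i]][1], grids[[i]][2], length.out = 9)
    expect_equal(apparent_ea(cases[[i]], T), fd_apparent_ea(cases[[i]], T),
                 tolerance = 1e-6,
                 label = sprintf("analytic Ea, %s", cases[[i]]$law))
  }
})

test_that("Arrhenius-plot curvature sign follows the AM deformation sign", {
  T <- seq(200, 800, length.out = 7)
  sub <- rate_law_params("am", A = 1e-10, eps_dd = 9170, d = -0.086)
  sup <- rate_law_params("am", A = 1.91e4, eps_dd = 2391, d = 0.207)
  expect_true(all(fd_lnk_curvature(sub, T) > 0))   # concave: sub-Arrhenius
  expect_true(all(fd_lnk_curvature(sup, seq(278, 338, length.out = 7)) < 0))
})

test_that("transitivity of the AM law is exactly affine in beta", {
  p <- rate_law_params("am", A = 1, eps_dd = 9170, d = -0.086)
  beta <- seq(1 / (R_CAL * 1000), 1 / (R_CAL * 200), length.out = 25)
  g <- transitivity_gamma(p, beta)
  # two-point affine interpolation must reproduce all points
  slope <- (g[25] - g[1]) / (beta[25] - beta[1])
  affine <- g[1] + slope * (beta - beta[1])
  expect_equal(g, affine, tolerance = 1e-12)
  expect_equal(slope, 0.086, tolerance = 1e-9)          # -d
  expect_equal(g[1] + slope * (0 - beta[1]), 1 / 9170,  # intercept
               tolerance = 1e-9)
  # d = 0 collapses to the constant 1/eps
  p0 <- rate_law_params("am", A = 1, eps_dd = 2500, d = 0)
  expect_equal(transitivity_gamma(p0, beta), rep(1 / 2500, 25))
  # Arrhenius: constant reciprocal
  pa <- rate_law_params("arrhenius", A = 1, Ea = 1000)
  expect_equal(transitivity_gamma(pa, beta), rep(1e-3, 25))
})

test_that("limiting equivalences: ascc, nts and vft collapse to simpler laws", {
  T <- seq(250, 600, length.out = 9)
  # ascc with E_nu -> 0 is Arrhenius with Ea = eps
  ascc0 <- rate_law_params("ascc", A = 3e4, eps_dd = 2441, E_nu = 1e-4)
  arr_e <- rate_law_params("arrhenius", A = 3e4, Ea = 2441)
  expect_equal(eval_rate_law(ascc0, T), eval_rate_law(arr_e, T),
               tolerance = 1e-6)
  # ascc equals AM with its derived d and shifted denominator at E_nu = 0
  am_eq <- rate_law_params("am", A = 3e4, eps_dd = 2441,
                           d = ascc_d(2441, 1e-4))
  expect_equal(eval_rate_law(ascc0, T), eval_rate_law(am_eq, T),
               tolerance = 1e-6)
  # nts -> Arrhenius as T0 -> 0
  nts0 <- rate_law_params("nts", A = 3.12e4, E0 = 1655, T0 = 1e-6)
  arr_n <- rate_law_params("arrhenius", A = 3.12e4, Ea = 1655)
  expect_equal(eval_rate_law(nts0, T), eval_rate_law(arr_n, T),
               tolerance = 1e-6)
  # vft -> Arrhenius as T0 -> 0 with B = -Ea/R
  vft0 <- rate_law_params("vft", A = 2e5, B = -5000 / R_CAL, T0 = 1e-8)
  arr_v <- rate_law_params("arrhenius", A = 2e5, Ea = 5000)
  expect_equal(eval_rate_law(vft0, T), eval_rate_law(arr_v, T),
               tolerance = 1e-6)
})

test_that("support violations raise domain errors instead of silent zeros", {
  # AM with d > 0 loses support at low T where d*eps*beta >= 1
  p <- rate_law_params("am", A = 1, eps_dd = 2391, d = 0.207)
  Tbad <- 2391 * 0.207 / R_CAL  # base exactly 0
  expect_error(eval_rate_law(p, Tbad * 0.9), "support")
  expect_error(eval_rate_law(rate_law_params("vft", A = 1, B = -100, T0 = 175),
                             150), "T > T0")
  expect_error(apparent_ea(p, Tbad * 0.9), "support")
  # singular transitivity at Ea = 0 (anti-Arrhenius NTS-like edge: Ea=0
  # impossible for these laws except E0=0)
  p0 <- rate_law_params("nts", A = 1, E0 = 0, T0 = 100)
  expect_error(transitivity_gamma(p0, 1 / (R_CAL * 300)), "singular")
})

test_that("parameter records are validated and serialize round-trip", {
  expect_error(rate_law_params("am", A = 1, Ea = 100), "requires fields")
  expect_error(rate_law_params("arrhenius", A = 1, Ea = 100, d = 1),
               "not belonging")
  expect_error(rate_law_params("ascc", A = 1, eps_dd = 0, E_nu = 5),
               "eps_dd != 0")
  p <- rate_law_params("nts", A = 3.12e4, E0 = 1655, T0 = 168)
  expect_equal(params_from_list(params_to_list(p)), p)
})
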