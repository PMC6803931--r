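#' Synthetic rate-constant series
#'
#' Deterministic generator: evaluates a rate law on a temperature grid and
#' optionally multiplies by lognormal noise, exp(N(0, sigma^2)), from a
#' seeded generator. Same arguments and seed give an identical series.
#' Multiplicative lognormal noise keeps rates positive and matches the
#' log-space fit objective.
#'
#' @param params a [rate_law_params()]
#' @param T_range length-2 temperature range, K (used with `n`)
#' @param n number of points, uniform in T over `T_range`
#' @param T_grid explicit temperature grid (overrides `T_range`/`n`)
#' @param noise "none" or "lognormal"
#' @param sigma log-sd of the lognormal noise
#' @param seed integer seed for the noise
#' @param units,label passed to [rate_series()]
#' @return a [rate_series()]
#' @examples
#' p <- rate_law_params("am", A = 1.11e-10, eps_dd = 9170, d = -0.086)
#' synth_rate_series(p, T_range = c(200, 1000), n = 30)
#' @export
synth_rate_series <- function(params, T_range = NULL, n = 30L, T_grid = NULL,
                              noise = c("none", "lognormal"), sigma = 0.05,
                              seed = 1L, units = "arbitrary", label = "") {
  noise <- match.arg(noise)
  stopifnot(inherits(params, "rate_law_params"))
  T <- if (!is.null(T_grid)) sort(as.numeric(T_grid))
       else seq(T_range[1], T_range[2], length.out = n)
  k <- eval_rate_law(params, T)
  if (noise == "lognormal") {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    k <- k * exp(stats::rnorm(length(k), 0, sigma))
  }
  rate_series(T, k, units = units, label = label)
}

#' Bundled benchmark parameter sets
#'
#' Published phenomenological fits for four prototype thermally activated
#' processes spanning the non-Arrhenius taxonomy: keto--enol tautomerization
#' of a benzoxazole (sub-Arrhenius, deep tunneling), the OH + H2 -> H + H2O
#' abstraction (sub-Arrhenius, moderate tunneling), an enzymatic hydride
#' transfer to NAD+ (super-Arrhenius), and OH + HBr -> Br + H2O
#' (anti-Arrhenius). Energies are in cal/mol, temperatures in K;
#' pre-exponential units follow the source data and are carried opaquely.
#' Each entry holds the fitted laws and the temperature window the process
#' was characterized in, and drives the package's parameter-recovery
#' self-tests: synthesize noise-free k(T) from these values, refit, and the
#' optimizer must return them.
#'
#' @return named list; each element has `label`, `T_range` and `laws` (a
#'   named list of [rate_law_params()])
#' @examples
#' benchmark_params()$oh_h2$laws$am
#' @export
benchmark_params <- function() {
  list(
    keto_enol = list(
      label = "keto-enol tautomerization (sub-Arrhenius, deep tunneling)",
      T_range = c(100, 300),
      laws = list(
        arrhenius = rate_law_params("arrhenius", A = 1.74e3, Ea = 214),
        am = rate_law_params("am", A = 3.32e6, eps_dd = 318.06, d = -0.81),
        ascc = rate_law_params("ascc", A = 2.33e4, eps_dd = 2441, E_nu = 429),
        nts = rate_law_params("nts", A = 3.12e4, E0 = 1655, T0 = 168))),
    oh_h2 = list(
      label = "OH + H2 -> H + H2O (sub-Arrhenius, moderate tunneling)",
      T_range = c(200, 1000),
      laws = list(
        arrhenius = rate_law_params("arrhenius", A = 2.16e-11, Ea = 4891),
        am = rate_law_params("am", A = 1.11e-10, eps_dd = 9170, d = -0.086))),
    enzymatic = list(
      label = "enzymatic hydride transfer to NAD+ (super-Arrhenius)",
      T_range = c(278, 338),
      laws = list(
        arrhenius = rate_law_params("arrhenius", A = 1.52e11, Ea = 14600),
        am = rate_law_params("am", A = 1.91e4, eps_dd = 2391, d = 0.207),
        vft = rate_law_params("vft", A = 1.25e5, B = -1298, T0 = 175))),
    oh_hbr = list(
      label = "OH + HBr -> Br + H2O (anti-Arrhenius)",
      T_range = c(120, 360),
      laws = list(
        arrhenius = rate_law_params("arrhenius", A = 1.66e-11, Ea = -94.6),
        am = rate_law_params("am", A = 7.43e-14, eps_dd = -324.61, d = 1.24))))
}

#' Toy reaction systems with hand-auditable partition functions
#'
#' Small fabricated systems (2--4 atoms, few modes) for exercising the TST,
#' tunneling and solution modules without external electronic-structure
#' inputs. Energies are synthetic. Templates:
#' \describe{
#'   \item{toy_unimolecular}{one nonlinear molecule isomerizing over a
#'     10 kcal/mol electronic barrier, nu‡ = 1200 1/cm.}
#'   \item{toy_bimolecular}{atom + linear diatomic through a linear TS with
#'     molar volumes set, 4 kcal/mol barrier, nu‡ = 1400 1/cm; products
#'     included so the thermochemistry cross-check has both routes.}
#'   \item{deep_tunnel}{hydrogen-transfer-like system with nu‡ = 1500 1/cm,
#'     putting the crossover temperature near 687 K so room temperature sits
#'     in the deep-tunneling window.}
#' }
#'
#' @param template one of "toy_unimolecular", "toy_bimolecular",
#'   "deep_tunnel"
#' @return a [reaction_system()]
#' @export
synth_reaction_system <- function(template = c("toy_unimolecular",
                                               "toy_bimolecular",
                                               "deep_tunnel")) {
  template <- match.arg(template)
  kc <- .kc
  kcal <- function(x) x * 1000 * kc$cal_to_J  # kcal/mol -> J/mol
  switch(template,
    toy_unimolecular = {
      r <- species("reactant", mass_amu = 30, geometry = "nonlinear",
                   rotational_constants_cm1 = c(2.0, 1.5, 1.0), sigma = 1,
                   frequencies_cm1 = c(500, 1000, 1500),
                   electronic_energy = 0, energy_units = "J/mol",
                   molar_volume_cm3 = 40)
      ts <- species("ts", mass_amu = 30, geometry = "nonlinear",
                    rotational_constants_cm1 = c(1.8, 1.4, 0.9), sigma = 1,
                    frequencies_cm1 = c(600, 1100),
                    electronic_energy = kcal(10), energy_units = "J/mol",
                    molar_volume_cm3 = 40)
      reaction_system(list(r), ts, nu_imag_cm1 = 1200)
    },
    toy_bimolecular = {
      a <- species("atom_A", mass_amu = 1.008, geometry = "atom",
                   degeneracy = 2, electronic_energy = 0,
                   energy_units = "J/mol", molar_volume_cm3 = 15)
      bc <- species("diatom_BC", mass_amu = 28, geometry = "linear",
                    rotational_constants_cm1 = 1.9313, sigma = 1,
                    frequencies_cm1 = 2143, electronic_energy = 0,
                    energy_units = "J/mol", molar_volume_cm3 = 35)
      ts <- species("ts_ABC", mass_amu = 29.008, geometry = "linear",
                    rotational_constants_cm1 = 1.2, sigma = 1,
                    frequencies_cm1 = c(800, 800, 2000),
                    electronic_energy = kcal(4), energy_units = "J/mol",
                    molar_volume_cm3 = 45)
      p1 <- species("diatom_AB", mass_amu = 2.016, geometry = "linear",
                    rotational_constants_cm1 = 30, sigma = 1,
                    frequencies_cm1 = 3500, electronic_energy = kcal(-6),
                    energy_units = "J/mol")
      p2 <- species("atom_C", mass_amu = 26.992, geometry = "atom",
                    degeneracy = 1, electronic_energy = 0,
                    energy_units = "J/mol")
      reaction_system(list(a, bc), ts, products = list(p1, p2),
                      nu_imag_cm1 = 1400, dH_cal_mol = -6000)
    },
    deep_tunnel = {
      r <- species("h_donor", mass_amu = 46, geometry = "nonlinear",
                   rotational_constants_cm1 = c(1.0, 0.8, 0.5), sigma = 1,
                   frequencies_cm1 = c(300, 900, 1400, 3000),
                   electronic_energy = 0, energy_units = "J/mol",
                   molar_volume_cm3 = 55)
      ts <- species("h_transfer_ts", mass_amu = 46, geometry = "nonlinear",
                    rotational_constants_cm1 = c(1.0, 0.8, 0.5), sigma = 1,
                    frequencies_cm1 = c(350, 950, 1350),
                    electronic_energy = kcal(6), energy_units = "J/mol",
                    molar_volume_cm3 = 55)
      reaction_system(list(r), ts, nu_imag_cm1 = 1500, dH_cal_mol = -2000)
    })
}

#' Fabricated quantum-chemistry frequency log
#'
#' Writes a minimal Gaussian-style frequency-output text containing exactly
#' the blocks [load_species()] reads (multiplicity, SCF energy, rotational
#' constants in GHz, symmetry number, frequencies with the imaginary mode as
#' a negative entry, molecular mass, optional molar volume), so that
#' `load_species(synth_qc_log(sp))` round-trips the species. A synthetic
#' stand-in for real electronic-structure output, for testing the extractor.
#'
#' @param sp a [species()]
#' @param nu_imag_cm1 optional imaginary-mode magnitude to embed as a
#'   negative frequency (transition states)
#' @param path optional file path; when given the text is written there
#' @return character vector of log lines (invisibly, when `path` is given)
#' @export
synth_qc_log <- function(sp, nu_imag_cm1 = NULL, path = NULL) {
  stopifnot(inherits(sp, "kin_species"))
  ghz <- function(b_cm1) b_cm1 * .kc$c_cm * 1e-9  # 1/cm -> GHz
  lines <- c(
    " Entering Gaussian-style synthetic frequency output.",
    sprintf(" Charge =  0 Multiplicity = %d", as.integer(sp$degeneracy)),
    sprintf(" SCF Done:  E(synth) = %18.9f     A.U. after   10 cycles",
            if (sp$energy_units == "hartree") sp$electronic_energy
            else sp$electronic_energy / .kc$hartree_J_mol))
  if (sp$geometry != "atom") {
    rc <- switch(sp$geometry,
      linear = c(0, rep(ghz(sp$rotational_constants_cm1), 2)),
      nonlinear = ghz(sp$rotational_constants_cm1))
    lines <- c(lines,
      sprintf(" Rotational constants (GHZ):%14.7f%14.7f%14.7f",
              rc[1], rc[2], rc[3]))
  }
  freqs <- sp$frequencies_cm1
  if (!is.null(nu_imag_cm1)) freqs <- c(-abs(nu_imag_cm1), freqs)
  if (length(freqs)) {
    for (i in seq(1, length(freqs), by = 3)) {
      chunk <- freqs[i:min(i + 2, length(freqs))]
      lines <- c(lines,
        paste0(" Frequencies --", paste(sprintf("%12.4f", chunk),
                                        collapse = "")))
    }
  }
  lines <- c(lines,
    sprintf(" Rotational symmetry number %2d.", as.integer(sp$sigma)),
    sprintf(" Molecular mass: %11.5f amu.", sp$mass_amu))
  if (!is.null(sp$molar_volume_cm3))
    lines <- c(lines,
      sprintf(" Molar volume = %10.3f cm**3/mol", sp$molar_volume_cm3))
  lines <- c(lines, " Normal termination of synthetic output.")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
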