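#' Molecular species for partition-function kinetics
#'
#' Rigid-rotor / harmonic-oscillator / ideal-gas description of a stationary
#' point. Symmetry number and electronic degeneracy are explicit fields with
#' defaults of 1 and are never inferred from the geometry (silent symmetry
#' inference is a classic source of factor-of-two errors).
#'
#' @param name species label
#' @param mass_amu molecular mass, amu
#' @param geometry "atom", "linear" or "nonlinear"
#' @param rotational_constants_cm1 rotational constant(s) in 1/cm: one value
#'   for a linear rotor, three for a nonlinear top; `NULL` for an atom
#' @param sigma rotational symmetry number, >= 1
#' @param frequencies_cm1 real vibrational wavenumbers, 1/cm (none for atoms)
#' @param electronic_energy electronic energy of the stationary point
#' @param energy_units "hartree" or "J/mol"
#' @param degeneracy electronic degeneracy (spin multiplicity), positive
#'   integer
#' @param molar_volume_cm3 optional molar volume, cm^3/mol (needed by the
#'   solution-kinetics module)
#' @return object of class `kin_species`
#' @export
species <- function(name, mass_amu, geometry = c("nonlinear", "linear", "atom"),
                    rotational_constants_cm1 = NULL, sigma = 1,
                    frequencies_cm1 = numeric(0), electronic_energy = 0,
                    energy_units = c("hartree", "J/mol"), degeneracy = 1,
                    molar_volume_cm3 = NULL) {
  geometry <- match.arg(geometry)
  energy_units <- match.arg(energy_units)
  stopifnot(is.numeric(mass_amu), mass_amu > 0, sigma >= 1, degeneracy >= 1)
  if (length(frequencies_cm1) && any(frequencies_cm1 <= 0))
    stop("frequencies must be positive real wavenumbers (imaginary modes are not Species fields)")
  if (geometry == "atom") {
    if (length(frequencies_cm1) || !is.null(rotational_constants_cm1))
      stop("an atom has no frequencies and no rotational constants")
  } else {
    nrc <- length(rotational_constants_cm1)
    if (geometry == "linear" && nrc != 1L)
      stop("linear rotor needs exactly one rotational constant")
    if (geometry == "nonlinear" && nrc != 3L)
      stop("nonlinear rotor needs three rotational constants")
    if (any(rotational_constants_cm1 <= 0))
      stop("rotational constants must be positive")
  }
  if (!is.null(molar_volume_cm3)) stopifnot(molar_volume_cm3 > 0)
  structure(list(name = as.character(name), mass_amu = mass_amu,
                 geometry = geometry,
                 rotational_constants_cm1 = rotational_constants_cm1,
                 sigma = sigma, frequencies_cm1 = as.numeric(frequencies_cm1),
                 electronic_energy = electronic_energy,
                 energy_units = energy_units, degeneracy = degeneracy,
                 molar_volume_cm3 = molar_volume_cm3),
            class = "kin_species")
}

#' @export
print.kin_species <- function(x, ...) {
  cat(sprintf("<kin_species '%s': %s, %.4f amu, %d modes, sigma=%g, g=%g>\n",
              x$name, x$geometry, x$mass_amu, length(x$frequencies_cm1),
              x$sigma, x$degeneracy))
  invisible(x)
}

# electronic energy in J/mol, honouring an override (value + units pair)
.energy_J_mol <- function(sp, override = NULL) {
  e <- sp$electronic_energy; u <- sp$energy_units
  if (!is.null(override)) {
    e <- override$value
    u <- if (is.null(override$units)) "hartree" else override$units
  }
  if (u == "hartree") e * .kc$hartree_J_mol else e
}

.zpe_J_mol <- function(sp) {
  if (!length(sp$frequencies_cm1)) return(0)
  0.5 * sum(sp$frequencies_cm1) * .kc$cm1_to_cal_mol * .kc$cal_to_J
}

#' Reaction system: reactants, transition state and optional products
#'
#' @param reactants list of one or two [species()] (sets the molecularity)
#' @param ts transition-state [species()] (real modes only; the imaginary
#'   mode enters as `nu_imag_cm1`)
#' @param products optional list of [species()] (enables the thermochemistry
#'   cross-check)
#' @param nu_imag_cm1 magnitude of the imaginary-mode wavenumber, 1/cm, > 0
#' @param dH_cal_mol optional reaction enthalpy, cal/mol (required by the
#'   Skodje--Truhlar correction; 0 allowed)
#' @param energy_override optional named list (names = species names) of
#'   lists `list(value=, units=)` replacing electronic energies with
#'   higher-level single points
#' @return object of class `reaction_system`
#' @export
reaction_system <- function(reactants, ts, products = NULL, nu_imag_cm1,
                            dH_cal_mol = NULL, energy_override = NULL) {
  if (inherits(reactants, "kin_species")) reactants <- list(reactants)
  stopifnot(is.list(reactants), length(reactants) %in% 1:2,
            all(vapply(reactants, inherits, TRUE, "kin_species")),
            inherits(ts, "kin_species"),
            is.numeric(nu_imag_cm1), nu_imag_cm1 > 0)
  if (!is.null(products)) {
    if (inherits(products, "kin_species")) products <- list(products)
    stopifnot(all(vapply(products, inherits, TRUE, "kin_species")))
  }
  structure(list(reactants = reactants, ts = ts, products = products,
                 nu_imag_cm1 = nu_imag_cm1,
                 molecularity = length(reactants),
                 dH_cal_mol = dH_cal_mol, energy_override = energy_override),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction_system: %s -> [%s] (molecularity %d, nu_imag %.6g 1/cm)>\n",
              paste(vapply(x$reactants, `[[`, "", "name"), collapse = " + "),
              x$ts$name, x$molecularity, x$nu_imag_cm1))
  invisible(x)
}

#' Partition functions of a species
#'
#' Rigid-rotor / harmonic-oscillator / ideal-gas factorization at temperature
#' T. The vibrational factor is ZPE-referenced,
#' q_vib = prod 1/(1 - exp(-theta_i/T)) >= 1, so the zero-point energy is
#' carried in the barrier, not in q_vib.
#'
#' @param sp a [species()]
#' @param T temperature, K (scalar)
#' @return list of class `partition_set`: `q_trans_per_V` (1/m^3), `q_rot`,
#'   `q_vib`, `g_elec`
#' @examples
#' a <- species("H", mass_amu = 1.00783, geometry = "atom", degeneracy = 2)
#' partition_functions(a, 298.15)
#' @export
partition_functions <- function(sp, T) {
  stopifnot(inherits(sp, "kin_species"), is.numeric(T), length(T) == 1L)
  if (!is.finite(T) || T <= 0) stop("T must be finite and > 0")
  kc <- .kc
  m_kg <- sp$mass_amu * 1e-3 / kc$N_A
  q_trans <- (2 * pi * m_kg * kc$kB * T / kc$h^2)^1.5
  q_rot <- switch(sp$geometry,
    atom = 1,
    linear = {
      th <- kc$c2 * sp$rotational_constants_cm1
      T / (sp$sigma * th)
    },
    nonlinear = {
      th <- kc$c2 * sp$rotational_constants_cm1
      sqrt(pi) / sp$sigma * sqrt(T^3 / prod(th))
    })
  q_vib <- if (length(sp$frequencies_cm1))
    prod(1 / (1 - exp(-kc$c2 * sp$frequencies_cm1 / T))) else 1
  structure(list(q_trans_per_V = q_trans, q_rot = q_rot, q_vib = q_vib,
                 g_elec = sp$degeneracy),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set: q_trans/V=%.6g 1/m^3, q_rot=%.6g, q_vib=%.6g, g=%g>\n",
              x$q_trans_per_V, x$q_rot, x$q_vib, x$g_elec))
  invisible(x)
}

# total per-volume partition function (dimensionful, 1/m^3)
.q_total <- function(sp, T) {
  q <- partition_functions(sp, T)
  q$q_trans_per_V * q$q_rot * q$q_vib * q$g_elec
}

#' Barrier height of a reaction system
#'
#' TS electronic energy minus summed reactant energies, optionally with the
#' zero-point correction from the harmonic frequencies, honouring any
#' energy overrides.
#'
#' @param system a [reaction_system()]
#' @param zpe_corrected include the delta-ZPE term
#' @return barrier in cal/mol
#' @export
barrier_height <- function(system, zpe_corrected = TRUE) {
  ov <- system$energy_override
  gete <- function(sp) .energy_J_mol(sp, ov[[sp$name]])
  e <- gete(system$ts) - sum(vapply(system$reactants, gete, numeric(1)))
  if (zpe_corrected)
    e <- e + .zpe_J_mol(system$ts) -
      sum(vapply(system$reactants, .zpe_J_mol, numeric(1)))
  e / .kc$cal_to_J
}

#' Reaction enthalpy from the species energies
#'
#' Zero-Kelvin enthalpy: summed product energies minus summed reactant
#' energies (with ZPE when requested). Requires products. Used as a
#' cross-check against a user-supplied `dH_cal_mol`.
#'
#' @inheritParams barrier_height
#' @return delta-H in cal/mol
#' @export
reaction_enthalpy <- function(system, zpe_corrected = TRUE) {
  if (is.null(system$products)) stop("system has no products")
  ov <- system$energy_override
  gete <- function(sp) .energy_J_mol(sp, ov[[sp$name]])
  e <- sum(vapply(system$products, gete, numeric(1))) -
    sum(vapply(system$reactants, gete, numeric(1)))
  if (zpe_corrected)
    e <- e + sum(vapply(system$products, .zpe_J_mol, numeric(1))) -
      sum(vapply(system$reactants, .zpe_J_mol, numeric(1)))
  e / .kc$cal_to_J
}

#' Transition-state-theory rate constant
#'
#' k = (kB T / h) (Q‡ / prod Qi) exp(-eps‡ / kB T) in the rigid-rotor /
#' harmonic-oscillator approximation. Unimolecular rates are in 1/s;
#' bimolecular rates are computed per molecule (cm^3 molecule^-1 s^-1) and
#' can be reported in molar units (cm^3 mol^-1 s^-1) instead.
#'
#' @param system a [reaction_system()]
#' @param T temperatures, K (vectorized)
#' @param zpe_corrected ZPE-correct the barrier (default TRUE)
#' @param units "molecule" (cm^3 molecule^-1 s^-1) or "molar"
#'   (cm^3 mol^-1 s^-1) for bimolecular systems; ignored for unimolecular
#' @param force_q_ratio diagnostic: override the partition-function ratio
#'   with a fixed number (dimensionless for unimolecular, m^3 for
#'   bimolecular)
#' @return numeric vector of rate constants
#' @export
tst_rate <- function(system, T, zpe_corrected = TRUE,
                     units = c("molecule", "molar"), force_q_ratio = NULL) {
  stopifnot(inherits(system, "reaction_system"), is.numeric(T))
  if (any(T <= 0)) stop("T must be > 0")
  units <- match.arg(units)
  kc <- .kc
  eps <- barrier_height(system, zpe_corrected)
  vapply(T, function(Ti) {
    qr <- if (!is.null(force_q_ratio)) force_q_ratio
      else .q_total(system$ts, Ti) /
        prod(vapply(system$reactants, .q_total, numeric(1), Ti))
    k <- kc$kB * Ti / kc$h * qr * exp(-eps / (kc$R_cal * Ti))
    if (system$molecularity == 2L) {
      k <- k * 1e6  # m^3 -> cm^3, per molecule
      if (units == "molar") k <- k * kc$N_A
    }
    k
  }, numeric(1))
}

#' Deformed transition-state theory (d-TST) rate constant
#'
#' TST with the barrier exponential replaced by the deformed exponential
#' (1 - d eps‡/kB T)^(1/d), with the deformation fixed by the imaginary-mode
#' and barrier energies, d = -(1/3) (h nu‡ / (2 eps‡))^2 <= 0. Uniformly
#' covers classical to moderate tunneling; recovers plain TST as nu‡ -> 0.
#'
#' @inheritParams tst_rate
#' @return list with `k` (numeric vector, same conventions as [tst_rate()])
#'   and the scalar deformation `d`
#' @export
dtst_rate <- function(system, T, zpe_corrected = TRUE,
                      units = c("molecule", "molar"), force_q_ratio = NULL) {
  stopifnot(inherits(system, "reaction_system"), is.numeric(T))
  if (any(T <= 0)) stop("T must be > 0")
  units <- match.arg(units)
  kc <- .kc
  eps <- barrier_height(system, zpe_corrected)
  if (eps <= 0) stop("d-TST requires a positive barrier")
  hnu <- system$nu_imag_cm1 * kc$cm1_to_cal_mol
  d <- -(hnu / (2 * eps))^2 / 3
  k <- vapply(T, function(Ti) {
    qr <- if (!is.null(force_q_ratio)) force_q_ratio
      else .q_total(system$ts, Ti) /
        prod(vapply(system$reactants, .q_total, numeric(1), Ti))
    ki <- kc$kB * Ti / kc$h * qr * .deformed_exp(eps / (kc$R_cal * Ti), d)
    if (system$molecularity == 2L) {
      ki <- ki * 1e6
      if (units == "molar") ki <- ki * kc$N_A
    }
    ki
  }, numeric(1))
  list(k = k, d = d)
}

#' Crossover temperature and tunneling regime
#'
#' Tc = h c nu‡ / (pi kB) = c2 nu‡ / pi. The four regime windows partition
#' the temperature axis: negligible (T > 2Tc), small (Tc < T <= 2Tc),
#' moderate (Tc/2 < T <= Tc), deep (T <= Tc/2).
#'
#' @param nu_imag_cm1 imaginary-mode wavenumber magnitude, 1/cm
#' @param T temperatures, K (vectorized)
#' @return list with `Tc` (K) and `regime` (factor with levels deep,
#'   moderate, small, negligible)
#' @examples
#' crossover_and_regime(1000, c(100, 400, 500, 1000))
#' @export
crossover_and_regime <- function(nu_imag_cm1, T) {
  stopifnot(nu_imag_cm1 > 0, all(T > 0))
  Tc <- .kc$c2 * nu_imag_cm1 / pi
  lev <- c("deep", "moderate", "small", "negligible")
  regime <- cut(T, breaks = c(0, Tc / 2, Tc, 2 * Tc, Inf), labels = lev,
                right = TRUE)
  list(Tc = Tc, regime = regime)
}

#' Tunneling transmission coefficients
#'
#' One-dimensional parabolic-barrier corrections multiplying the TST rate.
#' Throughout, the reduced-Planck energy is taken literally as
#' hbar*nu‡ = h*nu‡/(2 pi) and all energies are molar (cal/mol); write
#' b = 1/(R T), a = 1/(hbar nu‡) and u/2 = h nu‡/(2 kB T).
#' \describe{
#'   \item{bell35}{kappa = (a - b exp(eps (b - a))) / (a - b); the removable
#'     b = a point is evaluated by its limit 1 + a*eps.}
#'   \item{bell58_1t}{kappa = (u/2)/sin(u/2), the leading Bell-1958 term;
#'     diverges at u/2 = pi, i.e. T = Tc/2 with Tc = h nu‡/(pi kB).
#'     Evaluation is refused within |u/2 - pi| < 1e-3 and beyond the pole
#'     (u/2 >= pi), naming Tc in the error.}
#'   \item{bell58_2t}{the two-term truncation,
#'     (u/2)/sin(u/2) - exp(eps (b - a)) b/(a - b).}
#'   \item{st}{Skodje--Truhlar, pole-free: for b <= c (T >= Tc, with
#'     c = pi/(h nu‡) = 1/(kB Tc)) the two-term form with eps replaced by
#'     eps - dH; for b >= c the deep form
#'     kappa = b/(b - a) * (exp((b - a)(eps - dH)) - 1), continuous through
#'     b = a. The two branches do not meet exactly at b = c; the finite
#'     mismatch there is a documented property of the piecewise form.}
#' }
#'
#' @param method one of "bell35", "bell58_1t", "bell58_2t", "st"
#' @param nu_imag_cm1 imaginary-mode wavenumber magnitude, 1/cm
#' @param eps_cal_mol barrier height, cal/mol, > 0
#' @param T temperatures, K (vectorized)
#' @param dH_cal_mol reaction enthalpy, cal/mol (required for "st"; 0
#'   allowed)
#' @return numeric vector of kappa values (>= 0; -> 1 as T -> infinity)
#' @examples
#' tunneling_kappa("bell58_1t", 1000, 5000, 2 * crossover_and_regime(1000, 300)$Tc)
#' @export
tunneling_kappa <- function(method = c("bell35", "bell58_1t", "bell58_2t", "st"),
                            nu_imag_cm1, eps_cal_mol, T, dH_cal_mol = NULL) {
  method <- match.arg(method)
  stopifnot(nu_imag_cm1 > 0, eps_cal_mol > 0, all(T > 0))
  kc <- .kc
  Ehv <- nu_imag_cm1 * kc$cm1_to_cal_mol   # h nu‡ as cal/mol
  Ehb <- Ehv / (2 * pi)                    # hbar nu‡ as cal/mol
  a <- 1 / Ehb
  b <- 1 / (kc$R_cal * T)
  s <- Ehv * b / 2                         # u/2 = h nu‡ / (2 kB T)
  Tc <- kc$c2 * nu_imag_cm1 / pi
  sinc_term <- function(sv) {
    if (any(abs(sv - pi) < 1e-3) || any(sv >= pi))
      stop(sprintf(paste0("Bell-1958 leading term diverges at T = Tc/2 = %.4g K ",
                          "(crossover temperature Tc = %.4g K); refuse T <= Tc/2"),
                   Tc / 2, Tc))
    sv / sin(sv)
  }
  second_term <- function(E) exp(E * (b - a)) * b / (a - b)
  switch(method,
    bell35 = ifelse(abs(1 - b / a) < 1e-8,
                    1 + a * eps_cal_mol,
                    (a - b * exp(eps_cal_mol * (b - a))) / (a - b)),
    bell58_1t = sinc_term(s),
    bell58_2t = sinc_term(s) - second_term(eps_cal_mol),
    st = {
      if (is.null(dH_cal_mol))
        stop("Skodje-Truhlar correction requires dH_cal_mol (0 allowed)")
      E <- eps_cal_mol - dH_cal_mol
      cb <- pi / Ehv                       # 1/(kB Tc), molar
      deep <- b >= cb
      out <- numeric(length(b))
      if (any(!deep)) {
        sv <- s[!deep]                     # here s <= pi/2: pole-free
        out[!deep] <- sv / sin(sv) - exp(E * (b[!deep] - a)) * b[!deep] / (a - b[!deep])
      }
      if (any(deep)) {
        bd <- b[deep]
        x <- (bd - a) * E
        out[deep] <- ifelse(abs(x) < 1e-8, bd * E, bd / (bd - a) * expm1(x))
      }
      out
    })
}

#' Tunneling-corrected rate constant
#'
#' kappa(method) * k_TST for the Bell and Skodje--Truhlar methods,
#' [dtst_rate()] for "dtst", plain [tst_rate()] for "none". For "st" the
#' reaction enthalpy is taken from the system's `dH_cal_mol` (falling back
#' to [reaction_enthalpy()] when products are present).
#'
#' @inheritParams tst_rate
#' @param method one of "none", "dtst", "bell35", "bell58_1t", "bell58_2t",
#'   "st"
#' @return numeric vector of rate constants
#' @export
corrected_rate <- function(system, T, method = c("none", "dtst", "bell35",
                                                 "bell58_1t", "bell58_2t", "st"),
                           zpe_corrected = TRUE,
                           units = c("molecule", "molar"),
                           force_q_ratio = NULL) {
  method <- match.arg(method)
  units <- match.arg(units)
  if (method == "none")
    return(tst_rate(system, T, zpe_corrected, units, force_q_ratio))
  if (method == "dtst")
    return(dtst_rate(system, T, zpe_corrected, units, force_q_ratio)$k)
  eps <- barrier_height(system, zpe_corrected)
  dH <- system$dH_cal_mol
  if (method == "st" && is.null(dH) && !is.null(system$products))
    dH <- reaction_enthalpy(system, zpe_corrected)
  kap <- tunneling_kappa(method, system$nu_imag_cm1, eps, T, dH)
  kap * tst_rate(system, T, zpe_corrected, units, force_q_ratio)
}
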