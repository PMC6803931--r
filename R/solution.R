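#' Solvent viscosity model
#'
#' Temperature-dependent viscosity eta(T) in Poise, either in the direct
#' power-law parametrization eta = eta0 (1 - T*/T)^exponent or in the
#' deformed-exponential (Aquilanti--Mundim) form
#' eta = eta0 (1 - d eps/(R T))^(1/d) with eps in J/mol. The built-in default
#' is liquid water, eta(T) = 2.7024e-4 Poise * (1 - 213.0543/T)^(-2.75634),
#' fitted to handbook data; its domain is T > 213.0543 K.
#'
#' @param name solvent label
#' @param eta0 viscosity prefactor, Poise, > 0
#' @param parametrization "direct" or "am"
#' @param T_star characteristic temperature, K (direct)
#' @param exponent power-law exponent (direct)
#' @param eps_J_mol energy parameter, J/mol (am)
#' @param d_visc dimensionless deformation (am)
#' @param valid_T optional length-2 validity range, K
#' @return object of class `solvent_model`
#' @examples
#' am_viscosity(solvent_model(), 298.15)  # water, ~8.57e-3 Poise
#' @export
solvent_model <- function(name = "water", eta0 = 2.7024e-4,
                          parametrization = c("direct", "am"),
                          T_star = 213.0543, exponent = -2.75634,
                          eps_J_mol = NULL, d_visc = NULL, valid_T = NULL) {
  parametrization <- match.arg(parametrization)
  stopifnot(is.numeric(eta0), eta0 > 0)
  if (parametrization == "direct")
    stopifnot(is.numeric(T_star), is.numeric(exponent))
  else
    stopifnot(is.numeric(eps_J_mol), is.numeric(d_visc))
  structure(list(name = as.character(name), eta0 = eta0,
                 parametrization = parametrization, T_star = T_star,
                 exponent = exponent, eps_J_mol = eps_J_mol,
                 d_visc = d_visc, valid_T = valid_T),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("<solvent_model '%s': eta0=%.6g Poise, %s parametrization>\n",
              x$name, x$eta0, x$parametrization))
  invisible(x)
}

#' Solvent viscosity at temperature T
#'
#' Evaluates the [solvent_model()] law; raises a domain error where the base
#' of the fractional power is non-positive (e.g. water at or below
#' T* = 213.0543 K) rather than returning NaN.
#'
#' @param solvent a [solvent_model()]
#' @param T temperatures, K (vectorized)
#' @return viscosity in Poise
#' @export
am_viscosity <- function(solvent, T) {
  stopifnot(inherits(solvent, "solvent_model"), is.numeric(T))
  if (any(T <= 0)) stop("T must be > 0")
  if (!is.null(solvent$valid_T) &&
      (any(T < solvent$valid_T[1]) || any(T > solvent$valid_T[2])))
    stop("temperature outside the solvent model's validity range")
  if (solvent$parametrization == "direct") {
    base <- 1 - solvent$T_star / T
    if (any(base <= 0))
      stop(sprintf("viscosity law undefined at T <= T* = %.4f K", solvent$T_star))
    solvent$eta0 * base^solvent$exponent
  } else {
    d <- solvent$d_visc
    x <- solvent$eps_J_mol / (.kc$R_J * T)
    solvent$eta0 * .deformed_exp(x, d)  # (1 - d x)^(1/d); domain-checked
  }
}

# Stokes radius (cm) of a species from its molar volume (cm^3/mol)
.cage_radius_cm <- function(molar_volume_cm3) {
  (3 * molar_volume_cm3 / (4 * pi * .kc$N_A))^(1 / 3)
}

# Stokes-Einstein diffusion coefficient, cgs: kB in erg/K, eta in Poise,
# r in cm -> D in cm^2/s
.stokes_einstein_D <- function(r_cm, eta_poise, T) {
  (.kc$kB * 1e7) * T / (6 * pi * eta_poise * r_cm)
}

#' Collins--Kimball diffusion-limited rate
#'
#' Combines the activated (TST-level) rate with the Smoluchowski
#' diffusion-limited rate, 1/k_obs = 1/k_tst + 1/k_D. Cage radii come from
#' the molar volumes, r_i = (3 V_i / (4 pi N_A))^(1/3); diffusion constants
#' from Stokes--Einstein in cgs, D_i = kB T / (6 pi eta r_i); and
#' k_D = 4 pi r_AB D_AB N_A with r_AB = r_A + r_B and D_AB = D_A + D_B,
#' in cm^3 mol^-1 s^-1. `k_tst` must be supplied in cm^3 mol^-1 s^-1
#' (it may come from TST, d-TST or any tunneling-corrected rate).
#'
#' @param k_tst activated bimolecular rate constant, cm^3 mol^-1 s^-1
#' @param volume_A_cm3,volume_B_cm3 reactant molar volumes, cm^3/mol
#' @param solvent a [solvent_model()]
#' @param T temperature, K (scalar)
#' @return list of class `solution_rate`: `k_tst`, `k_D`, `k_obs`
#'   (cm^3 mol^-1 s^-1), `D_A`, `D_B`, `D_AB` (cm^2/s), `r_A`, `r_B`,
#'   `r_AB` (cm), `eta` (Poise), `model = "collins-kimball"`
#' @export
collins_kimball_rate <- function(k_tst, volume_A_cm3, volume_B_cm3,
                                 solvent = solvent_model(), T) {
  stopifnot(is.numeric(k_tst), k_tst > 0, length(T) == 1L)
  if (is.null(volume_A_cm3) || is.null(volume_B_cm3))
    stop("both reactant molar volumes are required")
  eta <- am_viscosity(solvent, T)
  r_A <- .cage_radius_cm(volume_A_cm3)
  r_B <- .cage_radius_cm(volume_B_cm3)
  D_A <- .stokes_einstein_D(r_A, eta, T)
  D_B <- .stokes_einstein_D(r_B, eta, T)
  D_AB <- D_A + D_B
  r_AB <- r_A + r_B
  k_D <- 4 * pi * r_AB * D_AB * .kc$N_A
  k_obs <- 1 / (1 / k_tst + 1 / k_D)
  structure(list(k_tst = k_tst, k_D = k_D, k_obs = k_obs,
                 D_A = D_A, D_B = D_B, D_AB = D_AB,
                 r_A = r_A, r_B = r_B, r_AB = r_AB, eta = eta,
                 T = T, model = "collins-kimball",
                 units = "cm3 mol-1 s-1"),
            class = "solution_rate")
}

#' Kramers friction-corrected rate
#'
#' k_obs = kappa_Kr * k_tst with the Kramers transmission factor
#' kappa_Kr = (sqrt(mu^2/4 + omega‡^2) - mu/2) / omega‡, where
#' omega‡ = 2 pi c nu‡ is the magnitude of the imaginary-mode angular
#' frequency and the friction constant is the Stokes drag over the
#' per-molecule mass, mu = 6 pi r_AB eta / (M/N_A), in 1/s (cgs: r in cm,
#' eta in Poise, M in g/mol). Applies to unimolecular and
#' pseudo-unimolecular processes; `k_tst` keeps its own units.
#'
#' @param k_tst activated rate constant (units preserved in `k_obs`)
#' @param r_AB_cm cage radius of the transition state, cm
#' @param M_g_mol transition-state molar mass, g/mol
#' @param nu_imag_cm1 imaginary-mode wavenumber magnitude, 1/cm
#' @param solvent a [solvent_model()]
#' @param T temperature, K (scalar)
#' @return list of class `solution_rate`: `k_tst`, `k_obs`, `kappa_kr`,
#'   `mu` (1/s), `omega_imag` (1/s), `eta` (Poise), `model = "kramers"`
#' @export
kramers_rate <- function(k_tst, r_AB_cm, M_g_mol, nu_imag_cm1,
                         solvent = solvent_model(), T) {
  stopifnot(is.numeric(k_tst), k_tst > 0, r_AB_cm > 0, M_g_mol > 0,
            length(T) == 1L)
  if (nu_imag_cm1 <= 0) stop("imaginary frequency must be positive")
  eta <- am_viscosity(solvent, T)
  omega <- 2 * pi * .kc$c_cm * nu_imag_cm1
  m_g <- M_g_mol / .kc$N_A
  mu <- 6 * pi * r_AB_cm * eta / m_g
  kappa <- (sqrt(mu^2 / 4 + omega^2) - mu / 2) / omega
  structure(list(k_tst = k_tst, k_obs = kappa * k_tst, kappa_kr = kappa,
                 mu = mu, omega_imag = omega, eta = eta, T = T,
                 model = "kramers", units = "as k_tst"),
            class = "solution_rate")
}

#' @export
print.solution_rate <- function(x, ...) {
  cat(sprintf("<solution_rate: %s at %.6g K>\n", x$model, x$T))
  cat(sprintf("  eta = %.6g Poise\n", x$eta))
  if (x$model == "collins-kimball") {
    cat(sprintf("  D_A = %.6g, D_B = %.6g cm^2/s; r_AB = %.6g cm\n",
                x$D_A, x$D_B, x$r_AB))
    cat(sprintf("  k_tst = %.6g, k_D = %.6g, k_obs = %.6g %s\n",
                x$k_tst, x$k_D, x$k_obs, x$units))
  } else {
    cat(sprintf("  mu = %.6g 1/s, omega_imag = %.6g 1/s, kappa_Kr = %.6g\n",
                x$mu, x$omega_imag, x$kappa_kr))
    cat(sprintf("  k_tst = %.6g, k_obs = %.6g (%s)\n",
                x$k_tst, x$k_obs, x$units))
  }
  invisible(x)
}
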