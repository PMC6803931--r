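#' Physical constants used throughout the package
#'
#' Single source of truth for every module. CODATA 2018 exact/recommended
#' values. Energies attached to rate-law parameters are molar and in cal/mol
#' (thermochemical calorie, 1 cal = 4.184 J); the inverse-temperature variable
#' used for Arrhenius-plane math is the molar beta = 1/(R*T) in mol/cal, so
#' that published parameter tables in cal/mol can be used verbatim.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{h, hbar}{Planck constant and reduced Planck constant, J s}
#'     \item{c_cm}{speed of light, cm/s}
#'     \item{N_A}{Avogadro constant, 1/mol}
#'     \item{R_J, R_cal}{molar gas constant, J/(mol K) and cal/(mol K)}
#'     \item{c2}{second radiation constant h*c/kB, cm K (wavenumber to
#'       temperature conversion)}
#'     \item{cal_to_J}{4.184 exactly}
#'     \item{hartree_J_mol}{1 hartree in J/mol}
#'     \item{cm1_to_cal_mol}{1 cm^-1 in cal/mol (h*c*N_A/4.184)}
#'   }
#' @examples
#' kc <- kin_constants()
#' kc$kB * 298.15 / kc$h  # universal TST frequency factor at 298.15 K
#' @export
kin_constants <- function() .kc

.kc <- local({
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  c_cm <- 2.99792458e10
  N_A <- 6.02214076e23
  R_J <- kB * N_A
  cal_to_J <- 4.184
  list(
    kB = kB, h = h, hbar = h / (2 * pi), c_cm = c_cm, N_A = N_A,
    R_J = R_J, R_cal = R_J / cal_to_J,
    c2 = h * c_cm / kB,
    cal_to_J = cal_to_J,
    hartree_J_mol = 4.3597447222071e-18 * N_A,
    cm1_to_cal_mol = h * c_cm * N_A / cal_to_J
  )
})

#' Inverse-temperature grid in the molar convention
#'
#' beta = 1/(R*T) with R in cal/(mol K), so apparent activation energies come
#' out in cal/mol. Strictly monotone T gives strictly monotone beta of the
#' opposite direction.
#'
#' @param T temperatures in K, strictly positive and strictly monotone
#' @return list with components `T` and `beta` (mol/cal) on the same grid
#' @export
beta_grid <- function(T) {
  stopifnot(is.numeric(T), length(T) >= 1L)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be finite and strictly positive")
  if (length(T) > 1L) {
    dT <- diff(T)
    if (!(all(dT > 0) || all(dT < 0)))
      stop("temperature grid must be strictly monotone")
  }
  list(T = T, beta = 1 / (.kc$R_cal * T))
}
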