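#' Phenomenological rate-law parameter records
#'
#' Constructs a parameter record for one of the five temperature-dependence
#' laws handled by the package. Only the fields belonging to the chosen law
#' may be supplied; temperatures and deformed-exponential supports are checked
#' at evaluation time, not here.
#'
#' The laws (energies in cal/mol, temperatures in K, beta = 1/(R*T)):
#' \describe{
#'   \item{arrhenius}{k = A exp(-Ea * beta)}
#'   \item{am}{Aquilanti--Mundim, k = A (1 - d * eps_dd * beta)^(1/d); the
#'     deformed exponential reduces to exp(-eps_dd * beta) as d -> 0. d < 0
#'     gives concave (sub-Arrhenius) curvature, d > 0 convex
#'     (super/anti-Arrhenius).}
#'   \item{ascc}{Aquilanti--Sanchez--Coutinho--Carvalho,
#'     k = A (1 - d * eps_dd / (R*T + E_nu))^(1/d) with the deformation
#'     derived, never free: d = -(1/3) (E_nu / (2 eps_dd))^2.}
#'   \item{nts}{Nakamura--Takayanagi--Sato,
#'     k = A exp(-E0 / (R * sqrt(T^2 + T0^2))).}
#'   \item{vft}{Vogel--Fulcher--Tammann, k = A exp(B / (T - T0)); B may be
#'     negative (B < 0 gives super-Arrhenius behaviour with Ea > 0).}
#' }
#'
#' @param law one of "arrhenius", "am", "ascc", "nts", "vft"
#' @param A pre-exponential factor; units carried opaquely (those of the
#'   source data)
#' @param Ea activation energy, cal/mol (arrhenius)
#' @param eps_dd barrier-like energy (the double-dagger epsilon), cal/mol
#'   (am, ascc)
#' @param d dimensionless deformation (am only; derived for ascc)
#' @param E_nu vibrational-quantum-like energy, cal/mol (ascc)
#' @param E0 limiting activation energy, cal/mol (nts)
#' @param T0 characteristic temperature, K (nts, vft)
#' @param B VFT temperature coefficient, K
#' @return object of class `rate_law_params`
#' @examples
#' rate_law_params("am", A = 1.11e-10, eps_dd = 9170, d = -0.086)
#' @seealso [eval_rate_law()], [apparent_ea()], [transitivity_gamma()]
#' @export
rate_law_params <- function(law = c("arrhenius", "am", "ascc", "nts", "vft"),
                            A, Ea = NULL, eps_dd = NULL, d = NULL,
                            E_nu = NULL, E0 = NULL, T0 = NULL, B = NULL) {
  law <- match.arg(law)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0)
  need <- switch(law,
    arrhenius = "Ea",
    am = c("eps_dd", "d"),
    ascc = c("eps_dd", "E_nu"),
    nts = c("E0", "T0"),
    vft = c("B", "T0"))
  given <- c(Ea = !is.null(Ea), eps_dd = !is.null(eps_dd), d = !is.null(d),
             E_nu = !is.null(E_nu), E0 = !is.null(E0), T0 = !is.null(T0),
             B = !is.null(B))
  if (!all(given[need]))
    stop(sprintf("law '%s' requires fields: %s", law,
                 paste(need, collapse = ", ")))
  extra <- names(given)[given & !(names(given) %in% need)]
  if (length(extra))
    stop(sprintf("fields not belonging to law '%s': %s", law,
                 paste(extra, collapse = ", ")))
  vals <- mget(need)
  for (nm in need)
    stopifnot(is.numeric(vals[[nm]]), length(vals[[nm]]) == 1L,
              is.finite(vals[[nm]]))
  if (law == "ascc" && eps_dd == 0) stop("ascc requires eps_dd != 0")
  if (law == "nts" && T0 < 0) stop("nts requires T0 >= 0")
  structure(c(list(law = law, A = A), vals), class = "rate_law_params")
}

#' @export
print.rate_law_params <- function(x, ...) {
  cat(sprintf("<rate_law_params: %s>\n", x$law))
  flds <- x[setdiff(names(x), "law")]
  cat(paste(sprintf("  %s = %g", names(flds), unlist(flds)), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Derived ASCC deformation
#'
#' The ASCC law treats the deformation as fixed by the barrier and the
#' vibrational-quantum energy: d = -(1/3) * (E_nu / (2 * eps_dd))^2, always
#' non-positive (the law covers sub-Arrhenius curvature only).
#'
#' @param eps_dd barrier energy, cal/mol, nonzero
#' @param E_nu vibrational energy, cal/mol
#' @return dimensionless d <= 0
#' @export
ascc_d <- function(eps_dd, E_nu) {
  stopifnot(is.numeric(eps_dd), is.numeric(E_nu))
  if (any(eps_dd == 0)) stop("eps_dd must be nonzero")
  -(E_nu / (2 * eps_dd))^2 / 3
}

# deformed exponential (1 - d x)^(1/d), continuous d -> 0 limit exp(-x).
# Domain error (not NaN/0) when the base is <= 0: silent zeros corrupt fits.
.deformed_exp <- function(x, d) {
  if (abs(d) < 1e-12) return(exp(-x))
  base <- 1 - d * x
  if (any(base <= 0))
    stop("deformed-exponential base <= 0: temperature outside the law's support")
  exp(log(base) / d)
}

# internal: effective deformation of a params record (ascc derives it)
.law_d <- function(p) {
  switch(p$law, am = p$d, ascc = ascc_d(p$eps_dd, p$E_nu),
         stop("no deformation for law ", p$law))
}

#' Evaluate a rate law on a temperature grid
#'
#' Elementwise k(T) per the law stored in `params`; units are those of the
#' pre-exponential factor A.
#'
#' @param params a [rate_law_params()] object
#' @param T temperatures in K (vector allowed)
#' @return numeric vector of rate values
#' @examples
#' p <- rate_law_params("arrhenius", A = 1.52e11, Ea = 14600)
#' eval_rate_law(p, 298.15)
#' @export
eval_rate_law <- function(params, T) {
  stopifnot(inherits(params, "rate_law_params"), is.numeric(T))
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be finite and > 0")
  kc <- .kc
  beta <- 1 / (kc$R_cal * T)
  p <- params
  switch(p$law,
    arrhenius = p$A * exp(-p$Ea * beta),
    am = p$A * .deformed_exp(p$eps_dd * beta, p$d),
    ascc = {
      d <- ascc_d(p$eps_dd, p$E_nu)
      p$A * .deformed_exp(p$eps_dd / (kc$R_cal * T + p$E_nu), d)
    },
    nts = p$A * exp(-p$E0 / (kc$R_cal * sqrt(T^2 + p$T0^2))),
    vft = {
      if (any(T <= p$T0))
        stop("VFT support requires T > T0")
      p$A * exp(p$B / (T - p$T0))
    })
}

#' Apparent activation energy of a rate law (closed form)
#'
#' The local Arrhenius-plot slope Ea(T) = -d ln k / d beta, evaluated
#' analytically for each law:
#' arrhenius: Ea; am: eps_dd / (1 - d * eps_dd * beta);
#' ascc: eps_dd * (R T)^2 / ((R T + E_nu) * (R T + E_nu - d * eps_dd));
#' nts: E0 * T^3 / (T^2 + T0^2)^(3/2); vft: -B * R * T^2 / (T - T0)^2.
#'
#' @inheritParams eval_rate_law
#' @return apparent activation energies in cal/mol, same length as `T`
#' @export
apparent_ea <- function(params, T) {
  stopifnot(inherits(params, "rate_law_params"), is.numeric(T))
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be finite and > 0")
  kc <- .kc
  R <- kc$R_cal
  beta <- 1 / (R * T)
  p <- params
  switch(p$law,
    arrhenius = rep(p$Ea, length(T)),
    am = {
      base <- 1 - p$d * p$eps_dd * beta
      if (any(base <= 0)) stop("temperature outside the law's support")
      p$eps_dd / base
    },
    ascc = {
      d <- ascc_d(p$eps_dd, p$E_nu)
      u <- R * T + p$E_nu
      if (any(u - d * p$eps_dd <= 0) || any(1 - d * p$eps_dd / u <= 0))
        stop("temperature outside the law's support")
      p$eps_dd * (R * T)^2 / (u * (u - d * p$eps_dd))
    },
    nts = p$E0 * T^3 / (T^2 + p$T0^2)^1.5,
    vft = {
      if (any(T <= p$T0)) stop("VFT support requires T > T0")
      -p$B * R * T^2 / (T - p$T0)^2
    })
}

#' Transitivity function of a rate law (closed form)
#'
#' gamma(beta) = 1/Ea(beta), the reciprocal apparent activation energy. In
#' the transitivity plane (gamma vs beta) the Aquilanti--Mundim law is exactly
#' affine: gamma = 1/eps_dd - d * beta.
#'
#' @param params a [rate_law_params()] object
#' @param beta molar inverse temperatures, mol/cal (see [beta_grid()])
#' @return gamma values in mol/cal
#' @export
transitivity_gamma <- function(params, beta) {
  stopifnot(is.numeric(beta))
  if (any(beta <= 0)) stop("beta must be > 0")
  if (params$law == "am") return(1 / params$eps_dd - params$d * beta)
  T <- 1 / (.kc$R_cal * beta)
  ea <- apparent_ea(params, T)
  if (any(ea == 0))
    stop("singular transitivity: apparent activation energy is zero")
  1 / ea
}

#' Serialize / deserialize rate-law parameters
#'
#' Flat key-value representation (law plus the fields of that law; energies
#' in cal/mol, temperatures in K) suitable for YAML round trips.
#'
#' @param params a [rate_law_params()] object
#' @return named list for `params_to_list`; `rate_law_params` for
#'   `params_from_list`
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "rate_law_params"))
  lapply(unclass(params), identity)
}

#' @param x named list as produced by [params_to_list()]
#' @rdname params_to_list
#' @export
params_from_list <- function(x) {
  stopifnot(is.list(x), !is.null(x$law))
  do.call(rate_law_params, x)
}
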