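# --- parameter packing -------------------------------------------------------
# The search works on theta = (log10(A), <law fields>) so that pre-exponential
# factors spanning 1e-14..1e12 live on a sane scale.

.law_fields <- function(law) switch(law,
  arrhenius = "Ea", am = c("eps_dd", "d"), ascc = c("eps_dd", "E_nu"),
  nts = c("E0", "T0"), vft = c("B", "T0"))

.pack <- function(params) {
  c(log10(params$A), unlist(params[.law_fields(params$law)], use.names = FALSE))
}

.unpack <- function(theta, law) {
  vals <- as.list(theta[-1])
  names(vals) <- .law_fields(law)
  do.call(rate_law_params, c(list(law = law, A = 10^theta[1]), vals))
}

# Data-driven default search box: seed an Arrhenius line through (beta, ln k)
# and open generous windows around it. Curved laws get wide energy windows
# because the local slope can badly underestimate the barrier scale.
.default_bounds <- function(series, law, guess = NULL) {
  R <- .kc$R_cal
  if (!is.null(guess)) {
    th <- .pack(guess)
    lo <- hi <- th
    lo[1] <- th[1] - 5; hi[1] <- th[1] + 5
    for (i in seq_along(th)[-1]) {
      hw <- max(4 * abs(th[i]), if (.law_fields(law)[i - 1] == "d") 2 else 2000)
      lo[i] <- th[i] - hw; hi[i] <- th[i] + hw
    }
    if (law %in% c("nts", "vft")) {  # keep T0 in-range physically
      j <- 1 + match("T0", .law_fields(law))
      lo[j] <- max(lo[j], 0)
      if (law == "vft") hi[j] <- min(hi[j], 0.95 * min(series$T))
    }
    if (law == "ascc") {  # E_nu >= 0 (vibrational quantum)
      j <- 1 + match("E_nu", .law_fields(law))
      lo[j] <- max(lo[j], 0)
    }
    return(list(lower = lo, upper = hi))
  }
  fit0 <- stats::lm(log(series$k) ~ I(1 / (R * series$T)))
  la0 <- coef(fit0)[[1]] / log(10)
  ea0 <- -coef(fit0)[[2]]
  escale <- max(abs(ea0), 500)
  switch(law,
    arrhenius = list(lower = c(la0 - 4, ea0 - 2 * escale),
                     upper = c(la0 + 4, ea0 + 2 * escale)),
    am = list(lower = c(la0 - 8, -8 * escale, -3),
              upper = c(la0 + 8, 8 * escale, 3)),
    ascc = list(lower = c(la0 - 8, -8 * escale, 0),
                upper = c(la0 + 8, 8 * escale, 8 * escale)),
    nts = list(lower = c(la0 - 8, -8 * escale, 0),
               upper = c(la0 + 8, 8 * escale, 2 * max(series$T))),
    vft = list(lower = c(la0 - 8, -8 * escale / R, 0),
               upper = c(la0 + 8, 8 * escale / R, 0.95 * min(series$T))))
}

#' Fit a phenomenological rate law to k(T) data
#'
#' Chi-square minimization by generalized simulated annealing, optionally
#' followed by a derivative-free simplex polish, in either of two planes:
#' \describe{
#'   \item{arrhenius}{the mean squared residual of the rates in the chosen
#'     residual space (default log10) is minimized; all five laws allowed.}
#'   \item{transitivity}{the transitivity series gamma(beta) is first built
#'     by numerical differentiation ([numerical_transitivity()]) and the
#'     squared gamma residuals against the law's closed form are minimized at
#'     interior points; since gamma is independent of A, the pre-exponential
#'     factor is recovered afterwards by zeroing the mean ln k residual.
#'     Only the arrhenius, am and vft laws are supported in this plane.}
#' }
#' Points where the candidate law is outside its support contribute +Inf and
#' the candidate is rejected. A fixed seed (in `config`) makes the whole fit
#' deterministic.
#'
#' @param series a [rate_series()]
#' @param law one of "arrhenius", "am", "ascc", "nts", "vft"
#' @param guess optional [rate_law_params()] start point; when given, the
#'   default search box is centred on it (the published workflow for laws
#'   with more than two parameters, which can have multiple chi-square
#'   minima)
#' @param config a [gsa_config()]
#' @param plane "arrhenius" or "transitivity"
#' @param space residual space for the arrhenius plane, see [chi_square()]
#' @param bounds optional list(lower, upper) on
#'   theta = (log10 A, law fields), overriding the defaults
#' @param polish run a Nelder--Mead refinement from the annealer's best point
#' @param smooth smoothing spec passed to [numerical_transitivity()]
#'   (transitivity plane only)
#' @return object of class `kin_fit`: fields `law`, `params`
#'   ([rate_law_params()]), `chi2`, `space`, `plane`, `n_eval`, `seed`,
#'   `converged`, `trace`, `series`, `bounds`
#' @examples
#' s <- synth_rate_series(rate_law_params("arrhenius", A = 1e12, Ea = 5000),
#'                        T_range = c(250, 500), n = 30)
#' fit <- fit_rate_data(s, "arrhenius", config = gsa_config(max_iter = 2000))
#' coef(fit)
#' @seealso [predict.kin_fit()], [simulate.kin_fit()], [plot.kin_fit()]
#' @export
fit_rate_data <- function(series, law = c("arrhenius", "am", "ascc", "nts", "vft"),
                          guess = NULL, config = gsa_config(),
                          plane = c("arrhenius", "transitivity"),
                          space = "log10", bounds = NULL, polish = TRUE,
                          smooth = NULL) {
  stopifnot(inherits(series, "rate_series"))
  law <- match.arg(law)
  plane <- match.arg(plane)
  if (plane == "transitivity" && !(law %in% c("arrhenius", "am", "vft")))
    stop("transitivity-plane fitting supports only arrhenius, am and vft")
  if (!is.null(guess)) {
    stopifnot(inherits(guess, "rate_law_params"))
    if (guess$law != law) stop("guess law does not match 'law'")
  }
  if (is.null(bounds)) bounds <- .default_bounds(series, law, guess)
  lower <- bounds$lower; upper <- bounds$upper

  if (plane == "arrhenius") {
    obs <- series$k
    objective <- function(theta) {
      p <- .unpack(theta, law)
      chi_square(obs, eval_rate_law(p, series$T), space)
    }
  } else {
    ts <- numerical_transitivity(series, smooth = smooth)
    keep <- !ts$endpoint & !ts$singular
    if (sum(keep) < 2L) stop("too few interior transitivity points")
    bet <- ts$beta[keep]; gam <- ts$gamma[keep]
    objective <- function(theta) {
      p <- .unpack(theta, law)
      mean((gam - transitivity_gamma(p, bet))^2)
    }
  }

  x0 <- if (!is.null(guess)) .pack(guess) else NULL
  res <- gsa_minimize(objective, lower, upper, x0 = x0, config = config)
  n_eval <- res$n_eval
  converged <- is.finite(res$value)
  if (polish && converged) {
    fpen <- function(theta) {
      if (any(theta < lower) || any(theta > upper)) return(Inf)
      v <- suppressWarnings(tryCatch(objective(theta), error = function(e) Inf))
      if (!is.finite(v)) Inf else v
    }
    for (rep in 1:2) {
      pol <- stats::optim(res$par, fpen, method = "Nelder-Mead",
                          control = list(maxit = 4000, reltol = 1e-14))
      n_eval <- n_eval + pol$counts[["function"]]
      if (pol$value <= res$value) { res$par <- pol$par; res$value <- pol$value }
    }
  }
  params <- .unpack(res$par, law)
  chi2 <- res$value
  if (plane == "transitivity") {
    # gamma is A-free: recover log10 A by zeroing the mean ln k residual
    pA1 <- params; pA1$A <- 1
    shift <- mean(log(series$k) - log(eval_rate_law(pA1, series$T)))
    params$A <- exp(shift)
    chi2 <- res$value  # objective stays the gamma-space residual
  }
  structure(list(law = law, params = params, chi2 = chi2,
                 space = if (plane == "arrhenius") space else "gamma",
                 plane = plane, n_eval = n_eval, seed = config$seed,
                 converged = converged, trace = res$trace, series = series,
                 bounds = list(lower = lower, upper = upper)),
            class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Rate-law fit: %s law, %s plane\n", x$law, x$plane))
  cat(sprintf("  chi2 (%s space, mean squared residual): %.6g\n",
              x$space, x$chi2))
  cat("  parameters:\n")
  cf <- coef(x)
  cat(paste(sprintf("    %-8s %.6g", names(cf), cf), collapse = "\n"), "\n")
  cat(sprintf("  %d objective evaluations, seed %d\n", x$n_eval, x$seed))
  invisible(x)
}

#' @export
coef.kin_fit <- function(object, ...) {
  p <- object$params
  out <- unlist(p[c("A", .law_fields(p$law))])
  if (p$law == "ascc") out <- c(out, d = ascc_d(p$eps_dd, p$E_nu))
  out
}

#' @export
summary.kin_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 ea_range = range(apparent_ea(object$params,
                                              object$series$T))),
            class = "summary.kin_fit")
}

#' @export
print.summary.kin_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residuals (%s space): min %.3g, median %.3g, max %.3g\n",
              x$fit$space, min(x$residuals), stats::median(x$residuals),
              max(x$residuals)))
  cat(sprintf("  apparent activation energy over the data range: %.6g to %.6g cal/mol\n",
              x$ea_range[1], x$ea_range[2]))
  invisible(x)
}

#' Predicted rates from a fitted law
#'
#' @param object a `kin_fit`
#' @param newdata optional list or data.frame with a `T` component
#'   (temperatures in K); defaults to the fitted data's temperatures
#' @param ... unused
#' @return numeric vector of predicted k(T)
#' @export
predict.kin_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$series$T else newdata$T
  eval_rate_law(object$params, T)
}

#' @export
residuals.kin_fit <- function(object, ...) {
  obs <- object$series$k
  mod <- predict(object)
  switch(object$space,
    log10 = log10(obs) - log10(mod),
    ln = log(obs) - log(mod),
    linear = obs - mod,
    relative = (obs - mod) / obs,
    gamma = log(obs) - log(mod))
}

#' Simulate rate series from a fitted law
#'
#' Draws lognormal multiplicative noise around the fitted curve; the log-sd
#' defaults to the root mean square ln-residual of the fit.
#'
#' @param object a `kin_fit`
#' @param nsim number of series
#' @param seed integer seed
#' @param sigma log-sd of the noise (optional)
#' @param ... unused
#' @return list of [rate_series()] of length `nsim`
#' @export
simulate.kin_fit <- function(object, nsim = 1, seed = 1L, sigma = NULL, ...) {
  if (is.null(sigma)) {
    lr <- log(object$series$k) - log(predict(object))
    sigma <- sqrt(mean(lr^2))
  }
  lapply(seq_len(nsim), function(i)
    synth_rate_series(object$params, T_grid = object$series$T,
                      noise = "lognormal", sigma = sigma,
                      seed = seed + i - 1L))
}

#' Arrhenius- or transitivity-plane plot of a fit
#'
#' Base-graphics diagnostic: data and fitted curve, with the conventional
#' 1000/T abscissa in the Arrhenius plane or beta in the transitivity plane.
#'
#' @param x a `kin_fit`
#' @param plane "arrhenius" or "transitivity"
#' @param ... passed to [plot()]
#' @export
plot.kin_fit <- function(x, plane = x$plane, ...) {
  s <- x$series
  Tfine <- seq(min(s$T), max(s$T), length.out = 200)
  if (plane == "arrhenius") {
    plot(1000 / s$T, log10(s$k), xlab = "1000/T (1/K)", ylab = "log10 k",
         main = sprintf("%s fit", x$law), ...)
    graphics::lines(1000 / Tfine, log10(eval_rate_law(x$params, Tfine)))
  } else {
    ts <- numerical_transitivity(s)
    plot(ts$beta, ts$gamma, xlab = "beta (mol/cal)", ylab = "gamma (cal/mol)^-1",
         main = sprintf("%s fit, transitivity plane", x$law), ...)
    graphics::lines(ts$beta, transitivity_gamma(x$params, ts$beta))
  }
  invisible(x)
}
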