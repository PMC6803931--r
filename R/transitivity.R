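#' Rate-constant series container
#'
#' Holds (T, k) observations with an optional per-point uncertainty and a
#' units tag. Rows are sorted by increasing temperature on construction;
#' duplicate temperatures are kept (the transitivity builder averages them in
#' ln k before differencing).
#'
#' @param T temperatures, K
#' @param k rate constants, strictly positive
#' @param sigma optional per-point uncertainty (same units as k)
#' @param units units tag for k, e.g. "cm3 mol-1 s-1", "cm3 molecule-1 s-1",
#'   "s-1" or "arbitrary"
#' @param label free-text label
#' @return data.frame of class `rate_series` with attributes `units`, `label`
#' @export
rate_series <- function(T, k, sigma = NULL, units = "arbitrary", label = "") {
  stopifnot(is.numeric(T), is.numeric(k), length(T) == length(k))
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be finite and > 0")
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be finite and > 0")
  if (!is.null(sigma)) stopifnot(length(sigma) == length(k), all(sigma >= 0))
  ord <- order(T)
  out <- data.frame(T = T[ord], k = k[ord])
  if (!is.null(sigma)) out$sigma <- sigma[ord]
  structure(out, class = c("rate_series", "data.frame"),
            units = as.character(units), label = as.character(label))
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series: %d points, %.6g-%.6g K, k in %s>%s\n",
              nrow(x), min(x$T), max(x$T), attr(x, "units"),
              if (nzchar(attr(x, "label"))) paste0(" ", attr(x, "label")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Savitzky--Golay smoothing
#'
#' Local least-squares polynomial smoothing; polynomials of degree <= `order`
#' pass through unchanged (including at the sequence ends, which use the
#' one-sided rows of the filter matrix).
#'
#' @param y numeric sequence
#' @param window odd integer window length, `order < window <= length(y)`
#' @param order polynomial order
#' @return smoothed numeric vector of the same length
#' @export
savgol_smooth <- function(y, window = 7L, order = 2L) {
  stopifnot(is.numeric(y))
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order < 0L || order >= window) stop("need 0 <= order < window")
  if (window > length(y)) stop("window exceeds sequence length")
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

# derivative of the interpolating quadratic through (x0,y0),(x1,y1),(x2,y2)
# evaluated at xe; exact for quadratics, 2nd order on unequal grids
.lagrange3_deriv <- function(x0, x1, x2, y0, y1, y2, xe) {
  y0 * (2 * xe - x1 - x2) / ((x0 - x1) * (x0 - x2)) +
  y1 * (2 * xe - x0 - x2) / ((x1 - x0) * (x1 - x2)) +
  y2 * (2 * xe - x0 - x1) / ((x2 - x0) * (x2 - x1))
}

#' Transitivity plot by numerical differentiation
#'
#' Builds the transitivity series gamma(beta) = 1/Ea(beta) from tabulated
#' (T, k) data. The apparent activation energy is the negative derivative of
#' ln k with respect to the molar inverse temperature beta = 1/(R*T),
#' estimated by the three-point unequal-spacing stencil at interior points
#' and by one-sided three-point stencils at the two endpoints (flagged as
#' lower-accuracy in the output). Duplicate temperatures are averaged in
#' ln k first. Optional Savitzky--Golay smoothing is applied to ln k before
#' differencing, since differentiating raw noisy k amplifies noise
#' multiplicatively.
#'
#' @param series a [rate_series()] (>= 3 distinct temperatures)
#' @param smooth `NULL` (none), `TRUE` (default window 7, order 2) or a list
#'   with elements `window` and `order`
#' @return data.frame of class `transitivity_series` with columns `T`,
#'   `beta` (mol/cal), `Ea` (cal/mol), `gamma` (mol/cal; `NA` where Ea = 0,
#'   flagged in `singular`), and logical `endpoint`; attribute `smoothed`
#' @examples
#' p <- rate_law_params("arrhenius", A = 1, Ea = 1000)
#' s <- rate_series(T = seq(200, 400, length.out = 20), k = eval_rate_law(p, seq(200, 400, length.out = 20)))
#' head(numerical_transitivity(s))
#' @export
numerical_transitivity <- function(series, smooth = NULL) {
  stopifnot(inherits(series, "rate_series"))
  lnk <- log(series$k)
  # average ln k over duplicate temperatures: stencils need distinct abscissae
  Tu <- sort(unique(series$T))
  if (length(Tu) < nrow(series))
    lnk <- vapply(Tu, function(t) mean(lnk[series$T == t]), numeric(1))
  else
    lnk <- lnk[order(series$T)]
  n <- length(Tu)
  if (n < 3L) stop("need at least 3 distinct temperatures")
  smoothed <- FALSE
  if (isTRUE(smooth)) smooth <- list(window = 7L, order = 2L)
  if (is.list(smooth)) {
    lnk <- savgol_smooth(lnk, window = smooth$window, order = smooth$order)
    smoothed <- TRUE
  }
  beta <- 1 / (.kc$R_cal * Tu)
  dlnk <- numeric(n)
  idx <- cbind(c(1L, seq_len(n - 2L), n - 2L),
               c(2L, seq_len(n - 2L) + 1L, n - 1L),
               c(3L, seq_len(n - 2L) + 2L, n))
  for (i in seq_len(n)) {
    j <- idx[i, ]
    dlnk[i] <- .lagrange3_deriv(beta[j[1]], beta[j[2]], beta[j[3]],
                                lnk[j[1]], lnk[j[2]], lnk[j[3]], beta[i])
  }
  Ea <- -dlnk
  singular <- Ea == 0
  gam <- ifelse(singular, NA_real_, 1 / Ea)
  out <- data.frame(T = Tu, beta = beta, Ea = Ea, gamma = gam,
                    singular = singular,
                    endpoint = seq_len(n) %in% c(1L, n))
  structure(out, class = c("transitivity_series", "data.frame"),
            smoothed = smoothed)
}

#' @export
print.transitivity_series <- function(x, ...) {
  cat(sprintf("<transitivity_series: %d points%s>\n", nrow(x),
              if (isTRUE(attr(x, "smoothed"))) ", Savitzky-Golay smoothed" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
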