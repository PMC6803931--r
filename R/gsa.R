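#' Generalized simulated annealing configuration
#'
#' Tuning knobs for the Tsallis-statistics annealer used by
#' [gsa_minimize()] and [fit_rate_data()]. The visiting-distribution index
#' `qv` controls the step-length tail (1 < qv < 3; heavier tails for larger
#' qv), the acceptance index `qa` the generalized Metropolis rule, and
#' `t_initial` the starting artificial temperature (`NULL` scales it to the
#' objective at the start point).
#'
#' @param qv visiting index, 1 < qv < 3
#' @param qa acceptance index (qa < 1; more negative is greedier)
#' @param t_initial initial visiting temperature or `NULL`
#' @param max_iter number of annealing iterations
#' @param seed integer seed; identical seed gives bitwise-identical runs
#' @param trace logical, keep the best-so-far objective history
#' @return list of class `gsa_config`
#' @export
gsa_config <- function(qv = 2.62, qa = -5, t_initial = NULL,
                       max_iter = 10000L, seed = 1L, trace = FALSE) {
  stopifnot(qv > 1, qv < 3, qa < 1, max_iter >= 1)
  structure(list(qv = qv, qa = qa, t_initial = t_initial,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 trace = isTRUE(trace)),
            class = "gsa_config")
}

# fold a proposal into [lower, upper] by triangle-wave reflection; robust to
# arbitrarily long heavy-tailed jumps (period-2w modulo, no loops)
.reflect_box <- function(x, lower, upper) {
  w <- upper - lower
  out <- x
  mv <- w > 0
  r <- (x[mv] - lower[mv]) %% (2 * w[mv])
  out[mv] <- lower[mv] + ifelse(r > w[mv], 2 * w[mv] - r, r)
  out[!mv] <- lower[!mv]
  out
}

#' Minimize a function by generalized simulated annealing
#'
#' Tsallis-statistics simulated annealing over a bounded box. The visiting
#' temperature follows the generalized schedule
#' Tqv(t) = Tqv(1) * (2^(qv-1) - 1) / ((1+t)^(qv-1) - 1); candidate steps are
#' per-coordinate draws from the one-dimensional Tsallis visiting
#' distribution (a q-Gaussian, sampled exactly as a scaled Student-t with
#' df = (3-qv)/(qv-1)), with the step width cooled in proportion to
#' (Tqv(t)/Tqv(1))^(1/(qv-1)) of the box width and proposals reflected back
#' into the box. Uphill moves are accepted with the generalized Metropolis
#' probability [1 + (qa-1) dE / Ta(t)]^(1/(1-qa)) (zero when the bracket is
#' non-positive), with acceptance temperature Ta(t) = Tqv(t)/t. Non-finite
#' objective values are treated as +Inf; on ties the earlier-found point is
#' kept, so the best-so-far trace is non-increasing and a fixed seed
#' reproduces the run bitwise.
#'
#' @param objective function of a numeric vector returning a scalar
#' @param lower,upper finite bounds defining the search box
#' @param x0 optional start point (defaults to the box midpoint)
#' @param config a [gsa_config()]
#' @return list with `par`, `value`, `n_eval`, `trace` (best-so-far values,
#'   or `NULL`)
#' @examples
#' gsa_minimize(function(x) (x - 2)^2, -10, 10,
#'              config = gsa_config(max_iter = 2000, seed = 1))$par
#' @export
gsa_minimize <- function(objective, lower, upper, x0 = NULL,
                         config = gsa_config()) {
  stopifnot(is.function(objective), is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), inherits(config, "gsa_config"))
  if (length(lower) == 0L) stop("empty bounds")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper < lower))
    stop("bounds must be finite with upper >= lower")
  D <- length(lower)
  w <- upper - lower
  f <- function(x) {
    v <- suppressWarnings(tryCatch(objective(x), error = function(e) Inf))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }
  if (is.null(x0)) x0 <- (lower + upper) / 2
  x0 <- .reflect_box(x0, lower, upper)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                 add = TRUE)
  set.seed(config$seed)

  qv <- config$qv; qa <- config$qa
  nu <- (3 - qv) / (qv - 1)      # Student-t df of the 1-D Tsallis visitor
  x <- x0; fx <- f(x)
  n_eval <- 1L
  t1 <- config$t_initial
  if (is.null(t1)) t1 <- 100 * max(abs(fx), 1)
  if (!is.finite(fx)) {
    # scan a few deterministic points for a finite start
    for (frac in seq(0.05, 0.95, by = 0.1)) {
      xt <- lower + frac * w; ft <- f(xt); n_eval <- n_eval + 1L
      if (is.finite(ft)) { x <- xt; fx <- ft; break }
    }
    if (!is.finite(fx)) stop("objective is non-finite everywhere tried")
    if (is.null(config$t_initial)) t1 <- 100 * max(abs(fx), 1)
  }
  best <- x; fbest <- fx
  trace <- if (config$trace) numeric(config$max_iter) else NULL
  pow <- qv - 1
  denom1 <- 2^pow - 1
  for (t in seq_len(config$max_iter)) {
    Tv <- t1 * denom1 / ((1 + t)^pow - 1)
    srel <- (Tv / t1)^(1 / pow)
    dx <- w * srel * stats::rt(D, df = nu) / sqrt(3 - qv)
    cand <- .reflect_box(x + dx, lower, upper)
    fc <- f(cand); n_eval <- n_eval + 1L
    if (fc < fx) {
      x <- cand; fx <- fc
    } else if (is.finite(fc)) {
      Ta <- Tv / t
      base <- 1 + (qa - 1) * (fc - fx) / Ta
      if (base > 0 && stats::runif(1) < base^(1 / (1 - qa))) {
        x <- cand; fx <- fc
      }
    }
    if (fx < fbest) { best <- x; fbest <- fx }
    if (config$trace) trace[t] <- fbest
  }
  list(par = best, value = fbest, n_eval = n_eval, trace = trace)
}

#' Mean squared residual between observed and modelled rates
#'
#' The fit objective: sum of squared residuals in the chosen residual space,
#' divided by the number of points. `log10` (the default space of
#' [fit_rate_data()]) and `ln` require strictly positive values; `relative`
#' uses (obs - model)/obs.
#'
#' @param observed,model numeric vectors of equal length
#' @param space one of "log10", "ln", "linear", "relative"
#' @return nonnegative scalar
#' @examples
#' chi_square(c(10, 100), c(10, 10), "log10")  # 0.5
#' @export
chi_square <- function(observed, model,
                       space = c("log10", "ln", "linear", "relative")) {
  space <- match.arg(space)
  stopifnot(is.numeric(observed), is.numeric(model),
            length(observed) == length(model), length(observed) >= 1L)
  r <- switch(space,
    log10 = {
      if (any(observed <= 0) || any(model <= 0))
        stop("nonpositive rate in logarithmic space")
      log10(observed) - log10(model)
    },
    ln = {
      if (any(observed <= 0) || any(model <= 0))
        stop("nonpositive rate in logarithmic space")
      log(observed) - log(model)
    },
    linear = observed - model,
    relative = (observed - model) / observed)
  mean(r^2)
}
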