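# shared oracles and small fixtures, built in code at test time

R_CAL <- kin_constants()$R_cal

# independent finite-difference apparent activation energy:
# centered difference of ln k with respect to beta = 1/(R T)
fd_apparent_ea <- function(params, T, h = 1e-6) {
  beta <- 1 / (R_CAL * T)
  db <- beta * h
  lnk <- function(b) log(eval_rate_law(params, 1 / (R_CAL * b)))
  -(lnk(beta + db) - lnk(beta - db)) / (2 * db)
}

# second derivative of ln k wrt beta (curvature in the Arrhenius plane)
fd_lnk_curvature <- function(params, T, h = 1e-5) {
  beta <- 1 / (R_CAL * T)
  db <- beta * h
  lnk <- function(b) log(eval_rate_law(params, 1 / (R_CAL * b)))
  (lnk(beta + db) - 2 * lnk(beta) + lnk(beta - db)) / db^2
}

# a convenient exactly-evaluable AM parameter set (moderate-tunneling-like)
am_ref_params <- function() rate_law_params("am", A = 1.11e-10,
                                            eps_dd = 9170, d = -0.086)

true_coefs <- function(params) {
  fields <- switch(params$law,
    arrhenius = "Ea", am = c("eps_dd", "d"), ascc = c("eps_dd", "E_nu"),
    nts = c("E0", "T0"), vft = c("B", "T0"))
  out <- unlist(params[c("A", fields)])
  if (params$law == "ascc")
    out <- c(out, d = ascc_d(params$eps_dd, params$E_nu))
  out
}

max_rel_err <- function(est, tru) max(abs(est / tru - 1))
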