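# Output files carry a provenance header (package version, seed, input
# hashes, resolved parameters) but no timestamps, so a seeded run reproduces
# its outputs byte-for-byte.
.provenance_header <- function(seed = NULL, inputs = character(),
                               extra = character()) {
  h <- c("# ratekin output",
         sprintf("# ratekin_version: %s",
                 as.character(utils::packageVersion("ratekin"))))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", as.integer(seed)))
  for (p in inputs)
    h <- c(h, sprintf("# input_md5 %s: %s", basename(p),
                      unname(tools::md5sum(p))))
  c(h, extra)
}

#' Read a delimited rate-constant table
#'
#' Accepts comma- or whitespace-delimited text with '#' comment lines and a
#' header row naming a temperature column (name starting with "T", kelvin)
#' and a rate column (name starting with "k"). A units tag may ride on the
#' rate column name after a dot or underscore (e.g. `k_cm3.mol.s`); otherwise
#' units are "arbitrary". Rows are validated (finite, k > 0, T > 0) with
#' offending line numbers reported; duplicate temperatures are preserved for
#' the transitivity builder to average.
#'
#' @param path file path
#' @return a [rate_series()] sorted by temperature
#' @export
read_rate_table <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  txt <- raw[keep]
  if (length(txt) < 2L) stop("rate table needs a header and at least one row")
  sep <- if (grepl(",", txt[1])) "," else ""
  parse_row <- function(s) {
    if (sep == ",") trimws(strsplit(s, ",")[[1]])
    else strsplit(trimws(s), "\\s+")[[1]]
  }
  hdr <- parse_row(txt[1])
  icolT <- grep("^[Tt]", hdr)[1]
  icolk <- grep("^[Kk]", hdr)[1]
  if (is.na(icolT) || is.na(icolk))
    stop("header must name a temperature column (T...) and a rate column (k...)")
  icols <- grep("^(sigma|err|unc)", hdr, ignore.case = TRUE)[1]
  units <- sub("^[Kk][._]?", "", hdr[icolk])
  if (!nzchar(units)) units <- "arbitrary"
  rows <- lapply(txt[-1], parse_row)
  Tv <- kv <- sv <- numeric(length(rows))
  has_sigma <- !is.na(icols)
  for (i in seq_along(rows)) {
    r <- suppressWarnings(as.numeric(rows[[i]]))
    ln <- lineno[i + 1L]
    if (length(r) < max(icolT, icolk) || anyNA(r[c(icolT, icolk)]))
      stop(sprintf("unparseable row at line %d of %s", ln, path))
    if (!is.finite(r[icolT]) || r[icolT] <= 0)
      stop(sprintf("nonpositive temperature at line %d of %s", ln, path))
    if (!is.finite(r[icolk]) || r[icolk] <= 0)
      stop(sprintf("nonpositive rate constant at line %d of %s", ln, path))
    Tv[i] <- r[icolT]; kv[i] <- r[icolk]
    if (has_sigma) sv[i] <- r[icols]
  }
  rate_series(Tv, kv, sigma = if (has_sigma) sv else NULL, units = units,
              label = basename(path))
}

#' Write a rate table / transitivity table
#'
#' Plain whitespace-delimited text with the standard provenance header.
#' `write_rate_table` writes (T, k[, sigma]); `write_transitivity_table`
#' writes the four-column (T, beta, Ea, gamma) transitivity-plane table.
#'
#' @param x a [rate_series()] or [numerical_transitivity()] result
#' @param path output path
#' @param seed optional seed to record in the header
#' @param inputs optional input paths whose md5 to record
#' @return `path`, invisibly
#' @export
write_rate_table <- function(x, path, seed = NULL, inputs = character()) {
  stopifnot(inherits(x, "rate_series"))
  hdr <- .provenance_header(seed, inputs,
                            sprintf("# units: %s", attr(x, "units")))
  cols <- c("T_K", paste0("k.", gsub("[^A-Za-z0-9.]", ".", attr(x, "units"))))
  body <- sprintf("%.10g %.10g", x$T, x$k)
  if (!is.null(x$sigma)) {
    cols <- c(cols, "sigma")
    body <- sprintf("%.10g %.10g %.10g", x$T, x$k, x$sigma)
  }
  writeLines(c(hdr, paste(cols, collapse = " "), body), path)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
write_transitivity_table <- function(x, path, seed = NULL,
                                     inputs = character()) {
  stopifnot(inherits(x, "transitivity_series"))
  hdr <- .provenance_header(seed, inputs,
    c("# units: T K, beta mol/cal, Ea cal/mol, gamma mol/cal",
      sprintf("# smoothed: %s", isTRUE(attr(x, "smoothed")))))
  writeLines(c(hdr, "T_K beta Ea gamma",
               sprintf("%.10g %.10g %.10g %.10g", x$T, x$beta, x$Ea,
                       x$gamma)), path)
  invisible(path)
}

.law_formula_name <- function(law) switch(law,
  arrhenius = "Arrhenius", am = "AquilantiMundim", ascc = "ASCC",
  nts = "NTS", vft = "VFT")

#' Write a fit report
#'
#' Human-readable "Fit_<FormulaName>.dat" (law, parameters, chi-square and
#' residual space, seed, evaluation count, per-point residual table) plus a
#' machine-readable flat key-value twin "Fit_<FormulaName>.yml".
#'
#' @param fit a [fit_rate_data()] result
#' @param dir output directory (created if missing)
#' @param inputs optional input paths whose md5 to record
#' @return named character vector with the two paths, invisibly
#' @export
write_fit_report <- function(fit, dir = ".", inputs = character()) {
  stopifnot(inherits(fit, "kin_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fname <- .law_formula_name(fit$law)
  dat <- file.path(dir, sprintf("Fit_%s.dat", fname))
  yml <- file.path(dir, sprintf("Fit_%s.yml", fname))
  cf <- coef(fit)
  res <- residuals(fit)
  lines <- c(
    .provenance_header(fit$seed, inputs),
    sprintf("# law: %s", fname),
    sprintf("# plane: %s", fit$plane),
    sprintf("# chi2: %.10g (%s space, mean squared residual)",
            fit$chi2, fit$space),
    sprintf("# n_eval: %d", fit$n_eval),
    "# parameters (energies cal/mol, temperatures K, A in source units):",
    sprintf("#   %-8s = %.10g", names(cf), cf),
    "T_K k_obs k_model residual",
    sprintf("%.10g %.10g %.10g %.10g", fit$series$T, fit$series$k,
            predict(fit), res))
  writeLines(lines, dat)
  yaml::write_yaml(c(list(law = fit$law, plane = fit$plane, chi2 = fit$chi2,
                          space = fit$space, seed = fit$seed,
                          n_eval = fit$n_eval),
                     as.list(cf)), yml)
  invisible(c(dat = dat, yml = yml))
}

#' Write / load a species spec file
#'
#' Flat YAML key-value representation of a [species()] (the supported input
#' path for molecular descriptors; the quantum-chemistry-log extractor is a
#' best-effort convenience). A write/read round trip reproduces the object
#' exactly.
#'
#' @param sp a [species()]
#' @param path file path (.yml/.yaml)
#' @return `path` invisibly for the writer
#' @export
write_species_spec <- function(sp, path) {
  stopifnot(inherits(sp, "kin_species"))
  x <- unclass(sp)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load a species from a spec file or quantum-chemistry log
#'
#' `x` may be a path to a YAML spec (as written by [write_species_spec()]),
#' a path to a Gaussian-style frequency log, or a character vector of log
#' lines (as produced by [synth_qc_log()]). Log extraction recognizes the
#' blocks "Multiplicity", "SCF Done" (hartree), "Rotational constants
#' (GHZ)" (a leading zero marks a linear rotor), "Frequencies --" (negative
#' entries are imaginary; the magnitude of the first is attached as
#' attribute `nu_imag_cm1`, with a warning if more than one), "Rotational
#' symmetry number", "Molecular mass" and optionally "Molar volume".
#' An explicit `energy_override` supersedes the parsed energy.
#'
#' @param x path or character vector of log lines
#' @param name species name (defaults to the file base name)
#' @param energy_override optional list(value=, units=) replacing the
#'   electronic energy
#' @return a [species()]; for transition-state logs the imaginary-mode
#'   magnitude is in `attr(, "nu_imag_cm1")`
#' @export
load_species <- function(x, name = NULL, energy_override = NULL) {
  if (length(x) == 1L && file.exists(x)) {
    if (grepl("\\.(ya?ml)$", x, ignore.case = TRUE)) {
      spec <- yaml::read_yaml(x)
      spec$rotational_constants_cm1 <-
        if (!is.null(spec$rotational_constants_cm1))
          as.numeric(spec$rotational_constants_cm1)
      spec$frequencies_cm1 <- as.numeric(spec$frequencies_cm1)
      sp <- do.call(species, spec)
      if (!is.null(energy_override)) {
        sp$electronic_energy <- energy_override$value
        sp$energy_units <- if (is.null(energy_override$units)) "hartree"
                           else energy_override$units
      }
      return(sp)
    }
    lines <- readLines(x)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(x))
  } else {
    lines <- x
  }
  if (is.null(name)) name <- "species"
  grab1 <- function(pattern) {
    m <- grep(pattern, lines, value = TRUE)
    if (length(m)) m[1] else NULL
  }
  nums <- function(s) {
    m <- regmatches(s, gregexpr("-?[0-9]+\\.?[0-9]*([eE][-+]?[0-9]+)?", s))[[1]]
    as.numeric(m)
  }
  fl <- grep("Frequencies --", lines, value = TRUE)
  freqs <- if (length(fl)) unlist(lapply(fl, nums)) else numeric(0)
  imag <- freqs[freqs < 0]
  real <- freqs[freqs > 0]
  if (length(imag) > 1L)
    warning("more than one imaginary mode; taking the first")
  rl <- grab1("Rotational constants \\(GHZ\\)")
  if (is.null(rl) && length(freqs))
    stop("frequency block without 'Rotational constants' in log")
  ml <- grab1("Molecular mass")
  if (is.null(ml)) stop("no 'Molecular mass' line in log")
  mass <- nums(ml)[1]
  mult <- grab1("Multiplicity")
  degeneracy <- if (!is.null(mult)) utils::tail(nums(mult), 1) else 1
  scf <- grab1("SCF Done")
  energy <- if (!is.null(scf)) nums(sub(".*=", "", scf))[1] else 0
  sigl <- grab1("Rotational symmetry number")
  sigma <- if (!is.null(sigl)) nums(sigl)[1] else 1
  voll <- grab1("Molar volume")
  vol <- if (!is.null(voll)) nums(voll)[1] else NULL
  if (is.null(rl)) {
    if (length(freqs)) stop("an atom cannot have a frequency block")
    sp <- species(name, mass_amu = mass, geometry = "atom", sigma = 1,
                  electronic_energy = energy, energy_units = "hartree",
                  degeneracy = degeneracy, molar_volume_cm3 = vol)
  } else {
    ghz <- nums(sub(".*:", "", rl))
    to_cm1 <- function(g) g * 1e9 / .kc$c_cm
    if (ghz[1] == 0) {
      geom <- "linear"; rc <- to_cm1(ghz[2])
    } else {
      geom <- "nonlinear"; rc <- to_cm1(ghz[1:3])
    }
    sp <- species(name, mass_amu = mass, geometry = geom,
                  rotational_constants_cm1 = rc, sigma = sigma,
                  frequencies_cm1 = real, electronic_energy = energy,
                  energy_units = "hartree", degeneracy = degeneracy,
                  molar_volume_cm3 = vol)
  }
  if (!is.null(energy_override)) {
    sp$electronic_energy <- energy_override$value
    sp$energy_units <- if (is.null(energy_override$units)) "hartree"
                       else energy_override$units
  }
  if (length(imag)) attr(sp, "nu_imag_cm1") <- abs(imag[1])
  sp
}

#' Load a reaction system from a YAML spec
#'
#' The spec holds `reactants` (list of species specs, inline),
#' `ts`, optional `products`, `nu_imag_cm1`, optional `dH_cal_mol` and
#' optional `energy_override` (named by species).
#'
#' @param path YAML file
#' @return a [reaction_system()]
#' @export
load_reaction_system <- function(path) {
  spec <- yaml::read_yaml(path)
  mk <- function(s) {
    s$rotational_constants_cm1 <-
      if (!is.null(s$rotational_constants_cm1))
        as.numeric(s$rotational_constants_cm1)
    s$frequencies_cm1 <- as.numeric(s$frequencies_cm1)
    do.call(species, s)
  }
  reaction_system(
    reactants = lapply(spec$reactants, mk),
    ts = mk(spec$ts),
    products = if (!is.null(spec$products)) lapply(spec$products, mk),
    nu_imag_cm1 = spec$nu_imag_cm1,
    dH_cal_mol = spec$dH_cal_mol,
    energy_override = spec$energy_override)
}

#' Load a solvent model from a YAML spec
#'
#' @param path YAML file with the [solvent_model()] fields
#' @return a [solvent_model()]
#' @export
load_solvent <- function(path) {
  do.call(solvent_model, yaml::read_yaml(path))
}

# parse "start:stop:count" into a temperature grid
.parse_tgrid <- function(s) {
  v <- as.numeric(strsplit(s, ":")[[1]])
  if (length(v) != 3L || anyNA(v) || v[3] < 1) stop("bad --Tgrid, use start:stop:count")
  seq(v[1], v[2], length.out = v[3])
}

.cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE; i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Thin shell over the package functions; the `exec/ratekin` script forwards
#' `commandArgs(trailingOnly = TRUE)` here. Subcommands:
#' \describe{
#'   \item{fit}{`--data table --law am [--plane arrhenius] [--space log10]
#'     [--seed 1] [--iters 10000] [--out dir]` — GSA fit; writes
#'     Fit_<FormulaName>.dat/.yml and plot-ready Arrhenius-plane
#'     (1000/T, log10 k) data.}
#'   \item{predict}{`--system sys.yml --method dtst --Tgrid 200:2000:50
#'     [--units molar] [--out dir]` — gas-phase k(T) table.}
#'   \item{solution}{`--system sys.yml --model kramers|collins-kimball
#'     --T 298.15 [--solvent solv.yml] [--method none] [--out dir]` —
#'     solvent-corrected rate at one temperature.}
#'   \item{transitivity}{`--data table [--savgol 7,2] [--out dir]` —
#'     four-column (T, beta, Ea, gamma) transitivity table.}
#' }
#' All randomness flows through `--seed`; a repeated seeded run writes
#' byte-identical files. A run log with the resolved parameters is written
#' alongside the outputs.
#'
#' @param args character vector of command-line arguments
#' @return 0 invisibly on success; errors propagate as R conditions (the
#'   shell wrapper maps them to a nonzero exit status)
#' @export
kin_cli <- function(args) {
  if (!length(args)) stop("usage: ratekin <fit|predict|solution|transitivity> --help")
  cmd <- args[1]
  flags <- .cli_flags(args[-1])
  out <- if (!is.null(flags$out)) flags$out else "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else 1L
  log_lines <- c(.provenance_header(seed),
                 sprintf("# command: %s", paste(args, collapse = " ")))
  written <- character(0)
  if (cmd == "fit") {
    if (is.null(flags$data) || is.null(flags$law))
      stop("fit requires --data and --law")
    series <- read_rate_table(flags$data)
    cfg <- gsa_config(seed = seed,
                      max_iter = if (!is.null(flags$iters))
                        as.integer(flags$iters) else 10000L)
    fit <- fit_rate_data(series, law = flags$law,
                         plane = if (!is.null(flags$plane)) flags$plane
                                 else "arrhenius",
                         space = if (!is.null(flags$space)) flags$space
                                 else "log10",
                         config = cfg)
    paths <- write_fit_report(fit, out, inputs = flags$data)
    # plot-ready Arrhenius-plane file: 1000/T vs log10 k, data and model
    arr <- file.path(out, sprintf("Arrhenius_%s.dat",
                                  .law_formula_name(fit$law)))
    writeLines(c(.provenance_header(seed, flags$data),
                 "invT_1000K log10_k_obs log10_k_model",
                 sprintf("%.10g %.10g %.10g", 1000 / series$T,
                         log10(series$k), log10(predict(fit)))), arr)
    written <- c(paths, arr)
    log_lines <- c(log_lines,
      sprintf("# law: %s plane: %s chi2: %.10g", fit$law, fit$plane,
              fit$chi2),
      sprintf("# param %s: %.10g", names(coef(fit)), coef(fit)))
  } else if (cmd == "predict") {
    if (is.null(flags$system) || is.null(flags$Tgrid))
      stop("predict requires --system and --Tgrid")
    sys <- load_reaction_system(flags$system)
    method <- if (!is.null(flags$method)) flags$method else "none"
    Tg <- .parse_tgrid(flags$Tgrid)
    units <- if (!is.null(flags$units)) flags$units else "molecule"
    k <- corrected_rate(sys, Tg, method = method, units = units)
    utag <- if (sys$molecularity == 2L) {
      if (units == "molar") "cm3 mol-1 s-1" else "cm3 molecule-1 s-1"
    } else "s-1"
    f <- file.path(out, sprintf("kT_%s.dat", method))
    writeLines(c(.provenance_header(seed, flags$system,
                                    sprintf("# units: %s", utag)),
                 "T_K k",
                 sprintf("%.10g %.10g", Tg, k)), f)
    written <- f
    log_lines <- c(log_lines, sprintf("# method: %s units: %s", method, utag))
  } else if (cmd == "solution") {
    if (is.null(flags$system) || is.null(flags$model) || is.null(flags$T))
      stop("solution requires --system, --model and --T")
    sys <- load_reaction_system(flags$system)
    solv <- if (!is.null(flags$solvent)) load_solvent(flags$solvent)
            else solvent_model()
    Ti <- as.numeric(flags$T)
    method <- if (!is.null(flags$method)) flags$method else "none"
    if (flags$model == "collins-kimball") {
      ktst <- corrected_rate(sys, Ti, method = method, units = "molar")
      vols <- vapply(sys$reactants, `[[`, numeric(1), "molar_volume_cm3")
      res <- collins_kimball_rate(ktst, vols[1], vols[2], solv, Ti)
      body <- c(sprintf("k_tst %.10g", res$k_tst),
                sprintf("k_D %.10g", res$k_D),
                sprintf("k_obs %.10g", res$k_obs),
                sprintf("D_A %.10g", res$D_A),
                sprintf("D_B %.10g", res$D_B))
    } else if (flags$model == "kramers") {
      un <- if (sys$molecularity == 2L) "molar" else "molecule"
      ktst <- corrected_rate(sys, Ti, method = method, units = un)
      res <- kramers_rate(ktst, .cage_radius_cm(sys$ts$molar_volume_cm3),
                          sys$ts$mass_amu, sys$nu_imag_cm1, solv, Ti)
      body <- c(sprintf("mu %.10g", res$mu),
                sprintf("kappa_kr %.10g", res$kappa_kr),
                sprintf("k_tst %.10g", res$k_tst),
                sprintf("k_obs %.10g", res$k_obs))
    } else stop("--model must be collins-kimball or kramers")
    f <- file.path(out, sprintf("solution_%s.dat", flags$model))
    writeLines(c(.provenance_header(seed, flags$system,
                                    sprintf("# eta_poise: %.10g", res$eta)),
                 body), f)
    written <- f
  } else if (cmd == "transitivity") {
    if (is.null(flags$data)) stop("transitivity requires --data")
    series <- read_rate_table(flags$data)
    smooth <- NULL
    if (!is.null(flags$savgol)) {
      wo <- as.integer(strsplit(flags$savgol, ",")[[1]])
      smooth <- list(window = wo[1], order = wo[2])
    }
    ts <- numerical_transitivity(series, smooth = smooth)
    f <- file.path(out, "transitivity.dat")
    write_transitivity_table(ts, f, seed = seed, inputs = flags$data)
    written <- f
  } else {
    stop("unknown subcommand: ", cmd)
  }
  log_lines <- c(log_lines, sprintf("# wrote: %s", basename(written)))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(0L)
}
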