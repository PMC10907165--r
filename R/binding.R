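# Single-site binding models and fits for ITC and fluorescence anisotropy.
#
# Concentration unit is uM throughout; volumes uL; heats ucal; enthalpies
# kcal/mol. With those units, heat(ucal) = volume(uL) * conc(uM) * dH(kcal/mol).

#' Equilibrium complex concentration for single-site binding
#'
#' Exact ligand-depletion solution of P + L <-> PL: the physically meaningful
#' root of the binding quadratic,
#' \deqn{[PL] = \frac{(K_d + L_t + P_t) - \sqrt{(K_d + L_t + P_t)^2 - 4 P_t L_t}}{2}.}
#' Evaluated in the algebraically equivalent form
#' `2*Pt*Lt / (S + sqrt(S^2 - 4*Pt*Lt))` with `S = Kd + Lt + Pt`, which avoids
#' catastrophic cancellation when the discriminant is close to `S^2` (weak
#' binding / strong depletion regimes).
#'
#' @param Pt total protein concentration (uM), vectorized.
#' @param Lt total ligand concentration (uM).
#' @param Kd dissociation constant (uM), > 0.
#' @return complex concentration (uM), always in `[0, min(Pt, Lt)]`.
#' @export
bound_complex <- function(Pt, Lt, Kd) {
  if (any(Pt < 0) || any(Lt < 0)) {
    stop("total concentrations must be non-negative", call. = FALSE)
  }
  if (any(Kd <= 0)) stop("Kd must be positive", call. = FALSE)
  S <- Kd + Lt + Pt
  disc <- S^2 - 4 * Pt * Lt
  disc[disc < 0] <- 0   # guard against roundoff for near-stoichiometric points
  denom <- S + sqrt(disc)
  out <- ifelse(denom > 0, 2 * Pt * Lt / denom, 0)
  pmin(out, pmin(Pt, Lt))
}

#' Anisotropy of a labeled peptide titrated with protein
#'
#' Observed anisotropy of a fixed concentration `Lt` of fluorescently labeled
#' peptide as a function of total protein `Pt`. In the default `"corrected"`
#' mode the signal is the bound fraction of the labeled species,
#' `A = A0 + (Amax - A0) * bound/Lt`, which is monotone in `Pt` and saturates
#' at `Amax`. The `"as_printed"` mode instead divides the binding quadratic's
#' numerator by `2*Pt` (the form some fitting protocols print); it is retained
#' for comparison but does not saturate at `Amax` when `Pt` is the titrated
#' species, and its `Pt = 0` value is taken as the `A0` limit.
#'
#' @param Pt total protein (uM), vectorized.
#' @param Lt total labeled peptide (uM).
#' @param A0,Amax anisotropy of free and fully bound peptide.
#' @param Kd dissociation constant (uM).
#' @param mode `"corrected"` (default) or `"as_printed"`.
#' @return anisotropy values.
#' @export
anisotropy_model <- function(Pt, Lt, A0, Amax, Kd,
                             mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  cplx <- bound_complex(Pt, Lt, Kd)
  if (mode == "corrected") {
    A0 + (Amax - A0) * cplx / Lt
  } else {
    frac <- ifelse(Pt > 0, cplx / Pt, 0)
    A0 + (Amax - A0) * frac
  }
}

#' Define an ITC protocol
#'
#' @param cell_volume calorimeter cell volume (uL).
#' @param cell_concentration macromolecule concentration loaded in the cell
#'   (uM; monomer units).
#' @param syringe_concentration injectant concentration (uM).
#' @param injection_volumes per-injection volumes (uL).
#' @param temperature experiment temperature (K).
#' @return list of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume = 200, cell_concentration = 100,
                         syringe_concentration = 1000,
                         injection_volumes = rep(2, 20),
                         temperature = 288) {
  if (cell_volume <= 0) stop("cell_volume must be positive", call. = FALSE)
  if (cell_concentration <= 0 || syringe_concentration <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (length(injection_volumes) < 2L) {
    stop("need at least 2 injections", call. = FALSE)
  }
  if (any(injection_volumes <= 0)) {
    stop("injection volumes must be positive", call. = FALSE)
  }
  structure(list(cell_volume = cell_volume,
                 cell_concentration = cell_concentration,
                 syringe_concentration = syringe_concentration,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "itc_protocol")
}

# Per-injection cell concentrations under the overflow-cell convention:
# injecting dV displaces an equal volume of well-mixed cell contents, so
# existing species are diluted by (1 - dV/V0) and the injectant adds
# syringe_conc * dV/V0.
itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  M <- protocol$cell_concentration
  X <- 0
  k <- length(protocol$injection_volumes)
  Mt <- Xt <- numeric(k)
  for (i in seq_len(k)) {
    f <- protocol$injection_volumes[i] / V0
    M <- M * (1 - f)
    X <- X * (1 - f) + protocol$syringe_concentration * f
    Mt[i] <- M; Xt[i] <- X
  }
  data.frame(injection = seq_len(k), Mt = Mt, Xt = Xt)
}

#' Model ITC injection heats for single-site binding
#'
#' Single-site isotherm with fitted stoichiometry `n` (injectant sites per
#' cell macromolecule monomer): after each injection the total injectant and
#' macromolecule concentrations are updated under the overflow-cell
#' convention, equilibrium complex is computed from the binding quadratic with
#' site concentration `n * [M]`, and the heat of injection i is
#' `cell_volume * dH * ([PL]_i - [PL]_{i-1} * (1 - dV_i/V0))` -- the enthalpy
#' of newly formed complex, accounting for complex displaced out of the cell
#' by the injection itself.
#'
#' @param Kd dissociation constant (uM).
#' @param n sites per macromolecule monomer (dimensionless; 0.5 means one
#'   injectant molecule bridges two macromolecules).
#' @param dH binding enthalpy (kcal/mol of injectant).
#' @param protocol an [itc_protocol()].
#' @param dilution_heat constant per-injection heat offset (ucal), default 0.
#' @return numeric vector of per-injection heats (ucal).
#' @export
itc_injection_heats <- function(Kd, n, dH, protocol, dilution_heat = 0) {
  stopifnot(inherits(protocol, "itc_protocol"))
  conc <- itc_concentrations(protocol)
  V0 <- protocol$cell_volume
  k <- nrow(conc)
  heats <- numeric(k)
  prev <- 0
  for (i in seq_len(k)) {
    cplx <- bound_complex(Pt = n * conc$Mt[i], Lt = conc$Xt[i], Kd = Kd)
    f <- protocol$injection_volumes[i] / V0
    heats[i] <- V0 * dH * (cplx - prev * (1 - f)) + dilution_heat
    prev <- cplx
  }
  heats
}

#' Build a titration series container
#'
#' @param mode `"itc"` or `"anisotropy"`.
#' @param heats per-injection heats (ucal; ITC mode).
#' @param protocol an [itc_protocol()] (ITC mode).
#' @param Pt protein totals (uM; anisotropy mode).
#' @param Lt labeled peptide total (uM; anisotropy mode).
#' @param anisotropy observed anisotropy values (anisotropy mode).
#' @param truth optional named list of generating parameters (synthetic data).
#' @return list of class `titration_series`.
#' @export
titration_series <- function(mode = c("itc", "anisotropy"),
                             heats = NULL, protocol = NULL,
                             Pt = NULL, Lt = NULL, anisotropy = NULL,
                             truth = NULL) {
  mode <- match.arg(mode)
  if (mode == "itc") {
    stopifnot(inherits(protocol, "itc_protocol"))
    if (length(heats) != length(protocol$injection_volumes)) {
      stop("heat count (", length(heats), ") does not match injection count (",
           length(protocol$injection_volumes), ")", call. = FALSE)
    }
  } else {
    if (is.null(Pt) || is.null(Lt) || is.null(anisotropy)) {
      stop("anisotropy series needs Pt, Lt and anisotropy", call. = FALSE)
    }
    if (length(Pt) != length(anisotropy)) {
      stop("Pt and anisotropy lengths differ", call. = FALSE)
    }
    if (Lt <= 0) stop("Lt must be positive", call. = FALSE)
    if (any(Pt < 0)) stop("Pt must be non-negative", call. = FALSE)
    if (is.unsorted(Pt)) {
      warning("Pt values are not increasing; fitting proceeds but check input")
    }
  }
  structure(list(mode = mode, heats = heats, protocol = protocol,
                 Pt = Pt, Lt = Lt, anisotropy = anisotropy, truth = truth),
            class = "titration_series")
}

new_binding_fit <- function(parameters, se, series, residuals, converged,
                            mode, diagnostics = character(0)) {
  structure(list(parameters = parameters, se = se, residuals = residuals,
                 converged = converged, mode = mode,
                 diagnostics = diagnostics,
                 rss = sum(residuals^2)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> mode=%s converged=%s\n", x$mode, x$converged))
  if (length(x$parameters) > 0L) {
    tab <- data.frame(estimate = unlist(x$parameters),
                      se = unlist(x$se)[names(x$parameters)])
    print(tab)
  }
  if (length(x$diagnostics) > 0L) {
    cat("diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Fit a single-site isotherm to ITC heats
#'
#' Nonlinear least squares of [itc_injection_heats()] against observed heats
#' over `(Kd, n, dH)` (Levenberg-Marquardt). The first injection is excluded
#' by default, the usual practice because of diffusion across the syringe tip
#' during equilibration. Initialization: `Kd` from the molar ratio at the
#' steepest observed heat change, `dH` from the first usable heat, `n = 1`.
#'
#' @param series an ITC-mode [titration_series()].
#' @param init optional named list with any of `Kd`, `n`, `dH` to override the
#'   automatic start.
#' @param fix_n fix stoichiometry at `init$n` instead of fitting it.
#' @param skip_first drop the first injection (default TRUE).
#' @return a `binding_fit` with parameters `Kd` (uM), `n`, `dH` (kcal/mol),
#'   standard errors, residuals and diagnostics. Degenerate data (for example
#'   all-zero heats) yield `converged = FALSE` with an explanatory diagnostic
#'   and no parameter estimates.
#' @export
fit_itc <- function(series, init = NULL, fix_n = FALSE, skip_first = TRUE) {
  stopifnot(inherits(series, "titration_series"), series$mode == "itc")
  protocol <- series$protocol
  heats <- series$heats
  use <- seq_along(heats)
  if (skip_first) use <- use[-1]
  if (length(use) < 5L) stop("need at least 5 usable injections", call. = FALSE)
  obs <- heats[use]

  if (max(abs(obs)) < .Machine$double.eps^0.5 ||
      stats::sd(obs) < 1e-6 * max(abs(obs), 1e-12)) {
    return(new_binding_fit(list(), list(), series,
                           residuals = obs, converged = FALSE, mode = "itc",
                           diagnostics = "no binding signal: heats are flat/zero"))
  }

  conc <- itc_concentrations(protocol)
  # steepest change in heat locates the equivalence region; start Kd there
  d <- abs(diff(obs))
  i_inf <- use[min(which.max(d) + 1L, length(use))]
  start <- list(
    Kd = max(conc$Mt[i_inf] / 2, 1e-3),
    n = 1,
    dH = heats[use[1]] / (protocol$cell_volume *
           min(protocol$syringe_concentration *
                 protocol$injection_volumes[use[1]] / protocol$cell_volume,
               conc$Mt[1]))
  )
  if (abs(start$dH) < 1e-8) start$dH <- sign(sum(obs)) * 1
  for (nm in names(init)) start[[nm]] <- init[[nm]]

  model_fun <- function(lKd, ln, dH) {
    itc_injection_heats(exp(lKd), exp(ln), dH, protocol)[use]
  }
  fit <- tryCatch({
    if (fix_n) {
      ln0 <- log(start$n)
      minpack.lm::nlsLM(
        obs ~ model_fun(lKd, ln0, dH),
        start = list(lKd = log(start$Kd), dH = start$dH),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        obs ~ model_fun(lKd, ln, dH),
        start = list(lKd = log(start$Kd), ln = log(start$n), dH = start$dH),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_binding_fit(list(), list(), series, residuals = obs,
                           converged = FALSE, mode = "itc",
                           diagnostics = paste("optimizer failure:",
                                               conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  Kd <- exp(cf[["lKd"]])
  n <- if (fix_n) start$n else exp(cf[["ln"]])
  dH <- cf[["dH"]]
  se <- list(Kd = NA_real_, n = NA_real_, dH = NA_real_)
  if (!is.null(vc)) {
    # delta method for the log-parameterized quantities
    se$Kd <- Kd * sqrt(vc["lKd", "lKd"])
    if (!fix_n) se$n <- n * sqrt(vc["ln", "ln"])
    se$dH <- sqrt(vc["dH", "dH"])
  }
  diags <- character(0)
  cval <- n * conc$Mt[1] / Kd
  if (cval > 1000) diags <- c(diags, "very high c-value: Kd weakly identified")
  if (cval < 0.1) diags <- c(diags, "very low c-value: n weakly identified")
  new_binding_fit(list(Kd = Kd, n = n, dH = dH), se, series,
                  residuals = stats::residuals(fit), converged = TRUE,
                  mode = "itc", diagnostics = diags)
}

#' Fit the ligand-depletion anisotropy isotherm
#'
#' Nonlinear least squares over `(Kd, A0, Amax)` with the labeled-peptide
#' total `Lt` fixed at its experimental value, using [anisotropy_model()].
#'
#' @param series an anisotropy-mode [titration_series()].
#' @param init optional named list with any of `Kd`, `A0`, `Amax`.
#' @param mode passed to [anisotropy_model()].
#' @return a `binding_fit` with parameters `Kd` (uM), `A0`, `Amax`. Flat data
#'   yield `converged = FALSE` with an unidentifiable-Kd diagnostic.
#' @export
fit_anisotropy <- function(series, init = NULL,
                           mode = c("corrected", "as_printed")) {
  stopifnot(inherits(series, "titration_series"), series$mode == "anisotropy")
  mode <- match.arg(mode)
  Pt <- series$Pt; Lt <- series$Lt; A <- series$anisotropy
  if (length(Pt) < 6L) stop("need at least 6 titration points", call. = FALSE)
  if (stats::sd(A) < 1e-12 || diff(range(A)) < 1e-6 * max(abs(A), 1e-12)) {
    return(new_binding_fit(list(), list(), series, residuals = A - mean(A),
                           converged = FALSE, mode = "anisotropy",
                           diagnostics = "flat anisotropy: Kd unidentifiable"))
  }
  Amid <- (min(A) + max(A)) / 2
  i_mid <- which.min(abs(A - Amid))
  start <- list(Kd = max(Pt[i_mid], 1e-3), A0 = min(A), Amax = max(A))
  for (nm in names(init)) start[[nm]] <- init[[nm]]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ anisotropy_model(Pt, Lt, A0, Amax, exp(lKd), mode = mode),
      start = list(lKd = log(start$Kd), A0 = start$A0, Amax = start$Amax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_binding_fit(list(), list(), series, residuals = A - mean(A),
                           converged = FALSE, mode = "anisotropy",
                           diagnostics = paste("optimizer failure:",
                                               conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  Kd <- exp(cf[["lKd"]])
  se <- list(Kd = NA_real_, A0 = NA_real_, Amax = NA_real_)
  if (!is.null(vc)) {
    se$Kd <- Kd * sqrt(vc["lKd", "lKd"])
    se$A0 <- sqrt(vc["A0", "A0"]); se$Amax <- sqrt(vc["Amax", "Amax"])
  }
  diags <- character(0)
  if (Kd > 10 * max(Pt)) {
    diags <- c(diags, "Kd above titrated range: poorly constrained")
  }
  new_binding_fit(list(Kd = Kd, A0 = cf[["A0"]], Amax = cf[["Amax"]]),
                  se, series, residuals = stats::residuals(fit),
                  converged = TRUE, mode = "anisotropy", diagnostics = diags)
}

#' Residual-resampling bootstrap confidence intervals for a binding fit
#'
#' Refits the model to `fitted + resampled residuals` `n_boot` times and
#' returns percentile intervals for each parameter. Deterministic under a
#' fixed seed.
#'
#' @param fit a converged `binding_fit`.
#' @param series the `titration_series` that produced it.
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `parameter`, `estimate`, `lower`, `upper`,
#'   `n_boot_used`.
#' @export
bootstrap_ci <- function(fit, series, n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "binding_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit", call. = FALSE)
  if (n_boot < 20) stop("n_boot must be at least 20", call. = FALSE)
  set.seed(seed)
  res <- fit$residuals
  pars <- names(fit$parameters)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(pars),
                  dimnames = list(NULL, pars))
  refit_one <- function() {
    if (fit$mode == "itc") {
      use <- seq_along(series$heats)[-1]
      model <- itc_injection_heats(fit$parameters$Kd, fit$parameters$n,
                                   fit$parameters$dH, series$protocol)
      newheats <- series$heats
      newheats[use] <- model[use] + sample(res, length(use), replace = TRUE)
      s2 <- titration_series("itc", heats = newheats, protocol = series$protocol)
      fit_itc(s2, init = fit$parameters)
    } else {
      model <- anisotropy_model(series$Pt, series$Lt, fit$parameters$A0,
                                fit$parameters$Amax, fit$parameters$Kd)
      s2 <- titration_series("anisotropy", Pt = series$Pt, Lt = series$Lt,
                             anisotropy = model +
                               sample(res, length(model), replace = TRUE))
      fit_anisotropy(s2, init = fit$parameters)
    }
  }
  for (b in seq_len(n_boot)) {
    fb <- tryCatch(refit_one(), error = function(e) NULL)
    if (!is.null(fb) && fb$converged) {
      draws[b, ] <- unlist(fb$parameters)[pars]
    }
  }
  ok <- stats::complete.cases(draws)
  a <- (1 - level) / 2
  data.frame(
    parameter = pars,
    estimate = unlist(fit$parameters)[pars],
    lower = apply(draws[ok, , drop = FALSE], 2,
                  stats::quantile, probs = a, names = FALSE),
    upper = apply(draws[ok, , drop = FALSE], 2,
                  stats::quantile, probs = 1 - a, names = FALSE),
    n_boot_used = sum(ok),
    row.names = NULL
  )
}
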