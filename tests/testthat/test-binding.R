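test_that("bound_complex solves the binding quadratic exactly", {
  expect_equal(bound_complex(0, 2, 19), 0)
  # complete binding in the tight limit: complex -> min(Pt, Lt)
  expect_equal(bound_complex(10, 2, 1e-9), 2, tolerance = 1e-6)
  expect_equal(bound_complex(2, 10, 1e-9), 2, tolerance = 1e-6)
  # weak-depletion point evaluated by hand from the quadratic
  expect_equal(bound_complex(45, 0.1, 45), 0.0499722, tolerance = 1e-5)
  # consistent with the Lt -> 0 hyperbola Pt/(Pt + Kd)
  expect_equal(bound_complex(45, 1e-6, 45) / 1e-6, 0.5, tolerance = 1e-4)
  expect_error(bound_complex(-1, 1, 1), "non-negative")
  expect_error(bound_complex(1, 1, 0), "positive")
})

test_that("bound_complex respects 0 <= c <= min(Pt, Lt) over random triples", {
  set.seed(99)
  n <- 1e5
  Pt <- 10^stats::runif(n, -3, 4)
  Lt <- 10^stats::runif(n, -3, 4)
  Kd <- 10^stats::runif(n, -4, 4)
  cplx <- bound_complex(Pt, Lt, Kd)
  expect_true(all(cplx >= 0))
  expect_true(all(cplx <= pmin(Pt, Lt) + 1e-12))
  # mass balance: free * free / complex reproduces Kd
  free_ratio <- (Pt - cplx) * (Lt - cplx) / cplx
  ok <- cplx > 1e-9
  expect_lt(max(abs(free_ratio[ok] / Kd[ok] - 1)), 1e-5)
})

test_that("anisotropy model has the right endpoints and monotonicity", {
  expect_equal(anisotropy_model(0, 0.1, 0.05, 0.2, 45), 0.05)
  expect_equal(anisotropy_model(1e6, 0.1, 0.05, 0.2, 45), 0.2, tolerance = 1e-4)
  # half saturation at Pt = Kd in the weak-depletion limit
  expect_equal(anisotropy_model(45, 1e-4, 0.05, 0.2, 45), 0.125,
               tolerance = 1e-3)
  Pt <- sort(10^stats::runif(200, -2, 3))
  A <- anisotropy_model(Pt, 0.1, 0.05, 0.2, 45)
  expect_true(all(diff(A) >= -1e-12))
  expect_true(all(A >= 0.05 - 1e-12 & A <= 0.2 + 1e-12))
  # the literal printed form divides by 2*Pt and does not saturate at Amax
  Ap <- anisotropy_model(c(100, 500), 0.1, 0.05, 0.2, 45, mode = "as_printed")
  expect_true(all(Ap < 0.06))
})

test_that("ITC heats follow the single-site model and saturate", {
  prot <- itc_protocol()
  expect_equal(itc_injection_heats(19, 0.5, 0, prot), rep(0, 20))
  # a saturating protocol: tight binding fills the cell well before the end
  h <- itc_injection_heats(1, 0.5, -8, prot)
  expect_lt(abs(h[20]), 0.01 * abs(h[1]))
  expect_true(all(diff(abs(h)) < 0))   # monotone decay for this protocol
  expect_error(itc_protocol(injection_volumes = c(2, 0)), "positive")
})

test_that("ITC heats agree with a from-scratch mass-balance oracle", {
  prot <- itc_protocol(cell_volume = 200, cell_concentration = 100,
                       syringe_concentration = 1000,
                       injection_volumes = rep(2, 25))
  for (Kd in c(1, 19, 200)) {
    h <- itc_injection_heats(Kd, 0.5, -8, prot)
    ho <- oracle_itc_heats(Kd, 0.5, -8, prot)
    expect_equal(h, ho, tolerance = 1e-8)
  }
  # total heat ~ enthalpy of everything ultimately bound
  h <- itc_injection_heats(0.01, 1, -8, prot)   # tight binding saturates cell
  conc <- dboxr:::itc_concentrations(prot)
  bound_total <- utils::tail(conc$Mt, 1)        # all sites filled
  displaced <- sum(h) / (200 * -8)              # complex formed per uL basis
  expect_gt(displaced, bound_total)             # includes displaced complex
  expect_lt(displaced, prot$cell_concentration)
})

test_that("fit_itc recovers noiseless truth essentially exactly", {
  ser <- gen_itc_series(Kd = 19, n = 0.5, dH = -8, noise_sd = 0, seed = 1)
  fit <- fit_itc(ser)
  expect_true(fit$converged)
  expect_equal(fit$parameters$Kd, 19, tolerance = 1e-3)
  expect_equal(fit$parameters$n, 0.5, tolerance = 1e-3)
  expect_equal(fit$parameters$dH, -8, tolerance = 1e-3)
})

test_that("fit_itc flags degenerate data instead of fitting it", {
  prot <- itc_protocol()
  ser <- titration_series("itc", heats = rep(0, 20), protocol = prot)
  fit <- fit_itc(ser)
  expect_false(fit$converged)
  expect_match(fit$diagnostics, "no binding signal")
  expect_length(fit$parameters, 0)
})

test_that("fit_anisotropy recovers noiseless truth and flags flat data", {
  ser <- gen_anisotropy_series(Kd = 45, A0 = 0.05, Amax = 0.2, noise_sd = 0,
                               seed = 1)
  fit <- fit_anisotropy(ser)
  expect_true(fit$converged)
  expect_equal(fit$parameters$Kd, 45, tolerance = 1e-4)
  expect_equal(fit$parameters$A0, 0.05, tolerance = 1e-6)
  expect_equal(fit$parameters$Amax, 0.2, tolerance = 1e-6)

  flat <- titration_series("anisotropy", Pt = sort(500 / 2^(0:10)), Lt = 0.1,
                           anisotropy = rep(0.08, 11))
  ffit <- fit_anisotropy(flat)
  expect_false(ffit$converged)
  expect_match(ffit$diagnostics, "unidentifiable")
})

test_that("bootstrap intervals are seeded, bracket the estimate, and guard n_boot", {
  ser <- gen_anisotropy_series(Kd = 45, seed = 2)
  fit <- fit_anisotropy(ser)
  ci1 <- bootstrap_ci(fit, ser, n_boot = 40, seed = 11)
  ci2 <- bootstrap_ci(fit, ser, n_boot = 40, seed = 11)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$estimate & ci1$estimate <= ci1$upper))
  expect_error(bootstrap_ci(fit, ser, n_boot = 10), "at least 20")
  bad <- fit_anisotropy(titration_series("anisotropy", Pt = sort(500 / 2^(0:10)),
                                         Lt = 0.1, anisotropy = rep(1, 11)))
  expect_error(bootstrap_ci(bad, ser), "non-converged")
})

test_that("bootstrap interval coverage is near nominal on synthetic truth", {
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    ser <- gen_anisotropy_series(Kd = 45, noise_sd = 0.002, seed = 1000 + r)
    fit <- fit_anisotropy(ser)
    ci <- bootstrap_ci(fit, ser, n_boot = 80, seed = r, level = 0.9)
    kd <- ci[ci$parameter == "Kd", ]
    if (kd$lower <= 45 && 45 <= kd$upper) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.80)   # nominal 0.90 within 10 points
})

test_that("titration CSV dialects round-trip including truth sidecars", {
  ser <- gen_itc_series(Kd = 19, n = 0.5, dH = -8, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_itc_csv(ser, p)
  back <- read_itc_csv(p)
  expect_equal(back$heats, ser$heats, tolerance = 1e-12)
  expect_true(file.exists(paste0(p, ".truth.json")))
  truth <- jsonlite::read_json(paste0(p, ".truth.json"))
  expect_equal(truth$Kd, 19)

  fa <- gen_anisotropy_series(Kd = 45, seed = 4)
  pa <- tempfile(fileext = ".csv")
  write_anisotropy_csv(fa, pa)
  backa <- read_anisotropy_csv(pa, Lt = 0.1)
  expect_equal(backa$anisotropy, fa$anisotropy, tolerance = 1e-12)
  # wrong dialect is reported with the offending columns
  expect_error(read_itc_csv(pa), "must have columns")
  expect_error(read_anisotropy_csv(p, Lt = 0.1), "must have columns")
})

test_that("fit_itc can hold the stoichiometry fixed", {
  ser <- gen_itc_series(Kd = 19, n = 0.5, dH = -8, noise_sd = 0, seed = 1)
  fit <- fit_itc(ser, init = list(n = 0.5), fix_n = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$parameters$n, 0.5)
  expect_true(is.na(fit$se$n))
  expect_equal(fit$parameters$Kd, 19, tolerance = 1e-3)
})
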