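test_that("closed-form and eigenvalue exchange broadening agree", {
  set.seed(42)
  for (k in 1:500) {
    m <- two_state(p_B = stats::runif(1, 1e-3, 0.45),
                   k_ex = 10^stats::runif(1, 1, 4.7))
    dw <- stats::runif(1, -2e4, 2e4)
    r1 <- rex_closed_form(dw, m)
    r2 <- rex_eigenvalue(dw, m)
    expect_lt(abs(r1 - r2) / max(r1, 1), 1e-8)
  }
})

test_that("exchange broadening limits and frozen values", {
  m <- two_state(0.1, 5000)
  expect_equal(rex_closed_form(0, m), 0, tolerance = 1e-12)
  expect_equal(rex_closed_form(1896, two_state(1e-12, 5000)), 0,
               tolerance = 1e-6)
  # frozen value recomputed from the complex arithmetic and eigenvalue routes
  expect_equal(rex_closed_form(1896, m), 59.72, tolerance = 1e-4 * 59.72)
  # fast limit: pA*pB*dw^2/kex within 1% at kex = 100*dw
  mf <- two_state(0.1, 189600)
  expect_equal(rex_closed_form(1896, mf), 0.9 * 0.1 * 1896^2 / 189600,
               tolerance = 0.01)
  expect_equal(0.9 * 0.1 * 1896^2 / 189600, 1.706, tolerance = 1e-3)
  # slow limit: lifetime broadening pB*kex within 5% at dw = 100*kex
  ms <- two_state(0.1, 5000)
  expect_equal(rex_closed_form(5e5, ms), 0.1 * 5000,
               tolerance = 0.05 * 500)
})

test_that("cpmg_experiment validates its pulse-count invariant", {
  f <- field_spec(800)
  expect_s3_class(cpmg_experiment("MQ", 0.04, c(25, 50, 2000), f),
                  "cpmg_experiment")
  expect_error(cpmg_experiment("MQ", 0.04, c(25, 33), f), "integer")
  expect_error(cpmg_experiment("MQ", -1, 25, f))
})

test_that("CPMG propagation reduces to the baseline without exchange", {
  f <- field_spec(800)
  for (kind in c("MQ", "SQ_H")) {
    ex <- cpmg_experiment(kind, 0.04, cpmg_frequencies(), f)
    m <- two_state(0, 872, 0.5, 0.2)
    expect_equal(cpmg_profile(m, ex, 12.3), rep(12.3, 28), tolerance = 1e-10)
  }
})

test_that("SQ propagation matches the exact closed-form dispersion", {
  f <- field_spec(800)
  ex <- cpmg_experiment("SQ_H", 0.04, cpmg_frequencies(), f)
  set.seed(11)
  for (k in 1:5) {
    m <- two_state(stats::runif(1, 0.01, 0.2), 10^stats::runif(1, 2, 3.7),
                   0, stats::runif(1, 0.05, 0.5))
    expect_lt(max(abs(cpmg_profile(m, ex, 10) -
                        sq_cpmg_closed_form(m, ex, 10))), 0.1)
  }
})

test_that("SQ propagation agrees with a Monte-Carlo jump simulation", {
  f <- field_spec(800)
  m <- two_state(0.029, 872, 0, 0.2)
  dw <- coherence_delta_omega("SQ_H", 0, 0.2, f)
  ex <- cpmg_experiment("SQ_H", 0.04, 250, f)
  set.seed(5)
  mc <- oracle_mc_sq_cpmg(250, 0.04, 872, 0.029, dw, 10, n = 30000)
  expect_equal(cpmg_profile(m, ex, 10), mc, tolerance = 0.6 / mc)
})

test_that("dispersion profiles are monotone and bracketed by the physical limits", {
  f <- field_spec(800)
  nu <- cpmg_frequencies()
  nu_hi <- round(50 * 872 / (2 * pi) * 0.04) / 0.04  # integer pulse count

  # SQ: single frequency difference, strictly non-increasing
  ms <- two_state(0.029, 872, 0, 0.2)
  ps <- cpmg_profile(ms, cpmg_experiment("SQ_H", 0.04, nu, f), 10)
  expect_true(all(diff(ps) <= 1e-6))
  # slow-pulsing end approaches the Hahn-echo rate from below
  dwH <- coherence_delta_omega("SQ_H", 0, 0.2, f)
  expect_lt(ps[1], 10 + rex_closed_form(dwH, ms) + 1e-9)
  # fast pulsing refocuses the SQ exchange contribution (within 2 % of the
  # dispersion amplitude)
  plat_s <- cpmg_profile(ms, cpmg_experiment("SQ_H", 0.04, nu_hi, f), 10)
  expect_lt(abs(plat_s - 10), 0.02 * (ps[1] - 10))

  # MQ: the train alternates ZQ/DQ coherences; the profile decreases apart
  # from genuine sub-0.1 s^-1 even/odd pulse-count staggering
  m <- two_state(0.029, 872, 0.5, -0.1)
  prof <- cpmg_profile(m, cpmg_experiment("MQ", 0.04, nu, f), 10)
  expect_true(all(diff(prof) <= 0.1))
  expect_gt(prof[1], prof[28])
  # slow-pulsing limit: Hahn echo spending T/2 on each of DQ+ and ZQ-
  dwZQ <- coherence_delta_omega("ZQ", 0.5, -0.1, f)
  dwDQ <- coherence_delta_omega("DQ", 0.5, -0.1, f)
  he_avg <- 10 + (rex_closed_form(dwZQ, m) + rex_closed_form(dwDQ, m)) / 2
  expect_lt(abs(prof[1] - he_avg), 0.5)
  # 13C pulses cannot refocus the 1H shift difference: the MQ plateau keeps
  # the lifetime-averaged 1H exchange contribution
  dwH2 <- coherence_delta_omega("SQ_H", 0, -0.1, f)
  plat_m <- cpmg_profile(m, cpmg_experiment("MQ", 0.04, nu_hi, f), 10)
  expect_lt(abs(plat_m - (10 + rex_closed_form(dwH2, m))),
            0.02 * (prof[1] - 10))
})

test_that("MQ dispersion with no 1H shift difference equals the 13C SQ-type dispersion", {
  f <- field_spec(950)
  nu <- cpmg_frequencies()
  m <- two_state(0.05, 1500, 0.8, 0)
  profMQ <- cpmg_profile(m, cpmg_experiment("MQ", 0.04, nu, f), 5)
  # same dispersion via the SQ engine at dw = dwC (scale dDelta_H so the 1H
  # frequency difference equals the 13C one)
  cst <- nmr_constants()
  m2 <- two_state(0.05, 1500, 0, 0.8 * cst$gamma_C / cst$gamma_H)
  profSQ <- cpmg_profile(m2, cpmg_experiment("SQ_H", 0.04, nu, f), 5)
  expect_equal(profMQ, profSQ, tolerance = 1e-10)
})

test_that("the effective rate is intensive in the relaxation period", {
  f <- field_spec(800)
  m <- two_state(0.05, 50000, 0.6, 0.1)  # deep fast exchange
  nu <- c(100, 500, 1000)
  r1 <- cpmg_profile(m, cpmg_experiment("MQ", 0.04, nu, f), 8)
  r2 <- cpmg_profile(m, cpmg_experiment("MQ", 0.08, nu, f), 8)
  expect_lt(max(abs(r1 - r2)), 1e-3)
})

test_that("MQ starting-coherence choices share the decay spectrum", {
  # the DQ-start and ZQ-start cycle propagators are XY vs YX products, so
  # they share eigenvalues; finite trains differ only through projection
  # factors that shrink with pulse count, and the signal-average option is
  # bracketed by the two pure starts
  f <- field_spec(800)
  nu <- c(50, 100, 500, 1000, 2000)
  m <- two_state(0.029, 872, 0.5, -0.1)
  ex <- cpmg_experiment("MQ", 0.04, nu, f)
  rd <- cpmg_profile(m, ex, 10, start = "DQ")
  rz <- cpmg_profile(m, ex, 10, start = "ZQ")
  ra <- cpmg_profile(m, ex, 10, start = "avg")
  expect_true(all(ra >= pmin(rd, rz) - 1e-9 & ra <= pmax(rd, rz) + 1e-9))
  expect_lt(max(abs(rd - rz)), 0.25)
  expect_lt(abs(rd[5] - rz[5]), 0.05)
})
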