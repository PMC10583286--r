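test_that("cross-correlated rates scale as expected", {
  f8 <- field_spec(800); f16 <- field_spec(1600)
  sys0 <- methyl_system(0, dsigma_C = 30, dsigma_H = 0.5)
  e0 <- eta_rates(sys0, f8)
  expect_true(all(unlist(e0) == 0))
  sys <- methyl_system(10e-9, dsigma_C = 30, dsigma_H = 0.5)
  e1 <- eta_rates(sys, f8); e2 <- eta_rates(sys, f16)
  # CSA-dipole rates are linear in B0, dipole-dipole rates field-independent
  expect_equal(e2$eta_CHC / e1$eta_CHC, 2, tolerance = 1e-12)
  expect_equal(e2$eta_C / e1$eta_C, 2, tolerance = 1e-12)
  expect_equal(e2$eta_H / e1$eta_H, 2, tolerance = 1e-12)
  expect_equal(e2$eta_HHHH, e1$eta_HHHH, tolerance = 1e-12)
  expect_equal(e2$eta_HHHC, e1$eta_HHHC, tolerance = 1e-12)
  expect_equal(e2$eta_CHCH, e1$eta_CHCH, tolerance = 1e-12)
  # eta_C / eta_H = (gC dsigma_C)/(gH dsigma_H), algebraic identity
  cst <- nmr_constants()
  expect_equal(e1$eta_C / e1$eta_H,
               (cst$gamma_C * 30) / (cst$gamma_H * 0.5), tolerance = 1e-12)
  # linearity in s2tau
  e3 <- eta_rates(methyl_system(20e-9, dsigma_C = 30, dsigma_H = 0.5), f8)
  expect_equal(unlist(e3), 2 * unlist(e1), tolerance = 1e-12)
  # the CSA-derived rate equals the quartet-decay cross rate (same formula)
  expect_identical(e1$eta_C, e1$eta_CHC)
})

test_that("quartet multiplet pattern and decays follow the lineshape algebra", {
  f <- field_spec(800)
  # s2tau -> 0: Delta -> 1, pattern (3+3):(3-1) = 6:2:2:6 = 3:1:1:3
  qm0 <- quartet_model(1, 0.5, 15, 25, 12, 125, 0, 0, f)
  qc0 <- mqrelax:::quartet_components(qm0)
  expect_equal(qc0$Delta, 1, tolerance = 1e-12)
  expect_equal(qc0$I, c(6, 2, 2, 6), tolerance = 1e-12)
  # degenerate limit: all four lines share the single decay R2_C
  expect_equal(qc0$R, rep(12, 4), tolerance = 1e-12)

  # zero 13C CSA: reflection symmetry of the spectrum about omega0_C
  qs <- quartet_model(1, 0.5, 15, 25, 12, 125, 10e-9, 0, f)
  wH <- seq(0.4, 0.6, by = 0.005)
  wC <- seq(13, 17, by = 0.01)  # symmetric about 15
  y <- quartet_lineshape(qs, 0.08, wH, wC)
  expect_equal(y, y[, ncol(y):1], tolerance = 1e-10)

  # outer-line decay asymmetry exp(-6 eta_CHC T); construct eta_CHC = 2 s^-1
  sys1 <- methyl_system(10e-9, dsigma_C = 1)
  per_ppm <- eta_rates(sys1, f)$eta_CHC
  ds <- 2 / per_ppm
  qa <- quartet_model(1, 0.5, 15, 25, 12, 125, 10e-9, ds, f)
  qca <- mqrelax:::quartet_components(qa)
  expect_equal(qca$R[1] - qca$R[4], 6 * 2, tolerance = 1e-10)
  Tdel <- 0.1
  ratio <- exp(-qca$R[1] * Tdel) / exp(-qca$R[4] * Tdel)
  expect_equal(ratio, exp(-6 * 2 * Tdel), tolerance = 1e-12)
  expect_equal(ratio, 0.3012, tolerance = 1e-4)

  # integrated intensity at T = 0 is proportional to 12 + 4*Delta
  # (broad lines so the Riemann sum resolves each Lorentzian)
  qm <- quartet_model(1, 0.5, 15, 150, 100, 125, 10e-9, 20, f)
  qc <- mqrelax:::quartet_components(qm)
  wHw <- seq(-4, 5, by = 0.005)
  wCw <- seq(-20, 50, by = 0.05)
  y0 <- quartet_lineshape(qm, 0, wHw, wCw, warn = FALSE)
  cst <- nmr_constants()
  dwH <- 2 * pi * diff(wHw[1:2]) * 800
  dwC <- 2 * pi * diff(wCw[1:2]) * 800 * cst$gamma_C / cst$gamma_H
  integral <- sum(y0) * dwH * dwC
  expect_equal(integral, pi^2 * (12 + 4 * qc$Delta), tolerance = 0.02)
})

test_that("peak clustering uses the strip windows on both sides of the threshold", {
  peaks <- data.frame(methyl_id = c("a", "b", "c"),
                      wH_ppm = c(0.50, 0.54, 0.56),
                      wC_ppm = c(15, 15.3, 15.3))
  cl <- cluster_peaks(peaks)
  expect_equal(cl[1], cl[2])       # 0.04 ppm apart: same cluster
  expect_equal(cl[2], cl[3])       # 0.02 ppm: linked
  peaks2 <- data.frame(methyl_id = c("a", "b"),
                       wH_ppm = c(0.50, 0.56), wC_ppm = c(15, 15))
  expect_false(cluster_peaks(peaks2)[1] == cluster_peaks(peaks2)[2])
  # 13C window
  peaks3 <- data.frame(methyl_id = c("a", "b"),
                       wH_ppm = c(0.50, 0.50), wC_ppm = c(15, 18))
  expect_false(cluster_peaks(peaks3)[1] == cluster_peaks(peaks3)[2])
})

test_that("quartet cluster fitting recovers the generating parameters", {
  truth <- truth_preset("slow-cluster")
  tm <- truth; tm$methyls <- tm$methyls[1, ]
  g <- gen_pseudo3d(tm, sigma = 0, wH_ppm = seq(0.3, 0.6, by = 0.004),
                    wC_ppm = seq(10, 16, by = 0.02))
  res <- fit_quartet_cluster(g$spectra, g$delays, g$wH_ppm, g$wC_ppm,
                             g$peaks, g$field)
  expect_equal(res$s2tau, 8e-9, tolerance = 1e-3)
  expect_equal(res$dsigma_C, 25, tolerance = 1e-3)
  expect_equal(res$J_CH, 125, tolerance = 1e-3)
  expect_true(res$converged)

  # sign flip of the CSA mirrors the asymmetry and is recovered with sign
  tneg <- tm; tneg$methyls$dSigmaC_ppm <- -25
  gneg <- gen_pseudo3d(tneg, sigma = 0, wH_ppm = seq(0.3, 0.6, by = 0.004),
                       wC_ppm = seq(10, 16, by = 0.02))
  resn <- fit_quartet_cluster(gneg$spectra, gneg$delays, gneg$wH_ppm,
                              gneg$wC_ppm, gneg$peaks, gneg$field)
  expect_equal(resn$dsigma_C, -25, tolerance = 1e-3)
})

test_that("overlapping multiplets are resolved by the joint cluster fit", {
  truth <- truth_preset("slow-cluster")
  to <- truth
  to$methyls$wH_ppm <- c(0.45, 0.48)
  to$methyls$wC_ppm <- c(13.0, 13.3)
  for (seed in c(7, 8)) {
    g <- gen_pseudo3d(to, sigma = 0.01, wH_ppm = seq(0.3, 0.65, by = 0.004),
                      wC_ppm = seq(10, 16.5, by = 0.02), seed = seed)
    expect_equal(cluster_peaks(g$peaks), c(1L, 1L))
    res <- fit_quartet_cluster(g$spectra, g$delays, g$wH_ppm, g$wC_ppm,
                               g$peaks, g$field, sigma = 0.01)
    expect_lt(max(abs(res$s2tau - c(8e-9, 10e-9)) / res$s2tau_err), 3.5)
    expect_lt(max(abs(res$dsigma_C - c(25, 35)) / res$dsigma_C_err), 3.5)
  }
})

test_that("IPAP spin-state relaxation yields the 1H CSA", {
  f <- field_spec(950)
  tt <- c(2, 5, 10, 15, 20, 30, 50, 75, 100, 150) * 1e-3
  # equal rates: zero CSA
  a <- 100 * exp(-30 * tt)
  r0 <- ipap_h_csa(tt, a, a, 0.01, 8e-9, f)
  expect_equal(r0$dsigma_H, 0, tolerance = 1e-6)
  # forward-generate from eta_rates and invert
  eta <- eta_rates(methyl_system(8e-9, dsigma_H = 0.8), f)
  Ra <- 30 + eta$eta_H; Rb <- 30 - eta$eta_H
  set.seed(3)
  aa <- 100 * exp(-Ra * tt) + rnorm(length(tt), 0, 0.3)
  ab <- 100 * exp(-Rb * tt) + rnorm(length(tt), 0, 0.3)
  r <- ipap_h_csa(tt, aa, ab, 0.3, 8e-9, f)
  expect_lt(abs(r$dsigma_H - 0.8), 3 * r$dsigma_H_err)
  # swapping the alpha/beta assignment flips the sign
  rsw <- ipap_h_csa(tt, ab, aa, 0.3, 8e-9, f)
  expect_equal(rsw$dsigma_H, -r$dsigma_H, tolerance = 1e-10)
  # s2tau = 0 cannot be inverted
  expect_error(ipap_h_csa(tt, aa, ab, 0.3, 0, f), "indeterminate")
})
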