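test_that("exponential decay fitting recovers exact and flat curves", {
  tt <- he_delays(950)
  a <- 100 * exp(-50 * tt)
  fit <- fit_decay(tt, a, sigma = 1e-6)
  expect_equal(fit$rate, 50, tolerance = 1e-7)
  expect_equal(fit$amp, 100, tolerance = 1e-6)
  # flat curve: rate 0 within error
  set.seed(1)
  flat <- 100 + rnorm(length(tt), 0, 0.5)
  f0 <- fit_decay(tt, flat, sigma = 0.5)
  expect_lt(abs(f0$rate), 3 * f0$rate_err + 1e-9)
  expect_error(fit_decay(tt[1:3], a[1:3]), "length")
})

test_that("decay-fit errors are calibrated (Monte-Carlo)", {
  tt <- he_delays(950)
  R <- 150; A <- 100; sig <- 1  # 1 % noise
  set.seed(99)
  hits <- vapply(1:1000, function(i) {
    a <- A * exp(-R * tt) + rnorm(length(tt), 0, sig)
    f <- fit_decay(tt, a, sigma = sig)
    abs(f$rate - R) <= 3 * f$rate_err
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("field regression matches the closed-form weighted LS oracle", {
  fields <- c(600, 700, 800, 950)
  B2 <- sapply(fields, function(f) field_spec(f)$B0^2)
  # noiseless linear model recovered to machine precision
  rates <- 20 + 0.05 * B2
  reg <- regress_field(rates, rep(0.1, 4), fields)
  expect_equal(reg$intercept, 20, tolerance = 1e-9)
  expect_equal(reg$slope, 0.05, tolerance = 1e-12)
  # equal rates at all fields: zero slope
  reg0 <- regress_field(rep(33, 4), rep(0.1, 4), fields)
  expect_equal(reg0$slope, 0, tolerance = 1e-12)
  # heteroscedastic data vs explicit normal equations
  set.seed(3)
  errs <- c(0.1, 0.5, 0.2, 1.0)
  y <- 20 + 0.05 * B2 + rnorm(4, 0, errs)
  reg2 <- regress_field(y, errs, fields)
  oc <- oracle_wls(y, B2, 1 / errs^2)
  expect_equal(reg2$intercept, oc[["intercept"]], tolerance = 1e-10)
  expect_equal(reg2$slope, oc[["slope"]], tolerance = 1e-10)
  expect_error(regress_field(y[1:2], errs[1:2], fields[1:2]), "3 distinct")
})

test_that("CSA subtraction isolates the exchange coefficient", {
  fields <- c(600, 700, 800, 950)
  B2 <- sapply(fields, function(f) field_spec(f)$B0^2)
  sys0 <- methyl_system(0)  # zero CSA
  reg <- regress_field(20 + 0.04 * B2, rep(0.1, 4), fields)
  con <- subtract_csa(reg, sys0, "DQ")
  expect_equal(con$beta_ex, reg$slope, tolerance = 1e-12)
  # slope exactly equal to the CSA term gives beta_ex = 0
  sys <- methyl_system(20e-9, dsigma_C = 30, dsigma_H = 0.4)
  bc <- csa_beta("QQ", sys)
  regc <- regress_field(15 + bc * B2, rep(0.1, 4), fields)
  expect_equal(subtract_csa(regc, sys, "QQ")$beta_ex, 0, tolerance = 1e-12)
  # forward-generated fast-exchange data invert to (xi_C + n xi_H)^2 exactly
  truth <- truth_preset("slow-cluster")
  tab <- fast_rate_table(truth, err = 0.1)
  xt <- truth_xi(truth)
  for (i in 1:2) {
    m <- truth$methyls[i, ]
    sysm <- methyl_system(m$s2tau_ns * 1e-9, dsigma_C = m$dSigmaC_ppm,
                          dsigma_H = m$dSigmaH_ppm)
    d <- tab[tab$methyl_id == m$methyl_id, ]
    for (co in c("ZQ", "DQ", "DQp", "QQ")) {
      dd <- d[d$coherence == co, ]
      con <- subtract_csa(regress_field(dd$rate, dd$err, dd$field_MHz),
                          sysm, co)
      expect_equal(con$beta_ex,
                   (xt$xi_C[i] + coherence_nH(co) * xt$xi_H[i])^2,
                   tolerance = 1e-10)
    }
  }
  # significantly negative beta_ex flags a CSA overestimate
  sys_big <- methyl_system(50e-9, dsigma_C = 60)
  reg_small <- regress_field(15 + 0.001 * B2, rep(0.01, 4), fields)
  expect_warning(conw <- subtract_csa(reg_small, sys_big, "DQ"),
                 "no detectable exchange")
  expect_false(conw$exchange_flag)
})

test_that("constraint lines are concurrent for consistent data and not otherwise", {
  truth <- truth_preset("slow-cluster")
  tab <- fast_rate_table(truth, err = 1)
  xt <- truth_xi(truth)
  m1 <- truth$methyls[1, ]
  sys1 <- methyl_system(m1$s2tau_ns * 1e-9, dsigma_C = m1$dSigmaC_ppm,
                        dsigma_H = m1$dSigmaH_ppm)
  d <- tab[tab$methyl_id == "M1", ]
  cons <- lapply(c("ZQ", "DQ", "DQp", "QQ"), function(co) {
    dd <- d[d$coherence == co, ]
    subtract_csa(regress_field(dd$rate, dd$err, dd$field_MHz), sys1, co)
  })
  ints <- xi_line_intersections(cons)
  d2 <- sqrt((ints$xi_H - xt$xi_H[1])^2 + (ints$xi_C - xt$xi_C[1])^2)
  nearest <- vapply(split(d2, paste(ints$i, ints$j)), min, numeric(1))
  expect_lt(max(nearest), 1e-9)

  # inconsistent (three-state-like) input: uncorrelated 1H/13C fluctuations
  # break the common intersection and lift the chi-square floor
  cons_bad <- cons
  cons_bad[[4]]$beta_ex <- cons_bad[[4]]$beta_ex * 2
  ints_b <- xi_line_intersections(cons_bad)
  d2b <- sqrt((ints_b$xi_H - xt$xi_H[1])^2 + (ints_b$xi_C - xt$xi_C[1])^2)
  nearest_b <- vapply(split(d2b, paste(ints_b$i, ints_b$j)), min, numeric(1))
  expect_gt(max(nearest_b), 1e-3)
  d_bad <- d
  qq <- d_bad$coherence == "QQ"
  d_bad$rate[qq] <- d_bad$rate[qq] +
    0.5 * (d_bad$rate[qq] - min(d_bad$rate[qq]))
  s_bad <- xi_surface(d_bad, sys1, n_grid = 101L)
  expect_gt(s_bad$min_chi2, 1e-4)
})

test_that("chi-square surface has its minima at the +/- truth pair", {
  truth <- truth_preset("slow-cluster")
  tab <- fast_rate_table(truth, err = 1)
  xt <- truth_xi(truth)
  m1 <- truth$methyls[1, ]
  sys1 <- methyl_system(m1$s2tau_ns * 1e-9, dsigma_C = m1$dSigmaC_ppm,
                        dsigma_H = m1$dSigmaH_ppm)
  d <- tab[tab$methyl_id == "M1", ]
  s <- xi_surface(d, sys1, n_grid = 151L)
  # perfect model: chi2 at the true point is numerically zero
  expect_lt(xi_chi2_at(d, sys1, xt$xi_H[1], xt$xi_C[1]), 1e-18)
  expect_lt(xi_chi2_at(d, sys1, -xt$xi_H[1], -xt$xi_C[1]), 1e-18)
  # grid minimum sits within two grid steps of the truth
  step <- diff(s$xi_H[1:2])
  dmin <- min(sqrt((s$minima$xi_H - xt$xi_H[1])^2 +
                     (s$minima$xi_C - xt$xi_C[1])^2))
  expect_lt(dmin, 2.5 * step)
  # global sign symmetry of the whole surface
  expect_equal(s$chi2, s$chi2[length(s$xi_H):1, length(s$xi_C):1],
               tolerance = 1e-9)
})

test_that("two-spin surfaces are xi-swap symmetric; four-spin data break the symmetry", {
  truth <- truth_preset("slow-cluster")
  tab <- fast_rate_table(truth, err = 1)
  m1 <- truth$methyls[1, ]
  sys1 <- methyl_system(m1$s2tau_ns * 1e-9, dsigma_C = m1$dSigmaC_ppm,
                        dsigma_H = m1$dSigmaH_ppm)
  d <- tab[tab$methyl_id == "M1", ]
  ax <- seq(-0.5, 0.5, length.out = 81)
  s2 <- xi_surface(d, sys1, xi_H = ax, xi_C = ax,
                   use_coherences = c("ZQ", "DQ"))
  expect_equal(s2$chi2, t(s2$chi2), tolerance = 1e-8)
  s4 <- xi_surface(d, sys1, xi_H = ax, xi_C = ax)
  expect_gt(max(abs(s4$chi2 - t(s4$chi2))), 1)
})

test_that("the 95% confidence region contains the truth at the nominal rate", {
  truth <- truth_preset("slow-cluster")
  clean <- fast_rate_table(truth, err = 1)
  xt <- truth_xi(truth)
  m1 <- truth$methyls[1, ]
  sys1 <- methyl_system(m1$s2tau_ns * 1e-9, dsigma_C = m1$dSigmaC_ppm,
                        dsigma_H = m1$dSigmaH_ppm)
  d0 <- clean[clean$methyl_id == "M1", ]
  d0$err <- 0.02 * d0$rate
  set.seed(17)
  contained <- vapply(1:200, function(i) {
    d <- d0
    d$rate <- d0$rate + rnorm(nrow(d0), 0, d0$err)
    s <- xi_surface(d, sys1, n_grid = 61L)
    xi_chi2_at(d, sys1, xt$xi_H[1], xt$xi_C[1]) - s$min_chi2 <= 6.18
  }, logical(1))
  expect_gte(mean(contained), 0.9)
})
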