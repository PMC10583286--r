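#' Cross-correlated relaxation rates of a methyl group
#'
#' Evaluates the dipole-dipole and CSA-dipole cross-correlated relaxation
#' rates that govern the intensities and decays of the 1H-coupled 13C quartet,
#' plus the CSA-derived rates used to extract the 13C and 1H CSAs:
#' \itemize{
#'   \item `eta_HHHH = (9/40) (mu0/4pi)^2 hbar^2 gH^4 / rHH^6 * s2tau`
#'   \item `eta_HHHC = (1/5)  (mu0/4pi)^2 hbar^2 gC gH^3 / (rCH^3 rHH^3) * s2tau`
#'   \item `eta_CHCH = (2/45) (mu0/4pi)^2 hbar^2 gC^2 gH^2 / rCH^6 * s2tau`
#'   \item `eta_CHC  = (4/45) (mu0/4pi) hbar gC gH / rCH^3 * gC B0 dsigma_C * s2tau`
#'   \item `eta_C` identical in form to `eta_CHC`; `eta_H` replaces
#'     `gC B0 dsigma_C` by `gH B0 dsigma_H`.
#' }
#' All rates are linear in `s2tau`; the CSA-dipole rates are additionally
#' linear in B0.
#'
#' @param system a [methyl_system()].
#' @param field a [field_spec()].
#' @param constants an [nmr_constants()] object.
#' @return named list of the six rates (s^-1), class `eta_rates`.
#' @export
eta_rates <- function(system, field, constants = nmr_constants()) {
  stopifnot(inherits(system, "methyl_system"), inherits(field, "field_spec"))
  k <- constants$mu0 / (4 * pi) * constants$hbar
  gH <- constants$gamma_H; gC <- constants$gamma_C
  rCH <- constants$r_CH; rHH <- constants$r_HH
  s2t <- system$s2tau
  csa_dip <- (4 / 45) * k * gC * gH / rCH^3 * field$B0 * s2t
  structure(list(
    eta_HHHH = (9 / 40) * k^2 * gH^4 / rHH^6 * s2t,
    eta_HHHC = (1 / 5) * k^2 * gC * gH^3 / (rCH^3 * rHH^3) * s2t,
    eta_CHCH = (2 / 45) * k^2 * gC^2 * gH^2 / rCH^6 * s2t,
    eta_CHC  = csa_dip * gC * system$dsigma_C * 1e-6,
    eta_C    = csa_dip * gC * system$dsigma_C * 1e-6,
    eta_H    = csa_dip * gH * system$dsigma_H * 1e-6
  ), class = "eta_rates")
}

#' Quartet lineshape model parameters
#'
#' Parameter set for the relaxation-weighted 1H-coupled HSQC multiplet of one
#' methyl group: amplitude, peak positions (ppm), 1H and 13C line relaxation
#' rates, the one-bond scalar coupling (~125 Hz), the order-parameter product
#' `s2tau` and the 13C CSA.
#'
#' @param amp overall amplitude.
#' @param omega0_H,omega0_C peak positions in ppm.
#' @param R2_H,R2_C line relaxation rates in s^-1 (> 0).
#' @param J_CH scalar coupling in Hz (around 125).
#' @param s2tau S2axis*tau_c in seconds.
#' @param dsigma_C 13C CSA in ppm.
#' @param field a [field_spec()].
#' @return An object of class `quartet_model`.
#' @export
quartet_model <- function(amp, omega0_H, omega0_C, R2_H, R2_C,
                          J_CH = 125, s2tau, dsigma_C, field) {
  stopifnot(R2_H > 0, R2_C > 0, s2tau >= 0, inherits(field, "field_spec"))
  if (J_CH < 100 || J_CH > 150)
    warning("J_CH = ", J_CH, " Hz is outside the typical methyl range")
  structure(list(amp = amp, omega0_H = omega0_H, omega0_C = omega0_C,
                 R2_H = R2_H, R2_C = R2_C, J_CH = J_CH,
                 s2tau = s2tau, dsigma_C = dsigma_C, field = field),
            class = "quartet_model")
}

# Lorentzian L(w; w0, R) = R / (R^2 + (w - w0)^2), angular-frequency units
lorentz <- function(w, w0, R) R / (R^2 + (w - w0)^2)

# quartet line decays and intensities for a model at mixing delay tau = 1/(2J)
quartet_components <- function(model, constants = nmr_constants()) {
  eta <- eta_rates(
    methyl_system(s2tau = model$s2tau, dsigma_C = model$dsigma_C),
    model$field, constants)
  tau <- 1 / (2 * model$J_CH)
  Delta <- exp(-4 * eta$eta_HHHH * tau) * cosh(2 * eta$eta_HHHC * tau)
  list(
    Delta = Delta,
    I = c(3 + 3 * Delta, 3 - Delta, 3 - Delta, 3 + 3 * Delta),
    R = c(model$R2_C + 3 * eta$eta_CHCH + 3 * eta$eta_CHC,
          model$R2_C - eta$eta_CHCH + eta$eta_CHC,
          model$R2_C - eta$eta_CHCH - eta$eta_CHC,
          model$R2_C + 3 * eta$eta_CHCH - 3 * eta$eta_CHC),
    # positions relative to the 13C centre, rad/s: +3piJ, +piJ, -piJ, -3piJ
    off = pi * model$J_CH * c(3, 1, -1, -3)
  )
}

#' Simulate a relaxation-weighted 13C quartet lineshape
#'
#' 2D intensity of the 1H-coupled HSQC multiplet after a 13C relaxation delay
#' `T`: four 13C Lorentzians at `omega0_C +/- pi*J, +/- 3*pi*J` (angular
#' units) with intensities `I_outer = 3 + 3*Delta`, `I_inner = 3 - Delta`,
#' `Delta = exp(-4*eta_HHHH*tau) * cosh(2*eta_HHHC*tau)`, `tau = 1/(2*J_CH)`,
#' and line-specific decays `exp(-R_line * T)` with
#' `R_aaa = R2C + 3*eta_CHCH + 3*eta_CHC`, `R_aab = R2C - eta_CHCH + eta_CHC`,
#' `R_abb = R2C - eta_CHCH - eta_CHC`, `R_bbb = R2C + 3*eta_CHCH - 3*eta_CHC`,
#' multiplied by a single 1H-dimension Lorentzian. The Lorentzian convention
#' is `L(w; w0, R) = R / (R^2 + (w - w0)^2)`.
#'
#' @param model a [quartet_model()].
#' @param T relaxation delay in seconds (>= 0).
#' @param wH_ppm,wC_ppm grid axes in ppm (1H and 13C dimensions).
#' @param constants an [nmr_constants()] object.
#' @param warn warn when the 13C axis does not cover the outer lines.
#' @return intensity matrix, rows = `wH_ppm`, columns = `wC_ppm`.
#' @export
quartet_lineshape <- function(model, T, wH_ppm, wC_ppm,
                              constants = nmr_constants(), warn = TRUE) {
  stopifnot(inherits(model, "quartet_model"), T >= 0)
  fld <- model$field
  larmor_C <- fld$larmor_MHz * constants$gamma_C / constants$gamma_H
  # ppm -> rad/s (absolute offsets; only differences matter)
  wH <- 2 * pi * wH_ppm * fld$larmor_MHz
  wC <- 2 * pi * wC_ppm * larmor_C
  w0H <- 2 * pi * model$omega0_H * fld$larmor_MHz
  w0C <- 2 * pi * model$omega0_C * larmor_C
  qc <- quartet_components(model, constants)
  if (warn && (min(wC) > w0C - 3 * pi * model$J_CH ||
               max(wC) < w0C + 3 * pi * model$J_CH))
    warning("13C axis does not cover the outer quartet lines (+/- 3*pi*J)")
  cdim <- numeric(length(wC))
  for (k in 1:4)
    cdim <- cdim + qc$I[k] * exp(-qc$R[k] * T) *
      lorentz(wC, w0C + qc$off[k], qc$R[k])
  model$amp * outer(lorentz(wH, w0H, model$R2_H), cdim)
}

#' Group peaks into clusters of potentially overlapping multiplets
#'
#' Single-linkage clustering: two peaks are linked when they fall within a
#' 0.05 ppm strip in 1H and a 2.4 ppm strip in 13C (the quartet footprint).
#'
#' @param peaks data.frame with columns `wH_ppm`, `wC_ppm`.
#' @param dH_ppm,dC_ppm strip half-windows (defaults 0.05 and 2.4 ppm).
#' @return integer vector of cluster ids, one per peak.
#' @export
cluster_peaks <- function(peaks, dH_ppm = 0.05, dC_ppm = 2.4) {
  stopifnot(is.data.frame(peaks), all(c("wH_ppm", "wC_ppm") %in% names(peaks)))
  n <- nrow(peaks)
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) i <- id[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(peaks$wH_ppm[i] - peaks$wH_ppm[j]) <= dH_ppm &&
        abs(peaks$wC_ppm[i] - peaks$wC_ppm[j]) <= dC_ppm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) id[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Fit quartet lineshapes to a pseudo-3D cluster
#'
#' Joint nonlinear least-squares fit of the [quartet_lineshape()] model to a
#' stack of 2D spectra acquired at several 13C relaxation delays, for all
#' peaks of one cluster simultaneously on a shared grid. Peak positions are
#' fixed at the supplied values (from a decoupled reference spectrum); per
#' peak, the amplitude, 1H and 13C line rates, the scalar coupling (bounded to
#' 100-150 Hz), `s2tau` and the 13C CSA are free. Standard errors come from
#' the Gauss-Newton covariance at the optimum (scaled by the residual
#' variance when `sigma` is not given).
#'
#' @param spectra list of intensity matrices, one per delay (rows = wH).
#' @param delays relaxation delays in seconds (>= 3).
#' @param wH_ppm,wC_ppm grid axes shared by all spectra.
#' @param peaks data.frame with columns `methyl_id`, `wH_ppm`, `wC_ppm`.
#' @param field a [field_spec()].
#' @param sigma known intensity noise (scalar); `NULL` to estimate from
#'   residuals.
#' @param start optional named list overriding starting values
#'   (`R2_H`, `R2_C`, `J_CH`, `s2tau`, `dsigma_C`).
#' @param constants an [nmr_constants()] object.
#' @return data.frame with one row per peak: estimates and standard errors of
#'   `s2tau`, `dsigma_C`, `J_CH`, `R2_H`, `R2_C`, `amp`, plus `converged` and
#'   `at_bound` flags.
#' @export
fit_quartet_cluster <- function(spectra, delays, wH_ppm, wC_ppm, peaks, field,
                                sigma = NULL, start = list(),
                                constants = nmr_constants()) {
  stopifnot(is.list(spectra), length(spectra) == length(delays),
            length(delays) >= 3L,
            is.data.frame(peaks), nrow(peaks) >= 1L,
            all(c("methyl_id", "wH_ppm", "wC_ppm") %in% names(peaks)),
            inherits(field, "field_spec"))
  np <- nrow(peaks)
  user_start <- length(start) > 0L
  s0 <- utils::modifyList(
    list(R2_H = 25, R2_C = 15, J_CH = 125, s2tau = 20e-9, dsigma_C = 25),
    start)
  # starting amplitude: match the tallest observed point in a window around
  # each peak against the same point of a unit-amplitude reference multiplet
  amp_start <- function(s2tau, dsigma_C) vapply(seq_len(np), function(i) {
    ih <- which(abs(wH_ppm - peaks$wH_ppm[i]) <= 0.05)
    ic <- which(abs(wC_ppm - peaks$wC_ppm[i]) <= 2.0)
    if (!length(ih) || !length(ic)) { ih <- seq_along(wH_ppm); ic <- seq_along(wC_ppm) }
    m0 <- quartet_model(1, peaks$wH_ppm[i], peaks$wC_ppm[i], s0$R2_H, s0$R2_C,
                        s0$J_CH, s2tau, dsigma_C, field)
    ref <- quartet_lineshape(m0, delays[1], wH_ppm[ih], wC_ppm[ic], constants,
                             warn = FALSE)
    max(max(spectra[[1]][ih, ic]) / max(ref, 1e-12), 1e-6)
  }, numeric(1))

  # parameter vector: per peak (amp, R2_H, R2_C, J_CH, s2tau_ns, dsigma_C)
  lower <- rep(c(1e-9, 0.1, 0.1, 100, 0, -150), np)
  upper <- rep(c(Inf, 1e3, 1e3, 150, 1e3, 150), np)

  model_stack <- function(p) {
    out <- lapply(delays, function(d) 0 * spectra[[1]])
    for (i in seq_len(np)) {
      q <- p[(i - 1) * 6 + 1:6]
      m <- quartet_model(q[1], peaks$wH_ppm[i], peaks$wC_ppm[i],
                         q[2], q[3], q[4], q[5] * 1e-9, q[6], field)
      for (k in seq_along(delays))
        out[[k]] <- out[[k]] + quartet_lineshape(m, delays[k], wH_ppm, wC_ppm,
                                                 constants, warn = FALSE)
    }
    out
  }
  resid_fn <- function(p) {
    mod <- model_stack(p)
    r <- unlist(lapply(seq_along(delays), function(k) mod[[k]] - spectra[[k]]))
    if (!is.null(sigma)) r <- r / sigma
    r
  }
  # the (s2tau, dsigma_C) pair has a secondary optimum of opposite asymmetry;
  # restart from a small grid unless the caller supplied starting values
  start_grid <- if (user_start)
    data.frame(s2tau = s0$s2tau, dsigma_C = s0$dsigma_C)
  else
    expand.grid(s2tau = c(5e-9, 25e-9), dsigma_C = c(25, -25))
  fit <- NULL
  for (s in seq_len(nrow(start_grid))) {
    st <- start_grid$s2tau[s]; sd <- start_grid$dsigma_C[s]
    a0 <- amp_start(st, sd)
    p0 <- unlist(lapply(seq_len(np), function(i)
      c(a0[i], s0$R2_H, s0$R2_C, s0$J_CH, st * 1e9, sd)))
    cand <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  if (is.null(fit)) stop("quartet fit failed from every start")
  p0 <- fit$par  # for length bookkeeping below
  dof <- length(fit$fvec) - length(p0)
  covm <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  scale2 <- if (is.null(sigma)) fit$deviance / max(dof, 1) else 1
  se <- if (is.null(covm)) rep(NA_real_, length(p0)) else {
    dg <- diag(covm) * scale2
    ifelse(dg >= 0, sqrt(dg), NA_real_)
  }
  p <- fit$par
  res <- do.call(rbind, lapply(seq_len(np), function(i) {
    q <- p[(i - 1) * 6 + 1:6]
    qe <- se[(i - 1) * 6 + 1:6]
    at_bound <- any(abs(q - lower[(i - 1) * 6 + 1:6]) < 1e-10) ||
      q[4] >= 150 - 1e-8 || q[4] <= 100 + 1e-8
    data.frame(methyl_id = peaks$methyl_id[i],
               amp = q[1], amp_err = qe[1],
               R2_H = q[2], R2_H_err = qe[2],
               R2_C = q[3], R2_C_err = qe[3],
               J_CH = q[4], J_CH_err = qe[4],
               s2tau = q[5] * 1e-9, s2tau_err = qe[5] * 1e-9,
               dsigma_C = q[6], dsigma_C_err = qe[6],
               converged = fit$info %in% 1:4, at_bound = at_bound)
  }))
  attr(res, "deviance") <- fit$deviance
  res
}

#' 1H CSA from IPAP spin-state-selective relaxation
#'
#' Fits single-exponential decays to the 13C |alpha> and |beta> sub-spectra
#' amplitudes, forms the CSA-dipolar cross-correlated rate
#' `eta_H = (R_alpha - R_beta)/2` and inverts
#' `eta_H = (4/45) (mu0 hbar gC gH / (4 pi rCH^3)) gH B0 dsigma_H s2tau`
#' for the 1H CSA. Errors are propagated to first order from both rate errors
#' and the `s2tau` uncertainty.
#'
#' @param times shared relaxation delays (s).
#' @param amp_alpha,amp_beta peak amplitudes of the two sub-spectra.
#' @param sigma amplitude noise (scalar or vector).
#' @param s2tau S2axis*tau_c in seconds (> 0); `s2tau_err` its 1-sigma error.
#' @param field a [field_spec()].
#' @param s2tau_err uncertainty on s2tau (s).
#' @param constants an [nmr_constants()] object.
#' @return list with `dsigma_H` (ppm), `dsigma_H_err`, `eta_H`, `eta_H_err`,
#'   `R_alpha`, `R_beta` (each a [fit_decay()] result).
#' @export
ipap_h_csa <- function(times, amp_alpha, amp_beta, sigma = 1, s2tau, field,
                       s2tau_err = 0, constants = nmr_constants()) {
  if (s2tau <= 0)
    stop("CSA indeterminate: s2tau must be positive")
  fa <- fit_decay(times, amp_alpha, sigma)
  fb <- fit_decay(times, amp_beta, sigma)
  if (!fa$converged || !fb$converged)
    stop("spin-state decay fit did not converge")
  eta_H <- (fa$rate - fb$rate) / 2
  eta_H_err <- sqrt(fa$rate_err^2 + fb$rate_err^2) / 2
  per_ppm <- (4 / 45) * constants$mu0 / (4 * pi) * constants$hbar *
    constants$gamma_C * constants$gamma_H / constants$r_CH^3 *
    constants$gamma_H * field$B0 * s2tau * 1e-6
  ds <- eta_H / per_ppm
  ds_err <- sqrt((eta_H_err / per_ppm)^2 + (ds * s2tau_err / s2tau)^2)
  list(dsigma_H = ds, dsigma_H_err = ds_err,
       eta_H = eta_H, eta_H_err = eta_H_err,
       R_alpha = fa, R_beta = fb)
}
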