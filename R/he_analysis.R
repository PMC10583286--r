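#' Fit a single-exponential decay to peak amplitudes
#'
#' Weighted least-squares fit of `A * exp(-R * t)` to peak amplitudes from a
#' Hahn-echo (or other relaxation) series. The fit is linear in `A` given `R`,
#' so the profile over `A` is solved in closed form and `R` is found by
#' one-dimensional minimisation of the profiled weighted residual sum of
#' squares; standard errors come from the local curvature (Gauss-Newton
#' covariance) at the optimum.
#'
#' @param times relaxation delays in seconds (>= 4 points, strictly
#'   increasing, non-negative).
#' @param amplitudes peak amplitudes (arbitrary units).
#' @param sigma amplitude noise, scalar or per-point vector (> 0).
#' @param coherence,field,methyl_id optional metadata carried into the result.
#' @return An object of class `decay_fit` with elements `rate`, `rate_err`,
#'   `amp`, `amp_err`, `chi2`, `converged` and the metadata.
#' @export
fit_decay <- function(times, amplitudes, sigma = 1, coherence = NULL,
                      field = NULL, methyl_id = NULL) {
  stopifnot(length(times) >= 4L, length(amplitudes) == length(times),
            all(is.finite(times)), all(is.finite(amplitudes)),
            all(diff(times) > 0), all(times >= 0), all(sigma > 0))
  w <- rep_len(1 / sigma^2, length(times))

  prof <- function(R) {
    e <- exp(-R * times)
    A <- sum(w * amplitudes * e) / sum(w * e^2)
    list(A = A, rss = sum(w * (amplitudes - A * e)^2))
  }
  # coarse log-spaced bracket then refine; include R = 0 (flat curve)
  span <- max(times) - min(times)
  grid <- c(0, 10^seq(log10(0.01 / span), log10(100 / span), length.out = 60))
  rss <- vapply(grid, function(R) prof(R)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(R) prof(R)$rss, c(lo, max(hi, lo + 1e-9)),
                         tol = 1e-12)
  R <- opt$minimum
  pr <- prof(R)
  A <- pr$A

  # Gauss-Newton covariance at the optimum: J columns d/dA, d/dR of model
  e <- exp(-R * times)
  J <- cbind(e, -A * times * e) * sqrt(w)
  JtJ <- crossprod(J)
  converged <- TRUE
  cov <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) < 0)) {
    converged <- FALSE
    cov <- matrix(NA_real_, 2, 2)
  }
  structure(list(rate = R, rate_err = sqrt(cov[2, 2]),
                 amp = A, amp_err = sqrt(cov[1, 1]),
                 chi2 = pr$rss, n = length(times), converged = converged,
                 coherence = coherence, field = field, methyl_id = methyl_id),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> R = %.4g +/- %.3g s^-1 (A = %.4g, chi2 = %.3g, n = %d)%s\n",
              x$rate, x$rate_err, x$amp, x$chi2, x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(rate = object$rate, amp = object$amp)
}

#' Weighted linear regression of relaxation rates against B0^2
#'
#' Fits `R2,obs = R2,0 + beta * B0^2` by inverse-variance-weighted linear
#' regression across static fields (>= 3 required). In the fast-exchange
#' limit the slope is the sum of the CSA and exchange coefficients,
#' `beta = beta_CSA + beta_ex`. Measurement errors are taken as known, so the
#' parameter covariance is `(X' W X)^-1` without residual rescaling.
#'
#' @param rates relaxation rates in s^-1.
#' @param errs standard errors of the rates (> 0).
#' @param fields_MHz 1H Larmor frequencies in MHz (>= 3 distinct values).
#' @param constants an [nmr_constants()] object.
#' @return An object of class `field_regression` with `intercept`, `slope`
#'   (s^-1 T^-2), `cov` (2x2), `chi2`, `n`.
#' @export
regress_field <- function(rates, errs, fields_MHz,
                          constants = nmr_constants()) {
  stopifnot(length(rates) == length(errs),
            length(rates) == length(fields_MHz), all(errs > 0))
  if (length(unique(fields_MHz)) < 3L)
    stop("at least 3 distinct fields are required")
  B2 <- vapply(fields_MHz, function(f) field_spec(f, constants)$B0^2,
               numeric(1))
  w <- 1 / errs^2
  X <- cbind(1, B2)
  XtWX <- crossprod(X, w * X)
  cov <- solve(XtWX)
  beta <- unname(drop(cov %*% crossprod(X, w * rates)))
  resid <- rates - drop(X %*% beta)
  dimnames(cov) <- NULL
  structure(list(intercept = beta[1], slope = beta[2], cov = cov,
                 chi2 = sum(w * resid^2), n = length(rates),
                 fields_MHz = fields_MHz),
            class = "field_regression")
}

#' @export
print.field_regression <- function(x, ...) {
  cat(sprintf(
    "<field_regression> R2,0 = %.4g +/- %.3g s^-1; beta = %.4g +/- %.3g s^-1 T^-2 (chi2 = %.3g, n = %d)\n",
    x$intercept, sqrt(x$cov[1, 1]), x$slope, sqrt(x$cov[2, 2]), x$chi2, x$n))
  invisible(x)
}

#' @export
coef.field_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Subtract the CSA contribution from a field-dependence slope
#'
#' Removes the computed CSA coefficient from the fitted B0^2 slope to leave
#' the pure exchange coefficient `beta_ex = slope - beta_CSA`, which
#' constrains `(xi_C + n_H*xi_H)^2 = beta_ex`, i.e. the line pair
#' `xi_C + n_H*xi_H = +/- sqrt(beta_ex)` in (xi_H, xi_C) space. Errors are
#' propagated to first order from the slope error and, optionally, from the
#' CSA and order-parameter uncertainties.
#'
#' @param reg a [regress_field()] result.
#' @param system a [methyl_system()] carrying the CSA values and s2tau.
#' @param coherence one of `"ZQ"`, `"DQ"`, `"DQp"`, `"QQ"`.
#' @param dsigma_C_err,dsigma_H_err,s2tau_err optional 1-sigma uncertainties
#'   on the CSA values (ppm) and s2tau (s).
#' @param constants an [nmr_constants()] object.
#' @return An object of class `xi_constraint` with `n_H`, `beta_ex`,
#'   `beta_ex_err` and a logical `exchange_flag` (FALSE with a warning when
#'   beta_ex is more than 2 sigma below zero).
#' @export
subtract_csa <- function(reg, system, coherence,
                         dsigma_C_err = 0, dsigma_H_err = 0, s2tau_err = 0,
                         constants = nmr_constants()) {
  stopifnot(inherits(reg, "field_regression"))
  coherence <- match_coherence(coherence, allow = c("ZQ", "DQ", "DQp", "QQ"))
  bcsa <- csa_beta(coherence, system, constants)
  nH <- .n_H[[coherence]]
  g <- constants$gamma_C * system$dsigma_C * 1e-6 +
    nH * constants$gamma_H * system$dsigma_H * 1e-6
  # d(bcsa)/d(dsigma_C) etc., first order
  dC <- (8 / 45) * g * system$s2tau * constants$gamma_C * 1e-6
  dH <- (8 / 45) * g * system$s2tau * nH * constants$gamma_H * 1e-6
  dS <- if (system$s2tau > 0) bcsa / system$s2tau else 0
  var_csa <- (dC * dsigma_C_err)^2 + (dH * dsigma_H_err)^2 +
    (dS * s2tau_err)^2
  beta_ex <- reg$slope - bcsa
  err <- sqrt(reg$cov[2, 2] + var_csa)
  flag <- TRUE
  if (beta_ex < -2 * err) {
    warning("beta_ex is > 2 sigma below zero: no detectable exchange or ",
            "CSA overestimate")
    flag <- FALSE
  }
  structure(list(n_H = nH, coherence = coherence,
                 beta_ex = beta_ex, beta_ex_err = err,
                 exchange_flag = flag),
            class = "xi_constraint")
}

#' @export
print.xi_constraint <- function(x, ...) {
  cat(sprintf("<xi_constraint> %s (n_H = %+d): beta_ex = %.4g +/- %.3g s^-1 T^-2\n",
              x$coherence, x$n_H, x$beta_ex, x$beta_ex_err))
  invisible(x)
}

#' Constraint lines and their intersections in (xi_H, xi_C) space
#'
#' Each coherence's exchange coefficient defines the line pair
#' `xi_C + n_H*xi_H = +/- sqrt(beta_ex)`. `xi_constraint_lines()` returns
#' the two lines of one constraint as intercept/slope pairs
#' (`xi_C = root - n_H*xi_H`); `xi_line_intersections()` returns all pairwise
#' intersections between the line pairs of a list of constraints (coherence
#' pairs with equal `n_H` are skipped as parallel). For consistent two-state
#' fast-exchange data the four line pairs are concurrent at +/- the true
#' (xi_H, xi_C).
#'
#' @param constraint,constraints one [subtract_csa()] result, or a list of
#'   them.
#' @return `xi_constraint_lines`: data.frame with columns `sign`, `root`,
#'   `n_H`. `xi_line_intersections`: data.frame with columns `i`, `j`,
#'   `sign_i`, `sign_j`, `xi_H`, `xi_C`.
#' @export
xi_constraint_lines <- function(constraint) {
  stopifnot(inherits(constraint, "xi_constraint"))
  if (constraint$beta_ex < 0)
    return(data.frame(sign = numeric(0), root = numeric(0),
                      n_H = numeric(0)))
  r <- sqrt(constraint$beta_ex)
  data.frame(sign = c(1, -1), root = c(r, -r), n_H = constraint$n_H)
}

#' @rdname xi_constraint_lines
#' @export
xi_line_intersections <- function(constraints) {
  stopifnot(is.list(constraints),
            all(vapply(constraints, inherits, TRUE, "xi_constraint")))
  out <- list()
  k <- 0L
  for (i in seq_along(constraints)) for (j in seq_along(constraints)) {
    if (j <= i) next
    ci <- constraints[[i]]; cj <- constraints[[j]]
    if (ci$n_H == cj$n_H || ci$beta_ex < 0 || cj$beta_ex < 0) next
    for (si in c(1, -1)) for (sj in c(1, -1)) {
      ri <- si * sqrt(ci$beta_ex); rj <- sj * sqrt(cj$beta_ex)
      xiH <- (ri - rj) / (ci$n_H - cj$n_H)
      xiC <- ri - ci$n_H * xiH
      k <- k + 1L
      out[[k]] <- data.frame(i = i, j = j, sign_i = si, sign_j = sj,
                             xi_H = xiH, xi_C = xiC)
    }
  }
  if (!k) return(data.frame(i = integer(0), j = integer(0),
                            sign_i = numeric(0), sign_j = numeric(0),
                            xi_H = numeric(0), xi_C = numeric(0)))
  do.call(rbind, out)
}

#' Chi-square surface over (xi_H, xi_C)
#'
#' For each candidate (xi_H, xi_C) on a grid, the B0^2 coefficient of each
#' coherence is fixed at `beta_CSA + (xi_C + n_H*xi_H)^2` and the per-coherence
#' exchange-free rate R2,0 is profiled out in closed form (weighted mean of
#' `rate - beta*B0^2`). The surface is the residual chi-square summed over the
#' four coherences and all fields. Minima come in +/- pairs because the model
#' depends on (xi_H, xi_C) only through squared linear combinations.
#' Confidence regions use the two-parameter Delta-chi-square thresholds 2.30
#' (68 %) and 6.18 (95 %).
#'
#' @param measurements data.frame with columns `coherence`, `field_MHz`,
#'   `rate`, `err` for one methyl group (all four coherences, >= 3 fields
#'   each).
#' @param system a [methyl_system()] providing the CSA parameters and s2tau.
#' @param xi_H,xi_C grid axes; by default symmetric ranges spanning 1.5x the
#'   largest `|sqrt(max(slope - beta_CSA, 0))|` across coherences, 301 points
#'   each.
#' @param n_grid grid size used when axes are auto-generated.
#' @param use_coherences coherences entering the chi-square sum (default all
#'   four; restricting to ZQ+DQ reproduces the xi_H/xi_C-symmetric two-spin
#'   analysis).
#' @param constants an [nmr_constants()] object.
#' @return An object of class `xi_surface`: list with `xi_H`, `xi_C` (axes),
#'   `chi2` (matrix, rows = xi_H), `min_chi2`, `minima` (data.frame of the
#'   +/- pair), `thresholds`.
#' @export
xi_surface <- function(measurements, system, xi_H = NULL, xi_C = NULL,
                       n_grid = 301L,
                       use_coherences = c("ZQ", "DQ", "DQp", "QQ"),
                       constants = nmr_constants()) {
  req <- c("coherence", "field_MHz", "rate", "err")
  stopifnot(is.data.frame(measurements), all(req %in% names(measurements)),
            length(use_coherences) >= 2L)
  cohs <- vapply(use_coherences, match_coherence, character(1),
                 allow = c("ZQ", "DQ", "DQp", "QQ"))
  meas <- split(measurements, factor(measurements$coherence, levels = cohs))
  for (co in cohs) {
    if (is.null(meas[[co]]) || length(unique(meas[[co]]$field_MHz)) < 3L)
      stop("need measurements at >= 3 fields for coherence ", co)
  }
  B2 <- lapply(meas, function(d)
    vapply(d$field_MHz, function(f) field_spec(f, constants)$B0^2, numeric(1)))
  w <- lapply(meas, function(d) 1 / d$err^2)
  bcsa <- vapply(cohs, csa_beta, numeric(1), system = system,
                 constants = constants)

  if (is.null(xi_H) || is.null(xi_C)) {
    # scale from per-coherence regression slopes
    rmax <- 0
    for (co in cohs) {
      d <- meas[[co]]
      reg <- regress_field(d$rate, d$err, d$field_MHz, constants)
      rmax <- max(rmax, sqrt(max(reg$slope - bcsa[[co]], 0)))
    }
    if (rmax <= 0) rmax <- 1e-3
    if (is.null(xi_H)) xi_H <- seq(-1.5 * rmax, 1.5 * rmax,
                                   length.out = n_grid)
    if (is.null(xi_C)) xi_C <- seq(-1.5 * rmax, 1.5 * rmax,
                                   length.out = n_grid)
  }
  if (!length(xi_H) || !length(xi_C)) stop("empty grid")

  XH <- matrix(xi_H, nrow = length(xi_H), ncol = length(xi_C))
  XC <- matrix(xi_C, nrow = length(xi_H), ncol = length(xi_C), byrow = TRUE)
  chi2 <- matrix(0, nrow = length(xi_H), ncol = length(xi_C))
  for (co in cohs) {
    beta <- bcsa[[co]] + (XC + .n_H[[co]] * XH)^2
    d <- meas[[co]]; b2 <- B2[[co]]; wc <- w[[co]]
    sw <- sum(wc)
    # profiled R2,0 = weighted mean of (rate - beta*B0^2), vectorised over grid
    r20 <- 0
    for (k in seq_along(b2))
      r20 <- r20 + wc[k] * (d$rate[k] - beta * b2[k])
    r20 <- r20 / sw
    for (k in seq_along(b2))
      chi2 <- chi2 + wc[k] * (d$rate[k] - r20 - beta * b2[k])^2
  }
  imin <- arrayInd(which.min(chi2), dim(chi2))
  mn <- data.frame(xi_H = c(xi_H[imin[1]], -xi_H[imin[1]]),
                   xi_C = c(xi_C[imin[2]], -xi_C[imin[2]]))
  structure(list(xi_H = xi_H, xi_C = xi_C, chi2 = chi2,
                 min_chi2 = min(chi2), minima = mn,
                 thresholds = c(`68%` = 2.30, `95%` = 6.18),
                 system = system),
            class = "xi_surface")
}

#' Evaluate the profiled chi-square at a single (xi_H, xi_C) point
#'
#' Same objective as [xi_surface()] on a 1x1 grid; useful for containment
#' tests against confidence thresholds.
#'
#' @inheritParams xi_surface
#' @param xi_H,xi_C scalar coordinates.
#' @return chi-square value.
#' @export
xi_chi2_at <- function(measurements, system, xi_H, xi_C,
                       constants = nmr_constants()) {
  s <- xi_surface(measurements, system, xi_H = xi_H, xi_C = xi_C,
                  constants = constants)
  s$chi2[1, 1]
}

#' @export
print.xi_surface <- function(x, ...) {
  cat(sprintf(
    "<xi_surface> %d x %d grid; min chi2 = %.4g at (xi_H, xi_C) = +/-(%.4g, %.4g)\n",
    length(x$xi_H), length(x$xi_C), x$min_chi2,
    x$minima$xi_H[1], x$minima$xi_C[1]))
  invisible(x)
}

#' @export
plot.xi_surface <- function(x, ...) {
  graphics::contour(x$xi_H, x$xi_C, x$chi2,
                    levels = x$min_chi2 + x$thresholds,
                    labels = names(x$thresholds),
                    xlab = expression(xi[H]), ylab = expression(xi[C]), ...)
  graphics::points(x$minima$xi_H, x$minima$xi_C, pch = 3)
  invisible(x)
}

#' Confidence contours of a chi-square surface
#'
#' @param x an [xi_surface()] object.
#' @param level `"68%"` or `"95%"`.
#' @return list of contour polygons (as returned by
#'   [grDevices::contourLines()]).
#' @export
xi_confidence_contours <- function(x, level = c("68%", "95%")) {
  stopifnot(inherits(x, "xi_surface"))
  level <- match.arg(level)
  grDevices::contourLines(x$xi_H, x$xi_C, x$chi2,
                          levels = x$min_chi2 + x$thresholds[[level]])
}
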