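#' Physical description of one methyl group
#'
#' Collects the parameters that determine the dipolar and CSA contributions to
#' methyl multiple-quantum relaxation: the product of the squared symmetry-axis
#' order parameter and the rotational correlation time (`s2tau`, seconds), the
#' correlation time itself (`tau_c`, needed only when external spins are
#' present), the 13C and 1H chemical shift anisotropies (ppm) and a list of
#' [external_spin()] partners.
#'
#' @param s2tau S2axis * tau_c in seconds (e.g. 50e-9 for 50 ns); must be
#'   non-negative.
#' @param tau_c rotational correlation time in seconds, required if
#'   `externals` is non-empty.
#' @param dsigma_C,dsigma_H chemical shift anisotropies in ppm.
#' @param externals list of [external_spin()] objects (may be empty).
#' @return An object of class `methyl_system`.
#' @export
methyl_system <- function(s2tau, tau_c = NULL, dsigma_C = 0, dsigma_H = 0,
                          externals = list()) {
  stopifnot(is.numeric(s2tau), length(s2tau) == 1L, s2tau >= 0,
            is.finite(dsigma_C), is.finite(dsigma_H))
  if (length(externals) && !all(vapply(externals, inherits, TRUE,
                                       "external_spin")))
    stop("externals must be a list of external_spin objects")
  structure(list(s2tau = s2tau, tau_c = tau_c,
                 dsigma_C = dsigma_C, dsigma_H = dsigma_H,
                 externals = externals),
            class = "methyl_system")
}

#' Normalised chemical shift differences
#'
#' In the fast-exchange limit, the exchange contribution to relaxation of each
#' methyl coherence is `(xi_C + n_H*xi_H)^2 * B0^2`, where
#' `xi_X = sqrt(pA*pB/kex) * gamma_X * dDelta_X * 1e-6` is the chemical shift
#' difference of nucleus X normalised by the thermodynamic and kinetic
#' parameters of the exchange process (units: s^-1/2 T^-1, so that xi^2*B0^2
#' is s^-1).
#'
#' @param xi_C,xi_H normalised shift differences.
#' @return An object of class `xi_pair`.
#' @export
xi_pair <- function(xi_C, xi_H) {
  stopifnot(is.finite(xi_C), is.finite(xi_H))
  structure(list(xi_C = xi_C, xi_H = xi_H), class = "xi_pair")
}

#' @rdname xi_pair
#' @param model a [two_state()] exchange model.
#' @param constants an [nmr_constants()] object.
#' @export
xi_from_exchange <- function(model, constants = nmr_constants()) {
  stopifnot(inherits(model, "two_state"))
  f <- sqrt((1 - model$p_B) * model$p_B / model$k_ex)
  xi_pair(xi_C = f * constants$gamma_C * model$dDelta_C * 1e-6,
          xi_H = f * constants$gamma_H * model$dDelta_H * 1e-6)
}

#' CSA contribution to multiple-quantum relaxation
#'
#' The CSA cross-correlated contribution to the transverse relaxation of a
#' methyl multiple-quantum coherence in the macromolecular limit is
#' `(4/45) * (gamma_C*dsigma_C + n_H*gamma_H*dsigma_H)^2 * B0^2 * s2tau`
#' (CSAs converted from ppm). `csa_beta()` returns the field-independent
#' coefficient of B0^2 (s^-1 T^-2); `csa_contribution()` multiplies by B0^2.
#'
#' @param coherence one of `"ZQ"`, `"DQ"`, `"DQp"`, `"QQ"`.
#' @param system a [methyl_system()].
#' @param field a [field_spec()].
#' @param constants an [nmr_constants()] object.
#' @return rate in s^-1 (`csa_contribution`) or s^-1 T^-2 (`csa_beta`).
#' @examples
#' sys <- methyl_system(s2tau = 50e-9, dsigma_C = 34.2)
#' csa_contribution("QQ", sys, field_spec(800))  # ~ 8.3 s^-1
#' @export
csa_contribution <- function(coherence, system, field,
                             constants = nmr_constants()) {
  stopifnot(inherits(field, "field_spec"))
  csa_beta(coherence, system, constants) * field$B0^2
}

#' @rdname csa_contribution
#' @export
csa_beta <- function(coherence, system, constants = nmr_constants()) {
  coherence <- match_coherence(coherence, allow = c("ZQ", "DQ", "DQp", "QQ"))
  stopifnot(inherits(system, "methyl_system"))
  g <- constants$gamma_C * system$dsigma_C * 1e-6 +
    .n_H[[coherence]] * constants$gamma_H * system$dsigma_H * 1e-6
  (4 / 45) * g^2 * system$s2tau
}

#' Fast-exchange contribution to multiple-quantum relaxation
#'
#' In the fast-exchange limit the exchange contribution is
#' `(xi_C + n_H*xi_H)^2 * B0^2`. The four-spin coherences (`n_H = +/-3`) are
#' 9-fold more sensitive to 1H shift differences than ZQ/DQ, which breaks the
#' xi_C/xi_H symmetry of the two-spin coherences. `exchange_beta()` returns
#' the coefficient of B0^2.
#'
#' @inheritParams csa_contribution
#' @param xi an [xi_pair()].
#' @return rate in s^-1 (`exchange_contribution_fast`) or s^-1 T^-2
#'   (`exchange_beta`).
#' @export
exchange_contribution_fast <- function(coherence, xi, field) {
  stopifnot(inherits(field, "field_spec"))
  exchange_beta(coherence, xi) * field$B0^2
}

#' @rdname exchange_contribution_fast
#' @export
exchange_beta <- function(coherence, xi) {
  coherence <- match_coherence(coherence, allow = c("ZQ", "DQ", "DQp", "QQ"))
  stopifnot(inherits(xi, "xi_pair"))
  (xi$xi_C + .n_H[[coherence]] * xi$xi_H)^2
}

# Dipolar coefficient tables: rate = sum over externals of
# (cb * b_C^2 + hb * b_H^2 + xb * b_C * b_H) * tau_c.
# Rows: ZQ, DQ, DQp, QQ. Intra-methyl dipolar relaxation of all four
# coherences is identically zero, so only external spins contribute.
.dip_H <- list(
  ZQ  = c(cb = 1 / 5, hb = 11 / 20, xb = -2 / 5),
  DQ  = c(cb = 1 / 5, hb = 11 / 20, xb = 2 / 5),
  DQp = c(cb = 1 / 5, hb = 39 / 20, xb = -6 / 5),
  QQ  = c(cb = 1 / 5, hb = 39 / 20, xb = 6 / 5)
)
.dip_D <- list(
  ZQ  = c(cb = 8 / 15, hb = 8 / 15, xb = -16 / 15),
  DQ  = c(cb = 8 / 15, hb = 8 / 15, xb = 16 / 15),
  DQp = c(cb = 8 / 15, hb = 24 / 5, xb = -16 / 5),
  QQ  = c(cb = 8 / 15, hb = 24 / 5, xb = 16 / 5)
)

#' Dipolar contribution from external spins
#'
#' Transverse relaxation of methyl ZQ, DQ, DQp and QQ coherences due to
#' dipolar interactions with external protons and deuterons, in the
#' macromolecular limit. Intra-methyl dipolar relaxation of these coherences
#' is identically zero, so an empty `externals` list gives 0.
#'
#' @inheritParams csa_contribution
#' @return rate in s^-1.
#' @export
dipolar_contribution <- function(coherence, system) {
  coherence <- match_coherence(coherence, allow = c("ZQ", "DQ", "DQp", "QQ"))
  stopifnot(inherits(system, "methyl_system"))
  if (!length(system$externals)) return(0)
  if (is.null(system$tau_c))
    stop("tau_c must be supplied when external spins are present")
  total <- 0
  for (ex in system$externals) {
    cf <- if (ex$kind == "proton") .dip_H[[coherence]] else .dip_D[[coherence]]
    total <- total +
      (cf[["cb"]] * ex$b_C^2 + cf[["hb"]] * ex$b_H^2 +
         cf[["xb"]] * ex$b_C * ex$b_H) * system$tau_c
  }
  total
}

#' Total forward relaxation rate of one coherence
#'
#' Sum of the dipolar, CSA and fast-exchange contributions.
#'
#' @inheritParams csa_contribution
#' @param xi an [xi_pair()] or `NULL` for no exchange.
#' @return rate in s^-1.
#' @export
total_rate_fast <- function(coherence, system, field, xi = NULL,
                            constants = nmr_constants()) {
  r <- dipolar_contribution(coherence, system) +
    csa_contribution(coherence, system, field, constants)
  if (!is.null(xi))
    r <- r + exchange_contribution_fast(coherence, xi, field)
  r
}

#' Sum and difference of ZQ and DQ relaxation rates
#'
#' The multiple-quantum relaxation rate and cross-correlated relaxation rate
#' are defined as `R_MQ = (R_ZQ + R_DQ)/2` and `dR_MQ = (R_ZQ - R_DQ)/2`, so
#' that `R_ZQ = R_MQ + dR_MQ` and `R_DQ = R_MQ - dR_MQ`. With Table-style
#' fast-exchange inputs `(xi_C -/+ xi_H)^2 B0^2` this yields
#' `R_MQ,ex = (xi_C^2 + xi_H^2) B0^2` and `dR_MQ,ex = -2 xi_C xi_H B0^2`.
#'
#' @param R_ZQ,R_DQ relaxation rates in s^-1.
#' @return named numeric vector `c(R_MQ =, dR_MQ =)`.
#' @export
mq_combine <- function(R_ZQ, R_DQ) {
  stopifnot(is.finite(R_ZQ), is.finite(R_DQ))
  c(R_MQ = (R_ZQ + R_DQ) / 2, dR_MQ = (R_ZQ - R_DQ) / 2)
}
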