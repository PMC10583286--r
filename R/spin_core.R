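#' Physical constants for methyl spin systems
#'
#' Returns the set of physical constants used throughout the package:
#' gyromagnetic ratios, vacuum permeability, the reduced Planck constant and
#' the effective intra-methyl internuclear distances. Values follow CODATA;
#' the effective distances `r_CH` = 1.106 A and `r_HH` = 1.813 A are the
#' common literature choices for a rapidly rotating methyl group and can be
#' overridden, either directly or through the `[constants]` section of a run
#' configuration file (see [read_run_config()]).
#'
#' @param ... named overrides for any constant, e.g. `r_CH = 1.09e-10`.
#'   Distances are in metres, gyromagnetic ratios in rad s^-1 T^-1.
#' @return An object of class `nmr_constants`: a named list with elements
#'   `gamma_H`, `gamma_C`, `gamma_D`, `mu0`, `hbar`, `r_CH`, `r_HH`.
#' @examples
#' cst <- nmr_constants()
#' cst$gamma_H / cst$gamma_C  # ~ 3.976
#' @export
nmr_constants <- function(...) {
  cst <- list(
    gamma_H = 2.6752218744e8,  # rad s^-1 T^-1
    gamma_C = 6.728284e7,
    gamma_D = 4.10706e7,
    mu0     = 4 * pi * 1e-7,   # T m A^-1
    hbar    = 1.054571817e-34, # J s
    r_CH    = 1.106e-10,       # m, effective methyl C-H distance
    r_HH    = 1.813e-10        # m, effective methyl H-H distance
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("constant overrides must be named")
    unknown <- setdiff(names(ov), names(cst))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    cst[names(ov)] <- ov
  }
  for (nm in c("mu0", "hbar", "r_CH", "r_HH"))
    if (cst[[nm]] <= 0) stop("constant ", nm, " must be positive")
  structure(cst, class = "nmr_constants")
}

#' Static field specification from the 1H Larmor frequency
#'
#' Fields are specified throughout by the 1H Larmor frequency in MHz, as is
#' conventional when reporting spectrometer strength; the static field B0 in
#' tesla is derived as `B0 = 2*pi*larmor_H*1e6 / gamma_H`.
#'
#' @param larmor_MHz 1H Larmor frequency in MHz (e.g. 600, 700, 800, 950).
#' @param constants an [nmr_constants()] object.
#' @return An object of class `field_spec` with elements `larmor_MHz` and
#'   `B0` (tesla).
#' @examples
#' field_spec(800)$B0  # ~ 18.79 T
#' @export
field_spec <- function(larmor_MHz, constants = nmr_constants()) {
  stopifnot(is.numeric(larmor_MHz), length(larmor_MHz) == 1L, larmor_MHz > 0)
  structure(
    list(larmor_MHz = larmor_MHz,
         B0 = 2 * pi * larmor_MHz * 1e6 / constants$gamma_H),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> 1H %.1f MHz (B0 = %.4f T)\n", x$larmor_MHz, x$B0))
  invisible(x)
}

# Canonical coherence names. DQp is the four-spin double-quantum coherence
# (often written DQ'); SQ_H is 1H single quantum (no 13C component).
.coherences <- c("ZQ", "DQ", "DQp", "QQ", "SQ_H")
.n_H <- c(ZQ = -1, DQ = 1, DQp = -3, QQ = 3, SQ_H = 1)
.n_C <- c(ZQ = 1, DQ = 1, DQp = 1, QQ = 1, SQ_H = 0)

#' Methyl coherences and their 1H frequency coefficients
#'
#' The methyl multiple-quantum coherences analysed here evolve at
#' `n_C*omega_C + n_H*omega_H`: ZQ (`omega_C - omega_H`), DQ
#' (`omega_C + omega_H`), DQp (`omega_C - 3*omega_H`, the four-spin
#' double-quantum coherence) and QQ (`omega_C + 3*omega_H`). `SQ_H` is a 1H
#' single-quantum coherence with no 13C component.
#'
#' @param coherence coherence name; `"DQprime"` is accepted as an alias for
#'   `"DQp"`.
#' @return `coherences()` returns the vector of valid names; `coherence_nH()`
#'   and `coherence_nC()` the signed integer frequency coefficients.
#' @export
coherences <- function() .coherences

#' @rdname coherences
#' @export
coherence_nH <- function(coherence) {
  .n_H[[match_coherence(coherence)]]
}

#' @rdname coherences
#' @export
coherence_nC <- function(coherence) {
  .n_C[[match_coherence(coherence)]]
}

match_coherence <- function(coherence, allow = .coherences) {
  if (identical(coherence, "DQprime")) coherence <- "DQp"
  if (!is.character(coherence) || length(coherence) != 1L ||
      !(coherence %in% allow))
    stop("unknown coherence '", paste(coherence, collapse = ","),
         "'; valid: ", paste(allow, collapse = ", "))
  coherence
}

#' Angular frequency difference of a coherence between exchanging states
#'
#' For chemical shift differences `dDelta_C` and `dDelta_H` (ppm) between two
#' exchanging states, the frequency difference of a multiple-quantum coherence
#' is the corresponding linear combination
#' `n_C*gamma_C*B0*dDelta_C*1e-6 + n_H*gamma_H*B0*dDelta_H*1e-6` (rad s^-1).
#' For `SQ_H` only the 1H term contributes.
#'
#' @param coherence one of `coherences()`.
#' @param dDelta_C,dDelta_H chemical shift differences in ppm.
#' @param field a [field_spec()].
#' @param constants an [nmr_constants()] object.
#' @return frequency difference in rad s^-1.
#' @examples
#' coherence_delta_omega("DQp", 1.5, 0.2, field_spec(800))  # ~ -1120 rad/s
#' @export
coherence_delta_omega <- function(coherence, dDelta_C, dDelta_H, field,
                                  constants = nmr_constants()) {
  coherence <- match_coherence(coherence)
  stopifnot(inherits(field, "field_spec"))
  .n_C[[coherence]] * constants$gamma_C * field$B0 * dDelta_C * 1e-6 +
    .n_H[[coherence]] * constants$gamma_H * field$B0 * dDelta_H * 1e-6
}

#' Dipolar coupling constant between two spins
#'
#' Evaluates `b_AB = (mu0 * hbar * gamma_A * gamma_B / (4*pi*r^3)) *
#' P2(cos(theta))`, with `P2(x) = (3*x^2 - 1)/2`. `theta` is the angle of the
#' internuclear vector relative to the methyl symmetry axis; couplings to
#' external spins pick up this geometric factor under rapid methyl rotation.
#'
#' @param gamma_A,gamma_B gyromagnetic ratios (rad s^-1 T^-1).
#' @param r_AB internuclear distance (m); must be positive.
#' @param theta angle in radians (default 0, full coupling).
#' @param constants an [nmr_constants()] object.
#' @return coupling constant in rad s^-1.
#' @export
dipolar_coupling <- function(gamma_A, gamma_B, r_AB, theta = 0,
                             constants = nmr_constants()) {
  if (!is.numeric(r_AB) || any(r_AB <= 0))
    stop("r_AB must be positive")
  p2 <- (3 * cos(theta)^2 - 1) / 2
  constants$mu0 * constants$hbar * gamma_A * gamma_B /
    (4 * pi * r_AB^3) * p2
}

#' External spin coupled to a methyl group
#'
#' Describes one external proton or deuteron through its dipolar couplings to
#' the methyl 13C and 1H spins (including the P2 geometry factor).
#'
#' @param kind `"proton"` or `"deuteron"`.
#' @param b_C,b_H dipolar couplings to the methyl 13C and 1H spins
#'   (rad s^-1), e.g. from [dipolar_coupling()].
#' @return An object of class `external_spin`.
#' @export
external_spin <- function(kind = c("proton", "deuteron"), b_C, b_H) {
  kind <- match.arg(kind)
  stopifnot(is.finite(b_C), is.finite(b_H))
  structure(list(kind = kind, b_C = b_C, b_H = b_H), class = "external_spin")
}
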