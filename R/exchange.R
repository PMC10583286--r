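#' Two-state chemical exchange model
#'
#' A two-site exchange process A <-> B with minor-state population `p_B`,
#' total exchange rate `k_ex = k_AB + k_BA` and per-nucleus chemical shift
#' differences between the states (ppm). Detailed balance fixes
#' `k_AB = p_B*k_ex` and `k_BA = (1-p_B)*k_ex`.
#'
#' @param p_B minor-state population, 0 < p_B < 0.5.
#' @param k_ex exchange rate in s^-1, > 0.
#' @param dDelta_C,dDelta_H chemical shift differences in ppm.
#' @return An object of class `two_state`.
#' @export
two_state <- function(p_B, k_ex, dDelta_C = 0, dDelta_H = 0) {
  stopifnot(is.numeric(p_B), p_B >= 0, p_B < 0.5,
            is.numeric(k_ex), k_ex > 0,
            is.finite(dDelta_C), is.finite(dDelta_H))
  structure(list(p_B = p_B, k_ex = k_ex,
                 dDelta_C = dDelta_C, dDelta_H = dDelta_H,
                 k_AB = p_B * k_ex, k_BA = (1 - p_B) * k_ex),
            class = "two_state")
}

#' @export
print.two_state <- function(x, ...) {
  cat(sprintf(
    "<two_state> pB = %.4g, kex = %.4g s^-1, dDelta = (%.3g C, %.3g H) ppm\n",
    x$p_B, x$k_ex, x$dDelta_C, x$dDelta_H))
  invisible(x)
}

#' Hahn-echo exchange broadening for two-state exchange
#'
#' Exchange contribution to the transverse relaxation rate measured by a
#' Hahn-echo experiment, valid in all exchange regimes:
#' `Rex = Re{ (kex + i*dw - sqrt((kex + i*dw)^2 - 4i*kex*pB*dw)) / 2 }`
#' (principal square-root branch), the real part of the slowly decaying
#' eigenvalue of the two-site Bloch-McConnell Liouvillian.
#' `rex_eigenvalue()` computes the same quantity numerically from the 2x2
#' evolution matrix and serves as an independent cross-check.
#'
#' In the fast limit (`kex >> dw`) `Rex -> pA*pB*dw^2/kex`; in the slow limit
#' (`dw >> kex`) `Rex -> pB*kex` (lifetime broadening).
#'
#' @param delta_omega frequency difference of the coherence between the two
#'   states, rad s^-1 (may be a vector).
#' @param model a [two_state()] model.
#' @return Rex in s^-1.
#' @examples
#' rex_closed_form(1896, two_state(0.1, 5000))  # ~ 59.7 s^-1
#' @export
rex_closed_form <- function(delta_omega, model) {
  stopifnot(inherits(model, "two_state"))
  z <- model$k_ex + 1i * delta_omega
  Re((z - sqrt(z^2 - 4i * model$k_ex * model$p_B * delta_omega)) / 2)
}

#' @rdname rex_closed_form
#' @export
rex_eigenvalue <- function(delta_omega, model) {
  stopifnot(inherits(model, "two_state"))
  vapply(delta_omega, function(dw) {
    L <- matrix(c(-model$k_AB, model$k_AB,
                  model$k_BA, -model$k_BA + 1i * dw), 2L, 2L)
    ev <- eigen(L, only.values = TRUE)$values
    # most slowly decaying mode = eigenvalue with least-negative real part
    -max(Re(ev))
  }, numeric(1))
}

#' CPMG experiment description
#'
#' @param kind `"MQ"` (methyl multiple-quantum CPMG, propagated in the
#'   \{ZQ-, ZQ+, DQ-, DQ+\} basis) or `"SQ_H"` (1H single-quantum CPMG,
#'   propagated in the transverse 1H basis).
#' @param T_relax constant-time relaxation period in seconds (e.g. 0.04).
#' @param nu_cpmg vector of CPMG frequencies in Hz. Each must give an integer
#'   pulse count `N = nu * T_relax` (within 1e-6 relative tolerance).
#' @param field a [field_spec()].
#' @return An object of class `cpmg_experiment`.
#' @export
cpmg_experiment <- function(kind = c("MQ", "SQ_H"), T_relax, nu_cpmg, field) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(T_relax), T_relax > 0,
            is.numeric(nu_cpmg), all(nu_cpmg > 0),
            inherits(field, "field_spec"))
  n <- nu_cpmg * T_relax
  if (any(abs(n - round(n)) > 1e-6 * pmax(n, 1)))
    stop("each nu_cpmg must give an integer pulse count N = nu * T_relax; ",
         "offending nu: ",
         paste(nu_cpmg[abs(n - round(n)) > 1e-6 * pmax(n, 1)], collapse = ", "))
  structure(list(kind = kind, T_relax = T_relax, nu_cpmg = nu_cpmg,
                 field = field),
            class = "cpmg_experiment")
}

# closed-form exp(M*t) for a 2x2 complex matrix
expm2 <- function(M, t) {
  mu <- (M[1, 1] + M[2, 2]) / 2
  detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  q <- sqrt(as.complex(mu^2 - detM))
  if (abs(q * t) < 1e-8) {
    c0 <- exp(mu * t) * (1 - mu * t)
    c1 <- exp(mu * t) * t
  } else {
    c0 <- exp(mu * t) * (cosh(q * t) - mu * sinh(q * t) / q)
    c1 <- exp(mu * t) * sinh(q * t) / q
  }
  c0 * diag(2) + c1 * M
}

# free-evolution Liouvillian for one coherence: state A on resonance,
# state B offset by dw
evol_matrix <- function(model, dw) {
  matrix(c(-model$k_AB, model$k_AB,
           model$k_BA, -model$k_BA + 1i * dw), 2L, 2L)
}

# M %*% M %*% ... (n times) by square-and-multiply; n >= 0
mat_power <- function(M, n) {
  P <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) P <- M %*% P
    M <- M %*% M
    n <- n %/% 2
  }
  P
}

# realification of a complex 2x2 matrix acting on stacked (Re, Im) 4-vectors
realify <- function(E) {
  rbind(cbind(Re(E), -Im(E)), cbind(Im(E), Re(E)))
}

#' Simulate a CPMG relaxation dispersion profile
#'
#' Numerical propagation of magnetisation through the CPMG echo train
#' `[tau - pi - tau]^N` with `N = nu * T_relax` refocusing pulses equally
#' spaced over the relaxation period (inter-pulse spacing `1/nu`, so
#' `tau = 1/(2*nu)`), assuming ideal pulses. For `kind = "MQ"` the state is
#' propagated in the \{ZQ-, ZQ+, DQ-, DQ+\} coherence basis where an ideal
#' 13C pi pulse acts as the permutation ZQ+/- <-> DQ-/+; for `kind = "SQ_H"`
#' a 1H pi pulse conjugates the transverse coherence. Each free-precession
#' segment evolves the two-site amplitude vector by the matrix exponential of
#' the complex Bloch-McConnell evolution matrix. The initial amplitudes are
#' the equilibrium populations (pA, pB) on the starting coherence, and the
#' signal is the magnitude of the complex sum over exchange sites, referenced
#' to T = 0:
#' `R_eff = r20 - log(|signal(T)|)/T`.
#'
#' @param model a [two_state()] model.
#' @param experiment a [cpmg_experiment()].
#' @param r20 exchange-free baseline rate in s^-1.
#' @param start starting coherence for MQ experiments: `"DQ"` (default),
#'   `"ZQ"`, or `"avg"` (mean of the signals starting on ZQ+ and DQ+; the
#'   choice is degenerate for ideal pulses and even pulse numbers).
#' @param constants an [nmr_constants()] object.
#' @return numeric vector of effective rates R_eff (s^-1), one per
#'   `experiment$nu_cpmg`.
#' @export
cpmg_profile <- function(model, experiment, r20, start = c("DQ", "ZQ", "avg"),
                         constants = nmr_constants()) {
  stopifnot(inherits(model, "two_state"),
            inherits(experiment, "cpmg_experiment"))
  start <- match.arg(start)
  Tt <- experiment$T_relax
  fld <- experiment$field
  v0 <- c(1 - model$p_B, model$p_B) + 0i

  if (experiment$kind == "SQ_H") {
    dw <- coherence_delta_omega("SQ_H", 0, model$dDelta_H, fld, constants)
    L <- evol_matrix(model, dw)
    reff <- vapply(experiment$nu_cpmg, function(nu) {
      N <- round(nu * Tt)
      E <- expm2(L, Tt / (2 * N))
      # element op v -> E Conj(E v) is antilinear; propagate its real 4x4
      # representation so the N-fold repetition can be composed directly
      RE <- realify(E)
      Cj <- diag(c(1, 1, -1, -1))
      U <- RE %*% Cj %*% RE
      x <- mat_power(U, N) %*% c(Re(v0), Im(v0))
      v <- complex(real = x[1:2], imaginary = x[3:4])
      r20 - log(Mod(sum(v))) / Tt
    }, numeric(1))
    return(reff)
  }

  # MQ: coherence order {ZQ-, ZQ+, DQ-, DQ+}; ideal 13C pi permutes
  # ZQ- <-> DQ+ and ZQ+ <-> DQ-. Amplitude starting on a single coherence
  # stays on a single coherence, hopping between a block pair, so the echo
  # train reduces to alternating 2x2 products.
  dwC <- coherence_delta_omega("ZQ", model$dDelta_C, 0, fld, constants)
  dwH <- constants$gamma_H * fld$B0 * model$dDelta_H * 1e-6
  dws <- c(ZQm = -(dwC - dwH), ZQp = dwC - dwH,
           DQm = -(dwC + dwH), DQp = dwC + dwH)
  perm <- c(ZQm = "DQp", ZQp = "DQm", DQm = "ZQp", DQp = "ZQm")
  Ls <- lapply(dws, function(dw) evol_matrix(model, dw))

  run <- function(block0) {
    other <- perm[[block0]]
    vapply(experiment$nu_cpmg, function(nu) {
      N <- round(nu * Tt)
      tau <- Tt / (2 * N)
      E0 <- expm2(Ls[[block0]], tau)
      E1 <- expm2(Ls[[other]], tau)
      elem <- E1 %*% E0                       # one [tau - pi - tau] element
      G <- (E0 %*% E1) %*% elem               # two elements, back on block0
      v <- mat2_power_apply(G, N %/% 2L, v0)
      if (N %% 2L == 1L) v <- elem %*% v
      r20 - log(Mod(sum(v))) / Tt
    }, numeric(1))
  }

  switch(start,
         DQ = run("DQp"),
         ZQ = run("ZQp"),
         avg = {
           rd <- run("DQp"); rz <- run("ZQp")
           # average the signals, not the rates
           -log((exp(-rd * Tt) + exp(-rz * Tt)) / 2) / Tt
         })
}

#' Exact closed-form 1H SQ CPMG dispersion for two-state exchange
#'
#' Analytical solution for the effective relaxation rate of a single-quantum
#' coherence under an ideal CPMG train with two-site exchange, used as an
#' independent oracle for [cpmg_profile()]. Over two echo elements the
#' (antilinear) evolution composes to the linear cycle propagator
#' `M2 = E * Conj(E)^2 * E` with `E = exp(L*tau)` evaluated in closed form;
#' `M2^m` is expressed exactly through its two eigenvalues (quadratic formula)
#' and spectral projectors, so no step-wise propagation is performed. This is
#' the established exact single-quantum dispersion solution, including minor
#' eigenvalue and projection contributions neglected by the classic
#' dominant-eigenvalue (Carver-Richards) approximation.
#'
#' @inheritParams cpmg_profile
#' @return numeric vector of effective rates (s^-1).
#' @export
sq_cpmg_closed_form <- function(model, experiment, r20,
                                constants = nmr_constants()) {
  stopifnot(inherits(model, "two_state"),
            inherits(experiment, "cpmg_experiment"),
            experiment$kind == "SQ_H")
  Tt <- experiment$T_relax
  dw <- coherence_delta_omega("SQ_H", 0, model$dDelta_H, experiment$field,
                              constants)
  L <- evol_matrix(model, dw)
  v0 <- c(1 - model$p_B, model$p_B) + 0i
  vapply(experiment$nu_cpmg, function(nu) {
    N <- round(nu * Tt)
    E <- expm2(L, Tt / (2 * N))
    M2 <- E %*% Conj(E) %*% Conj(E) %*% E
    m <- N %/% 2L
    vm <- if (m == 0L) v0 else mat2_power_apply(M2, m, v0)
    if (N %% 2L == 1L) vm <- E %*% Conj(E %*% vm)  # trailing odd element
    r20 - log(Mod(sum(vm))) / Tt
  }, numeric(1))
}

# closed-form A^m %*% v for 2x2 complex A via spectral decomposition
mat2_power_apply <- function(A, m, v) {
  tr <- A[1, 1] + A[2, 2]
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- sqrt(as.complex(tr^2 - 4 * detA))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (abs(l1 - l2) < 1e-12 * max(abs(l1), 1)) {
    # degenerate: A = l*I + Np with Np nilpotent; A^m = l^m I + m l^(m-1) Np
    Np <- A - l1 * diag(2)
    return((l1^m) * v + m * l1^(m - 1) * (Np %*% v))
  }
  P1 <- (A - l2 * diag(2)) / (l1 - l2)
  P2 <- (A - l1 * diag(2)) / (l2 - l1)
  l1^m * (P1 %*% v) + l2^m * (P2 %*% v)
}
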