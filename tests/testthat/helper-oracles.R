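# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: constants are typed out again, matrix
# exponentials are replaced by stochastic simulation, and least squares by
# explicit normal equations.

# Independent constants table (CODATA / standard effective distances)
ORC <- list(
  gamma_H = 2.6752218744e8,
  gamma_C = 6.728284e7,
  gamma_D = 4.10706e7,
  mu0 = 1.25663706212e-6,
  hbar = 1.054571817e-34
)

# brute-force dipolar coupling from the printed definition
oracle_dipolar <- function(gamma_A, gamma_B, r, theta) {
  p2 <- 0.5 * (3 * cos(theta)^2 - 1)
  ORC$mu0 * ORC$hbar * gamma_A * gamma_B / (4 * pi * r^3) * p2
}

# weighted straight-line fit by explicit normal equations
oracle_wls <- function(y, x, w) {
  S <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x^2)
  Sy <- sum(w * y); Sxy <- sum(w * x * y)
  det <- S * Sxx - Sx^2
  c(intercept = (Sxx * Sy - Sx * Sxy) / det,
    slope = (S * Sxy - Sx * Sy) / det)
}

# Monte-Carlo jump simulation of a single-quantum CPMG experiment:
# explicit stochastic trajectories with phase accumulation and ideal
# refocusing pulses (phase conjugation), no matrix algebra anywhere.
oracle_mc_sq_cpmg <- function(nu, Tt, kex, pB, dw, r20, n = 30000) {
  N <- round(nu * Tt)
  delta <- Tt / N
  tp <- (seq_len(N) - 0.5) * delta
  kAB <- pB * kex; kBA <- (1 - pB) * kex
  events <- sort(c(tp, Tt))
  sig <- 0 + 0i
  for (i in seq_len(n)) {
    s <- if (stats::runif(1) < pB) 2L else 1L
    phase <- 0; sgn <- 1; tcur <- 0
    for (te in events) {
      repeat {
        rate <- if (s == 1L) kAB else kBA
        dt <- stats::rexp(1, rate)
        if (tcur + dt >= te) {
          if (s == 2L) phase <- phase + sgn * dw * (te - tcur)
          tcur <- te
          break
        }
        if (s == 2L) phase <- phase + sgn * dw * dt
        tcur <- tcur + dt
        s <- 3L - s
      }
      if (te < Tt) sgn <- -sgn
    }
    sig <- sig + exp(1i * phase)
  }
  r20 - log(Mod(sig / n)) / Tt
}

# convenience: noiseless fast-exchange rate table with unit errors
fast_rate_table <- function(truth, fields = c(600, 700, 800, 950), err = 1) {
  tab <- true_he_rates(truth, fields, rex_mode = "fast")
  tab$err <- err
  tab
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
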