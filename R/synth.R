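#' Ground truth for synthetic relaxation data
#'
#' Bundles per-methyl physical parameters and per-cluster two-state exchange
#' parameters into a serialisable ground-truth object from which every input
#' of the analysis pipeline can be generated with known answers.
#'
#' @param methyls data.frame with columns `methyl_id`, `cluster_id`,
#'   `dSigmaC_ppm`, `dSigmaH_ppm`, `s2tau_ns`, `dDeltaC_ppm`, `dDeltaH_ppm`,
#'   `R20_ZQ`, `R20_DQ`, `R20_DQp`, `R20_QQ`, and optionally `wH_ppm`,
#'   `wC_ppm`, `R2H`, `R2C`, `amp` (for lineshape generation).
#' @param clusters data.frame with columns `cluster_id`, `p_B`, `k_ex`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(methyls, clusters) {
  req_m <- c("methyl_id", "cluster_id", "dSigmaC_ppm", "dSigmaH_ppm",
             "s2tau_ns", "dDeltaC_ppm", "dDeltaH_ppm",
             "R20_ZQ", "R20_DQ", "R20_DQp", "R20_QQ")
  req_c <- c("cluster_id", "p_B", "k_ex")
  stopifnot(is.data.frame(methyls), all(req_m %in% names(methyls)),
            is.data.frame(clusters), all(req_c %in% names(clusters)),
            all(methyls$cluster_id %in% clusters$cluster_id))
  structure(list(methyls = methyls, clusters = clusters),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d methyl(s) in %d cluster(s)\n",
              nrow(x$methyls), nrow(x$clusters)))
  invisible(x)
}

#' Preset ground truths mirroring typical exchange regimes
#'
#' Two presets span the regimes observed in small protein domains:
#' `"slow-cluster"` (p_B = 0.029, k_ex = 872 s^-1, intermediate exchange at
#' high field) and `"fast-cluster"` (p_B = 0.05, k_ex = 6900 s^-1, fast
#' exchange). Each preset has two methyls with distinct shift differences,
#' CSAs in the typical residue-type ranges and exchange-free rates in the
#' 10-45 s^-1 range observed for methyl multiple-quantum coherences.
#'
#' @param name preset name.
#' @return a [ground_truth()] object.
#' @export
truth_preset <- function(name = c("slow-cluster", "fast-cluster")) {
  name <- match.arg(name)
  methyls <- data.frame(
    methyl_id = c("M1", "M2"),
    cluster_id = "c1",
    dSigmaC_ppm = c(25, 35),
    dSigmaH_ppm = c(0.5, 0.8),
    s2tau_ns = c(8, 10),
    dDeltaC_ppm = c(0.8, 0.5),
    dDeltaH_ppm = c(-0.12, 0.08),
    R20_ZQ = c(14, 18), R20_DQ = c(19, 23),
    R20_DQp = c(24, 28), R20_QQ = c(30, 34),
    wH_ppm = c(0.45, 0.90), wC_ppm = c(13.0, 22.5),
    R2H = c(25, 30), R2C = c(12, 15), amp = c(100, 100)
  )
  clusters <- switch(name,
    "slow-cluster" = data.frame(cluster_id = "c1", p_B = 0.029, k_ex = 872),
    "fast-cluster" = data.frame(cluster_id = "c1", p_B = 0.05, k_ex = 6900))
  ground_truth(methyls, clusters)
}

#' Relaxation delay lists for Hahn-echo experiments
#'
#' Typical per-field delay lists (s) for four-spin Hahn-echo measurements at
#' 600, 700, 800 and 950 MHz.
#'
#' @param field_MHz one of 600, 700, 800, 950 (other values get the 950 MHz
#'   list).
#' @return numeric vector of delays in seconds.
#' @export
he_delays <- function(field_MHz) {
  ms <- switch(as.character(field_MHz),
    "600" = c(0.1, 1, 2, 3.5, 5.5, 8, 11, 15, 20, 26, 33, 41, 50, 60),
    "700" = c(0.1, 1, 2, 4, 7, 11, 16, 22, 29, 37, 46, 56),
    "800" = c(0.1, 1, 2, 3, 5, 8, 12, 16, 22, 29, 37, 46, 56),
    c(0.1, 1, 2, 3, 5, 7, 10, 13, 16, 22, 29, 37, 46, 56))
  ms * 1e-3
}

#' Default CPMG frequency list
#'
#' 28 CPMG frequencies from 25 Hz to 2 kHz, all multiples of 25 Hz so that
#' the pulse count over a 40 ms relaxation period is an integer.
#'
#' @return numeric vector of frequencies in Hz.
#' @export
cpmg_frequencies <- function() {
  c(25, 50, 75, 100, 150, 200, 250, 300, 350, 400, 450, 500, 550, 600,
    650, 700, 750, 800, 900, 1000, 1100, 1200, 1300, 1400, 1500, 1600,
    1800, 2000)
}

truth_model <- function(truth, methyl_row) {
  cl <- truth$clusters[truth$clusters$cluster_id == methyl_row$cluster_id, ]
  two_state(p_B = cl$p_B, k_ex = cl$k_ex,
            dDelta_C = methyl_row$dDeltaC_ppm,
            dDelta_H = methyl_row$dDeltaH_ppm)
}

truth_system <- function(methyl_row) {
  methyl_system(s2tau = methyl_row$s2tau_ns * 1e-9,
                dsigma_C = methyl_row$dSigmaC_ppm,
                dsigma_H = methyl_row$dSigmaH_ppm)
}

#' True Hahn-echo rates implied by a ground truth
#'
#' @param truth a [ground_truth()].
#' @param fields_MHz static fields.
#' @param rex_mode `"eigenvalue"` composes the general closed-form
#'   Liouvillian-eigenvalue exchange broadening (valid in all regimes);
#'   `"fast"` uses the fast-exchange Table-form `(xi_C + n*xi_H)^2 B0^2`
#'   so that the fast-exchange analysis model is exact by construction.
#' @param constants an [nmr_constants()] object.
#' @return data.frame `methyl_id`, `coherence`, `field_MHz`, `rate` with the
#'   noiseless R2,obs (R2,0 + CSA + exchange).
#' @export
true_he_rates <- function(truth, fields_MHz = c(600, 700, 800, 950),
                          rex_mode = c("eigenvalue", "fast"),
                          constants = nmr_constants()) {
  rex_mode <- match.arg(rex_mode)
  cohs <- c("ZQ", "DQ", "DQp", "QQ")
  out <- list(); k <- 0L
  for (i in seq_len(nrow(truth$methyls))) {
    row <- truth$methyls[i, ]
    model <- truth_model(truth, row)
    sys <- truth_system(row)
    xi <- xi_from_exchange(model, constants)
    for (co in cohs) for (f in fields_MHz) {
      r20 <- row[[paste0("R20_", co)]]
      fs <- field_spec(f, constants)
      rate <- if (rex_mode == "eigenvalue")
        he_model(r20, co, fs, sys, model, constants)
      else
        r20 + csa_contribution(co, sys, fs, constants) +
          exchange_contribution_fast(co, xi, fs)
      k <- k + 1L
      out[[k]] <- data.frame(
        methyl_id = row$methyl_id, coherence = co, field_MHz = f,
        rate = rate)
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic Hahn-echo decay curves
#'
#' Amplitudes follow `A * exp(-R2,obs * T)` with R2,obs composed from the
#' ground truth (exchange-free rate + CSA + Liouvillian-eigenvalue exchange
#' broadening), plus i.i.d. additive Gaussian noise of standard deviation
#' `sigma_rel * A`. The paired noiseless amplitudes are kept alongside.
#'
#' @param truth a [ground_truth()].
#' @param fields_MHz static fields (1H MHz).
#' @param sigma_rel amplitude noise relative to the t = 0 amplitude.
#' @param amp reference amplitude.
#' @param seed RNG seed for reproducibility (`NULL` to use the current RNG
#'   state).
#' @param rex_mode exchange composition mode, see [true_he_rates()].
#' @param constants an [nmr_constants()] object.
#' @return list of decay-curve records (`methyl_id`, `coherence`,
#'   `field_MHz`, `times`, `amplitudes`, `noiseless`, `sigma`, `rate_true`),
#'   class `he_curves`.
#' @export
gen_he <- function(truth, fields_MHz = c(600, 700, 800, 950),
                   sigma_rel = 0.01, amp = 100, seed = NULL,
                   rex_mode = c("eigenvalue", "fast"),
                   constants = nmr_constants()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  rates <- true_he_rates(truth, fields_MHz, rex_mode, constants)
  curves <- vector("list", nrow(rates))
  for (k in seq_len(nrow(rates))) {
    tt <- he_delays(rates$field_MHz[k])
    clean <- amp * exp(-rates$rate[k] * tt)
    noisy <- clean + stats::rnorm(length(tt), 0, sigma_rel * amp)
    # keep a positive weighting sigma even for noiseless generation
    curves[[k]] <- list(methyl_id = rates$methyl_id[k],
                        coherence = rates$coherence[k],
                        field_MHz = rates$field_MHz[k],
                        times = tt, amplitudes = noisy, noiseless = clean,
                        sigma = max(sigma_rel, 1e-8) * amp,
                        rate_true = rates$rate[k])
  }
  structure(curves, class = "he_curves")
}

#' Fit synthetic (or measured) decay curves into a rate table
#'
#' Applies [fit_decay()] to each curve and assembles the standard rate table
#' consumed by the field-dependence and joint-fit analyses.
#'
#' @param curves an `he_curves` list from [gen_he()], or any list of records
#'   with `times`, `amplitudes`, `sigma` and metadata.
#' @param noiseless use the paired noiseless amplitudes instead.
#' @return data.frame `methyl_id`, `coherence`, `field_MHz`, `rate`, `err`.
#' @export
he_rate_table <- function(curves, noiseless = FALSE) {
  out <- lapply(curves, function(cv) {
    a <- if (noiseless) cv$noiseless else cv$amplitudes
    f <- fit_decay(cv$times, a, cv$sigma)
    data.frame(methyl_id = cv$methyl_id, coherence = cv$coherence,
               field_MHz = cv$field_MHz, rate = f$rate, err = f$rate_err)
  })
  do.call(rbind, out)
}

#' Generate synthetic CPMG dispersion datasets
#'
#' Effective rates come from numerical propagation ([cpmg_profile()]) plus a
#' per-(methyl, experiment, field) baseline; noise is additive Gaussian on the
#' constant-time signal amplitude `exp(-R_eff * T)` (relative to the
#' reference), so rate errors grow with the decay, as in real constant-time
#' referencing.
#'
#' @param truth a [ground_truth()].
#' @param mq_fields_MHz fields for MQ CPMG (default 800 and 950).
#' @param sq_fields_MHz fields for 1H SQ CPMG (default 800).
#' @param nu_cpmg CPMG frequencies (Hz).
#' @param T_relax constant-time period (s).
#' @param baseline baseline rate used for every profile (s^-1), or a function
#'   `(methyl_row, experiment, field)` returning one.
#' @param sigma_rel amplitude noise relative to the reference signal.
#' @param seed RNG seed (`NULL` to use current state).
#' @param constants an [nmr_constants()] object.
#' @return data.frame `methyl_id`, `experiment`, `field_MHz`, `nu_cpmg_Hz`,
#'   `Reff`, `err`, `T_relax_s`, `Reff_true`.
#' @export
gen_cpmg <- function(truth, mq_fields_MHz = c(800, 950),
                     sq_fields_MHz = 800, nu_cpmg = cpmg_frequencies(),
                     T_relax = 0.04, baseline = 10, sigma_rel = 0.01,
                     seed = NULL, constants = nmr_constants()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  base_fn <- if (is.function(baseline)) baseline else
    function(row, kind, f) baseline
  out <- list(); k <- 0L
  for (i in seq_len(nrow(truth$methyls))) {
    row <- truth$methyls[i, ]
    model <- truth_model(truth, row)
    for (spec in c(lapply(mq_fields_MHz, function(f) list(kind = "MQ", f = f)),
                   lapply(sq_fields_MHz, function(f) list(kind = "SQ_H", f = f)))) {
      ex <- cpmg_experiment(spec$kind, T_relax, nu_cpmg,
                            field_spec(spec$f, constants))
      b <- base_fn(row, spec$kind, spec$f)
      rtrue <- cpmg_profile(model, ex, b, constants = constants)
      sig <- exp(-rtrue * T_relax) +
        stats::rnorm(length(rtrue), 0, sigma_rel)
      sig <- pmax(sig, 1e-6)
      k <- k + 1L
      out[[k]] <- data.frame(
        methyl_id = row$methyl_id, experiment = spec$kind,
        field_MHz = spec$f, nu_cpmg_Hz = nu_cpmg,
        Reff = -log(sig) / T_relax,
        err = max(sigma_rel, 1e-8) * exp(rtrue * T_relax) / T_relax,
        T_relax_s = T_relax, Reff_true = rtrue)
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic pseudo-3D quartet spectra
#'
#' Forward-simulates the relaxation-weighted 1H-coupled HSQC multiplets of all
#' methyls in the ground truth on a shared grid at several relaxation delays,
#' with additive Gaussian intensity noise.
#'
#' @param truth a [ground_truth()] whose `methyls` include `wH_ppm`,
#'   `wC_ppm` (and optionally `R2H`, `R2C`, `amp`).
#' @param delays relaxation delays in seconds.
#' @param field_MHz static field (default 800).
#' @param wH_ppm,wC_ppm grid axes; defaults cover all peaks with margins.
#' @param J_CH scalar coupling used in generation (Hz).
#' @param sigma absolute intensity noise standard deviation.
#' @param seed RNG seed.
#' @param constants an [nmr_constants()] object.
#' @return list with `spectra` (list of matrices), `wH_ppm`, `wC_ppm`,
#'   `delays`, `field`, `peaks` (data.frame) and `truth_pars`.
#' @export
gen_pseudo3d <- function(truth, delays = c(0.0011, 0.05, 0.1, 0.15),
                         field_MHz = 800, wH_ppm = NULL, wC_ppm = NULL,
                         J_CH = 125, sigma = 0, seed = NULL,
                         constants = nmr_constants()) {
  stopifnot(inherits(truth, "ground_truth"),
            all(c("wH_ppm", "wC_ppm") %in% names(truth$methyls)))
  if (!is.null(seed)) set.seed(seed)
  m <- truth$methyls
  if (is.null(m$R2H)) m$R2H <- 25
  if (is.null(m$R2C)) m$R2C <- 12
  if (is.null(m$amp)) m$amp <- 100
  fld <- field_spec(field_MHz, constants)
  larmor_C <- fld$larmor_MHz * constants$gamma_C / constants$gamma_H
  # default grid: cover quartets (half-width 3*pi*J in rad/s -> ppm) + margin
  jc_ppm <- 3 * pi * J_CH / (2 * pi * larmor_C)
  if (is.null(wH_ppm))
    wH_ppm <- seq(min(m$wH_ppm) - 0.15, max(m$wH_ppm) + 0.15, by = 0.004)
  if (is.null(wC_ppm))
    wC_ppm <- seq(min(m$wC_ppm) - jc_ppm - 1.5, max(m$wC_ppm) + jc_ppm + 1.5,
                  by = 0.02)
  spectra <- lapply(delays, function(d) {
    y <- matrix(0, length(wH_ppm), length(wC_ppm))
    for (i in seq_len(nrow(m))) {
      qm <- quartet_model(m$amp[i], m$wH_ppm[i], m$wC_ppm[i], m$R2H[i],
                          m$R2C[i], J_CH, m$s2tau_ns[i] * 1e-9,
                          m$dSigmaC_ppm[i], fld)
      y <- y + quartet_lineshape(qm, d, wH_ppm, wC_ppm, constants,
                                 warn = FALSE)
    }
    if (sigma > 0) y <- y + matrix(stats::rnorm(length(y), 0, sigma),
                                   nrow(y), ncol(y))
    y
  })
  list(spectra = spectra, wH_ppm = wH_ppm, wC_ppm = wC_ppm, delays = delays,
       field = fld,
       peaks = data.frame(methyl_id = m$methyl_id, wH_ppm = m$wH_ppm,
                          wC_ppm = m$wC_ppm),
       truth_pars = m)
}

#' Tables needed to joint-fit a ground truth
#'
#' Convenience extractors matching the [global_fit()] input contracts.
#'
#' @param truth a [ground_truth()].
#' @return `truth_csa_table`: data.frame `methyl_id`, `dSigmaC_ppm`,
#'   `dSigmaH_ppm`, `s2tau_ns`; `truth_cluster_table`: data.frame
#'   `methyl_id`, `cluster_id`.
#' @export
truth_csa_table <- function(truth) {
  truth$methyls[, c("methyl_id", "dSigmaC_ppm", "dSigmaH_ppm", "s2tau_ns")]
}

#' @rdname truth_csa_table
#' @export
truth_cluster_table <- function(truth) {
  truth$methyls[, c("methyl_id", "cluster_id")]
}

#' True normalised shift differences of a ground truth
#'
#' @param truth a [ground_truth()].
#' @param constants an [nmr_constants()] object.
#' @return data.frame `methyl_id`, `xi_C`, `xi_H`.
#' @export
truth_xi <- function(truth, constants = nmr_constants()) {
  out <- lapply(seq_len(nrow(truth$methyls)), function(i) {
    row <- truth$methyls[i, ]
    xi <- xi_from_exchange(truth_model(truth, row), constants)
    data.frame(methyl_id = row$methyl_id, xi_C = xi$xi_C, xi_H = xi$xi_H)
  })
  do.call(rbind, out)
}
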