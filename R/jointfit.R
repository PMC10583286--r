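#' Predicted Hahn-echo rate under two-state exchange
#'
#' Composes the field-dependent Hahn-echo model
#' `R2,obs = R2,0 + R_CSA(B0) + Rex(B0)`, with the CSA contribution from
#' [csa_contribution()] and the exchange contribution from the closed-form
#' Liouvillian eigenvalue [rex_closed_form()] evaluated at the coherence's
#' frequency difference. Valid in all exchange regimes (not just fast
#' exchange), so predictions are naturally plotted against B0 rather than
#' B0^2.
#'
#' @param r20 field-independent exchange-free rate (s^-1).
#' @param coherence one of `"ZQ"`, `"DQ"`, `"DQp"`, `"QQ"`.
#' @param field a [field_spec()].
#' @param system a [methyl_system()] (CSA parameters, fixed inputs).
#' @param model a [two_state()] exchange model.
#' @param constants an [nmr_constants()] object.
#' @return predicted rate in s^-1.
#' @export
he_model <- function(r20, coherence, field, system, model,
                     constants = nmr_constants()) {
  dw <- coherence_delta_omega(coherence, model$dDelta_C, model$dDelta_H,
                              field, constants)
  r20 + csa_contribution(coherence, system, field, constants) +
    rex_closed_form(dw, model)
}

# build methyl_system objects from a CSA table row
system_from_csa_row <- function(row) {
  methyl_system(s2tau = row$s2tau_ns * 1e-9,
                dsigma_C = row$dSigmaC_ppm,
                dsigma_H = row$dSigmaH_ppm)
}

#' Global joint fit of Hahn-echo and CPMG data
#'
#' Simultaneous weighted Levenberg-Marquardt fit of field-dependent Hahn-echo
#' relaxation rates and CPMG relaxation dispersion profiles for one or more
#' residue clusters. Methyls in a cluster share the exchange parameters
#' (`p_B`, `k_ex`); each methyl has free chemical shift differences
#' (`dDelta_C`, `dDelta_H`), one field-independent `R2,0` per Hahn-echo
#' coherence, and one baseline per (CPMG experiment, field). CSA parameters
#' and `s2tau` are fixed inputs taken from `csa_table`. Hahn-echo rates are
#' modelled by [he_model()] and CPMG profiles by numerical propagation
#' ([cpmg_profile()]). The sign ambiguity (negating both shift differences
#' leaves the fit invariant) is resolved by constraining `dDelta_C >= 0`.
#'
#' To avoid local minima the optimiser is restarted from a grid of starting
#' values log-spaced in `k_ex` over `[1e2, 1e5]` s^-1 and spanning
#' `p_B in [0.005, 0.2]`; the best-chi-square solution is returned with all
#' starts logged. Parameter standard errors come from the curvature of the
#' chi-square surface (inverse Gauss-Newton Hessian at the optimum).
#'
#' @param he_data data.frame: `methyl_id`, `coherence`, `field_MHz`, `rate`,
#'   `err`.
#' @param cpmg_data optional data.frame: `methyl_id`, `experiment` ("MQ" or
#'   "SQ_H"), `field_MHz`, `nu_cpmg_Hz`, `Reff`, `err` and optionally
#'   `T_relax_s` (default 0.04 s).
#' @param clusters data.frame: `methyl_id`, `cluster_id`. Every methyl in the
#'   data must appear exactly once.
#' @param csa_table data.frame: `methyl_id`, `dSigmaC_ppm`, `dSigmaH_ppm`,
#'   `s2tau_ns`.
#' @param n_starts number of (k_ex, p_B) starting points (default 8).
#' @param start optional named list of starting values: `k_ex`, `p_B`
#'   (scalars), `dDelta_C`, `dDelta_H` (scalar or one value per methyl, in
#'   the order the methyls appear in the data). Supplying `k_ex`/`p_B`
#'   disables the multi-start grid.
#' @param sign_refine after the best start converges, greedily re-fit with
#'   each methyl's `dDelta_H` sign flipped to escape the discrete relative
#'   sign branch (default TRUE; disable for calibration replicates started on
#'   the known branch).
#' @param constants an [nmr_constants()] object.
#' @return An object of class `mq_fit`.
#' @export
global_fit <- function(he_data, cpmg_data = NULL, clusters, csa_table,
                       n_starts = 8, start = NULL, sign_refine = TRUE,
                       constants = nmr_constants()) {
  stopifnot(is.data.frame(he_data),
            all(c("methyl_id", "coherence", "field_MHz", "rate", "err")
                %in% names(he_data)),
            is.data.frame(clusters),
            all(c("methyl_id", "cluster_id") %in% names(clusters)),
            is.data.frame(csa_table))
  methyls <- unique(c(he_data$methyl_id,
                      if (!is.null(cpmg_data)) cpmg_data$methyl_id))
  if (!all(methyls %in% clusters$methyl_id))
    stop("every methyl must be assigned to a cluster")
  if (!all(methyls %in% csa_table$methyl_id))
    stop("every methyl needs a CSA table entry")
  cl_of <- stats::setNames(clusters$cluster_id, clusters$methyl_id)
  cl_ids <- unique(cl_of[methyls])
  systems <- lapply(methyls, function(m)
    system_from_csa_row(csa_table[csa_table$methyl_id == m, , drop = FALSE][1, ]))
  names(systems) <- methyls

  # ---- parameter bookkeeping ---------------------------------------------
  # per cluster: log10(kex), pB; per methyl: dDC (>=0), dDH;
  # per (methyl, coherence): r20_HE; per (methyl, experiment, field): baseline
  par_info <- data.frame(name = character(0), type = character(0),
                         id = character(0), stringsAsFactors = FALSE)
  add_par <- function(name, type, id)
    rbind(par_info, data.frame(name = name, type = type, id = id))
  for (cl in cl_ids) {
    par_info <- add_par(paste0("lkex.", cl), "lkex", as.character(cl))
    par_info <- add_par(paste0("pB.", cl), "pB", as.character(cl))
  }
  for (m in methyls) {
    par_info <- add_par(paste0("dDC.", m), "dDC", m)
    par_info <- add_par(paste0("dDH.", m), "dDH", m)
  }
  he_groups <- unique(he_data[, c("methyl_id", "coherence")])
  for (k in seq_len(nrow(he_groups)))
    par_info <- add_par(
      paste0("r20.", he_groups$methyl_id[k], ".", he_groups$coherence[k]),
      "r20", paste(he_groups$methyl_id[k], he_groups$coherence[k]))
  cp_groups <- NULL
  if (!is.null(cpmg_data) && nrow(cpmg_data)) {
    if (!"T_relax_s" %in% names(cpmg_data)) cpmg_data$T_relax_s <- 0.04
    cp_groups <- unique(cpmg_data[, c("methyl_id", "experiment", "field_MHz",
                                      "T_relax_s")])
    for (k in seq_len(nrow(cp_groups)))
      par_info <- add_par(
        paste0("base.", cp_groups$methyl_id[k], ".",
               cp_groups$experiment[k], ".", cp_groups$field_MHz[k]),
        "base", paste(cp_groups$methyl_id[k], cp_groups$experiment[k],
                      cp_groups$field_MHz[k]))
  }
  npar <- nrow(par_info)
  idx <- stats::setNames(seq_len(npar), par_info$name)
  ndata <- nrow(he_data) + if (is.null(cpmg_data)) 0L else nrow(cpmg_data)
  if (npar >= ndata)
    stop("parameter count (", npar, ") must be below data count (", ndata, ")")

  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  lower[par_info$type == "lkex"] <- 0;     upper[par_info$type == "lkex"] <- 7
  lower[par_info$type == "pB"] <- 1e-5;    upper[par_info$type == "pB"] <- 0.499
  lower[par_info$type == "dDC"] <- 0;      upper[par_info$type == "dDC"] <- 20
  lower[par_info$type == "dDH"] <- -5;     upper[par_info$type == "dDH"] <- 5
  lower[par_info$type == "r20"] <- 0
  lower[par_info$type == "base"] <- 0

  fields <- unique(he_data$field_MHz)
  fspecs <- lapply(fields, field_spec, constants = constants)
  names(fspecs) <- as.character(fields)
  getfield <- function(f) {
    key <- as.character(f)
    if (is.null(fspecs[[key]])) fspecs[[key]] <<- field_spec(f, constants)
    fspecs[[key]]
  }

  # precompute experiment objects per cpmg group
  cp_exps <- NULL
  if (!is.null(cp_groups)) {
    cp_exps <- lapply(seq_len(nrow(cp_groups)), function(k) {
      g <- cp_groups[k, ]
      rows <- cpmg_data$methyl_id == g$methyl_id &
        cpmg_data$experiment == g$experiment &
        cpmg_data$field_MHz == g$field_MHz
      list(rows = which(rows),
           exp = cpmg_experiment(g$experiment, g$T_relax_s,
                                 cpmg_data$nu_cpmg_Hz[rows],
                                 getfield(g$field_MHz)))
    })
  }

  # ---- precomputed static tables for fast residuals -----------------------
  nhe <- nrow(he_data)
  he_B0 <- vapply(he_data$field_MHz, function(f) getfield(f)$B0, numeric(1))
  he_csa <- vapply(seq_len(nhe), function(k)
    csa_beta(he_data$coherence[k], systems[[he_data$methyl_id[k]]],
             constants), numeric(1)) * he_B0^2
  he_cC <- vapply(he_data$coherence, coherence_nC, numeric(1)) *
    constants$gamma_C * he_B0 * 1e-6
  he_cH <- vapply(he_data$coherence, coherence_nH, numeric(1)) *
    constants$gamma_H * he_B0 * 1e-6
  he_r20_idx <- vapply(seq_len(nhe), function(k)
    idx[[paste0("r20.", he_data$methyl_id[k], ".", he_data$coherence[k])]],
    integer(1))
  m_of_he <- match(he_data$methyl_id, methyls)
  dDC_idx <- vapply(methyls, function(m) idx[[paste0("dDC.", m)]], integer(1))
  dDH_idx <- vapply(methyls, function(m) idx[[paste0("dDH.", m)]], integer(1))
  lkex_idx_m <- vapply(methyls, function(m)
    idx[[paste0("lkex.", cl_of[[m]])]], integer(1))
  pB_idx_m <- vapply(methyls, function(m)
    idx[[paste0("pB.", cl_of[[m]])]], integer(1))
  cp_base_idx <- if (is.null(cp_groups)) integer(0) else
    vapply(seq_len(nrow(cp_groups)), function(k)
      idx[[paste0("base.", cp_groups$methyl_id[k], ".",
                  cp_groups$experiment[k], ".", cp_groups$field_MHz[k])]],
      integer(1))
  cp_m_idx <- if (is.null(cp_groups)) integer(0) else
    match(cp_groups$methyl_id, methyls)

  resid_fn <- function(p) {
    dDC_m <- p[dDC_idx]; dDH_m <- p[dDH_idx]
    kex_m <- 10^p[lkex_idx_m]; pB_m <- p[pB_idx_m]
    # HE block, fully vectorised closed-form Rex
    dw <- he_cC * dDC_m[m_of_he] + he_cH * dDH_m[m_of_he]
    kex <- kex_m[m_of_he]; pB <- pB_m[m_of_he]
    z <- kex + 1i * dw
    rex <- Re((z - sqrt(z^2 - 4i * kex * pB * dw)) / 2)
    pred_he <- p[he_r20_idx] + he_csa + rex
    r <- (he_data$rate - pred_he) / he_data$err
    if (!is.null(cp_exps)) {
      pred_cp <- numeric(nrow(cpmg_data))
      for (k in seq_along(cp_exps)) {
        mi <- cp_m_idx[k]
        model <- two_state(p_B = pB_m[mi], k_ex = kex_m[mi],
                           dDelta_C = dDC_m[mi], dDelta_H = dDH_m[mi])
        pred_cp[cp_exps[[k]]$rows] <-
          cpmg_profile(model, cp_exps[[k]]$exp, p[cp_base_idx[k]],
                       constants = constants)
      }
      r <- c(r, (cpmg_data$Reff - pred_cp) / cpmg_data$err)
    }
    r
  }

  # ---- starting values ----------------------------------------------------
  p0 <- numeric(npar)
  for (k in seq_len(nrow(he_groups))) {
    m <- he_groups$methyl_id[k]; co <- he_groups$coherence[k]
    d <- he_data[he_data$methyl_id == m & he_data$coherence == co, ]
    p0[idx[[paste0("r20.", m, ".", co)]]] <- max(min(d$rate) * 0.8, 0.1)
  }
  if (!is.null(cp_groups)) for (k in seq_len(nrow(cp_groups))) {
    g <- cp_groups[k, ]
    d <- cpmg_data[cp_exps[[k]]$rows, ]
    p0[idx[[paste0("base.", g$methyl_id, ".", g$experiment, ".",
                   g$field_MHz)]]] <-
      max(d$Reff[which.max(d$nu_cpmg_Hz)] * 0.9, 0.1)
  }
  dDC0 <- if (!is.null(start$dDelta_C)) start$dDelta_C else 0.5
  dDH0 <- if (!is.null(start$dDelta_H)) start$dDelta_H else 0.1
  p0[par_info$type == "dDC"] <- rep_len(dDC0, sum(par_info$type == "dDC"))
  p0[par_info$type == "dDH"] <- rep_len(dDH0, sum(par_info$type == "dDH"))

  if (!is.null(start$k_ex) || !is.null(start$p_B)) {
    kex_grid <- if (!is.null(start$k_ex)) start$k_ex else 1e3
    pB_grid <- if (!is.null(start$p_B)) start$p_B else 0.05
    starts <- data.frame(lkex = log10(kex_grid), pB = pB_grid)
  } else {
    nk <- max(2L, ceiling(n_starts / 2))
    kex_grid <- 10^seq(2, 5, length.out = nk)
    pB_grid <- c(0.02, 0.1)
    starts <- expand.grid(lkex = log10(kex_grid), pB = pB_grid)
    starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  }

  best <- NULL
  starts_log <- list()
  for (s in seq_len(nrow(starts))) {
    p <- p0
    p[par_info$type == "lkex"] <- starts$lkex[s]
    p[par_info$type == "pB"] <- starts$pB[s]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    starts_log[[s]] <- c(lkex0 = starts$lkex[s], pB0 = starts$pB[s],
                         chi2 = fit$deviance)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimiser starts failed")

  # the relative sign of dDelta_H vs dDelta_C is a discrete branch the LM
  # steps cannot cross; greedily try flipping each methyl's dDelta_H
  refit <- function(p) tryCatch(
    minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (sign_refine) repeat {
    improved <- FALSE
    for (m in methyls) {
      i <- idx[[paste0("dDH.", m)]]
      p <- best$par
      if (abs(p[i]) < 1e-6) p[i] <- -0.1 else p[i] <- -p[i]
      alt <- refit(p)
      if (!is.null(alt) && alt$deviance < best$deviance - 1e-9) {
        best <- alt
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  covm <- tryCatch(solve(best$hessian), error = function(e) NULL)
  cond <- tryCatch({
    sv <- svd(best$hessian)$d
    max(sv) / max(min(sv), .Machine$double.eps)
  }, error = function(e) NA_real_)
  se <- if (is.null(covm)) rep(NA_real_, npar) else {
    dg <- diag(covm)
    ifelse(dg >= 0, sqrt(dg), NA_real_)
  }
  corr_flags <- character(0)
  if (!is.null(covm)) {
    cc <- stats::cov2cor(covm)
    hi <- which(abs(cc) > 0.95 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hi))
      corr_flags <- apply(hi, 1, function(ij)
        paste0(par_info$name[ij[1]], " ~ ", par_info$name[ij[2]]))
  }
  pars <- stats::setNames(best$par, par_info$name)
  ses <- stats::setNames(se, par_info$name)

  structure(list(
    par = pars, se = ses, cov = covm, par_info = par_info,
    chi2 = best$deviance, dof = ndata - npar,
    residuals = best$fvec, converged = best$info %in% 1:4,
    condition_number = cond, corr_flags = corr_flags,
    starts_log = starts_log,
    methyls = methyls, clusters = cl_of[methyls], systems = systems,
    he_data = he_data, cpmg_data = cpmg_data,
    constants = constants
  ), class = "mq_fit")
}

#' Extract exchange parameters from an mq_fit
#'
#' @param fit an `mq_fit` object.
#' @param cluster_id cluster identifier (defaults to the first).
#' @return list with `k_ex`, `k_ex_err`, `p_B`, `p_B_err`.
#' @export
exchange_parameters <- function(fit, cluster_id = NULL) {
  stopifnot(inherits(fit, "mq_fit"))
  if (is.null(cluster_id)) cluster_id <- fit$clusters[[1]]
  lk <- fit$par[[paste0("lkex.", cluster_id)]]
  lk_se <- fit$se[[paste0("lkex.", cluster_id)]]
  kex <- 10^lk
  list(k_ex = kex, k_ex_err = kex * log(10) * lk_se,
       p_B = fit$par[[paste0("pB.", cluster_id)]],
       p_B_err = fit$se[[paste0("pB.", cluster_id)]])
}

#' Back-calculate normalised shift differences from a joint fit
#'
#' Converts fitted (p_B, k_ex, dDelta_C, dDelta_H) into the normalised shift
#' differences `xi_X = sqrt(pA*pB/kex) * gamma_X * dDelta_X * 1e-6` for each
#' methyl, for comparison with the Hahn-echo-only (xi_H, xi_C) analysis.
#'
#' @param fit an `mq_fit` object.
#' @return data.frame with columns `methyl_id`, `xi_C`, `xi_H`.
#' @export
back_calculate_xi <- function(fit) {
  stopifnot(inherits(fit, "mq_fit"))
  out <- lapply(fit$methyls, function(m) {
    cl <- as.character(fit$clusters[[m]])
    model <- two_state(p_B = fit$par[[paste0("pB.", cl)]],
                       k_ex = 10^fit$par[[paste0("lkex.", cl)]],
                       dDelta_C = fit$par[[paste0("dDC.", m)]],
                       dDelta_H = fit$par[[paste0("dDH.", m)]])
    xi <- xi_from_exchange(model, fit$constants)
    data.frame(methyl_id = m, xi_C = xi$xi_C, xi_H = xi$xi_H)
  })
  do.call(rbind, out)
}

#' Combined methyl chemical shift difference
#'
#' Reporting convenience: `dDelta_CH = sqrt((dDelta_C/4)^2 + dDelta_H^2)`,
#' the combined 1H/13C shift magnitude commonly used to project exchange
#' amplitudes onto structures.
#'
#' @param dDelta_C,dDelta_H shift differences in ppm.
#' @return combined shift in ppm.
#' @export
combined_shift <- function(dDelta_C, dDelta_H) {
  sqrt((dDelta_C / 4)^2 + dDelta_H^2)
}

#' @export
print.mq_fit <- function(x, ...) {
  cat(sprintf("<mq_fit> chi2 = %.4g on %d dof%s\n", x$chi2, x$dof,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  for (cl in unique(x$clusters)) {
    ex <- exchange_parameters(x, cl)
    cat(sprintf("  cluster %s: kex = %.4g +/- %.3g s^-1, pB = %.4g +/- %.3g\n",
                cl, ex$k_ex, ex$k_ex_err, ex$p_B, ex$p_B_err))
  }
  if (length(x$corr_flags))
    cat("  strongly correlated (>0.95):",
        paste(utils::head(x$corr_flags, 5), collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.mq_fit <- function(object, ...) object$par

#' @export
vcov.mq_fit <- function(object, ...) object$cov

#' @export
residuals.mq_fit <- function(object, ...) object$residuals

#' @export
summary.mq_fit <- function(object, ...) {
  df <- data.frame(estimate = object$par, se = object$se)
  # report kex on the natural scale as well
  lk <- object$par_info$type == "lkex"
  df$estimate[lk] <- 10^df$estimate[lk]
  df$se[lk] <- df$estimate[lk] * log(10) * object$se[lk]
  rownames(df) <- sub("^lkex", "kex", object$par_info$name)
  out <- list(table = df, chi2 = object$chi2, dof = object$dof,
              chi2_red = object$chi2 / max(object$dof, 1),
              condition_number = object$condition_number,
              corr_flags = object$corr_flags)
  class(out) <- "summary.mq_fit"
  out
}

#' @export
print.summary.mq_fit <- function(x, ...) {
  cat(sprintf("Global HE+CPMG fit: chi2 = %.4g on %d dof (reduced %.3g)\n",
              x$chi2, x$dof, x$chi2_red))
  cat(sprintf("Hessian condition number: %.3g\n", x$condition_number))
  print(round(x$table, 6))
  if (length(x$corr_flags))
    cat("strongly correlated pairs:", paste(x$corr_flags, collapse = "; "),
        "\n")
  invisible(x)
}
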