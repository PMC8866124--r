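#' Lipari-Szabo motion parameters
#'
#' @param s2 Generalized order parameter in `[0, 1]`.
#' @param tau_c_ns Overall (isotropic) rotational correlation time, ns (> 0).
#' @param tau_e_ps Effective internal correlation time, ps (>= 0).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(s2, tau_c_ns, tau_e_ps = 0) {
  stopifnot(is.numeric(s2), s2 >= 0, s2 <= 1,
            tau_c_ns > 0, tau_e_ps >= 0)
  structure(list(s2 = s2, tau_c_ns = tau_c_ns, tau_e_ps = tau_e_ps),
            class = "motion_params")
}

#' Lipari-Szabo spectral density
#'
#' `J(w) = (2/5) [ S2 tc / (1 + (w tc)^2) + (1 - S2) t' / (1 + (w t')^2) ]`
#' with `1/t' = 1/tc + 1/te`.
#'
#' @param m A [motion_params()].
#' @param omega Angular frequency, rad/s (vectorized).
#' @return J(omega) in s/rad; positive and non-increasing in `|omega|`.
#' @export
spectral_density <- function(m, omega) {
  stopifnot(inherits(m, "motion_params"))
  tc <- m$tau_c_ns * 1e-9
  te <- m$tau_e_ps * 1e-12
  j <- m$s2 * tc / (1 + (omega * tc)^2)
  if (te > 0 && m$s2 < 1) {
    tp <- 1 / (1 / tc + 1 / te)
    j <- j + (1 - m$s2) * tp / (1 + (omega * tp)^2)
  }
  0.4 * j
}

# Dipolar and CSA interaction constants for the backbone amide 15N-1H pair.
# N-H bond length 1.02 Angstrom, 15N CSA -172 ppm (field-independent):
# community defaults, documented as such.
.MF_CONST <- list(r_nh = 1.02e-10, csa = -172e-6,
                  mu0 = 4e-7 * pi, hbar = 1.054571817e-34)

#' Predict backbone 15N relaxation rates from motion parameters
#'
#' Standard dipolar + CSA expressions for R1, R2 and the heteronuclear
#' 1H-15N NOE in terms of the Lipari-Szabo spectral density evaluated at
#' {0, wN, wH - wN, wH, wH + wN}.
#'
#' @param m A [motion_params()].
#' @param field_mhz Static field as 1H Larmor frequency, MHz.
#' @param d_scale Multiplier on the dipolar coupling constant (default 1;
#'   exposed for scaling checks).
#' @return Named numeric vector: `r1`, `r2` (1/s), `noe` (dimensionless).
#' @export
predict_rates <- function(m, field_mhz, d_scale = 1) {
  k <- .MF_CONST
  g_h <- .GAMMA[["1H"]]; g_n <- .GAMMA[["15N"]]
  w_h <- 2 * pi * field_mhz * 1e6
  w_n <- w_h * abs(g_n / g_h)
  d <- d_scale * k$mu0 * k$hbar * g_h * abs(g_n) / (4 * pi * k$r_nh^3)
  c2 <- (w_n * k$csa)^2 / 3
  j <- function(w) spectral_density(m, w)
  r1 <- (d^2 / 4) * (j(w_h - w_n) + 3 * j(w_n) + 6 * j(w_h + w_n)) +
    c2 * j(w_n)
  r2 <- (d^2 / 8) * (4 * j(0) + j(w_h - w_n) + 3 * j(w_n) + 6 * j(w_h) +
                       6 * j(w_h + w_n)) +
    (c2 / 6) * (4 * j(0) + 3 * j(w_n))
  noe <- 1 + (d^2 / 4) * (g_h / g_n) *
    (6 * j(w_h + w_n) - j(w_h - w_n)) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

# Per-residue chi-square against one or more fields.
.mf_chi2 <- function(s2, tau_e_ps, tau_c_ns, sub) {
  m <- motion_params(s2, tau_c_ns, tau_e_ps)
  tot <- 0
  for (i in seq_len(nrow(sub))) {
    pred <- predict_rates(m, sub$field_mhz[i])
    tot <- tot + ((sub$r1[i] - pred[["r1"]]) / sub$r1_err[i])^2 +
      ((sub$r2[i] - pred[["r2"]]) / sub$r2_err[i])^2 +
      ((sub$noe[i] - pred[["noe"]]) / sub$noe_err[i])^2
  }
  tot
}

# Fit one residue at fixed tau_c: model {S2} and {S2, tau_e}, AIC selection.
.mf_fit_residue <- function(sub, tau_c_ns, refine = TRUE) {
  s2_grid <- seq(0.02, 1, by = 0.02)
  chi_1 <- vapply(s2_grid, .mf_chi2, numeric(1), tau_e_ps = 0,
                  tau_c_ns = tau_c_ns, sub = sub)
  j1 <- which.min(chi_1)
  fit1 <- list(s2 = s2_grid[j1], tau_e = 0, chi2 = chi_1[j1], k = 1L)
  if (refine) {
    o <- stats::optimize(function(s) .mf_chi2(s, 0, tau_c_ns, sub),
                         c(max(0, fit1$s2 - 0.05), min(1, fit1$s2 + 0.05)))
    fit1$s2 <- o$minimum; fit1$chi2 <- o$objective
  }
  te_grid <- c(5, 20, 50, 100, 300, 1000)
  best2 <- fit1
  best2$chi2 <- Inf
  for (te in te_grid) {
    chi <- vapply(s2_grid, .mf_chi2, numeric(1), tau_e_ps = te,
                  tau_c_ns = tau_c_ns, sub = sub)
    j <- which.min(chi)
    if (chi[j] < best2$chi2) {
      best2 <- list(s2 = s2_grid[j], tau_e = te, chi2 = chi[j], k = 2L)
    }
  }
  if (refine) {
    o <- try(stats::optim(c(best2$s2, log(best2$tau_e)), function(p) {
      if (p[1L] < 0 || p[1L] > 1) return(1e12)
      .mf_chi2(p[1L], exp(p[2L]), tau_c_ns, sub)
    }, method = "Nelder-Mead",
    control = list(maxit = 200, reltol = 1e-10)), silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best2$chi2) {
      best2 <- list(s2 = o$par[1L], tau_e = exp(o$par[2L]), chi2 = o$value,
                    k = 2L)
    }
  }
  # AIC model selection between {S2} and {S2, tau_e}
  if (best2$chi2 + 2 * 2 < fit1$chi2 + 2 * 1) best2 else fit1
}

#' Model-free fit of a backbone 15N relaxation dataset
#'
#' Grid-scan plus local refinement of per-residue Lipari-Szabo parameters
#' (model set {S2} and {S2, tau_e}; AIC selection) with the overall
#' correlation time shared across residues. When `tau_c_ns` is `NULL` it is
#' optimized globally: a coarse scan over 1-20 ns followed by golden-section
#' refinement of the total chi-square (grid-only residue fits during the
#' scan; full refinement at the optimum).
#'
#' @param data Data frame from [make_relaxation_set()] or with the same
#'   columns (`residue`, `field_mhz`, `r1`, `r1_err`, `r2`, `r2_err`,
#'   `noe`, `noe_err`).
#' @param tau_c_ns Fixed overall correlation time, ns, or `NULL` to fit it.
#' @return Data frame per residue: `residue`, `s2`, `tau_e_ps`, `chi2`,
#'   `model`; attribute `"tau_c_ns"` carries the shared correlation time.
#' @export
fit_modelfree <- function(data, tau_c_ns = NULL) {
  need <- c("residue", "field_mhz", "r1", "r1_err", "r2", "r2_err",
            "noe", "noe_err")
  stopifnot(all(need %in% names(data)))
  subs <- split(as.data.frame(data), data$residue)
  total_chi2 <- function(tc, refine = FALSE) {
    sum(vapply(subs, function(sub) {
      .mf_fit_residue(sub, tc, refine = refine)$chi2
    }, numeric(1)))
  }
  if (is.null(tau_c_ns)) {
    grid <- seq(1, 20, by = 1)
    vals <- vapply(grid, total_chi2, numeric(1))
    j <- which.min(vals)
    lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
    tau_c_ns <- stats::optimize(total_chi2, c(lo, hi), tol = 1e-3)$minimum
  }
  fits <- lapply(subs, .mf_fit_residue, tau_c_ns = tau_c_ns, refine = TRUE)
  out <- data.frame(
    residue = names(subs),
    s2 = vapply(fits, `[[`, numeric(1), "s2"),
    tau_e_ps = vapply(fits, `[[`, numeric(1), "tau_e"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    model = ifelse(vapply(fits, `[[`, integer(1), "k") == 1L,
                   "S2", "S2+tau_e"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "tau_c_ns") <- tau_c_ns
  out
}
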