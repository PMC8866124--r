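#' Two-site chemical exchange parameter set
#'
#' Global kinetic parameters of a two-site (major A / minor B) exchange
#' process, plus optional per-spin chemical-shift differences. Detailed
#' balance fixes the microscopic rates: `k_AB = p_minor * k_ex` and
#' `k_BA = p_major * k_ex`, with `k_ex = k_AB + k_BA`.
#'
#' @param k_ex Total exchange rate constant, 1/s (> 0).
#' @param p_minor Minor-state fractional population in `[0, 0.5]`; the value
#'   0.5 corresponds to symmetric exchange such as an aromatic ring flip.
#' @param ddelta Optional data frame with columns `spin`, `nucleus`,
#'   `ddelta_ppm` giving per-spin shift differences (magnitudes by default;
#'   signed values are accepted when known externally).
#' @return An object of class `exchange_params`.
#' @export
exchange_params <- function(k_ex, p_minor, ddelta = NULL) {
  stopifnot(is.numeric(k_ex), length(k_ex) == 1L, is.finite(k_ex),
            is.numeric(p_minor), length(p_minor) == 1L, is.finite(p_minor))
  if (k_ex <= 0) stop("invalid_k_ex: k_ex must be > 0", call. = FALSE)
  if (p_minor < 0 || p_minor > 0.5) {
    stop("invalid_p_minor: p_minor must lie in [0, 0.5]", call. = FALSE)
  }
  if (!is.null(ddelta)) {
    stopifnot(is.data.frame(ddelta),
              all(c("spin", "nucleus", "ddelta_ppm") %in% names(ddelta)))
  }
  structure(
    list(k_ex = k_ex, p_minor = p_minor, p_major = 1 - p_minor,
         k_ab = p_minor * k_ex, k_ba = (1 - p_minor) * k_ex,
         ddelta = ddelta),
    class = "exchange_params"
  )
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("Two-site exchange: k_ex = %.4g /s, p_minor = %.4g (%.2f%%)\n",
              x$k_ex, x$p_minor, 100 * x$p_minor))
  if (!is.null(x$ddelta)) {
    cat(sprintf("  %d per-spin shift differences attached\n", nrow(x$ddelta)))
  }
  invisible(x)
}

#' Spin probe description
#'
#' One observed spin: identity, nucleus, and its exchange-free relaxation
#' rates at the static field of the schedule it is simulated under.
#'
#' @param spin Spin identifier, e.g. `"526-CE"` or a residue number.
#' @param nucleus `"15N"`, `"1HN"` or `"13C"`; determines the gyromagnetic
#'   ratio used to convert ppm to rad/s.
#' @param r2_0 Base (exchange-free) transverse relaxation rate, 1/s.
#' @param r1 Longitudinal relaxation rate, 1/s (used by R1rho only).
#' @return An object of class `spin_probe`.
#' @export
spin_probe <- function(spin, nucleus, r2_0, r1 = 1.5) {
  stopifnot(is.numeric(r2_0), r2_0 >= 0, is.numeric(r1), r1 >= 0)
  gamma_ratio(nucleus)  # validates the nucleus
  structure(list(spin = as.character(spin), nucleus = as.character(nucleus),
                 r2_0 = r2_0, r1 = r1),
            class = "spin_probe")
}

#' Constant-time CPMG schedule
#'
#' @param relax_time Constant relaxation delay T, s.
#' @param nu_cpmg CPMG frequencies, Hz. Each must yield an even integer
#'   refocusing-pulse count `N = 2 * T * nu` within `tol`.
#' @param field_mhz Static field expressed as the 1H Larmor frequency, MHz.
#' @param tol Rounding tolerance on N (default 1e-6).
#' @return An object of class `cpmg_schedule`.
#' @export
cpmg_schedule <- function(relax_time, nu_cpmg, field_mhz, tol = 1e-6) {
  stopifnot(relax_time > 0, field_mhz > 0, all(nu_cpmg > 0))
  n <- 2 * relax_time * nu_cpmg
  bad <- abs(n - round(n)) > tol | round(n) %% 2 != 0
  if (any(bad)) {
    stop("invalid_nu_cpmg: nu = ", paste(nu_cpmg[bad], collapse = ", "),
         " Hz does not give an even pulse count N = 2*T*nu", call. = FALSE)
  }
  structure(list(relax_time = relax_time, nu_cpmg = nu_cpmg,
                 field_mhz = field_mhz, n_pulses = as.integer(round(n))),
            class = "cpmg_schedule")
}

#' On-resonance spin-lock schedule
#'
#' @param omega1_hz Spin-lock field strengths omega1/2pi, Hz (> 0).
#' @param offset_hz Carrier offset from the population-average shift, Hz
#'   (0 = on resonance; only 0 is supported by the on-resonance model).
#' @param delay Relaxation delay, s.
#' @param field_mhz Static field (1H MHz).
#' @return An object of class `spinlock_schedule`.
#' @export
spinlock_schedule <- function(omega1_hz, offset_hz = 0, delay = 0.02,
                              field_mhz = 700) {
  if (any(omega1_hz <= 0)) stop("invalid_omega1: omega1 must be > 0",
                                call. = FALSE)
  structure(list(omega1_hz = omega1_hz, offset_hz = offset_hz,
                 delay = delay, field_mhz = field_mhz),
            class = "spinlock_schedule")
}

#' Convert a chemical-shift difference from ppm to angular frequency
#'
#' @param delta_ppm Shift difference in ppm.
#' @param nucleus Nucleus code (`"15N"`, `"1HN"`, `"1H"`, `"13C"`).
#' @param field_mhz Static field as 1H Larmor frequency, MHz (> 0).
#' @return Angular frequency difference, rad/s. Linear in both `delta_ppm`
#'   and `field_mhz`.
#' @export
#' @examples
#' ppm_to_angular(1, "15N", 600)  # ~382 rad/s
ppm_to_angular <- function(delta_ppm, nucleus, field_mhz) {
  stopifnot(is.numeric(field_mhz), all(field_mhz > 0))
  2 * pi * delta_ppm * field_mhz * gamma_ratio(nucleus)
}

## ---- 2x2 complex matrix helpers (Bloch-McConnell transverse block) -------

# exp(M) for a 2x2 complex matrix via the Cayley-Hamilton closed form:
# M = (tr/2) I + B with B^2 = Delta^2 I, so exp(M) = e^(tr/2) *
# (cosh(Delta) I + sinh(Delta)/Delta * B).
.expm2 <- function(m) {
  half_tr <- (m[1L] + m[4L]) / 2
  # Delta^2 = (tr/2)^2 - det
  d2 <- half_tr * half_tr - (m[1L] * m[4L] - m[3L] * m[2L])
  d <- sqrt(d2)
  ch <- cosh(d)
  sh_over_d <- if (Mod(d) < 1e-8) 1 + d2 / 6 else sinh(d) / d
  b <- m
  b[1L] <- b[1L] - half_tr
  b[4L] <- b[4L] - half_tr
  out <- sh_over_d * b
  out[1L] <- out[1L] + ch
  out[4L] <- out[4L] + ch
  exp(half_tr) * out
}

.mat2mul <- function(a, b) {
  c(a[1L] * b[1L] + a[3L] * b[2L],
    a[2L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[3L] + a[3L] * b[4L],
    a[2L] * b[3L] + a[4L] * b[4L])
}

.mat2pow <- function(m, n) {
  out <- c(1 + 0i, 0i, 0i, 1 + 0i)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .mat2mul(m, out)
    m <- .mat2mul(m, m)
    n <- n %/% 2L
  }
  out
}

# Exchange-only effective relaxation rate (R2,0 = 0) from numerical
# propagation of the two-state transverse magnetization through the
# constant-time CPMG element (tau - 180 - 2tau - 180 - tau)^(N/2), with
# ideal 180 pulses modeled as complex conjugation of the magnetization.
# Detection follows the major-state resonance: R2ex = -(1/T) log(|M_A(T)|/p_A).
.bm_rex_one <- function(k_ex, p_minor, domega, relax_time, n_pulses) {
  if (p_minor == 0 || domega == 0) return(0)
  p_a <- 1 - p_minor
  kf <- p_minor * k_ex
  kr <- p_a * k_ex
  tau <- relax_time / (2 * n_pulses)
  l0 <- c(complex(real = -kf), complex(real = kf),
          complex(real = kr), complex(real = -kr, imaginary = domega))
  a <- .expm2(l0 * tau)
  # pulse = conjugation: one CP element propagator is A * conj(A %*% A) * A
  e <- .mat2mul(a, .mat2mul(Conj(.mat2mul(a, a)), a))
  p <- .mat2pow(e, n_pulses %/% 2L)
  m_a <- p[1L] * p_a + p[3L] * p_minor
  -log(Mod(m_a) / p_a) / relax_time
}

#' Simulate a CPMG relaxation dispersion profile (Bloch-McConnell)
#'
#' Numerically propagates the two-state transverse magnetization through the
#' constant-time CPMG pulse train and returns the effective transverse
#' relaxation rate at every scheduled CPMG frequency. With equal base rates
#' in the two states the exchange contribution is exactly additive, so the
#' propagation is carried out with `R2,0 = 0` and the base rate added back.
#'
#' @param params [exchange_params()].
#' @param spin [spin_probe()]; supplies `R2,0` and the nucleus.
#' @param schedule [cpmg_schedule()].
#' @param ddelta_ppm Shift difference for this spin, ppm. If `NULL`, looked
#'   up in `params$ddelta` by (spin, nucleus).
#' @return Numeric vector of R2eff values (1/s), one per `nu_cpmg`.
#' @export
simulate_cpmg_profile <- function(params, spin, schedule, ddelta_ppm = NULL) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(spin, "spin_probe"),
            inherits(schedule, "cpmg_schedule"))
  dd <- .resolve_ddelta(params, spin, ddelta_ppm)
  domega <- ppm_to_angular(dd, spin$nucleus, schedule$field_mhz)
  rex <- vapply(schedule$n_pulses, function(n) {
    .bm_rex_one(params$k_ex, params$p_minor, domega, schedule$relax_time, n)
  }, numeric(1))
  out <- spin$r2_0 + rex
  if (any(!is.finite(out))) stop("non_finite_r2eff", call. = FALSE)
  out
}

.resolve_ddelta <- function(params, spin, ddelta_ppm) {
  if (!is.null(ddelta_ppm)) return(ddelta_ppm)
  tab <- params$ddelta
  if (is.null(tab)) {
    stop("missing_ddelta: no shift difference supplied for spin ",
         spin$spin, call. = FALSE)
  }
  hit <- tab$spin == spin$spin & tab$nucleus == spin$nucleus
  if (sum(hit) != 1L) {
    stop("missing_ddelta: expected exactly one ddelta entry for (",
         spin$spin, ", ", spin$nucleus, "), found ", sum(hit), call. = FALSE)
  }
  tab$ddelta_ppm[hit]
}

#' Luz-Meiboom fast-exchange CPMG contribution
#'
#' Closed-form exchange contribution to R2eff in the fast-exchange limit
#' (`k_ex >> |domega|`):
#' `R_ex = (p_A p_B domega^2 / k_ex) * (1 - (4 nu / k_ex) * tanh(k_ex / (4 nu)))`.
#' The caller is responsible for the regime; no validity check is applied.
#'
#' @param params [exchange_params()].
#' @param domega Shift difference, rad/s.
#' @param nu_cpmg CPMG frequencies, Hz.
#' @return Exchange contribution R_ex (1/s), non-negative and monotone
#'   non-increasing in `nu_cpmg`.
#' @export
luz_meiboom_rex <- function(params, domega, nu_cpmg) {
  stopifnot(inherits(params, "exchange_params"))
  phi <- params$p_major * params$p_minor * domega^2
  x <- params$k_ex / (4 * nu_cpmg)
  (phi / params$k_ex) * (1 - tanh(x) / x)
}

# Vectorized 2x2 complex matrix helpers: each matrix is a list of four
# equal-length component vectors (m11, m21, m12, m22).
.vexpm2 <- function(m) {
  half_tr <- (m[[1L]] + m[[4L]]) / 2
  d2 <- half_tr * half_tr - (m[[1L]] * m[[4L]] - m[[3L]] * m[[2L]])
  d <- sqrt(d2)
  sh <- sinh(d) / d
  small <- which(Mod(d) < 1e-8)
  if (length(small)) sh[small] <- 1 + d2[small] / 6
  ch <- cosh(d)
  f <- exp(half_tr)
  list(f * (ch + sh * (m[[1L]] - half_tr)),
       f * sh * m[[2L]],
       f * sh * m[[3L]],
       f * (ch + sh * (m[[4L]] - half_tr)))
}

.vmul2 <- function(a, b) {
  list(a[[1L]] * b[[1L]] + a[[3L]] * b[[2L]],
       a[[2L]] * b[[1L]] + a[[4L]] * b[[2L]],
       a[[1L]] * b[[3L]] + a[[3L]] * b[[4L]],
       a[[2L]] * b[[3L]] + a[[4L]] * b[[4L]])
}

# Exact closed-form exchange contribution (R2,0 = 0): analytic
# eigendecomposition of the 2x2 CPMG element propagator, including the
# initial-condition amplitudes that the textbook dominant-eigenvalue
# expression drops. Vectorized elementwise over (domega, n_pulses), which
# are recycled to a common length.
.cr_exact_rex <- function(k_ex, p_minor, domega, relax_time, n_pulses) {
  n_out <- max(length(domega), length(n_pulses), length(relax_time))
  if (p_minor == 0) return(rep(0, n_out))
  domega <- rep_len(domega, n_out)
  n_pulses <- rep_len(n_pulses, n_out)
  relax_time <- rep_len(relax_time, n_out)
  p_a <- 1 - p_minor
  kf <- p_minor * k_ex
  kr <- p_a * k_ex
  tau <- relax_time / (2 * n_pulses)
  l0 <- list(complex(real = -kf) * tau,
             complex(real = kf) * tau,
             complex(real = kr) * tau,
             complex(real = -kr, imaginary = domega) * tau)
  a <- .vexpm2(l0)
  e <- .vmul2(a, .vmul2(lapply(.vmul2(a, a), Conj), a))
  half_tr <- (e[[1L]] + e[[4L]]) / 2
  disc <- sqrt(half_tr * half_tr - (e[[1L]] * e[[4L]] - e[[3L]] * e[[2L]]))
  mu1 <- half_tr + disc
  mu2 <- half_tr - disc
  # eigenvectors (E12, mu - E11); det of eigenvector matrix = -2 E12 disc
  e12 <- e[[3L]]
  det_v <- e12 * (mu2 - mu1)
  c1 <- (p_a * (mu2 - e[[1L]]) - p_minor * e12) / det_v
  c2 <- (p_minor * e12 - p_a * (mu1 - e[[1L]])) / det_v
  pw <- n_pulses %/% 2L
  m_a <- (c1 * exp(pw * log(mu1)) + c2 * exp(pw * log(mu2))) * e12
  rex <- -log(Mod(m_a) / p_a) / relax_time
  # degenerate-eigenvalue corners are numerically unsafe; flag for fallback
  rex[Mod(det_v) < 1e-12 * Mod(e12)] <- NaN
  rex[domega == 0] <- 0
  rex
}

# Textbook Carver-Richards dominant-eigenvalue expression (R2,0 = 0),
# vectorized over nu. Log-domain branch guards against cosh overflow in
# slow-exchange corners.
.cr_rex <- function(k_ex, p_minor, domega, nu_cpmg) {
  if (p_minor == 0 || domega == 0) return(rep(0, length(nu_cpmg)))
  p_a <- 1 - p_minor
  kf <- p_minor * k_ex
  kr <- p_a * k_ex
  psi <- k_ex^2 - domega^2
  zeta <- 2 * domega * (kf - kr)
  root <- sqrt(psi^2 + zeta^2)
  dplus <- 0.5 * (1 + (psi + 2 * domega^2) / root)
  dminus <- 0.5 * (-1 + (psi + 2 * domega^2) / root)
  eta_plus <- sqrt(pmax(psi + root, 0) / 2) / (2 * nu_cpmg)
  eta_minus <- sqrt(pmax(-psi + root, 0) / 2) / (2 * nu_cpmg)
  big <- eta_plus > 300
  acosh_y <- numeric(length(nu_cpmg))
  if (any(!big)) {
    y <- dplus * cosh(eta_plus[!big]) - dminus * cos(eta_minus[!big])
    acosh_y[!big] <- log(y + sqrt(pmax(y^2 - 1, 0)))
  }
  if (any(big)) {
    # cosh(eta) ~ exp(eta)/2 and acosh(y) ~ log(2 y) for huge y
    acosh_y[big] <- log(dplus) + eta_plus[big]
  }
  k_ex / 2 - nu_cpmg * acosh_y
}

#' Carver-Richards closed-form CPMG profile
#'
#' Closed-form R2eff for two-site exchange with equal base rates in both
#' states, used as a fast forward engine for fitting and as an analytic
#' cross-check of the stepwise numerical propagator. With
#' `amplitude = "exact"` (the default) the expression retains the exact
#' initial-condition amplitudes of the CPMG element propagator via its
#' analytic 2x2 eigendecomposition, which is exact for ideal pulses at all
#' exchange regimes; `amplitude = "dominant"` gives the textbook
#' Carver-Richards dominant-eigenvalue expression, which deviates in slow
#' exchange with a sizable minor population. Corners where either branch
#' fails to produce a finite value fall back to numerical propagation (a
#' documented fallback).
#'
#' @inheritParams simulate_cpmg_profile
#' @param amplitude `"exact"` (default) or `"dominant"`; see Details.
#' @return Numeric vector of R2eff values (1/s), one per `nu_cpmg`.
#' @export
carver_richards_profile <- function(params, spin, schedule,
                                    ddelta_ppm = NULL,
                                    amplitude = c("exact", "dominant")) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(spin, "spin_probe"),
            inherits(schedule, "cpmg_schedule"))
  amplitude <- match.arg(amplitude)
  dd <- .resolve_ddelta(params, spin, ddelta_ppm)
  domega <- ppm_to_angular(dd, spin$nucleus, schedule$field_mhz)
  rex <- if (amplitude == "exact") {
    .cr_exact_rex(params$k_ex, params$p_minor, domega,
                  schedule$relax_time, schedule$n_pulses)
  } else {
    .cr_rex(params$k_ex, params$p_minor, domega, schedule$nu_cpmg)
  }
  bad <- !is.finite(rex)
  if (any(bad)) {
    rex[bad] <- vapply(schedule$n_pulses[bad], function(n) {
      .bm_rex_one(params$k_ex, params$p_minor, domega,
                  schedule$relax_time, n)
    }, numeric(1))
  }
  spin$r2_0 + rex
}

#' On-resonance rotating-frame relaxation rate R1rho
#'
#' Two-site exchange model for on-resonance spin-lock dispersion. The
#' authoritative implementation (`method = "eigen"`) extracts the dominant
#' decay eigenvalue of the full 6x6 two-state rotating-frame evolution
#' matrix (x, y, z components of both states, including R1, R2,0, omega1 and
#' the state offsets relative to the population-average shift). The
#' asymmetric-population closed form (`method = "analytic"`,
#' Trott-Palmer-style) is retained as a cross-check:
#' `R1rho = R2,0 + p_A p_B domega^2 k_ex / (om_A^2 om_B^2 / om_e^2 + k_ex^2)`
#' with effective fields `om_X^2 = omega1^2 + Omega_X^2`.
#'
#' @param params [exchange_params()].
#' @param spin [spin_probe()] (R1 and R2,0 used).
#' @param schedule [spinlock_schedule()].
#' @param ddelta_ppm Shift difference, ppm (or `NULL` to look up).
#' @param method `"eigen"` (default) or `"analytic"`.
#' @return Numeric vector of R1rho values (1/s), one per `omega1_hz`.
#' @export
r1rho_on_resonance <- function(params, spin, schedule, ddelta_ppm = NULL,
                               method = c("eigen", "analytic")) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(spin, "spin_probe"),
            inherits(schedule, "spinlock_schedule"))
  method <- match.arg(method)
  dd <- .resolve_ddelta(params, spin, ddelta_ppm)
  domega <- ppm_to_angular(dd, spin$nucleus, schedule$field_mhz)
  p_b <- params$p_minor
  p_a <- 1 - p_b
  # carrier at the population-average shift
  om_a <- -p_b * domega + 2 * pi * schedule$offset_hz
  om_b <- p_a * domega + 2 * pi * schedule$offset_hz
  omega1 <- 2 * pi * schedule$omega1_hz
  if (method == "analytic") {
    kex <- params$k_ex
    denom <- (omega1^2 + om_a^2) * (omega1^2 + om_b^2) /
      (omega1^2 + (p_a * om_a + p_b * om_b)^2) + kex^2
    return(spin$r2_0 + p_a * p_b * domega^2 * kex / denom)
  }
  vapply(omega1, function(w1) {
    .r1rho_eigen(params$k_ex, p_b, om_a, om_b, w1, spin$r2_0, spin$r1)
  }, numeric(1))
}

.r1rho_eigen <- function(k_ex, p_b, om_a, om_b, omega1, r2_0, r1) {
  p_a <- 1 - p_b
  kf <- p_b * k_ex
  kr <- p_a * k_ex
  # dMx = -R2 Mx - Om My; dMy = Om Mx - R2 My - w1 Mz; dMz = w1 My - R1 Mz
  block <- function(om) {
    matrix(c(-r2_0, -om, 0,
             om, -r2_0, -omega1,
             0, omega1, -r1), 3, 3, byrow = TRUE)
  }
  # rows/cols: Ax Ay Az Bx By Bz
  l <- matrix(0, 6, 6)
  l[1:3, 1:3] <- block(om_a) - diag(kf, 3)
  l[4:6, 4:6] <- block(om_b) - diag(kr, 3)
  l[1:3, 4:6] <- diag(kr, 3)
  l[4:6, 1:3] <- diag(kf, 3)
  v0 <- c(p_a, 0, 0, p_b, 0, 0)
  eg <- eigen(l)
  coeff <- solve(eg$vectors, v0)
  detect <- as.vector(crossprod(Conj(eg$vectors), v0))
  weight <- Mod(coeff * detect)
  -Re(eg$values[which.max(weight)])
}
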