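test_that("ppm to angular-frequency conversion matches the gyromagnetic table", {
  expect_equal(ppm_to_angular(0, "15N", 600), 0)
  # oracle: 2*pi * 600 * |gamma_N/gamma_H| = 2*pi * 600 * 0.10137
  expect_equal(ppm_to_angular(1, "15N", 600), 2 * pi * 600 * 0.10137,
               tolerance = 5e-4)
  # linearity in both arguments
  expect_equal(ppm_to_angular(2.5, "1HN", 600),
               2.5 * ppm_to_angular(1, "1HN", 600))
  expect_equal(ppm_to_angular(1, "13C", 1200),
               2 * ppm_to_angular(1, "13C", 600))
  expect_error(ppm_to_angular(1, "31P", 600), "unknown_nucleus")
})

test_that("parameter constructors enforce their invariants", {
  p <- exchange_params(2600, 0.028)
  expect_equal(p$k_ab + p$k_ba, p$k_ex)          # detailed balance
  expect_equal(p$k_ab, 0.028 * 2600)
  expect_error(exchange_params(-5, 0.1), "invalid_k_ex")
  expect_error(exchange_params(100, 0.7), "invalid_p_minor")
  expect_error(cpmg_schedule(0.032, c(40), 600), "invalid_nu_cpmg")
  expect_error(spinlock_schedule(c(-100)), "invalid_omega1")
})

test_that("degenerate exchange gives flat CPMG profiles at R2,0", {
  sch <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  s <- spin_probe("10", "15N", 8.5)
  flat1 <- simulate_cpmg_profile(exchange_params(2600, 0), s, sch,
                                 ddelta_ppm = 3)
  flat2 <- simulate_cpmg_profile(exchange_params(2600, 0.028), s, sch,
                                 ddelta_ppm = 0)
  expect_equal(flat1, rep(8.5, 4))
  expect_equal(flat2, rep(8.5, 4), tolerance = 1e-10)
  expect_equal(carver_richards_profile(exchange_params(2600, 0), s, sch,
                                       ddelta_ppm = 3), rep(8.5, 4))
})

test_that("closed form agrees with numerical propagation across regimes", {
  sch <- cpmg_schedule(0.032, c(31.25, 62.5, 125, 250, 500, 750, 1000), 600)
  s <- spin_probe("10", "15N", 8)
  # published-regime grid
  worst <- 0
  for (kex in c(100, 300, 1000, 3000, 10000)) {
    for (pb in c(0.005, 0.05, 0.15, 0.3)) {
      for (dd in c(0.2, 1, 3, 6)) {
        p <- exchange_params(kex, pb)
        bm <- simulate_cpmg_profile(p, s, sch, ddelta_ppm = dd)
        cr <- carver_richards_profile(p, s, sch, ddelta_ppm = dd)
        worst <- max(worst, max(abs(bm - cr)))
      }
    }
  }
  expect_lt(worst, 0.5)
  # wild-type kinetics: tighter bound
  p <- exchange_params(2600, 0.028)
  expect_lt(max(abs(simulate_cpmg_profile(p, s, sch, ddelta_ppm = 3) -
                      carver_richards_profile(p, s, sch, ddelta_ppm = 3))),
            0.2)
  # slow-exchange corner
  p_slow <- exchange_params(100, 0.05)
  expect_lt(max(abs(simulate_cpmg_profile(p_slow, s, sch, ddelta_ppm = 5) -
                      carver_richards_profile(p_slow, s, sch,
                                              ddelta_ppm = 5))), 0.5)
})

test_that("textbook dominant-eigenvalue expression is a documented approximation", {
  sch <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  s <- spin_probe("10", "15N", 8)
  p <- exchange_params(2600, 0.028)
  bm <- simulate_cpmg_profile(p, s, sch, ddelta_ppm = 3)
  crd <- carver_richards_profile(p, s, sch, ddelta_ppm = 3,
                                 amplitude = "dominant")
  expect_lt(max(abs(bm - crd)), 0.5)
  expect_gt(max(abs(bm - crd)), 1e-6)  # genuinely distinct route
})

test_that("Luz-Meiboom limit behaves and matches propagation in fast exchange", {
  p <- exchange_params(50000, 0.028)
  nus <- c(100, 250, 500, 1000, 2000)
  expect_equal(luz_meiboom_rex(p, 0, nus), rep(0, 5))
  rex <- luz_meiboom_rex(p, ppm_to_angular(2, "15N", 600), nus)
  expect_true(all(diff(rex) <= 0))          # monotone non-increasing
  expect_true(all(rex >= 0))
  expect_lt(luz_meiboom_rex(p, 1000, 1e7), 1e-4)  # nu -> Inf limit
  # fast-regime agreement with propagation (k_ex/domega >= 10)
  sch <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  for (dd in c(0.5, 2, 5)) {
    dom <- ppm_to_angular(dd, "15N", 600)
    skip_point <- p$k_ex / dom < 10
    if (skip_point) next
    bm <- simulate_cpmg_profile(p, spin_probe("x", "15N", 0), sch,
                                ddelta_ppm = dd)
    lm <- luz_meiboom_rex(p, dom, sch$nu_cpmg)
    expect_lt(max(abs(bm - lm) / pmax(lm, 1e-9)), 0.05)
  }
})

test_that("shift-sign reflection leaves R2eff unchanged", {
  # relabeling the states maps domega to -domega; the detected major-state
  # decay is invariant under this reflection (complex-conjugation symmetry
  # of the two-state Liouvillian)
  sch <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  s <- spin_probe("10", "15N", 8)
  for (pb in c(0.1, 0.3, 0.5)) {
    a <- simulate_cpmg_profile(exchange_params(1500, pb), s, sch,
                               ddelta_ppm = 2)
    b <- simulate_cpmg_profile(exchange_params(1500, pb), s, sch,
                               ddelta_ppm = -2)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("R2eff depends on the field only through the shift difference", {
  s <- spin_probe("10", "15N", 8)
  p <- exchange_params(2000, 0.04)
  sch1 <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  sch2 <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 1200)
  expect_equal(simulate_cpmg_profile(p, s, sch1, ddelta_ppm = 3),
               simulate_cpmg_profile(p, s, sch2, ddelta_ppm = 1.5),
               tolerance = 1e-12)
})

test_that("profiles are monotone non-increasing with floor R2,0", {
  sch <- cpmg_schedule(0.032, c(31.25, 62.5, 125, 250, 500, 750, 1000), 600)
  s <- spin_probe("10", "15N", 8)
  for (kex in c(300, 2600, 20000)) {
    for (pb in c(0.02, 0.2)) {
      r2 <- simulate_cpmg_profile(exchange_params(kex, pb), s, sch,
                                  ddelta_ppm = 2.5)
      expect_true(all(diff(r2) <= 1e-9))
      expect_gte(min(r2), s$r2_0 - 1e-9)
    }
  }
})

test_that("on-resonance R1rho: degenerate, plateau and cross-check behavior", {
  sch <- spinlock_schedule(c(700, 1500, 3000, 6000, 10000), field_mhz = 700)
  s <- spin_probe("526-CE", "13C", 12, r1 = 2)
  p <- exchange_params(2600, 0.028)
  # ddelta = 0: R1rho = R2,0 at all spin-lock fields (theta = 90 degrees)
  expect_equal(r1rho_on_resonance(p, s, sch, ddelta_ppm = 0),
               rep(12, 5), tolerance = 1e-8)
  r1r <- r1rho_on_resonance(p, s, sch, ddelta_ppm = 1.5)
  expect_true(all(diff(r1r) <= 0))          # monotone non-increasing
  # eigenvalue route vs asymmetric-population closed form within 2%
  ana <- r1rho_on_resonance(p, s, sch, ddelta_ppm = 1.5, method = "analytic")
  expect_lt(max(abs(r1r - ana) / ana), 0.02)
  # strong spin lock quenches exchange to < 1% of the low-field plateau
  dom <- ppm_to_angular(1.5, "13C", 700)
  plateau <- p$p_major * p$p_minor * dom^2 / p$k_ex
  rex_hi <- r1rho_on_resonance(p, s, spinlock_schedule(10000,
                                                       field_mhz = 700),
                               ddelta_ppm = 1.5) - 12
  expect_lt(rex_hi, 0.01 * plateau)
})
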