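test_that("intensity-to-R2eff conversion is the exact closed form", {
  expect_equal(r2eff_from_intensities(1, 1, 0.032), 0)
  expect_equal(r2eff_from_intensities(0.5, 1, 0.032), log(2) / 0.032)
  expect_equal(r2eff_from_intensities(exp(-1), 1, 0.020), 50)
  expect_error(r2eff_from_intensities(-0.1, 1, 0.032),
               "nonpositive_intensity")
  # inverse of the forward model up to machine precision
  r2 <- c(5, 12.3, 40)
  expect_equal(r2eff_from_intensities(exp(-r2 * 0.032), 1, 0.032), r2)
})

test_that("pooled standard deviation matches direct summation", {
  expect_equal(pooled_sd(list(c(3, 3, 3), c(7, 7))), 0)
  expect_equal(pooled_sd(list(c(2, 5))), 3 / sqrt(2))
  pools <- list(c(1.2, 1.5, 0.9), c(4.4, 4.0), c(10, 10.4, 9.6, 10.2))
  # brute-force evaluation of the pooled formula
  num <- sum(sapply(pools, function(x) sum((x - mean(x))^2)))
  den <- sum(sapply(pools, length) - 1)
  expect_equal(pooled_sd(pools), sqrt(num / den))
  # singleton pools carry no information
  expect_equal(pooled_sd(c(pools, list(5))), sqrt(num / den))
  expect_error(pooled_sd(list(1, 2, 3)), "no_replicates")
})

test_that("Monte Carlo error propagation matches the delta method", {
  expect_equal(propagate_r2eff_errors(0.7, 1, 0, 0.032), 0)
  sig <- propagate_r2eff_errors(0.7, 1, 0.005, 0.032, n_draws = 4000,
                                seed = 11)
  # first-order propagation: both I and I0 perturbed independently
  delta <- 0.005 / 0.032 * sqrt(1 / 0.7^2 + 1)
  expect_equal(sig, delta, tolerance = 0.1)
  # approximate linearity in sigma_i in the small-noise regime
  sig2 <- propagate_r2eff_errors(0.7, 1, 0.01, 0.032, n_draws = 4000,
                                 seed = 11)
  expect_equal(sig2 / sig, 2, tolerance = 0.1)
  # reproducibility under a fixed seed
  expect_identical(sig, propagate_r2eff_errors(0.7, 1, 0.005, 0.032,
                                               n_draws = 4000, seed = 11))
  # both the peak and the reference drowned in noise: model invalid
  expect_error(propagate_r2eff_errors(0.004, 0.02, 0.05, 0.032,
                                      n_draws = 200, seed = 1),
               "noise_model_invalid")
})

test_that("global fit recovers ground truth from noiseless data", {
  ds <- make_dispersion_dataset("wildtype", n_spins = 3, noise = 0,
                                seed = 21)
  fit <- global_fit(ds, seed = 21)
  expect_lt(abs(fit$params$k_ex / 2600 - 1), 1e-3)
  expect_lt(abs(fit$params$p_minor / 0.028 - 1), 1e-3)
  expect_lt(fit$chisq, 1e-3)
  # per-spin shift differences recovered too
  gt <- attr(ds, "ground_truth")$params$ddelta
  est <- merge(gt, fit$params$ddelta, by = c("spin", "nucleus"))
  expect_lt(max(abs(est$ddelta_ppm.x - est$ddelta_ppm.y)), 0.01)
})

test_that("fit is invariant to record order and duplication with halved weight", {
  prep <- make_small_prep(31)
  f1 <- global_fit(prep, warm_start = c(2000, 0.05))
  f2 <- global_fit(prep[sample(nrow(prep)), ], warm_start = c(2000, 0.05))
  expect_equal(f1$params$k_ex, f2$params$k_ex, tolerance = 1e-5)
  dup <- rbind(prep, prep)
  dup$sigma <- prep$sigma * sqrt(2)   # duplicated record at halved weight
  f3 <- global_fit(dup, warm_start = c(2000, 0.05))
  expect_equal(f1$params$k_ex, f3$params$k_ex, tolerance = 1e-4)
  expect_equal(f1$params$p_minor, f3$params$p_minor, tolerance = 1e-4)
})

test_that("parameter recovery holds across a kinetics grid at 2% noise", {
  # 3x3 grid of truths spanning slow-to-fast regimes; median relative
  # error of k_ex < 10% with two fields
  errs <- c()
  for (kex in c(800, 2600, 8000)) {
    for (pb in c(0.02, 0.05, 0.1)) {
      fx <- list(k_ex = kex, p_minor = pb,
                 dd_span = c("15N" = 4.7, "1HN" = 1.1, "13C" = 2))
      ds <- make_dispersion_dataset(fx, n_spins = 4, noise = 0.02,
                                    seed = 100 + kex + round(1000 * pb))
      fit <- global_fit(ds)
      errs <- c(errs, abs(fit$params$k_ex / kex - 1))
    }
  }
  expect_lt(stats::median(errs), 0.1)
})

test_that("null data yield no spurious exchange amplitude", {
  fx <- list(k_ex = 2600, p_minor = 0,
             dd_span = c("15N" = 4.7, "1HN" = 1.1, "13C" = 2))
  ds <- make_dispersion_dataset(fx, n_spins = 4, seed = 5)
  fit <- global_fit(ds, seed = 5)
  # fitted exchange contribution is negligible relative to the measurement
  # uncertainty, however the (unidentifiable) kinetic parameters land
  prep <- prepare_r2eff(ds, seed = 5)
  sch <- cpmg_schedule(0.032, c(31.25, 125, 500, 1000), 600)
  rex_max <- 0
  for (i in seq_len(nrow(fit$params$ddelta))) {
    row <- fit$params$ddelta[i, ]
    prof <- carver_richards_profile(
      fit$params, spin_probe(row$spin, row$nucleus, 0), sch,
      ddelta_ppm = row$ddelta_ppm)
    rex_max <- max(rex_max, max(prof))
  }
  expect_lt(rex_max, 3 * stats::median(prep$sigma))
  # and the per-spin detection criterion does not prefer exchange
  one <- prep[prep$spin == "S01" & prep$nucleus == "15N" &
                prep$field_mhz == 600, ]
  de <- detect_exchange(one$r2eff, one$sigma, one$nu_cpmg_hz)
  expect_false(de$exchange)
  expect_gt(de$aic_exchange, de$aic_flat - 4)
})

test_that("Monte Carlo uncertainties are seed-stable and scale with noise", {
  prep <- make_small_prep(41, sigma = 0.3)
  fit <- global_fit(prep, warm_start = c(2000, 0.05))
  m1 <- mc_parameter_uncertainty(fit, n_draws = 25, seed = 7)
  m1b <- mc_parameter_uncertainty(fit, n_draws = 25, seed = 7)
  expect_identical(m1$uncertainties, m1b$uncertainties)
  expect_gt(m1$uncertainties["k_ex"], 0)
  # zero-noise refits: sigma ~ 0
  ds0 <- make_dispersion_dataset("wildtype", n_spins = 2, noise = 0,
                                 seed = 42)
  f0 <- global_fit(ds0, seed = 42)
  p0 <- f0$prep
  p0$sigma <- 1e-6
  f0b <- global_fit(p0, warm_start = c(2600, 0.028))
  m0 <- mc_parameter_uncertainty(f0b, n_draws = 20, seed = 3)
  expect_lt(m0$uncertainties["k_ex"] / 2600, 1e-3)
  # noisier data give larger parameter uncertainty
  prep_hi <- make_small_prep(41, sigma = 0.3)
  prep_hi$sigma <- 0.9
  fit_hi <- global_fit(prep_hi, warm_start = c(2000, 0.05))
  m_hi <- mc_parameter_uncertainty(fit_hi, n_draws = 25, seed = 7)
  expect_gt(m_hi$uncertainties["k_ex"], m1$uncertainties["k_ex"])
})

test_that("exchange detection requires enough points and rejects cleanly", {
  nu <- c(31.25, 62.5, 125, 250, 375, 500, 750, 1000)
  expect_error(detect_exchange(rep(10, 4), rep(0.3, 4), nu[1:4]),
               "too_few_points")
  # zero-noise flat profile: no exchange
  de <- detect_exchange(rep(10, 8), rep(0.3, 8), nu)
  expect_false(de$exchange)
  # strong dispersion is detected with certainty
  p <- exchange_params(2000, 0.03)
  rex <- luz_meiboom_rex(p, ppm_to_angular(2, "15N", 600), nu)
  set.seed(1)
  y <- 10 + rex * (10 / max(rex)) + rnorm(8, 0, 0.3)
  de2 <- detect_exchange(y, rep(0.3, 8), nu)
  expect_true(de2$exchange)
  expect_lt(de2$p_value, 0.01)
})
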