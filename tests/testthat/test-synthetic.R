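test_that("fixtures carry the published kinetics and spans", {
  wt <- fixture_library("wildtype")
  expect_equal(wt$k_ex, 2600)
  expect_equal(wt$p_minor, 0.028)
  expect_equal(unname(wt$dd_span["15N"]), 4.7)
  expect_equal(unname(wt$dd_span["1HN"]), 1.1)
  expect_equal(fixture_library("H493A")$k_ex, 2830)
  expect_equal(fixture_library("V517A")$k_ex, 6800)
  expect_gt(fixture_library("V517A")$p_minor, 0.4)  # populations near-inverted
  expect_error(fixture_library("nosuch"), "unknown_fixture")
})

test_that("dispersion generator is a pure function of (parameters, seed)", {
  d1 <- make_dispersion_dataset("wildtype", n_spins = 3, seed = 12)
  d2 <- make_dispersion_dataset("wildtype", n_spins = 3, seed = 12)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- make_dispersion_dataset("wildtype", n_spins = 3, seed = 13)
  expect_false(identical(d1$intensity, d3$intensity))
  # ground truth is serialized alongside
  gt <- attr(d1, "ground_truth")
  expect_equal(gt$params$k_ex, 2600)
  expect_identical(gt$seed, 12L)
  expect_true(all(c("spin", "nucleus", "ddelta_ppm") %in%
                    names(gt$params$ddelta)))
  # one spin pinned at each span maximum
  dd <- gt$params$ddelta
  expect_equal(max(dd$ddelta_ppm[dd$nucleus == "15N"]), 4.7)
  expect_equal(max(dd$ddelta_ppm[dd$nucleus == "1HN"]), 1.1)
})

test_that("noise-free intensities invert exactly through the forward model", {
  ds <- make_dispersion_dataset("wildtype", n_spins = 2, noise = 0,
                                seed = 3)
  df <- as.data.frame(ds)
  gt <- attr(ds, "ground_truth")
  r2 <- r2eff_from_intensities(df$intensity, df$intensity_ref,
                               df$relax_time_s)
  for (i in sample(nrow(df), 10)) {
    probe_r20 <- gt$r2_0$r2_0[gt$r2_0$spin == df$spin[i] &
                                gt$r2_0$nucleus == df$nucleus[i] &
                                gt$r2_0$field_mhz == df$field_mhz[i]]
    sch <- cpmg_schedule(df$relax_time_s[i], df$nu_cpmg_hz[i],
                         df$field_mhz[i])
    want <- simulate_cpmg_profile(gt$params,
                                  spin_probe(df$spin[i], df$nucleus[i],
                                             probe_r20), sch)
    expect_equal(r2[i], want, tolerance = 1e-10)
  }
})

test_that("generated noise has the nominal standard deviation", {
  # same seed with and without noise shares the ground truth and RNG
  # layout, so the paired difference isolates the injected noise
  noisy <- as.data.frame(make_dispersion_dataset("wildtype", n_spins = 15,
                                                 noise = 0.02, seed = 61))
  clean <- as.data.frame(make_dispersion_dataset("wildtype", n_spins = 15,
                                                 noise = 0, seed = 61))
  # replicate positions are themselves random draws; compare the
  # deterministic primary points only
  noisy <- noisy[noisy$replicate_index == 0L, ]
  clean <- clean[clean$replicate_index == 0L, ]
  key <- function(d) paste(d$dataset_id, d$spin, d$nu_cpmg_hz)
  m <- match(key(noisy), key(clean))
  expect_false(anyNA(m))
  # keep points far from the low-intensity censoring floor
  well_above <- clean$intensity[m] > 0.2
  resid <- (noisy$intensity - clean$intensity[m])[well_above]
  expect_gt(length(resid), 500)
  expect_equal(stats::sd(resid), 0.02, tolerance = 0.06)
  expect_equal(mean(resid), 0, tolerance = 0.005)
})

test_that("sequence family plants the intended group signatures", {
  fam <- make_sequence_family(15, 15, seed = 6)
  expect_identical(length(fam), 30L)
  expect_identical(attr(fam, "labels"), rep(c(1L, 2L), each = 15))
  # all sequences pass the anchor filter
  expect_identical(attr(filter_by_anchor(fam), "n_retained"), 30L)
  m <- build_score_matrix(fam)
  truth <- attr(fam, "labels")
  # group 2 rows have larger 541 scores on average, and smaller 493
  expect_gt(mean(m[truth == 2, "541"]), mean(m[truth == 1, "541"]))
  expect_lt(mean(m[truth == 2, "493"]), mean(m[truth == 1, "493"]))
  # determinism
  fam2 <- make_sequence_family(15, 15, seed = 6)
  expect_identical(fam$seqs, fam2$seqs)
})

test_that("breathing cage geometry matches its analytic description", {
  cage <- make_breathing_cage(1.5, radius = 6, n_atoms = 500)
  expect_identical(nrow(cage$closed), 500L)
  r_closed <- sqrt(cage$closed$x^2 + cage$closed$y^2 + cage$closed$z^2)
  expect_equal(r_closed, rep(6, 500), tolerance = 1e-9)
  r_open <- sqrt(cage$open$x^2 + cage$open$y^2 + cage$open$z^2)
  expect_equal(sort(unique(round(r_open, 6))), c(6, 7.5))
  expect_equal(cage$analytic_volume,
               4 / 3 * pi * (6 - vdw_radius("C") - 1.09)^3)
  # displacement zero: open equals closed
  cage0 <- make_breathing_cage(0)
  expect_identical(as.data.frame(cage0$closed), as.data.frame(cage0$open))
})

test_that("relaxation generator orders rates by rigidity and is seeded", {
  motion <- data.frame(residue = c("rigid", "floppy"),
                       s2 = c(0.85, 0.4), tau_e_ps = c(20, 200))
  rs <- make_relaxation_set(motion, tau_c_ns = 5, fields = 600,
                            noise = 0.01, seed = 2)
  expect_gt(rs$r2[rs$residue == "rigid"], rs$r2[rs$residue == "floppy"])
  rs2 <- make_relaxation_set(motion, tau_c_ns = 5, fields = 600,
                             noise = 0.01, seed = 2)
  expect_identical(rs, rs2)
  expect_identical(attr(rs, "ground_truth")$tau_c_ns, 5)
})
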