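test_that("dihedral angles match an independent cross-product oracle", {
  # brute-force oracle: the classic one-line atan2 identity
  # atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
  oracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    y <- sqrt(sum(b2^2)) * sum(b1 * pracma::cross(b2, b3))
    x <- sum(pracma::cross(b1, b2) * pracma::cross(b2, b3))
    atan2(y, x) * 180 / pi
  }
  set.seed(8)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    got <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    want <- oracle(p[1, ], p[2, ], p[3, ], p[4, ])
    d <- abs(got - want)
    expect_lt(min(d, abs(d - 360)), 1e-6)
  }
  # coplanar cis geometry: exactly zero
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
})

test_that("chi2 is constructed, folded, and errors on missing atoms", {
  for (chi in c(0, 2, -41, -64, 88)) {
    tyr <- make_tyrosine(chi2_deg = chi)
    expect_equal(chi2_dihedral(tyr, 526), chi, tolerance = 1e-6)
  }
  # ring two-fold symmetry: chi2 and chi2 + 180 are the same state
  tyr <- make_tyrosine(chi2_deg = 2 + 180)
  expect_equal(chi2_dihedral(tyr, 526), 2, tolerance = 1e-6)
  # rigid-transform invariance
  tyr2 <- make_tyrosine(chi2_deg = -55)
  set.seed(2)
  moved <- apply_rigid(tyr2, random_rotation(), c(4, -2, 9))
  expect_equal(chi2_dihedral(moved, 526), -55, tolerance = 1e-6)
  incomplete <- structure_df(as.data.frame(tyr2[tyr2$atom != "CD1", ]))
  expect_error(chi2_dihedral(incomplete, 526), "missing_atom: CD1")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  tyr <- make_tyrosine(chi2_deg = 10)
  # identical structures
  fit0 <- superpose(tyr, tyr)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  # known rotation + translation recovered
  set.seed(3)
  rot <- random_rotation()
  tr <- c(5, -3, 2)
  moved <- apply_rigid(tyr, rot, tr)
  fit <- superpose(moved, tyr)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-6)
  # translation-only: identity rotation, exact translation
  shifted <- apply_rigid(tyr, diag(3), c(1, 2, 3))
  fit_t <- superpose(shifted, tyr)
  expect_equal(fit_t$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit_t$translation, c(-1, -2, -3), tolerance = 1e-8)
  expect_error(superpose(tyr[1:2, ], tyr[1:2, ]), "degenerate_selection")
})

test_that("superposition agrees with the bio3d reference implementation", {
  tyr <- make_tyrosine(chi2_deg = 25)
  set.seed(6)
  target <- tyr
  target$x <- target$x + rnorm(nrow(tyr), sd = 0.3)
  target$y <- target$y + rnorm(nrow(tyr), sd = 0.3)
  target$z <- target$z + rnorm(nrow(tyr), sd = 0.3)
  moved <- apply_rigid(tyr, random_rotation(), c(2, 2, -1))
  fit <- superpose(moved, target)
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(as.matrix(
    target[, c("x", "y", "z")]))),
    mobile = as.vector(t(as.matrix(moved[, c("x", "y", "z")])))))
  rmsd_ref <- sqrt(mean(colSums((matrix(ref, 3) -
                                   t(as.matrix(target[, c("x", "y",
                                                          "z")])))^2)))
  expect_equal(fit$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("PDB write/read round-trips structures and takes model 1 only", {
  cage <- make_breathing_cage(1)$open
  path <- tempfile(fileext = ".pdb")
  write_pdb(cage, path)
  back <- read_pdb(path)
  expect_identical(nrow(back), nrow(cage))
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(cage[, c("x", "y", "z")]), tolerance = 5e-4,
               ignore_attr = TRUE)
  expect_identical(back$atom, cage$atom)
  # multi-model file: first model retained
  tyr_a <- make_tyrosine(0); tyr_b <- make_tyrosine(60)
  traj <- linear_morph(tyr_a, tyr_b, n_frames = 3)
  mpath <- tempfile(fileext = ".pdb")
  write_pdb(traj, mpath)
  first <- read_pdb(mpath)
  expect_identical(nrow(first), nrow(tyr_a))
  expect_equal(first$x, traj$frames[[1]]$x, tolerance = 5e-4)
  # a hand-counted toy file
  hand <- c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
            "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
            "END")
  hpath <- tempfile(fileext = ".pdb")
  writeLines(hand, hpath)
  expect_identical(nrow(read_pdb(hpath)), 2L)
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_pdb(empty))
})

test_that("linear morph interpolates exactly between superposed endpoints", {
  a <- make_tyrosine(chi2_deg = 0)
  b0 <- make_tyrosine(chi2_deg = 70)
  set.seed(4)
  b <- apply_rigid(b0, random_rotation(), c(8, 0, -5))
  traj <- linear_morph(a, b, n_frames = 11)
  expect_identical(length(traj$frames), 11L)
  expect_equal(traj$lambda, seq(0, 1, length.out = 11))
  # frame 0 is a; last frame is b after superposition
  expect_equal(as.matrix(traj$frames[[1]][, c("x", "y", "z")]),
               as.matrix(a[, c("x", "y", "z")]), ignore_attr = TRUE)
  sup_b <- superpose(b, a)$transformed
  expect_equal(as.matrix(traj$frames[[11]][, c("x", "y", "z")]),
               as.matrix(sup_b[, c("x", "y", "z")]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # midframe is the coordinate mean
  mid <- (as.matrix(a[, c("x", "y", "z")]) +
            as.matrix(sup_b[, c("x", "y", "z")])) / 2
  expect_equal(as.matrix(traj$frames[[6]][, c("x", "y", "z")]), mid,
               tolerance = 1e-10, ignore_attr = TRUE)
  # per-atom displacement linear in frame index
  d1 <- as.matrix(traj$frames[[2]][, c("x", "y", "z")]) -
    as.matrix(traj$frames[[1]][, c("x", "y", "z")])
  d9 <- as.matrix(traj$frames[[10]][, c("x", "y", "z")]) -
    as.matrix(traj$frames[[9]][, c("x", "y", "z")])
  expect_lt(max(abs(d1 - d9)), 1e-9)
  disjoint <- make_breathing_cage(0)$closed
  disjoint$chain <- "Z"
  expect_error(linear_morph(a, disjoint), "empty_atom_intersection")
})

test_that("glycine substitution strips exactly the side chain", {
  tyr <- make_tyrosine(chi2_deg = 30)
  gly <- mutate_to_glycine(tyr, 526)
  expect_identical(nrow(tyr) - nrow(gly), 8L)   # Tyr side chain: 8 heavy atoms
  expect_true(all(gly$resname == "GLY"))
  bb <- c("N", "CA", "C", "O")
  expect_identical(sort(gly$atom), sort(bb))
  # backbone coordinates bit-identical
  for (a in bb) {
    expect_identical(unlist(tyr[tyr$atom == a, c("x", "y", "z")]),
                     unlist(gly[gly$atom == a, c("x", "y", "z")]))
  }
  # applying to a glycine is the identity
  gly2 <- mutate_to_glycine(gly, 526)
  expect_identical(as.data.frame(gly), as.data.frame(gly2))
  expect_error(mutate_to_glycine(tyr, 999), "residue_absent")
})
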