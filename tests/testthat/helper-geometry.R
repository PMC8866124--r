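# Shared geometry helpers for structure tests: internal-coordinate atom
# placement and a tyrosine-like residue built at a prescribed chi2.

# Place atom D given atoms a, b, c: |c-d| = bond, angle(b,c,d) = angle_deg,
# dihedral(a,b,c,d) = dihedral_deg.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Tyrosine-like residue with a prescribed chi2 (CA-CB-CG-CD1), full ring.
make_tyrosine <- function(chi2_deg = 0, resno = 526, chain = "A") {
  n <- c(-1.45, 0, 0.5)
  ca <- c(0, 0, 0)
  cb <- c(1.52, 0, 0)
  cg <- place_atom(n, ca, cb, 1.51, 114, -60)
  cd1 <- place_atom(ca, cb, cg, 1.39, 120.9, chi2_deg)
  cd2 <- place_atom(ca, cb, cg, 1.39, 120.9, chi2_deg + 180)
  ce1 <- place_atom(cb, cg, cd1, 1.39, 120, 180)
  ce2 <- place_atom(cb, cg, cd2, 1.39, 120, 180)
  cz <- place_atom(cg, cd1, ce1, 1.39, 120, 0)
  oh <- place_atom(cd1, ce1, cz, 1.38, 120, 180)
  co <- place_atom(cb, ca, n, 1.52, 111, 120)
  o <- place_atom(ca, n, co, 1.23, 121, 0)
  xyz <- rbind(n, ca, co, o, cb, cg, cd1, cd2, ce1, ce2, cz, oh)
  structure_df(data.frame(
    chain = chain, resno = resno, resname = "TYR",
    atom = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
             "CZ", "OH"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C", "O"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# Random rigid rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(s, rot, trans = c(0, 0, 0)) {
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(rot)
  s$x <- xyz[, 1] + trans[1]
  s$y <- xyz[, 2] + trans[2]
  s$z <- xyz[, 3] + trans[3]
  s
}

# Small r2eff-mode dispersion data frame for fast fitting tests.
make_small_prep <- function(seed, k_ex = 2600, p_minor = 0.028,
                            dd_ppm = 3, sigma = 0.3,
                            fields = c(600, 850)) {
  set.seed(seed)
  nus <- c(31.25, 62.5, 125, 250, 375, 500, 750, 1000)
  np <- as.integer(2 * 0.032 * nus)
  rows <- NULL
  for (f in fields) {
    par <- exchange_params(k_ex, p_minor)
    probe <- spin_probe("S1", "15N", 10)
    sch <- cpmg_schedule(0.032, nus, f)
    r2 <- simulate_cpmg_profile(par, probe, sch, ddelta_ppm = dd_ppm)
    rows <- rbind(rows, data.frame(
      spin = "S1", nucleus = "15N", field_mhz = f, relax_time_s = 0.032,
      nu_cpmg_hz = nus, r2eff = r2 + rnorm(length(nus), 0, sigma),
      sigma = sigma, stringsAsFactors = FALSE))
  }
  rows
}
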