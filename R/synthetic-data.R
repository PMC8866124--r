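#' Named ground-truth parameter fixtures
#'
#' Two-site exchange parameter sets used to generate synthetic dispersion
#' data with known ground truth. `wildtype` carries the kinetics of the
#' wild-type JIP1 SH3 domain (minor population 2.8%, exchange rate
#' 2,600 /s); `H493A` (2,830 /s) and `V517A` (6,800 /s) carry the variant
#' exchange rates, with minor populations reflecting that H493A slightly
#' stabilizes the minor state and V517A nearly inverts the populations.
#' Shift-difference draws are bounded by the observed spans (4.7 ppm for
#' 15N, 1.1 ppm for 1HN).
#'
#' @param name Fixture name; one of `"wildtype"`, `"H493A"`, `"V517A"`.
#' @return List with `k_ex`, `p_minor` and the per-nucleus `dd_span` (ppm).
#' @export
fixture_library <- function(name = NULL) {
  lib <- list(
    wildtype = list(k_ex = 2600, p_minor = 0.028),
    H493A = list(k_ex = 2830, p_minor = 0.07),
    V517A = list(k_ex = 6800, p_minor = 0.45)
  )
  span <- c("15N" = 4.7, "1HN" = 1.1, "13C" = 2)
  lib <- lapply(lib, function(x) c(x, list(dd_span = span)))
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown_fixture: '", name, "' (available: ",
         paste(names(lib), collapse = ", "), ")", call. = FALSE)
  }
  lib[[name]]
}

# Default constant-time CPMG schedules per nucleus: relaxation delay and
# CPMG frequencies matching the acquired experiments (15N: 32 ms,
# 31.25-1000 Hz; 1HN: 20 ms, 50-2000 Hz; 13C: 20 ms, 100-1000 Hz).
.default_schedules <- function() {
  list(
    "15N" = list(relax_time = 0.032,
                 nu_cpmg = c(31.25, 62.5, 125, 187.5, 250, 312.5, 375,
                             500, 625, 750, 875, 1000)),
    "1HN" = list(relax_time = 0.020,
                 nu_cpmg = c(50, 100, 200, 300, 400, 600, 800, 1000,
                             1200, 1400, 1600, 2000)),
    "13C" = list(relax_time = 0.020,
                 nu_cpmg = seq(100, 1000, by = 100))
  )
}

# Exchange-free base-rate draw ranges per nucleus (1/s), typical of a small
# (~8 kDa) domain at 15 C.
.R20_RANGE <- list("15N" = c(7, 13), "1HN" = c(14, 26), "13C" = c(10, 20))

#' Generate a synthetic relaxation dispersion dataset with known truth
#'
#' Intensities are computed from the numerical Bloch-McConnell forward model
#' (`I = I0 * exp(-R2eff * T)` with `I0 = 1`), perturbed with Gaussian noise
#' of standard deviation `noise * I0`, and accompanied by technical
#' replicates at `n_replicates` randomly chosen CPMG frequencies per spin
#' and dataset. Per-spin shift differences are drawn uniformly within the
#' fixture's per-nucleus span, with the first spin pinned at the span
#' maximum so that span recovery is testable. Points whose noisy intensity
#' is non-positive are dropped (peaks broadened into the noise floor are
#' lost to peak picking); weak positive intensities are kept and carry a
#' correspondingly large propagated R2eff uncertainty.
#'
#' @param fixture Fixture name (see [fixture_library()]) or a list with
#'   `k_ex`, `p_minor`, `dd_span`.
#' @param n_spins Number of spins (>= 1).
#' @param fields Named list mapping nucleus to static fields (1H MHz).
#' @param schedules Named list of `list(relax_time, nu_cpmg)` per nucleus;
#'   defaults to the acquired experiments.
#' @param noise Gaussian intensity noise as a fraction of `I0` (>= 0).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param n_replicates Replicated CPMG frequencies per spin and dataset.
#' @return A `dispersion_dataset` (intensity mode) whose
#'   `"ground_truth"` attribute records the exact parameters, base rates,
#'   noise level and seed used.
#' @export
make_dispersion_dataset <- function(fixture = "wildtype", n_spins = 15L,
                                    fields = list("15N" = c(600, 850),
                                                  "1HN" = c(600, 950)),
                                    schedules = NULL, noise = 0.02,
                                    seed = 1L, n_replicates = 2L) {
  stopifnot(noise >= 0, n_spins >= 1L)
  fx <- if (is.character(fixture)) fixture_library(fixture) else fixture
  if (is.null(schedules)) schedules <- .default_schedules()
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  spins <- sprintf("S%02d", seq_len(n_spins))
  nuclei <- names(fields)
  # ground-truth shift differences: uniform within span, first spin pinned
  dd <- do.call(rbind, lapply(nuclei, function(nuc) {
    span <- fx$dd_span[[nuc]]
    vals <- stats::runif(n_spins, 0, span)
    vals[1L] <- span
    data.frame(spin = spins, nucleus = nuc, ddelta_ppm = vals,
               stringsAsFactors = FALSE)
  }))
  truth <- exchange_params(fx$k_ex, fx$p_minor, ddelta = dd)
  r2_0_tab <- do.call(rbind, lapply(nuclei, function(nuc) {
    do.call(rbind, lapply(fields[[nuc]], function(fm) {
      rng <- .R20_RANGE[[nuc]]
      data.frame(spin = spins, nucleus = nuc, field_mhz = fm,
                 r2_0 = stats::runif(n_spins, rng[1L], rng[2L]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rows <- list()
  for (nuc in nuclei) {
    sch_def <- schedules[[nuc]]
    for (fm in fields[[nuc]]) {
      sch <- cpmg_schedule(sch_def$relax_time, sch_def$nu_cpmg, fm)
      did <- paste0(nuc, "_", fm)
      for (sp in spins) {
        r2_0 <- r2_0_tab$r2_0[r2_0_tab$spin == sp & r2_0_tab$nucleus == nuc &
                                r2_0_tab$field_mhz == fm]
        probe <- spin_probe(sp, nuc, r2_0)
        r2 <- simulate_cpmg_profile(truth, probe, sch)
        i_ref <- 1 + stats::rnorm(1L, 0, noise)
        nu_rep <- if (n_replicates > 0L) {
          sample(sch$nu_cpmg, min(n_replicates, length(sch$nu_cpmg)))
        } else numeric(0)
        nu_all <- c(sch$nu_cpmg, nu_rep)
        rep_idx <- c(integer(length(sch$nu_cpmg)),
                     seq_along(nu_rep))
        r2_all <- c(r2, r2[match(nu_rep, sch$nu_cpmg)])
        intens <- exp(-r2_all * sch$relax_time) +
          stats::rnorm(length(r2_all), 0, noise)
        # peak picking at the conventional S/N >= 3 threshold: peaks
        # broadened below it are lost; retained weak peaks carry a
        # correspondingly large propagated R2eff uncertainty
        keep <- if (noise > 0) intens >= 3 * noise else rep(TRUE, length(intens))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = did, spin = sp, nucleus = nuc, field_mhz = fm,
          relax_time_s = sch$relax_time, nu_cpmg_hz = nu_all,
          intensity = intens, intensity_ref = i_ref,
          replicate_index = rep_idx,
          stringsAsFactors = FALSE)[keep, ]
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  out <- dispersion_dataset(df, mode = "intensity")
  attr(out, "ground_truth") <- list(
    fixture = if (is.character(fixture)) fixture else "custom",
    params = truth, r2_0 = r2_0_tab, noise = noise,
    seed = as.integer(seed), n_spins = n_spins, fields = fields)
  out
}

#' Generate an aligned SH3-like sequence family with planted groups
#'
#' Plants the two size-score signatures at the reference positions: group 1
#' (eclipsed-like) carries a large residue at position 493, a small one at
#' 517 and a small one at 541; group 2 (staggered-like) carries a small
#' residue at 493, Ile/Leu at 517 and a larger residue at 541. All
#' sequences carry Tyr or Phe at the 526 anchor.
#'
#' @param n_group1,n_group2 Sequences per group (>= 1 each).
#' @param seed Integer seed.
#' @return An `aligned_family` with a `"labels"` attribute holding the
#'   planted group of each sequence (1 or 2).
#' @export
make_sequence_family <- function(n_group1 = 20L, n_group2 = 20L, seed = 1L) {
  stopifnot(n_group1 >= 1L, n_group2 >= 1L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  len <- 60L
  cols <- c("493" = 5L, "517" = 29L, "520" = 32L, "526" = 38L, "541" = 53L)
  pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  n <- n_group1 + n_group2
  labels <- rep(c(1L, 2L), c(n_group1, n_group2))
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(pool, len, replace = TRUE)
    if (labels[i] == 1L) {
      s[cols["493"]] <- sample(c("H", "Y", "F", "R"), 1L)
      s[cols["517"]] <- sample(c("V", "A", "T"), 1L)
      s[cols["541"]] <- sample(c("A", "G", "S"), 1L)
    } else {
      s[cols["493"]] <- sample(c("A", "S", "G", "T"), 1L)
      s[cols["517"]] <- sample(c("I", "L"), 1L)
      s[cols["541"]] <- sample(c("L", "F", "Y", "W", "M"), 1L)
    }
    s[cols["520"]] <- sample(c("Q", "R", "K"), 1L)
    s[cols["526"]] <- sample(c("Y", "F"), 1L)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("SH3_%s%02d", c("grp1_", "grp2_")[labels],
                         stats::ave(seq_len(n), labels, FUN = seq_along))
  fam <- aligned_family(seqs, ref_columns = cols)
  attr(fam, "labels") <- labels
  attr(fam, "seed") <- as.integer(seed)
  fam
}

#' Generate a two-state breathing-cage toy structure pair
#'
#' A spherical shell of pseudo-carbon atoms (quasi-uniform Fibonacci
#' lattice) encloses an empty cavity whose pocket volume is analytically
#' `(4/3) * pi * (R - r_vdw - cutoff)^3`. The "open" partner displaces one
#' gate atom radially outward by `gate_displacement`, emulating the local
#' breathing motion that transiently enlarges the pocket.
#'
#' @param gate_displacement Outward radial displacement of the gate patch,
#'   Angstrom (>= 0).
#' @param seed Integer seed (controls nothing stochastic at present but is
#'   recorded for provenance).
#' @param radius Shell radius, Angstrom.
#' @param n_atoms Number of shell pseudo-atoms.
#' @param cutoff Probe cutoff used for the analytic volume, Angstrom.
#' @param gate_radius Chord radius of the displaced gate patch, Angstrom;
#'   all shell atoms within this distance of the gate pole move together
#'   (a single atom of a dense shell leaves no opening, because its
#'   neighbors' exclusion spheres still cover the hole).
#' @return List: `closed` and `open` structures, `analytic_volume`
#'   (Angstrom^3, closed cage), `gate_atoms` (row indices), `radius`.
#' @export
make_breathing_cage <- function(gate_displacement = 1, seed = 1L,
                                radius = 6, n_atoms = 600L, cutoff = 1.09,
                                gate_radius = 4) {
  stopifnot(gate_displacement >= 0, radius > 0, n_atoms >= 50L)
  # Fibonacci sphere lattice
  i <- seq_len(n_atoms) - 0.5
  phi <- acos(1 - 2 * i / n_atoms)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- radius * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi),
                        cos(phi))
  mk <- function(coords) {
    structure_df(data.frame(
      chain = "A", resno = seq_len(n_atoms), resname = "CAG",
      atom = "C", element = "C",
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE))
  }
  closed <- mk(xyz)
  pole <- xyz[1L, ]
  gate <- which(sqrt(colSums((t(xyz) - pole)^2)) <= gate_radius)
  open_xyz <- xyz
  scale <- (radius + gate_displacement) / radius
  open_xyz[gate, ] <- xyz[gate, ] * scale
  open <- mk(open_xyz)
  r_excl <- vdw_radius("C") + cutoff
  list(closed = closed, open = open,
       analytic_volume = 4 / 3 * pi * (radius - r_excl)^3,
       gate_atoms = gate, radius = radius, cutoff = cutoff,
       gate_displacement = gate_displacement, seed = as.integer(seed))
}

#' Generate a synthetic backbone 15N relaxation dataset
#'
#' Forward-computes R1, R2 and heteronuclear NOE from per-residue
#' Lipari-Szabo motion parameters and perturbs each rate with Gaussian
#' noise proportional to its value.
#'
#' @param motion Data frame with columns `residue`, `s2`, `tau_e_ps`.
#' @param tau_c_ns Overall rotational correlation time, ns (shared).
#' @param fields Static fields, 1H MHz.
#' @param noise Fractional Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return Data frame with per-residue, per-field `r1`, `r2`, `noe` and
#'   their sigmas; ground truth attached as attribute `"ground_truth"`.
#' @export
make_relaxation_set <- function(motion, tau_c_ns = 5, fields = 600,
                                noise = 0.02, seed = 1L) {
  stopifnot(all(c("residue", "s2", "tau_e_ps") %in% names(motion)),
            noise >= 0)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (fm in fields) {
    for (i in seq_len(nrow(motion))) {
      m <- motion_params(motion$s2[i], tau_c_ns, motion$tau_e_ps[i])
      r <- predict_rates(m, fm)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = motion$residue[i], field_mhz = fm,
        r1 = r[["r1"]] * (1 + stats::rnorm(1L, 0, noise)),
        r1_err = max(noise * r[["r1"]], 1e-6),
        r2 = r[["r2"]] * (1 + stats::rnorm(1L, 0, noise)),
        r2_err = max(noise * r[["r2"]], 1e-6),
        noe = r[["noe"]] + stats::rnorm(1L, 0, noise * abs(r[["noe"]])),
        noe_err = max(noise * abs(r[["noe"]]), 1e-6))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(motion = motion, tau_c_ns = tau_c_ns,
                                    noise = noise, seed = as.integer(seed))
  out
}
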