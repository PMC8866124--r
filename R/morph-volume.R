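#' Linear morph trajectory between two conformations
#'
#' Superposes `b` onto `a` (Kabsch, over the shared atoms), then builds
#' `n_frames` structures by per-atom linear Cartesian interpolation:
#' frame i has coordinates `(1 - lambda_i) a + lambda_i b` with
#' `lambda_i = (i-1)/(n_frames-1)`. Atoms not shared by both structures are
#' dropped (and reported via the `"dropped"` attribute).
#'
#' @param a,b [structure_df()] start and end conformations.
#' @param n_frames Number of frames (>= 2).
#' @param superpose_first Superpose `b` onto `a` before interpolating
#'   (default TRUE).
#' @return A `morph_trajectory`: list with `frames` (list of structures)
#'   and `lambda` (frame fractions in `[0, 1]`).
#' @export
linear_morph <- function(a, b, n_frames = 21L, superpose_first = TRUE) {
  stopifnot(inherits(a, "structure_df"), inherits(b, "structure_df"),
            n_frames >= 2L)
  ka <- .atom_key(a); kb <- .atom_key(b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("empty_atom_intersection", call. = FALSE)
  dropped <- c(setdiff(ka, kb), setdiff(kb, ka))
  a2 <- structure_df(as.data.frame(a[match(shared, ka), ]))
  b2 <- structure_df(as.data.frame(b[match(shared, kb), ]))
  if (superpose_first) b2 <- superpose(b2, a2)$transformed
  ca <- .coords(a2); cb <- .coords(b2)
  lambda <- seq(0, 1, length.out = n_frames)
  frames <- lapply(lambda, function(l) {
    fr <- a2
    xyz <- (1 - l) * ca + l * cb
    fr$x <- xyz[, 1L]; fr$y <- xyz[, 2L]; fr$z <- xyz[, 3L]
    fr
  })
  structure(list(frames = frames, lambda = lambda),
            class = "morph_trajectory", dropped = dropped)
}

#' Replace a residue by glycine
#'
#' Removes all side-chain atoms (CB and beyond) of the residue, keeps the
#' backbone (N, CA, C, O, OXT), and renames the residue GLY. Used before
#' pocket-volume calculations so that the complete pocket normally occupied
#' by the side chain is measured.
#'
#' @param s A [structure_df()].
#' @param resno Residue number.
#' @param chain Chain identifier (default `"A"`).
#' @return The modified structure.
#' @export
mutate_to_glycine <- function(s, resno, chain = "A") {
  stopifnot(inherits(s, "structure_df"))
  in_res <- s$chain == chain & s$resno == resno
  if (!any(in_res)) {
    stop("residue_absent: ", resno, " chain ", chain, call. = FALSE)
  }
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA")
  drop <- in_res & !s$atom %in% backbone
  out <- as.data.frame(s[!drop, ])
  out$resname[out$chain == chain & out$resno == resno] <- "GLY"
  structure_df(out)
}

#' Aromatic ring centroid
#'
#' Mean position of the ring carbons (CG, CD1, CD2, CE1, CE2, CZ) of a
#' residue; used to center the pocket inclusion sphere on the ring.
#'
#' @inheritParams mutate_to_glycine
#' @return Numeric xyz triple, Angstrom.
#' @export
ring_centroid <- function(s, resno, chain = "A") {
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  m <- s$chain == chain & s$resno == resno & s$atom %in% ring
  if (!any(m)) stop("missing_atom: no ring atoms in residue ", resno,
                    call. = FALSE)
  colMeans(.coords(s)[m, , drop = FALSE])
}

#' Pocket definition for grid-based void-volume measurement
#'
#' @param center Inclusion-sphere center, xyz in Angstrom.
#' @param radius Inclusion-sphere radius, Angstrom (> 0; default 8).
#' @param spacing Grid spacing delta, Angstrom (> 0; default 0.5).
#' @param cutoff Probe distance cutoff added to each atom's van der Waals
#'   radius, Angstrom (default 1.09, the van der Waals radius of hydrogen,
#'   compensating for the heavy-atom-only representation).
#' @param seed_point Point from which the contiguous pocket is grown
#'   (defaults to `center`).
#' @return An object of class `pocket_definition`.
#' @export
pocket_definition <- function(center, radius = 8, spacing = 0.5,
                              cutoff = 1.09, seed_point = NULL) {
  stopifnot(length(center) == 3L, radius > 0, spacing > 0, cutoff >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 spacing = spacing, cutoff = cutoff,
                 seed_point = if (is.null(seed_point)) as.numeric(center)
                 else as.numeric(seed_point)),
            class = "pocket_definition")
}

#' Grid-based pocket volume
#'
#' Measures the void volume around a site: a cubic grid of spacing `delta`
#' (origin snapped to the inclusion center) fills the inclusion sphere;
#' every grid point within `vdW radius + cutoff` of any atom center is
#' deleted; the contiguous component containing the seed point (6-neighbor
#' flood fill) is retained; the volume is `count * delta^3`.
#'
#' @param s A [structure_df()].
#' @param p A [pocket_definition()].
#' @param closed_as_zero If TRUE, a seed point falling inside an atom's
#'   exclusion radius reports volume 0 (pocket closed) instead of raising
#'   an error.
#' @return Volume in Angstrom^3.
#' @export
pocket_volume <- function(s, p, closed_as_zero = FALSE) {
  stopifnot(inherits(s, "structure_df"), inherits(p, "pocket_definition"))
  d <- p$spacing
  n <- ceiling(p$radius / d)
  ax <- seq(-n, n) * d
  dim3 <- length(ax)
  gx <- rep(ax, times = dim3 * dim3)
  gy <- rep(rep(ax, each = dim3), times = dim3)
  gz <- rep(ax, each = dim3 * dim3)
  inside <- (gx^2 + gy^2 + gz^2) <= p$radius^2
  free <- inside
  xyz <- .coords(s)
  r_excl <- vdw_radius(s$element) + p$cutoff
  ctr <- p$center
  if (nrow(xyz) > 0L) {
    # prune atoms that cannot reach the inclusion sphere
    d_ctr <- sqrt(colSums((t(xyz) - ctr)^2))
    keep <- d_ctr <= p$radius + max(r_excl)
    xyz <- xyz[keep, , drop = FALSE]
    r_excl <- r_excl[keep]
  }
  if (nrow(xyz) > 0L) {
    idx_free <- which(free)
    gpts <- cbind(gx[idx_free] + ctr[1L], gy[idx_free] + ctr[2L],
                  gz[idx_free] + ctr[3L])
    blocked <- logical(length(idx_free))
    chunk <- 200L
    for (a0 in seq(1L, nrow(xyz), by = chunk)) {
      a1 <- min(nrow(xyz), a0 + chunk - 1L)
      sub <- xyz[a0:a1, , drop = FALSE]
      live <- which(!blocked)
      if (length(live) == 0L) break
      d2 <- outer(rowSums(gpts[live, , drop = FALSE]^2),
                  rowSums(sub^2), "+") -
        2 * gpts[live, , drop = FALSE] %*% t(sub)
      hit <- d2 <= matrix((r_excl[a0:a1])^2, length(live), a1 - a0 + 1L,
                          byrow = TRUE)
      blocked[live[rowSums(hit) > 0L]] <- TRUE
    }
    free[idx_free[blocked]] <- FALSE
  }
  # seed cell
  sp <- p$seed_point - ctr
  si <- pmin(pmax(round(sp / d), -n), n) + n + 1L
  seed_lin <- si[1L] + (si[2L] - 1L) * dim3 + (si[3L] - 1L) * dim3^2
  if (!free[seed_lin]) {
    if (closed_as_zero) return(0)
    stop("seed_excluded: the seed point lies inside an exclusion radius ",
         "(pocket closed); use closed_as_zero = TRUE to report 0",
         call. = FALSE)
  }
  # 6-neighbor flood fill by iterative dilation
  free_arr <- array(free, dim = c(dim3, dim3, dim3))
  reached <- array(FALSE, dim = dim(free_arr))
  reached[si[1L], si[2L], si[3L]] <- TRUE
  repeat {
    grown <- reached
    grown[-1L, , ] <- grown[-1L, , ] | reached[-dim3, , ]
    grown[-dim3, , ] <- grown[-dim3, , ] | reached[-1L, , ]
    grown[, -1L, ] <- grown[, -1L, ] | reached[, -dim3, ]
    grown[, -dim3, ] <- grown[, -dim3, ] | reached[, -1L, ]
    grown[, , -1L] <- grown[, , -1L] | reached[, , -dim3]
    grown[, , -dim3] <- grown[, , -dim3] | reached[, , -1L]
    grown <- grown & free_arr
    if (sum(grown) == sum(reached)) break
    reached <- grown
  }
  sum(reached) * d^3
}

#' Pocket-volume profile along a morph trajectory
#'
#' Computes the pocket volume of every frame (with the target residue
#' replaced by glycine in each frame when `residue` is given) and the
#' expansion statistic `max(volume) - volume[1]`.
#'
#' @param traj A `morph_trajectory`.
#' @param p A [pocket_definition()].
#' @param residue,chain Optional residue replaced by glycine in every frame.
#' @param closed_as_zero Passed to [pocket_volume()].
#' @return A `volume_profile`: data frame (`frame`, `lambda`, `volume_a3`)
#'   with attribute `"expansion"` (Angstrom^3).
#' @export
volume_profile <- function(traj, p, residue = NULL, chain = "A",
                           closed_as_zero = FALSE) {
  stopifnot(inherits(traj, "morph_trajectory"))
  vols <- vapply(traj$frames, function(fr) {
    if (!is.null(residue)) fr <- mutate_to_glycine(fr, residue, chain)
    pocket_volume(fr, p, closed_as_zero = closed_as_zero)
  }, numeric(1))
  out <- data.frame(frame = seq_along(vols), lambda = traj$lambda,
                    volume_a3 = vols)
  attr(out, "expansion") <- max(vols) - vols[1L]
  class(out) <- c("volume_profile", "data.frame")
  out
}
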