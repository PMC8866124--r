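#' Composite 1H/15N chemical-shift coordinates
#'
#' Maps a 2D amide peak (1H ppm, 15N ppm) into the composite shift space
#' used for distance computations, scaling the 15N dimension by `w_n`
#' (community-standard chemical-shift-perturbation weighting).
#'
#' @param peak Numeric length-2 vector `c(h, n)` in ppm.
#' @param w_n 15N weight relative to 1H (default 0.14).
#' @return Numeric length-2 vector in composite ppm.
#' @export
composite_shift <- function(peak, w_n = 0.14) {
  stopifnot(length(peak) == 2L, all(is.finite(peak)))
  c(peak[[1L]], w_n * peak[[2L]])
}

#' Deviation from collinearity of three 2D peaks
#'
#' For a residue observed in the wild type and two variants in fast
#' exchange along the same major/minor axis, the three peaks fall on a
#' straight line. This returns the perpendicular distance (composite ppm)
#' of the middle point from the line through the two outer points; 0 means
#' exactly collinear.
#'
#' @param p_wt,p_m1,p_m2 2D peaks, `c(h_ppm, n_ppm)`.
#' @param w_n 15N composite weight.
#' @return Distance in composite ppm, with attribute `"middle"` naming
#'   which input was classified as the middle point.
#' @export
collinearity_deviation <- function(p_wt, p_m1, p_m2, w_n = 0.14) {
  pts <- rbind(composite_shift(p_wt, w_n), composite_shift(p_m1, w_n),
               composite_shift(p_m2, w_n))
  rownames(pts) <- c("p_wt", "p_m1", "p_m2")
  # middle point = the one whose projection onto the principal axis of the
  # triple lies between the other two
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  t_par <- (sweep(pts, 2L, ctr) %*% sv$v[, 1L])[, 1L]
  mid <- order(t_par)[2L]
  outer_idx <- setdiff(1:3, mid)
  a <- pts[outer_idx[1L], ]
  b <- pts[outer_idx[2L], ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len < 1e-12) stop("coincident_endpoints", call. = FALSE)
  v <- pts[mid, ] - a
  cross <- abs(ab[1L] * v[2L] - ab[2L] * v[1L])
  structure(cross / len, middle = rownames(pts)[mid])
}

#' Fractional position of a peak along the major/minor shift axis
#'
#' Under fast-exchange averaging the observed shift is
#' `delta_obs = (1 - f) delta_major + f delta_minor`, so the scalar
#' projection of `(p_obs - p_major)` onto `(p_minor - p_major)` in
#' composite space estimates the minor-state fraction `f`. The value is
#' returned unclipped with an in-range flag.
#'
#' @param p_obs,p_major,p_minor 2D peaks, `c(h_ppm, n_ppm)`.
#' @param w_n 15N composite weight.
#' @return Fraction `f` with attribute `"in_range"` (`TRUE` if in [0, 1]).
#' @export
fractional_position <- function(p_obs, p_major, p_minor, w_n = 0.14) {
  a <- composite_shift(p_major, w_n)
  b <- composite_shift(p_minor, w_n)
  o <- composite_shift(p_obs, w_n)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-24) stop("coincident_endpoints", call. = FALSE)
  f <- sum((o - a) * ab) / len2
  structure(f, in_range = f >= 0 && f <= 1)
}

#' Compare two sets of fitted shift differences
#'
#' Agreement statistics between the |ddelta| values of two proteins over
#' their shared residues, per nucleus: least-squares slope through the
#' origin, Pearson correlation and RMSD.
#'
#' @param a,b Data frames with columns `residue`, `nucleus`, `value`
#'   (ppm; magnitudes by default, signed if restored externally).
#' @return Data frame with one row per shared nucleus: `nucleus`, `n`,
#'   `slope`, `correlation`, `rmsd`.
#' @export
compare_delta_sets <- function(a, b) {
  need <- c("residue", "nucleus", "value")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  merged <- merge(a[need], b[need], by = c("residue", "nucleus"),
                  suffixes = c("_a", "_b"))
  if (nrow(merged) < 3L) {
    stop("too_few_shared: need >= 3 shared residues", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(merged, merged$nucleus), function(d) {
    data.frame(nucleus = d$nucleus[1L], n = nrow(d),
               slope = sum(d$value_a * d$value_b) / sum(d$value_a^2),
               correlation = if (nrow(d) >= 3L)
                 stats::cor(d$value_a, d$value_b) else NA_real_,
               rmsd = sqrt(mean((d$value_a - d$value_b)^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
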