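#' Physical and chemical constant tables
#'
#' Authoritative constant sets shipped with the package: gyromagnetic ratios
#' used for ppm to rad/s conversions, Bondi van der Waals radii used by the
#' pocket-volume grid, and the heavy-atom side-chain size-score table used by
#' the sequence PCA.
#'
#' @name ringflipr-constants
NULL

# Gyromagnetic ratios, rad s^-1 T^-1 (CODATA-style values, 5 significant digits
# are guaranteed for the derived |gamma_X / gamma_1H| ratios).
.GAMMA <- c(
  "1H"  = 267.52219e6,
  "1HN" = 267.52219e6,
  "15N" = -27.126189e6,
  "13C" = 67.282840e6
)

#' Gyromagnetic ratio magnitude relative to 1H
#'
#' @param nucleus One of `"1H"`, `"1HN"`, `"15N"`, `"13C"`.
#' @return `|gamma_nucleus / gamma_1H|` (dimensionless).
#' @export
gamma_ratio <- function(nucleus) {
  nucleus <- as.character(nucleus)
  if (!nucleus %in% names(.GAMMA)) {
    stop("unknown_nucleus: '", nucleus, "' (known: ",
         paste(unique(names(.GAMMA)), collapse = ", "), ")", call. = FALSE)
  }
  abs(.GAMMA[[nucleus]] / .GAMMA[["1H"]])
}

# Bondi van der Waals radii (Angstrom) for heavy atoms; the pocket-volume
# calculation operates on heavy atoms only and compensates for the absent
# protons through the probe cutoff (see pocket_volume()).
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)

#' Van der Waals radius lookup (Bondi set)
#'
#' @param element Element symbol (case-insensitive). Unknown elements fall
#'   back to the carbon radius of 1.70 Angstrom.
#' @return Radius in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(as.character(element))
  r <- .VDW_RADII[el]
  r[is.na(r)] <- .VDW_RADII[["C"]]
  unname(r)
}

# Side-chain heavy-atom counts for the 20 canonical amino acids; glycine has
# no side-chain heavy atom (0), tryptophan has the largest side chain (10).
.SIZE_SCORES <- c(
  A = 1L, C = 2L, D = 4L, E = 5L, F = 7L, G = 0L, H = 6L, I = 4L, K = 5L,
  L = 4L, M = 4L, N = 4L, P = 3L, Q = 5L, R = 7L, S = 2L, T = 3L, V = 3L,
  Y = 8L, W = 10L
)

#' Amino-acid side-chain size score
#'
#' Number of heavy (non-hydrogen) atoms in the side chain of a canonical
#' amino acid, the feature used to score alignment positions before PCA.
#'
#' @param residue Character vector of one-letter amino-acid codes.
#' @return Integer vector of heavy-atom counts (0 for G through 10 for W).
#' @export
#' @examples
#' size_score(c("G", "A", "W"))
size_score <- function(residue) {
  code <- toupper(as.character(residue))
  bad <- !code %in% names(.SIZE_SCORES)
  if (any(bad)) {
    stop("non_canonical_residue: ", paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(.SIZE_SCORES[code])
}

#' The full 20-entry size-score table
#'
#' @return Named integer vector mapping one-letter codes to heavy-atom counts.
#' @export
size_score_table <- function() .SIZE_SCORES
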