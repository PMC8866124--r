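#' Atomic structure container
#'
#' A light-weight atom table: one row per atom with columns `chain`,
#' `resno`, `resname`, `atom` (PDB-convention atom name, e.g. `"CD1"`),
#' `element` and Cartesian coordinates `x`, `y`, `z` in Angstrom. Keys
#' `(chain, resno, atom)` must be unique and coordinates finite.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `structure_df`.
#' @export
structure_df <- function(df) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("nonfinite_coordinates", call. = FALSE)
  }
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    stop("duplicate_atom_keys: ", key[duplicated(key)][1L], call. = FALSE)
  }
  class(df) <- c("structure_df", "data.frame")
  df
}

.coords <- function(s) as.matrix(s[, c("x", "y", "z")])

.atom_key <- function(s) paste(s$chain, s$resno, s$atom)

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records through bio3d; multi-model files are reduced
#' to the first model and alternate locations to altloc 'A' (or blank).
#'
#' @param path Path to a PDB file.
#' @return A [structure_df()].
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no_atom_records: ", path, call. = FALSE)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, ]
  el <- at$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1L, 1L)
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  structure_df(data.frame(
    chain = ch, resno = at$resno, resname = at$resid, atom = at$elety,
    element = toupper(el), x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Write a structure (or morph trajectory) to a PDB file
#'
#' A single structure is written as one model; a `morph_trajectory` is
#' written as a multi-model PDB. Coordinates are written to 0.001 Angstrom.
#'
#' @param s A `structure_df` or `morph_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  frames <- if (inherits(s, "morph_trajectory")) s$frames else list(s)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (length(frames) > 1L) writeLines(sprintf("MODEL     %4d", k), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(fr)),
      ifelse(nchar(fr$atom) < 4L, paste0(" ", fr$atom), fr$atom),
      fr$resname, fr$chain, fr$resno, fr$x, fr$y, fr$z, fr$element)
    writeLines(lines, con)
    if (length(frames) > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Side-chain chi2 dihedral angle
#'
#' Signed torsion over the atoms CA-CB-CG-CD1 of an aromatic (Tyr, Phe,
#' His-like) residue, folded into (-90, +90] degrees using the two-fold
#' symmetry of the ring (chi2 and chi2 + 180 are equivalent). An eclipsed
#' ring has chi2 near 0, a staggered ring near +/-40 to 90 degrees.
#'
#' @param s A [structure_df()].
#' @param resno Residue number.
#' @param chain Chain identifier (default `"A"`).
#' @param fold Fold into (-90, 90] using ring symmetry (default TRUE).
#' @return Angle in degrees.
#' @export
chi2_dihedral <- function(s, resno, chain = "A", fold = TRUE) {
  stopifnot(inherits(s, "structure_df"))
  names4 <- c("CA", "CB", "CG", "CD1")
  sel <- lapply(names4, function(a) {
    i <- which(s$chain == chain & s$resno == resno & s$atom == a)
    if (length(i) != 1L) {
      stop("missing_atom: ", a, " of residue ", resno, " chain ", chain,
           call. = FALSE)
    }
    as.numeric(s[i, c("x", "y", "z")])
  })
  ang <- dihedral_angle(sel[[1L]], sel[[2L]], sel[[3L]], sel[[4L]])
  if (fold) {
    ang <- ((ang + 90) %% 180) - 90
    if (ang == -90) ang <- 90
  }
  ang
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction over the three bond vectors.
#'
#' @param p1,p2,p3,p4 Numeric xyz triples.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1]) / sqrt(sum(b2^2))
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Least-squares superposition (Kabsch)
#'
#' Optimal rotation and translation mapping `mobile` onto `target` over a
#' selection of matched atoms, via singular value decomposition of the
#' cross-covariance with the standard reflection guard.
#'
#' @param mobile,target [structure_df()] objects.
#' @param selection Optional character vector of atom keys
#'   (`"chain resno atom"`) to superpose on; defaults to all atoms shared
#'   between the two structures.
#' @return List: `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the selection), and `transformed` (the full mobile
#'   structure after the transform).
#' @export
superpose <- function(mobile, target, selection = NULL) {
  stopifnot(inherits(mobile, "structure_df"), inherits(target, "structure_df"))
  km <- .atom_key(mobile); kt <- .atom_key(target)
  shared <- if (is.null(selection)) intersect(km, kt) else selection
  im <- match(shared, km); it <- match(shared, kt)
  if (anyNA(im) || anyNA(it) || length(shared) < 3L) {
    stop("degenerate_selection: need >= 3 matched atoms", call. = FALSE)
  }
  a <- .coords(mobile)[im, , drop = FALSE]
  b <- .coords(target)[it, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  if (qr(a0)$rank < 2L) stop("degenerate_selection: collinear atoms",
                             call. = FALSE)
  sv <- svd(crossprod(a0, b0))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cb - as.vector(rot %*% ca)
  moved <- mobile
  xyz <- t(rot %*% t(.coords(mobile))) + matrix(trans, nrow(mobile), 3L,
                                                byrow = TRUE)
  moved$x <- xyz[, 1L]; moved$y <- xyz[, 2L]; moved$z <- xyz[, 3L]
  fitted <- t(rot %*% t(a)) + matrix(trans, nrow(a), 3L, byrow = TRUE)
  list(rotation = rot, translation = as.vector(trans),
       rmsd = sqrt(mean(rowSums((fitted - b)^2))), transformed = moved)
}
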