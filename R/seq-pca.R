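#' Aligned sequence family
#'
#' A named set of equal-length (gapped) aligned sequences plus the mapping
#' from reference positions of the JIP1 SH3 domain (493, 517, 520, 526,
#' 541) to alignment columns.
#'
#' @param seqs Named character vector of aligned sequences (gap = `-`).
#' @param ref_columns Named integer vector mapping reference positions
#'   (names, e.g. `"526"`) to 1-based alignment columns.
#' @return An object of class `aligned_family`.
#' @export
aligned_family <- function(seqs, ref_columns) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), is.numeric(ref_columns),
            !is.null(names(ref_columns)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- names(seqs)[widths != widths[1L]][1L]
    stop("ragged_alignment: sequence '", bad, "' has a different length",
         call. = FALSE)
  }
  if (any(ref_columns < 1L | ref_columns > widths[1L])) {
    stop("column_out_of_range", call. = FALSE)
  }
  structure(list(seqs = seqs, ref_columns = as.integer(ref_columns) |>
                   stats::setNames(names(ref_columns))),
            class = "aligned_family")
}

#' @export
length.aligned_family <- function(x) length(x$seqs)

.family_column <- function(family, position) {
  cols <- family$ref_columns
  position <- as.character(position)
  if (!position %in% names(cols)) {
    stop("unmapped_position: ", position, call. = FALSE)
  }
  substr(family$seqs, cols[[position]], cols[[position]])
}

#' Filter a family by the identity of the anchor position
#'
#' Retains (in order) the sequences carrying one of the allowed residues at
#' the anchor column; the count retained is reported as an attribute.
#'
#' @param family An [aligned_family()].
#' @param anchor Reference position of the anchor (default `"526"`).
#' @param allowed Allowed one-letter codes (default Tyr/Phe).
#' @return The filtered family (possibly empty), with attribute
#'   `"n_retained"`.
#' @export
filter_by_anchor <- function(family, anchor = "526", allowed = c("Y", "F")) {
  stopifnot(inherits(family, "aligned_family"))
  keep <- .family_column(family, anchor) %in% allowed
  out <- family
  out$seqs <- family$seqs[keep]
  attr(out, "n_retained") <- sum(keep)
  lb <- attr(family, "labels")
  if (!is.null(lb)) attr(out, "labels") <- lb[keep]
  out
}

#' Heavy-atom size-score matrix at selected alignment positions
#'
#' Looks up the residues at the mapped columns and converts them to
#' side-chain heavy-atom counts. Sequences with a gap or non-canonical
#' code at a scored column are excluded (with the reason recorded in the
#' `"excluded"` attribute), mirroring the exclusion of family members with
#' insertions at the scored positions.
#'
#' @param family An [aligned_family()].
#' @param positions Reference positions to score
#'   (default `c("493", "517", "541")`).
#' @return Integer matrix (domains x positions) with row names; attribute
#'   `"excluded"` is a data frame of dropped sequences and reasons.
#' @export
build_score_matrix <- function(family,
                               positions = c("493", "517", "541")) {
  stopifnot(inherits(family, "aligned_family"))
  chars <- vapply(positions, function(p) .family_column(family, p),
                  character(length(family$seqs)))
  chars <- matrix(chars, nrow = length(family$seqs),
                  dimnames = list(names(family$seqs), positions))
  ok_code <- function(x) x %in% names(size_score_table())
  good <- apply(chars, 1L, function(r) all(ok_code(r)))
  excluded <- data.frame(name = rownames(chars)[!good],
                         reason = apply(chars[!good, , drop = FALSE], 1L,
                                        function(r) {
                                          bad <- r[!ok_code(r)][1L]
                                          if (bad == "-") "gap at scored column"
                                          else paste0("non-canonical code '",
                                                      bad, "'")
                                        }),
                         stringsAsFactors = FALSE)
  m <- apply(chars[good, , drop = FALSE], c(1L, 2L), size_score)
  storage.mode(m) <- "integer"
  attr(m, "excluded") <- excluded
  m
}

#' Principal component analysis of a size-score matrix
#'
#' Column-centered (and by default unit-variance-scaled) PCA by singular
#' value decomposition. Zero-variance columns are dropped with a warning
#' before scaling. Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param m Numeric matrix (domains x features), >= 3 rows.
#' @param scale. Unit-variance scaling (default TRUE; set FALSE for
#'   raw-centering mode).
#' @return An object of class `pca_result`: `scores`, `loadings`,
#'   `explained` (variance fractions summing to 1), `sdev`, `center`,
#'   `scale`, `degenerate` flag.
#' @export
run_pca <- function(m, scale. = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("too_few_rows: PCA needs >= 3 rows", call. = FALSE)
  v <- apply(m, 2L, stats::var)
  if (all(v == 0)) {
    return(structure(list(scores = matrix(0, nrow(m), 0L),
                          loadings = matrix(0, ncol(m), 0L),
                          explained = numeric(0), sdev = numeric(0),
                          center = colMeans(m), scale = rep(1, ncol(m)),
                          degenerate = TRUE),
                     class = "pca_result"))
  }
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev,
                 center = pc$center,
                 scale = if (isTRUE(scale.)) pc$scale else rep(1, ncol(m)),
                 degenerate = FALSE),
            class = "pca_result")
}

#' Two-group assignment on component scores
#'
#' k-means (best of `nstart` restarts, fixed seed) on the first two
#' component scores. Group labels are anchored: group 1 is the cluster
#' containing the reference row (when present), so that the "group 1 =
#' eclipsed-like, group 2 = staggered-like" semantics are stable; without
#' the reference, clusters are ordered by their first-component center.
#'
#' @param pca A `pca_result`.
#' @param k Number of groups (default 2; must not exceed the rows).
#' @param reference Row name anchoring group 1 (default `"JIP1"`).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Random restarts (default 20).
#' @return Integer vector of group labels (named by row).
#' @export
assign_groups <- function(pca, k = 2L, reference = "JIP1", seed = 42L,
                          nstart = 20L) {
  stopifnot(inherits(pca, "pca_result"))
  n <- nrow(pca$scores)
  if (k > n) stop("k_exceeds_rows", call. = FALSE)
  if (n == 1L) return(stats::setNames(1L, rownames(pca$scores)))
  x <- pca$scores[, seq_len(min(2L, ncol(pca$scores))), drop = FALSE]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  labels <- km$cluster
  if (!is.null(reference) && reference %in% rownames(x)) {
    ref_cl <- labels[[reference]]
    ord <- c(ref_cl, setdiff(sort(unique(labels)), ref_cl))
  } else {
    ord <- order(km$centers[, 1L])
  }
  out <- match(labels, ord)
  stats::setNames(as.integer(out), rownames(x))
}
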