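#' Dispersion dataset container
#'
#' Validates the tabular dispersion format: one row per measured point with
#' columns `dataset_id`, `spin`, `nucleus`, `field_mhz`, `relax_time_s`,
#' `nu_cpmg_hz`, `replicate_index` plus either the intensity pair
#' (`intensity`, `intensity_ref`) or the precomputed pair (`r2eff`,
#' `r2eff_err`) -- never both.
#'
#' @param df Data frame in one of the two modes.
#' @param mode `"intensity"` or `"r2eff"`; inferred from the columns when
#'   missing.
#' @return `df` with classes `dispersion_dataset`/`data.frame` and
#'   attribute `"mode"`.
#' @export
dispersion_dataset <- function(df, mode = NULL) {
  base_cols <- c("dataset_id", "spin", "nucleus", "field_mhz",
                 "relax_time_s", "nu_cpmg_hz", "replicate_index")
  stopifnot(is.data.frame(df))
  missing_base <- setdiff(base_cols, names(df))
  if (length(missing_base)) {
    stop("missing_column: ", paste(missing_base, collapse = ", "),
         call. = FALSE)
  }
  has_int <- all(c("intensity", "intensity_ref") %in% names(df))
  has_r2 <- all(c("r2eff", "r2eff_err") %in% names(df))
  if (has_int && has_r2) stop("mixed_modes: both intensity and r2eff ",
                              "columns present", call. = FALSE)
  if (!has_int && !has_r2) {
    stop("missing_column: need intensity/intensity_ref or r2eff/r2eff_err",
         call. = FALSE)
  }
  inferred <- if (has_int) "intensity" else "r2eff"
  if (!is.null(mode) && mode != inferred) {
    stop("mode_mismatch: declared '", mode, "' but columns say '",
         inferred, "'", call. = FALSE)
  }
  num_cols <- c("field_mhz", "relax_time_s", "nu_cpmg_hz",
                if (has_int) c("intensity", "intensity_ref")
                else c("r2eff", "r2eff_err"))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1L]
      stop("non_numeric_cell: column '", cc, "', row ", bad_row,
           call. = FALSE)
    }
  }
  if (has_int && any(df$intensity_ref <= 0)) {
    stop("invalid_reference: intensity_ref must be > 0", call. = FALSE)
  }
  if (has_r2 && any(df$r2eff_err < 0)) {
    stop("invalid_sigma: r2eff_err must be >= 0", call. = FALSE)
  }
  structure(df, class = c("dispersion_dataset", "data.frame"),
            mode = inferred)
}

#' Read a dispersion table from CSV
#'
#' @param path CSV path (UTF-8, dot decimal separator, exact header).
#' @return A [dispersion_dataset()].
#' @export
read_dispersion_table <- function(path) {
  if (!file.exists(path)) stop("file_not_found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  base_num <- intersect(c("field_mhz", "relax_time_s", "nu_cpmg_hz",
                          "intensity", "intensity_ref", "r2eff",
                          "r2eff_err"), names(df))
  for (cc in base_num) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !all(is.na(df[[cc]]))) {
      stop("non_numeric_cell: column '", cc, "', row ",
           which(is.na(v) & !is.na(df[[cc]]))[1L], call. = FALSE)
    }
    df[[cc]] <- v
  }
  if ("replicate_index" %in% names(df)) {
    df$replicate_index <- as.integer(df$replicate_index)
  }
  dispersion_dataset(df)
}

#' Write a dispersion dataset to CSV
#'
#' @param data A [dispersion_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_table <- function(data, path) {
  stopifnot(inherits(data, "dispersion_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an aligned FASTA family
#'
#' @param path Aligned FASTA path (equal gapped lengths; gap `-`).
#' @param ref_columns Named integer vector mapping reference positions to
#'   alignment columns (see [aligned_family()]).
#' @return An [aligned_family()].
#' @export
read_fasta <- function(path, ref_columns) {
  if (!file.exists(path)) stop("file_not_found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  aligned_family(seqs, ref_columns)
}

#' Write an aligned family to FASTA
#'
#' @param family An [aligned_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(family, path) {
  stopifnot(inherits(family, "aligned_family"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(family$seqs), path)
  invisible(path)
}

#' Structured report for a global dispersion fit
#'
#' JSON-serializable report with stable key ordering: input digest, model
#' configuration, fitted parameters with uncertainties, per-spin shift
#' differences, chi-square statistics, seeds and package version.
#' Regenerating from the same inputs and seeds reproduces the report
#' bit-identically (no timestamps are embedded).
#'
#' @param fit A `dispersion_fit`.
#' @param path Optional path; when given the report is written as
#'   pretty-printed JSON.
#' @return The report list, invisibly when writing.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dispersion_fit"))
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(fit$prep, tmp, row.names = FALSE)
  digest <- unname(tools::md5sum(tmp))
  rep <- list(
    format = "ringflipr-fit-report",
    package_version = as.character(utils::packageVersion("ringflipr")),
    input_digest = digest,
    model = list(type = "two-site exchange", engine = "closed-form",
                 shared = c("k_ex", "p_minor"),
                 per_spin = "ddelta", per_field = "r2_0"),
    parameters = list(
      k_ex_s1 = fit$params$k_ex,
      p_minor = fit$params$p_minor,
      k_ex_sigma = unname(fit$uncertainties["k_ex"]),
      p_minor_sigma = unname(fit$uncertainties["p_minor"])),
    ddelta_ppm = fit$params$ddelta,
    r2_0 = fit$r2_0,
    chisq = fit$chisq,
    red_chisq = fit$red_chisq,
    n_points = fit$n_points,
    n_par = fit$n_par,
    seed = fit$seed,
    mc_seed = if (is.null(fit$mc_seed)) NULL else fit$mc_seed
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(rep))
  }
  rep
}
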