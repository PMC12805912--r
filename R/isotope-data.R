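#' Read a delimited table of isotope records
#'
#' Reads one row per individual x tissue observation of (delta13C, delta15N)
#' with its grouping labels. The header must contain the seven columns
#' `individual_id`, `species`, `season`, `campaign`, `tissue`, `d13C`, `d15N`
#' (extra columns are kept). Comma and tab dialects are supported.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A tibble of validated isotope records, row order preserved.
#' @seealso [write_isotope_table()], [validate_isotope_records()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_isotope_table(simulate_isotopes(default_study_design(), seed = 1), f)
#' head(read_isotope_table(f))
#' @export
read_isotope_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "nichepart_io_error")
  }
  raw <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  missing <- setdiff(.required_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "nichepart_schema_error")
  }
  for (col in c("d13C", "d15N")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0L) {
      abort(sprintf("Non-numeric or non-finite %s value on data row %d ('%s').",
                    col, bad[1L], raw[[col]][bad[1L]]),
            class = "nichepart_parse_error")
    }
    raw[[col]] <- num
  }
  validate_isotope_records(tibble::as_tibble(raw))
}

#' Write isotope records to a delimited file
#'
#' @param records A data frame of isotope records (see [read_isotope_table()]).
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(records, path, delim = ",") {
  records <- validate_isotope_records(records)
  utils::write.table(as.data.frame(records), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a table of isotope records
#'
#' Enforces the record invariants: required columns present, finite isotope
#' values, known season levels, and uniqueness of
#' (individual_id, tissue, season) combinations.
#'
#' @param records A data frame with the isotope-record columns.
#' @return The records as a tibble (unchanged values).
#' @export
validate_isotope_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(.required_cols, names(records))
  if (length(missing) > 0L) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "nichepart_schema_error")
  }
  for (col in c("d13C", "d15N")) {
    if (!is.numeric(records[[col]]) || any(!is.finite(records[[col]]))) {
      abort(sprintf("Column %s must be finite numeric.", col),
            class = "nichepart_validation_error")
    }
  }
  bad_season <- setdiff(unique(records$season), .seasons)
  if (length(bad_season) > 0L) {
    abort(sprintf("Unknown season level(s): %s (expected %s).",
                  paste(bad_season, collapse = ", "),
                  paste(.seasons, collapse = ", ")),
          class = "nichepart_validation_error")
  }
  key <- paste(records$individual_id, records$tissue, records$season, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    abort(sprintf("Duplicate (individual_id, tissue, season) combination: %s",
                  gsub("\r", " / ", dup)),
          class = "nichepart_validation_error")
  }
  records
}

#' Z-score standardise isotope values within tissue
#'
#' Standardises `d13C` and `d15N` to mean 0 and SD 1 (sample SD, n - 1
#' divisor) within each tissue, pooling across species and, by default,
#' seasons. Standardisation removes systematic tissue offsets (different
#' discrimination factors and integration windows) while preserving species
#' and season contrasts within tissue up to an affine transform. The
#' transform used is stored so it can be re-applied or inverted.
#'
#' @param records A data frame of isotope records.
#' @param per_season If `TRUE`, standardise within tissue x season instead of
#'   pooling seasons into one transform per tissue. Default `FALSE`.
#' @return A tibble of class `"nichepart_std"` with columns `z13C`, `z15N`
#'   added; the per-tissue `(mean, sd)` table is available via
#'   [standardization_table()].
#' @examples
#' rec <- simulate_isotopes(default_study_design(), seed = 1)
#' std <- standardize(rec)
#' standardization_table(std)
#' @export
standardize <- function(records, per_season = FALSE) {
  records <- validate_isotope_records(records)
  keys <- if (per_season) c("tissue", "season") else "tissue"
  tab <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_d13C = mean(.data$d13C), sd_d13C = sd(.data$d13C),
      mean_d15N = mean(.data$d15N), sd_d15N = sd(.data$d15N),
      .groups = "drop"
    )
  degenerate <- tab |>
    dplyr::filter(.data$n < 2L | .data$sd_d13C == 0 | .data$sd_d15N == 0)
  if (nrow(degenerate) > 0L) {
    abort(sprintf(
      "Degenerate tissue(s) for standardisation (single record or zero variance): %s",
      paste(degenerate$tissue, collapse = ", ")),
      class = "nichepart_degenerate_tissue_error")
  }
  out <- records |>
    dplyr::left_join(tab, by = keys) |>
    dplyr::mutate(
      z13C = (.data$d13C - .data$mean_d13C) / .data$sd_d13C,
      z15N = (.data$d15N - .data$mean_d15N) / .data$sd_d15N
    ) |>
    dplyr::select(-dplyr::all_of(c("n", "mean_d13C", "sd_d13C",
                                   "mean_d15N", "sd_d15N")))
  attr(out, "standardization") <- tab
  attr(out, "per_season") <- per_season
  class(out) <- c("nichepart_std", class(out))
  out
}

#' Retrieve the standardisation table of a standardised dataset
#'
#' @param x An object returned by [standardize()].
#' @return A tibble with one row per tissue (or tissue x season) giving the
#'   mean and SD applied to each isotope.
#' @export
standardization_table <- function(x) {
  tab <- attr(x, "standardization")
  if (is.null(tab)) {
    abort("`x` carries no standardisation table; was it created by standardize()?",
          class = "nichepart_validation_error")
  }
  tab
}

#' Apply a stored standardisation transform to raw records
#'
#' Reproduces the `z13C`/`z15N` values of [standardize()] on (possibly new)
#' raw records using a previously computed table.
#'
#' @param records A data frame of isotope records.
#' @param table A standardisation table from [standardization_table()].
#' @return A tibble with `z13C` and `z15N` columns added.
#' @export
apply_standardization <- function(records, table) {
  records <- validate_isotope_records(records)
  keys <- intersect(c("tissue", "season"), names(table))
  missing <- setdiff(unique(records$tissue), unique(table$tissue))
  if (length(missing) > 0L) {
    abort(sprintf("Tissue(s) absent from standardisation table: %s",
                  paste(missing, collapse = ", ")),
          class = "nichepart_validation_error")
  }
  records |>
    dplyr::left_join(table, by = keys) |>
    dplyr::mutate(
      z13C = (.data$d13C - .data$mean_d13C) / .data$sd_d13C,
      z15N = (.data$d15N - .data$mean_d15N) / .data$sd_d15N
    ) |>
    dplyr::select(-dplyr::all_of(c("n", "mean_d13C", "sd_d13C",
                                   "mean_d15N", "sd_d15N")))
}
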