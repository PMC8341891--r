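#' Column mapping for measurement tables
#'
#' Museum spreadsheets rarely share column names. A schema maps the four
#' required roles onto the column names actually present in a CSV file.
#'
#' @param specimen_id,feature,value,distorted Column names in the source
#'   file holding, respectively: the specimen label, the feature
#'   (measurement) name, the measurement in millimetres, and the 0/1
#'   distortion flag.
#'
#' @return A named character vector usable as the `schema` argument of
#'   [read_measurements()].
#' @export
#' @examples
#' measurement_schema(value = "length_mm", distorted = "deformed")
measurement_schema <- function(specimen_id = "specimen_id",
                               feature = "feature",
                               value = "value_mm",
                               distorted = "distorted") {
  c(specimen_id = specimen_id, feature = feature,
    value = value, distorted = distorted)
}

#' Read and validate a specimen measurement table
#'
#' Reads a CSV with one row per specimen-by-feature measurement. Each
#' measurement carries its own distortion score, because fossilisation
#' does not deform a specimen uniformly: a skull can have an intact snout
#' and a crushed braincase. Rows whose measurement cell is blank (the
#' feature was broken or not visible, so no measurement was taken) are
#' dropped and counted.
#'
#' @param path Path to a CSV file (comma-separated, header row, UTF-8).
#' @param schema Named character vector mapping the roles
#'   `specimen_id`, `feature`, `value`, `distorted` to column names in the
#'   file; see [measurement_schema()].
#' @param quiet Suppress the message reporting dropped rows.
#'
#' @return A tibble with columns `specimen_id`, `feature`, `value_mm` and
#'   `distorted` (integer 0/1), of class `"measurement_tbl"`. The number
#'   of dropped blank rows is available as `attr(x, "n_dropped")`.
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_cranial_measurements.csv",
#'                     package = "distallom")
#' head(read_measurements(path))
read_measurements <- function(path, schema = measurement_schema(),
                              quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: column(s) ",
                 paste0("`", missing_cols, "`", collapse = ", "),
                 " not found in ", path))
  }
  df <- tibble(
    specimen_id = as.character(raw[[schema[["specimen_id"]]]]),
    feature     = as.character(raw[[schema[["feature"]]]]),
    value_mm    = as.numeric(raw[[schema[["value"]]]]),
    distorted   = raw[[schema[["distorted"]]]]
  )
  keep <- !is.na(df$value_mm)
  n_dropped <- sum(!keep)
  df <- df[keep, ]
  if (n_dropped > 0 && !quiet) {
    inform(paste0("Dropped ", n_dropped,
                  " row(s) with a blank measurement cell."))
  }
  out <- validate_measurements(df)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "provenance") <- path
  out
}

#' Validate an in-memory measurement table
#'
#' Applies the same contract as [read_measurements()] to a data frame
#' already in memory (e.g. simulator output converted with
#' [sim_to_measurements()]).
#'
#' @param df Data frame with columns `specimen_id`, `feature`, `value_mm`,
#'   `distorted`.
#' @return The validated table as a `"measurement_tbl"` tibble.
#' @export
validate_measurements <- function(df) {
  need <- c("specimen_id", "feature", "value_mm", "distorted")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("measurement table is missing column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", ")))
  }
  df <- as_tibble(df)[need]
  if (nrow(df) == 0) abort("measurement table is empty.")
  bad_val <- which(!is.na(df$value_mm) & df$value_mm <= 0)
  if (length(bad_val) > 0) {
    i <- bad_val[1]
    abort(paste0("non-positive measurement for specimen `",
                 df$specimen_id[i], "`, feature `", df$feature[i],
                 "` (value ", df$value_mm[i], " mm)."))
  }
  flag <- df$distorted
  if (is.logical(flag)) flag <- as.integer(flag)
  flag <- suppressWarnings(as.numeric(flag))
  if (anyNA(flag) || !all(flag %in% c(0, 1))) {
    abort("`distorted` must be 0 or 1 for every measurement.")
  }
  df$distorted <- as.integer(flag)
  dup <- duplicated(df[c("specimen_id", "feature")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0("duplicate measurement: specimen `", df$specimen_id[i],
                 "`, feature `", df$feature[i], "`."))
  }
  class(df) <- c("measurement_tbl", class(df))
  df
}

#' Pair two features into log-scale regression inputs
#'
#' Builds the regression table for an allometric fit: one row per
#' specimen that has both the reference feature (e.g. skull or femur
#' length) and the focal feature (e.g. snout length or midshaft
#' diameter). The power-law scaling relationship is linear after log
#' transformation, so both measurements are returned as log10 values.
#' Missing measurements are handled pairwise per feature pair, not by
#' dropping whole specimens.
#'
#' The distortion flag of a pair is that of the focal (`y`) measurement:
#' reference lengths (total skull or femur length) are typically robust
#' to deformation, and it is distortion of the focal measurement that
#' inflates residual variance. If a reference measurement is itself
#' flagged, a warning is raised and the focal flag is kept.
#'
#' @param table A `"measurement_tbl"` (see [read_measurements()]).
#' @param x_feature,y_feature Feature names for the reference (x) and
#'   focal (y) measurement.
#'
#' @return A tibble with columns `specimen_id`, `x`, `y` (log10 mm) and
#'   `c` (integer distortion flag of the focal measurement).
#' @export
to_log_pairs <- function(table, x_feature, y_feature) {
  table <- validate_measurements(table)
  xs <- dplyr::filter(table, .data$feature == x_feature)
  ys <- dplyr::filter(table, .data$feature == y_feature)
  if (nrow(xs) == 0) abort(paste0("feature `", x_feature, "` not present."))
  if (nrow(ys) == 0) abort(paste0("feature `", y_feature, "` not present."))
  pairs <- dplyr::inner_join(
    dplyr::select(xs, "specimen_id", x_mm = "value_mm",
                  x_distorted = "distorted"),
    dplyr::select(ys, "specimen_id", y_mm = "value_mm", c = "distorted"),
    by = "specimen_id")
  if (nrow(pairs) < 3) {
    abort(paste0("insufficient data: only ", nrow(pairs),
                 " specimen(s) have both `", x_feature, "` and `",
                 y_feature, "` (need at least 3)."))
  }
  if (any(pairs$x_distorted == 1)) {
    warn(paste0(sum(pairs$x_distorted == 1), " reference (`", x_feature,
                "`) measurement(s) are flagged distorted; the pair keeps ",
                "the focal-measurement flag."))
  }
  dplyr::transmute(pairs, .data$specimen_id,
                   x = log10(.data$x_mm), y = log10(.data$y_mm),
                   c = as.integer(.data$c))
}

#' Shapiro-Wilk normality check
#'
#' Screens a measurement vector for non-normality before regression or
#' bootstrap work, as is standard for small morphometric samples.
#' Delegates to [stats::shapiro.test()].
#'
#' @param values Numeric vector, 3 to 5000 values, not all identical.
#' @return A one-row tibble with columns `statistic` (W), `p_value`, `n`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires between 3 and 5000 values.")
  }
  if (diff(range(values)) == 0) {
    abort("degenerate input: all values are identical.")
  }
  sw <- stats::shapiro.test(values)
  tibble(statistic = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Per-feature normality screen of a measurement table
#'
#' Runs [normality_check()] on the log10 measurements of every feature
#' with at least 3 non-constant values; features that cannot be tested
#' are reported with `NA` and a reason.
#'
#' @param table A `"measurement_tbl"`.
#' @param log10_scale Test log10 measurements (the scale the regression
#'   uses) rather than raw millimetres.
#' @return A tibble with one row per feature: `feature`, `n`,
#'   `statistic`, `p_value`, `note`.
#' @export
normality_screen <- function(table, log10_scale = TRUE) {
  table <- validate_measurements(table)
  one <- function(v) {
    if (log10_scale) v <- log10(v)
    if (length(v) < 3) {
      return(tibble(statistic = NA_real_, p_value = NA_real_,
                    note = "fewer than 3 values"))
    }
    if (diff(range(v)) == 0) {
      return(tibble(statistic = NA_real_, p_value = NA_real_,
                    note = "constant values"))
    }
    res <- normality_check(v)
    tibble(statistic = res$statistic, p_value = res$p_value, note = NA_character_)
  }
  table |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n = dplyr::n(), one(.data$value_mm),
                     .groups = "drop")
}
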