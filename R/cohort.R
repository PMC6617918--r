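COHORT_REQUIRED <- c("patient_id", "surgeon_interface_pct",
                     "patient_interface_pct", "destination_altitude_m")

COHORT_COLUMNS <- c("patient_id", "age", "sex", "surgeon_interface_pct",
                    "patient_interface_pct", "origin_altitude_m",
                    "destination_altitude_m", "travel_mode",
                    "visual_acuity", "likert_item1", "likert_item2")

TRAVEL_MODES <- c("airplane", "train_highspeed", "train_ordinary", "car_bus")

# default origin: the study site sits essentially at sea level (10 m)
DEFAULT_ORIGIN_M <- 10

validate_cohort_rows <- function(df) {
  checks <- list(
    surgeon_interface_pct = function(x)
      is.na(x) | (x >= 0 & x <= 100),
    patient_interface_pct = function(x)
      is.na(x) | (x >= 0 & x <= 100),
    origin_altitude_m = function(x)
      is.na(x) | (x >= ALTITUDE_RANGE[1] & x <= ALTITUDE_RANGE[2]),
    destination_altitude_m = function(x)
      is.na(x) | (x >= ALTITUDE_RANGE[1] & x <= ALTITUDE_RANGE[2]),
    travel_mode = function(x) is.na(x) | x %in% TRAVEL_MODES,
    likert_item1 = function(x) is.na(x) | x %in% 1:5,
    likert_item2 = function(x) is.na(x) | x %in% 1:5)
  problems <- purrr::imap(checks, function(f, col) {
    if (!col %in% names(df)) return(integer(0))
    which(!f(df[[col]]))
  })
  problems <- purrr::compact(problems[lengths(problems) > 0])
  if (length(problems) > 0) {
    msg <- purrr::imap_chr(problems, function(rows, col)
      sprintf("field `%s`: invalid value in row(s) %s", col,
              paste(rows, collapse = ", ")))
    abort(paste0("Cohort validation failed:\n  ",
                 paste(msg, collapse = "\n  ")),
          class = "gasrisk_validation_error")
  }
  if (anyDuplicated(df$patient_id)) {
    abort("`patient_id` values must be unique.",
          class = "gasrisk_validation_error")
  }
  invisible(df)
}

new_cohort <- function(df, provenance) {
  structure(df, class = c("gasrisk_cohort", class(tibble())),
            provenance = provenance)
}

#' Read and validate a cohort CSV
#'
#' Expects a UTF-8 comma-separated file with a header row; columns may be
#' in any order and unknown extra columns are preserved. Interface heights
#' are stored as percentages 0-100. When `origin_altitude_m` is absent it
#' defaults to 10 m (a sea-level tertiary centre). Rows violating the
#' schema are reported with their row number and offending field.
#'
#' @param path Path to the CSV file.
#' @return A cohort tibble (class `gasrisk_cohort`) with a `provenance`
#'   attribute recording the source path.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cohort file not found: %s", path),
          class = "gasrisk_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Cohort CSV is missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "gasrisk_schema_error")
  }
  if (nrow(df) == 0L) {
    abort("Cohort must be nonempty.", class = "gasrisk_validation_error")
  }
  if (!"origin_altitude_m" %in% names(df)) {
    df$origin_altitude_m <- DEFAULT_ORIGIN_M
  }
  df$patient_id <- as.character(df$patient_id)
  validate_cohort_rows(df)
  new_cohort(df, provenance = list(source = path,
                                   read_at = format(Sys.time()),
                                   n = nrow(df)))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the write -> read round trip preserves all
#' schema fields.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' Per-patient expansion risk, both judges
#'
#' Runs the full risk assessment once with the surgeon-judged and once
#' with the patient-judged interface height for every cohort row.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @param geom,atm,policy Model components; see [assess_risk()].
#' @return A tibble with `nrow(cohort) * 2` rows: `patient_id`, `judge`
#'   (`"surgeon"`/`"patient"`), then the [assess_risk()] columns.
#' @export
cohort_risk_table <- function(cohort,
                              geom = vitreous_geometry(),
                              atm = atmosphere_model(),
                              policy = risk_policy()) {
  df <- as_tibble(cohort)
  if (nrow(df) == 0L) {
    abort("Cohort must be nonempty.", class = "gasrisk_validation_error")
  }
  long <- df |>
    dplyr::select(dplyr::all_of(c("patient_id", "surgeon_interface_pct",
                                  "patient_interface_pct",
                                  "origin_altitude_m",
                                  "destination_altitude_m"))) |>
    tidyr::pivot_longer(
      cols = c("surgeon_interface_pct", "patient_interface_pct"),
      names_to = "judge", names_pattern = "(surgeon|patient)",
      values_to = "h_pct")
  res <- assess_risk(long$h_pct, long$origin_altitude_m,
                     long$destination_altitude_m, geom, atm, policy)
  dplyr::bind_cols(long[c("patient_id", "judge")], res)
}

#' Cohort-level summary of the risk table
#'
#' Median/range of the interface heights, destination altitudes and
#' expanded volumes, per judge, matching the descriptive format used for
#' skewed clinical variables.
#'
#' @param risk_table Output of [cohort_risk_table()].
#' @return A tibble with one row per judge and summary statistic.
#' @export
cohort_risk_summary <- function(risk_table) {
  risk_table |>
    dplyr::group_by(.data$judge) |>
    dplyr::reframe(
      dplyr::bind_rows(
        dplyr::mutate(summarize_range(.data$h_pct),
                      variable = "interface_pct"),
        dplyr::mutate(summarize_range(.data$delta_v),
                      variable = "delta_v_ml"))) |>
    dplyr::relocate("variable", .after = "judge")
}

#' Full interobserver agreement analysis of a cohort
#'
#' Bundles the cohort-level statistics: Bland-Altman bias and limits of
#' agreement between the surgeon- and patient-judged interface heights,
#' the two-sided Wilcoxon matched-pairs signed-rank test on the heights
#' and on the computed volume expansions, median/range summaries, the
#' destination-altitude summary, the travel-mode split, and Likert
#' tabulations.
#'
#' @param cohort A cohort data frame.
#' @param geom,atm,policy Model components; see [assess_risk()].
#' @param multiplier Limits-of-agreement multiplier; see [bland_altman()].
#' @return A list of class `cohort_agreement` with components
#'   `bland_altman`, `wilcoxon_heights`, `wilcoxon_delta_v`, `heights`,
#'   `delta_v`, `destination_altitude`, `travel_mode`, `likert`, `n`.
#' @export
cohort_agreement <- function(cohort,
                             geom = vitreous_geometry(),
                             atm = atmosphere_model(),
                             policy = risk_policy(),
                             multiplier = 1.96) {
  df <- as_tibble(cohort)
  risk <- cohort_risk_table(df, geom, atm, policy)
  wide_dv <- risk |>
    dplyr::select(dplyr::all_of(c("patient_id", "judge", "delta_v"))) |>
    tidyr::pivot_wider(names_from = "judge", values_from = "delta_v")
  heights <- dplyr::bind_rows(
    surgeon = summarize_range(df$surgeon_interface_pct),
    patient = summarize_range(df$patient_interface_pct),
    .id = "judge")
  delta_v <- risk |>
    dplyr::group_by(.data$judge) |>
    dplyr::reframe(summarize_range(.data$delta_v))
  modes <- if ("travel_mode" %in% names(df)) {
    df |>
      dplyr::mutate(mode_group = dplyr::if_else(
        grepl("^train", .data$travel_mode), "train", .data$travel_mode)) |>
      dplyr::count(.data$mode_group, name = "count") |>
      dplyr::mutate(proportion = .data$count / sum(.data$count))
  } else NULL
  likert <- purrr::map(
    purrr::keep(c("likert_item1", "likert_item2"), ~ .x %in% names(df)),
    ~ tabulate_likert(df[[.x]]))
  names(likert) <- purrr::keep(c("likert_item1", "likert_item2"),
                               ~ .x %in% names(df))
  structure(list(
    n = nrow(df),
    bland_altman = bland_altman(df, .data$surgeon_interface_pct,
                                .data$patient_interface_pct,
                                multiplier = multiplier),
    wilcoxon_heights = wilcoxon_signed_rank(df, .data$surgeon_interface_pct,
                                            .data$patient_interface_pct),
    wilcoxon_delta_v = wilcoxon_signed_rank(wide_dv, .data$surgeon,
                                            .data$patient),
    heights = heights,
    delta_v = delta_v,
    destination_altitude = summarize_range(df$destination_altitude_m),
    travel_mode = modes,
    likert = likert),
    class = "cohort_agreement")
}

#' @export
print.cohort_agreement <- function(x, ...) {
  cat(sprintf("<cohort_agreement> n = %d patients\n", x$n))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman bias %.2f%%, LoA [%.2f, %.2f]%%\n",
              ba$bias, ba$loa_low, ba$loa_high))
  cat(sprintf("  Wilcoxon on heights: P = %.2f (%s)\n",
              x$wilcoxon_heights$p_value, x$wilcoxon_heights$method))
  cat(sprintf("  Wilcoxon on expanded volumes: P = %.2f (%s)\n",
              x$wilcoxon_delta_v$p_value, x$wilcoxon_delta_v$method))
  invisible(x)
}

#' Serialise a cohort agreement report to JSON
#'
#' @param x A `cohort_agreement` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(x, path) {
  stopifnot(inherits(x, "cohort_agreement"))
  out <- list(
    n = x$n,
    bland_altman = glance(x$bland_altman),
    wilcoxon_heights = x$wilcoxon_heights,
    wilcoxon_delta_v = x$wilcoxon_delta_v,
    heights = x$heights,
    delta_v = x$delta_v,
    destination_altitude = x$destination_altitude,
    travel_mode = x$travel_mode,
    likert = x$likert)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
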