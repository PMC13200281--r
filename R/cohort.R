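#' Construct and validate a paired-device cohort table
#'
#' A cohort is a long-format tibble of thickness measurements with one row
#' per eye x device x visit x sector. Validation enforces the structural
#' invariants the downstream model relies on: finite non-negative visit
#' times, finite positive thicknesses, admissible device and sector labels,
#' and uniqueness of the (eye, device, time, sector) key. Rows violating an
#' invariant are reported with row numbers; nothing is dropped silently.
#'
#' @param x A data frame with columns `eye_id`, `device`
#'   (`"spectralis"`/`"cirrus"`, case-insensitive), `t_years`, `sector`
#'   (`"G"`, `"1"`..`"12"`), `thickness_um`, and optionally `quality_ok`
#'   (logical, defaults to `TRUE`).
#' @param min_visits Minimum number of distinct visit times required per eye
#'   (the study design used at least 4 scan pairs). Set to 0 to disable.
#' @return A validated cohort tibble (class `rnfl_cohort`), rows ordered by
#'   eye, device, time, sector.
#' @export
as_rnfl_cohort <- function(x, min_visits = 4L) {
  x <- tibble::as_tibble(x)
  required <- c("eye_id", "device", "t_years", "sector", "thickness_um")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"quality_ok" %in% names(x)) x$quality_ok <- TRUE

  x$eye_id <- as.character(x$eye_id)
  x$device <- tolower(as.character(x$device))
  x$sector <- as.character(x$sector)
  x$t_years <- as.numeric(x$t_years)
  x$thickness_um <- as.numeric(x$thickness_um)
  x$quality_ok <- as.logical(x$quality_ok)

  bad <- which(
    !x$device %in% device_levels() |
      !x$sector %in% sector_levels() |
      !is.finite(x$t_years) | x$t_years < 0 |
      !is.finite(x$thickness_um) | x$thickness_um <= 0 |
      is.na(x$quality_ok)
  )
  if (length(bad) > 0) {
    stop("cohort rows violate invariants (device/sector label, ",
         "non-negative finite time, positive finite thickness): rows ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }

  key <- paste(x$eye_id, x$device, format(x$t_years, digits = 15), x$sector)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (eye_id, device, t_years, sector) keys: ",
         paste(utils::head(key[dup], 5L), collapse = "; "),
         if (sum(dup) > 5L) " ..." else "", call. = FALSE)
  }

  if (min_visits > 0) {
    nv <- x |>
      dplyr::distinct(.data$eye_id, .data$t_years) |>
      dplyr::count(.data$eye_id)
    short <- nv$eye_id[nv$n < min_visits]
    if (length(short) > 0) {
      stop("eyes with fewer than ", min_visits, " visits: ",
           paste(utils::head(short, 10L), collapse = ", "),
           if (length(short) > 10L) " ..." else "", call. = FALSE)
    }
  }

  x <- dplyr::arrange(x, .data$eye_id, .data$device, .data$t_years,
                      factor(.data$sector, levels = sector_levels()))
  class(x) <- c("rnfl_cohort", class(x))
  x
}

#' Read a cohort from a long-format CSV file
#'
#' The file must contain columns for eye, device, time (either `t_years` or
#' an ISO-8601 `visit_date`, converted per eye to years since first visit),
#' sector and thickness. Column names can be remapped through `schema`.
#'
#' @param path Path to a delimited text file.
#' @param schema Named character vector mapping canonical column names
#'   (`eye_id`, `device`, `t_years`, `visit_date`, `sector`, `thickness_um`,
#'   `quality_ok`) to the file's column names; only names that differ need
#'   to be listed.
#' @param min_visits Passed to [as_rnfl_cohort()].
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema = NULL, min_visits = 4L) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        stop("schema maps ", canon, " to missing column ", schema[[canon]],
             call. = FALSE)
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  if (!"t_years" %in% names(df)) {
    if ("visit_date" %in% names(df)) {
      df <- dates_to_years(df)
    } else {
      stop("cohort file needs a t_years or visit_date column", call. = FALSE)
    }
  }
  as_rnfl_cohort(df, min_visits = min_visits)
}

#' Write a cohort to CSV
#'
#' Emits a header and deterministic row order (eye, device, time, sector) so
#' that repeated writes of the same cohort are byte-identical.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- dplyr::arrange(cohort, .data$eye_id, .data$device, .data$t_years,
                           factor(.data$sector, levels = sector_levels()))
  out <- cohort[, c("eye_id", "device", "t_years", "sector",
                    "thickness_um", "quality_ok")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Re-express visit times as years since each eye's first retained visit
#'
#' Subtracts, per eye, the earliest visit time from all of that eye's times
#' (both devices share the eye's time axis because scans were acquired in
#' the same session). Idempotent: applying it twice equals applying it once.
#'
#' @param cohort A cohort tibble.
#' @return The cohort with `t_years` baseline-anchored per eye.
#' @export
align_time_axis <- function(cohort) {
  out <- cohort |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::mutate(t_years = .data$t_years - min(.data$t_years)) |>
    dplyr::ungroup()
  class(out) <- unique(c("rnfl_cohort", class(out)))
  out
}

#' @export
print.rnfl_cohort <- function(x, ...) {
  n_eyes <- dplyr::n_distinct(x$eye_id)
  cat("<rnfl_cohort> ", n_eyes, " eyes, ", nrow(x), " measurements, sectors: ",
      paste(sort(unique(x$sector)), collapse = " "), "\n", sep = "")
  NextMethod()
}
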