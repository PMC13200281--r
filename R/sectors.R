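#' Admissible sector labels
#'
#' RNFL measurements are summarized globally (`"G"`, the mean over the whole
#' peripapillary circle) and in 12 clock-hour sectors labelled `"1"` to
#' `"12"` in right-eye format: clock hour 12 is superior and numbering
#' proceeds clockwise.
#'
#' @return Character vector of the 13 admissible sector labels, `"G"` first.
#' @export
#' @examples
#' sector_levels()
sector_levels <- function() {
  c("G", as.character(1:12))
}

#' Device labels
#'
#' @return Character vector of the two device labels, Spectralis first.
#' @export
device_levels <- function() {
  c("spectralis", "cirrus")
}

#' Number of A-scans in a circle-scan profile
#' @keywords internal
PROFILE_LENGTH <- 768L
PIXELS_PER_SECTOR <- 64L

#' Aggregate a 768-point circle-scan profile into clock-hour sectors
#'
#' A Spectralis peripapillary circle scan exports 768 thickness values
#' (A-scans). These are divided into 12 contiguous blocks of 64 pixels, each
#' block averaged into one clock-hour thickness; the global value `G` is the
#' mean over all 768 pixels. By construction the mean of the 12 sector values
#' equals `G` exactly (up to floating point), because all blocks have equal
#' size.
#'
#' The exported profile's pixel 0 position is not standardized, so the anchor
#' is declared explicitly: `anchor_hour` names the clock hour assigned to the
#' first 64-pixel block (pixels 1--64). The default anchor is clock hour 9,
#' the temporal midline in right-eye format, matching the usual TSNIT export
#' convention; pixels proceed clockwise in right-eye orientation, so
#' successive blocks map to hours 9, 10, 11, 12, 1, ...
#'
#' @param values Numeric vector of exactly 768 finite, non-negative
#'   thicknesses (micrometers).
#' @param anchor_hour Integer in 1..12; the clock hour of the first block.
#' @return A tibble with columns `sector` (`"G"`, `"1"`..`"12"`) and
#'   `thickness_um`, 13 rows, `G` first then hours 1..12.
#' @export
#' @examples
#' p <- rep(80, 768)
#' aggregate_profile(p) # every sector 80
aggregate_profile <- function(values, anchor_hour = 9L) {
  if (length(values) != PROFILE_LENGTH) {
    stop("profile must have exactly ", PROFILE_LENGTH, " values, got ",
         length(values), call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("profile values must be finite and non-negative", call. = FALSE)
  }
  anchor_hour <- as.integer(anchor_hour)
  if (length(anchor_hour) != 1L || is.na(anchor_hour) ||
      anchor_hour < 1L || anchor_hour > 12L) {
    stop("anchor_hour must be a single integer in 1..12", call. = FALSE)
  }
  block_means <- colMeans(matrix(values, nrow = PIXELS_PER_SECTOR))
  hours <- ((anchor_hour - 1L + 0:11) %% 12L) + 1L
  sector_vals <- numeric(12)
  sector_vals[hours] <- block_means
  tibble::tibble(
    sector = sector_levels(),
    thickness_um = c(mean(values), sector_vals)
  )
}

#' Aggregate a table of circle-scan profiles into sector measurements
#'
#' Takes one row per visit with 768 profile columns and returns long-format
#' sector measurements ready to combine into a cohort table.
#'
#' @param profiles A data frame with columns `eye_id`, `t_years` (or
#'   `visit_date`), and 768 numeric profile columns (all remaining columns,
#'   in pixel order).
#' @param anchor_hour Passed to [aggregate_profile()].
#' @return A tibble with columns `eye_id`, `t_years`, `sector`,
#'   `thickness_um`, 13 rows per input row.
#' @export
aggregate_profiles <- function(profiles, anchor_hour = 9L) {
  profiles <- tibble::as_tibble(profiles)
  if (!"eye_id" %in% names(profiles)) {
    stop("profiles must have an eye_id column", call. = FALSE)
  }
  if (!"t_years" %in% names(profiles)) {
    if ("visit_date" %in% names(profiles)) {
      profiles <- dates_to_years(profiles)
    } else {
      stop("profiles must have a t_years or visit_date column", call. = FALSE)
    }
  }
  value_cols <- setdiff(names(profiles), c("eye_id", "t_years", "visit_date"))
  if (length(value_cols) != PROFILE_LENGTH) {
    stop("expected ", PROFILE_LENGTH, " profile value columns, found ",
         length(value_cols), call. = FALSE)
  }
  purrr::pmap_dfr(
    list(profiles$eye_id, profiles$t_years,
         seq_len(nrow(profiles))),
    function(eye, t, i) {
      vals <- as.numeric(profiles[i, value_cols])
      out <- aggregate_profile(vals, anchor_hour = anchor_hour)
      tibble::tibble(eye_id = eye, t_years = t,
                     sector = out$sector, thickness_um = out$thickness_um)
    }
  )
}

# convert visit_date (ISO-8601) to per-eye years since first visit
dates_to_years <- function(df) {
  dates <- if (inherits(df$visit_date, "Date")) df$visit_date else
    as.Date(as.character(df$visit_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("visit_date contains values not parseable as ISO-8601 dates",
         call. = FALSE)
  }
  df$t_years <- as.numeric(dates - ave(dates, df$eye_id, FUN = min)) / 365.25
  df
}
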