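#' Robust outlier screening of longitudinal thickness series
#'
#' Screens every (eye, sector, device) series for gross outliers against a
#' robust linear trend. The rule, per series:
#'
#' 1. Fit a least-median-of-squares (LMS) line: among the lines through every
#'    pair of observations, take the one minimising the median absolute
#'    residual. With fewer than half the points contaminated, the LMS line
#'    tracks the clean trend even when two spikes fall in a short series.
#' 2. Reweighted least squares: points whose LMS residual exceeds
#'    `3 * s_trim` (with `s_trim` the small-sample-inflated LMS scale
#'    `1.4826 * (1 + 5/(n - 2)) * sqrt(median(res^2))` of Rousseeuw) are set
#'    aside and an ordinary least-squares line is refit on the remainder,
#'    restoring efficiency on clean series.
#' 3. The series scale is the larger of the degrees-of-freedom-corrected LMS
#'    scale and the inlier residual SD of the refit line.
#' 4. Because short series can under-estimate their own noise, the scale is
#'    floored at the median of all series scales in the same (sector, device)
#'    stratum, pooling measurement-noise information across eyes.
#' 5. An observation is flagged when its absolute residual from the refit
#'    line exceeds `k` times the floored scale.
#'
#' Series shorter than `min_n` observations are never flagged. The rule is
#' deterministic, invariant to adding a constant to all thicknesses, and
#' equivariant under time shifts.
#'
#' The global series (`sector == "G"`) is screened on its own values,
#' independently of the clock-hour sectors.
#'
#' @param cohort A cohort tibble (see [as_rnfl_cohort()]).
#' @param k Robustness multiplier on the pooled scale (default 4).
#' @param min_n Minimum series length to screen (default 4, the study's
#'   minimum scan-pair count).
#' @param abs_floor Absolute scale floor (micrometers) guarding against
#'   flagging floating point noise on perfectly linear series.
#' @return A tibble of flags with columns `eye_id`, `t_years`, `sector`,
#'   `device`, `thickness_um`, `residual`.
#' @export
flag_outliers <- function(cohort, k = 4, min_n = 4L, abs_floor = 1e-6) {
  per <- cohort |>
    dplyr::group_by(.data$eye_id, .data$sector, .data$device) |>
    dplyr::group_modify(function(d, g) {
      if (nrow(d) < min_n) {
        return(tibble::tibble(t_years = d$t_years,
                              thickness_um = d$thickness_um,
                              residual = NA_real_, scale = NA_real_))
      }
      fit <- robust_line(d$t_years, d$thickness_um)
      tibble::tibble(t_years = d$t_years, thickness_um = d$thickness_um,
                     residual = fit$residual, scale = fit$scale)
    }) |>
    dplyr::ungroup()
  scales <- per |>
    dplyr::distinct(.data$eye_id, .data$sector, .data$device, .data$scale) |>
    dplyr::filter(!is.na(.data$scale)) |>
    dplyr::group_by(.data$sector, .data$device) |>
    dplyr::summarise(pooled_scale = stats::median(.data$scale),
                     .groups = "drop")
  per |>
    dplyr::left_join(scales, by = c("sector", "device")) |>
    dplyr::filter(!is.na(.data$residual),
                  abs(.data$residual) >
                    k * pmax(.data$scale, .data$pooled_scale, abs_floor)) |>
    dplyr::select("eye_id", "t_years", "sector", "device",
                  "thickness_um", "residual")
}

# Least-median-of-squares line over all point pairs.
lms_line <- function(t, y) {
  stopifnot(length(t) >= 2)
  ij <- utils::combn(length(t), 2)
  best <- list(slope = 0, intercept = stats::median(y))
  best_crit <- stats::median(abs(y - best$intercept))
  for (p in seq_len(ncol(ij))) {
    i <- ij[1, p]; j <- ij[2, p]
    if (t[i] == t[j]) next
    slope <- (y[j] - y[i]) / (t[j] - t[i])
    intercept <- y[i] - slope * t[i]
    crit <- stats::median(abs(y - intercept - slope * t))
    if (crit < best_crit) {
      best_crit <- crit
      best <- list(slope = slope, intercept = intercept)
    }
  }
  best
}

# LMS fit followed by reweighted least squares; returns residuals from the
# refit line and a per-series scale (see flag_outliers for the rule).
robust_line <- function(t, y) {
  n <- length(t)
  fit0 <- lms_line(t, y)
  res0 <- y - fit0$intercept - fit0$slope * t
  med_sq <- stats::median(res0^2)
  s_trim <- 1.4826 * (1 + 5 / (n - 2)) * sqrt(med_sq)
  s_lms <- 1.4826 * sqrt(med_sq) * sqrt(n / (n - 2))
  w <- abs(res0) <= 3 * max(s_trim, 1e-9)
  if (sum(w) >= 3 && length(unique(t[w])) >= 2) {
    cf <- stats::coef(stats::lm(y[w] ~ t[w]))
    res <- y - cf[[1]] - cf[[2]] * t
    nw <- sum(w)
    scale <- max(s_lms, stats::sd(res[w]) * sqrt(nw / (nw - 2)))
  } else {
    res <- res0
    scale <- s_lms
  }
  list(residual = res, scale = scale)
}

#' Remove flagged observations from both devices
#'
#' The paired-removal rule: when a sector measurement at a given visit is
#' flagged as an outlier on either device, the (eye, visit, sector) cell is
#' removed from both devices, keeping the two devices' retained data on an
#' identical support.
#'
#' @param cohort A cohort tibble.
#' @param flags A flags tibble from [flag_outliers()] (or a manually
#'   assembled one with columns `eye_id`, `t_years`, `sector`, `device`).
#' @return A list with elements `cohort` (the cleaned cohort) and `report`
#'   (class `rnfl_qc_report`): flags, removed pairs, and counts of cells
#'   flagged on Spectralis only, Cirrus only, or both.
#' @export
apply_paired_removal <- function(cohort, flags) {
  if (nrow(flags) > 0) {
    present <- dplyr::semi_join(
      flags, cohort, by = c("eye_id", "t_years", "sector", "device"))
    if (nrow(present) != nrow(flags)) {
      missing <- dplyr::anti_join(
        flags, cohort, by = c("eye_id", "t_years", "sector", "device"))
      stop("flags reference observations absent from the cohort, e.g. (",
           missing$eye_id[1], ", t=", missing$t_years[1], ", sector ",
           missing$sector[1], ", ", missing$device[1], ")", call. = FALSE)
    }
  }
  by_cell <- flags |>
    dplyr::distinct(.data$eye_id, .data$t_years, .data$sector, .data$device) |>
    dplyr::group_by(.data$eye_id, .data$t_years, .data$sector) |>
    dplyr::summarise(
      on_spectralis = any(.data$device == "spectralis"),
      on_cirrus = any(.data$device == "cirrus"),
      .groups = "drop"
    )
  counts <- c(
    spectralis_only = sum(by_cell$on_spectralis & !by_cell$on_cirrus),
    cirrus_only = sum(!by_cell$on_spectralis & by_cell$on_cirrus),
    both = sum(by_cell$on_spectralis & by_cell$on_cirrus)
  )
  removed_pairs <- by_cell[, c("eye_id", "t_years", "sector")]
  cleaned <- dplyr::anti_join(cohort, removed_pairs,
                              by = c("eye_id", "t_years", "sector"))
  class(cleaned) <- unique(c("rnfl_cohort", class(cleaned)))
  report <- structure(
    list(flags = flags, removed_pairs = removed_pairs, counts = counts),
    class = "rnfl_qc_report"
  )
  list(cohort = cleaned, report = report)
}

#' Screen and clean a cohort in one step
#'
#' Runs [flag_outliers()] and [apply_paired_removal()], optionally merging a
#' manual exclusion list (the "semi" part of semiautomated screening: a
#' reviewer can force-remove specific observations).
#'
#' @inheritParams flag_outliers
#' @param manual_exclusions Optional tibble with columns `eye_id`, `t_years`,
#'   `sector`, `device` of observations to remove regardless of the
#'   automatic rule.
#' @return As [apply_paired_removal()].
#' @export
qc_cohort <- function(cohort, k = 4, min_n = 4L, manual_exclusions = NULL) {
  flags <- flag_outliers(cohort, k = k, min_n = min_n)
  if (!is.null(manual_exclusions) && nrow(manual_exclusions) > 0) {
    manual <- tibble::as_tibble(manual_exclusions)
    manual$thickness_um <- NA_real_
    manual$residual <- NA_real_
    flags <- dplyr::bind_rows(flags, manual) |>
      dplyr::distinct(.data$eye_id, .data$t_years, .data$sector, .data$device,
                      .keep_all = TRUE)
  }
  apply_paired_removal(cohort, flags)
}

#' @export
print.rnfl_qc_report <- function(x, ...) {
  cat("<rnfl_qc_report> ", nrow(x$flags), " flags, ",
      nrow(x$removed_pairs), " cells removed from both devices\n",
      "  flagged on Spectralis only: ", x$counts[["spectralis_only"]],
      ", Cirrus only: ", x$counts[["cirrus_only"]],
      ", both: ", x$counts[["both"]], "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rnfl_qc_report <- function(x, ...) {
  x$flags
}
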