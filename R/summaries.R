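#' Tidy population-level posterior draws
#'
#' Extracts from a fit one row per posterior draw with the population means,
#' the log-residual-SD variances (the diagonal entries of Sigma needed for
#' the average residual SD), and the residual correlation. All derived
#' quantities downstream are computed draw-wise on this table and only then
#' summarized, never from marginal summaries.
#'
#' @param fit An `rnfl_fit`.
#' @return A tibble with columns `chain`, `draw`, `mu_alpha_spectralis`,
#'   `mu_alpha_cirrus`, `mu_beta_spectralis`, `mu_beta_cirrus`,
#'   `mu_lambda_spectralis`, `mu_lambda_cirrus`, `var_lambda_spectralis`,
#'   `var_lambda_cirrus`, `rho`.
#' @export
pop_draws <- function(fit) {
  cols <- c(mu_alpha_spectralis = "mu[1]", mu_alpha_cirrus = "mu[2]",
            mu_beta_spectralis = "mu[3]", mu_beta_cirrus = "mu[4]",
            mu_lambda_spectralis = "mu[5]", mu_lambda_cirrus = "mu[6]",
            var_lambda_spectralis = "Sigma[5,5]",
            var_lambda_cirrus = "Sigma[6,6]", rho = "rho")
  mats <- lapply(seq_along(fit$samples), function(ch) {
    m <- as.matrix(fit$samples[[ch]])[, cols, drop = FALSE]
    colnames(m) <- names(cols)
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = ch, draw = dplyr::row_number(), .before = 1)
  })
  dplyr::bind_rows(mats)
}

cri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE)
}

sign_verdict <- function(lower, upper, threshold = 0) {
  dplyr::case_when(
    upper < threshold ~ "negative",
    lower > threshold ~ "positive",
    TRUE ~ "null"
  )
}

#' Summarize one sector's posterior into the standard reporting table
#'
#' Produces, for each device, the posterior mean and equal-tailed 95%
#' credible interval of the population intercept (micrometers), rate of
#' change (micrometers/year) and average residual SD (micrometers), plus the
#' Spectralis - Cirrus differences of intercept and rate of change and the
#' Spectralis / Cirrus ratio of average residual SDs. Differences and ratios
#' are computed draw by draw and then summarized. The average residual SD is
#' the population mean of the lognormal eye-level residual-SD distribution,
#' `exp(mu_lambda + Sigma_lambda/2)` per draw.
#'
#' Verdicts follow the credible-interval decision rule: a quantity is
#' significantly negative (positive) when the upper (lower) 95% CrI limit is
#' below (above) 0; a ratio is significantly smaller (larger) when its upper
#' (lower) limit is below (above) 1.
#'
#' @param x An `rnfl_fit`, or a draws tibble as returned by [pop_draws()].
#' @param level Credible level (default 0.95).
#' @param sector Sector label recorded in the output (taken from the fit
#'   when `x` is a fit).
#' @return A tibble of class `rnfl_sector_summary` with columns `sector`,
#'   `quantity` (`intercept`/`roc`/`resid_sd`), `contrast` (`spectralis`,
#'   `cirrus`, `difference`, `ratio`), `mean`, `lower`, `upper`, `verdict`.
#' @export
summarize_sector <- function(x, level = 0.95, sector = NULL) {
  if (inherits(x, "rnfl_fit")) {
    if (!attr(x$diagnostics, "pass")) {
      warning("summarizing a fit whose convergence diagnostics failed",
              call. = FALSE)
    }
    sector <- x$sector
    d <- pop_draws(x)
  } else {
    d <- tibble::as_tibble(x)
    if (is.null(sector)) sector <- NA_character_
  }
  if (nrow(d) == 0) stop("no posterior draws to summarize", call. = FALSE)

  d <- d |>
    dplyr::mutate(
      resid_sd_spectralis = exp(.data$mu_lambda_spectralis +
                                  .data$var_lambda_spectralis / 2),
      resid_sd_cirrus = exp(.data$mu_lambda_cirrus +
                              .data$var_lambda_cirrus / 2),
      diff_intercept = .data$mu_alpha_spectralis - .data$mu_alpha_cirrus,
      diff_roc = .data$mu_beta_spectralis - .data$mu_beta_cirrus,
      ratio_resid_sd = .data$resid_sd_spectralis / .data$resid_sd_cirrus
    )

  row <- function(quantity, contrast, draws, threshold = 0) {
    ci <- cri(draws, level)
    tibble::tibble(sector = sector, quantity = quantity, contrast = contrast,
                   mean = mean(draws), lower = ci[1], upper = ci[2],
                   verdict = sign_verdict(ci[1], ci[2], threshold))
  }
  ratio_ci <- cri(d$ratio_resid_sd, level)
  ratio_row <- tibble::tibble(
    sector = sector, quantity = "resid_sd", contrast = "ratio",
    mean = mean(d$ratio_resid_sd), lower = ratio_ci[1], upper = ratio_ci[2],
    verdict = if (ratio_ci[2] < 1) "smaller" else
      if (ratio_ci[1] > 1) "larger" else "null"
  )
  out <- dplyr::bind_rows(
    row("intercept", "spectralis", d$mu_alpha_spectralis),
    row("intercept", "cirrus", d$mu_alpha_cirrus),
    row("intercept", "difference", d$diff_intercept),
    row("roc", "spectralis", d$mu_beta_spectralis),
    row("roc", "cirrus", d$mu_beta_cirrus),
    row("roc", "difference", d$diff_roc),
    row("resid_sd", "spectralis", d$resid_sd_spectralis),
    row("resid_sd", "cirrus", d$resid_sd_cirrus),
    ratio_row
  )
  class(out) <- c("rnfl_sector_summary", class(out))
  out
}

#' Classify each eye's rate of change from its posterior draws
#'
#' An eye's rate of change on a device is significantly negative when the
#' upper limit of the equal-tailed 95% credible interval of its eye-level
#' slope draws is below 0, significantly positive when the lower limit is
#' above 0, and null otherwise (equivalent to a one-sided posterior
#' probability of at least 0.975).
#'
#' @param fit An `rnfl_fit`.
#' @param level Credible level (default 0.95).
#' @return A tibble of class `rnfl_classification` with columns `eye_id`,
#'   `device`, `mean`, `lower`, `upper`, `verdict`; attribute `"sector"`.
#' @export
classify_slopes <- function(fit, level = 0.95) {
  out <- purrr::map_dfr(device_levels(), function(dev) {
    m <- eye_beta_draws(fit, dev)
    q <- apply(m, 2, cri, level = level)
    tibble::tibble(eye_id = colnames(m), device = dev,
                   mean = colMeans(m), lower = q[1, ], upper = q[2, ],
                   verdict = sign_verdict(q[1, ], q[2, ]))
  })
  attr(out, "sector") <- fit$sector
  class(out) <- c("rnfl_classification", class(out))
  out
}

#' Proportions of significantly progressing (and improving) eyes
#'
#' @param classification A tibble from [classify_slopes()].
#' @return A tibble with one row per device x direction: `n_significant`,
#'   `n_eyes` (the sector's analyzed eyes, the denominator), `proportion`.
#' @export
slope_proportions <- function(classification) {
  stopifnot(nrow(classification) >= 1)
  classification |>
    dplyr::group_by(.data$device) |>
    dplyr::summarise(
      negative = sum(.data$verdict == "negative"),
      positive = sum(.data$verdict == "positive"),
      n_eyes = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("negative", "positive"),
                        names_to = "direction", values_to = "n_significant") |>
    dplyr::mutate(proportion = .data$n_significant / .data$n_eyes) |>
    dplyr::select("device", "direction", "n_significant", "n_eyes",
                  "proportion") |>
    dplyr::arrange(.data$direction,
                   factor(.data$device, levels = device_levels()))
}

#' Bayesian McNemar comparison of paired proportions from cell counts
#'
#' Places a Dirichlet posterior on the probabilities of the 2x2 paired
#' significance table (both devices significant; Spectralis only; Cirrus
#' only; neither) and reports the posterior of the difference in marginal
#' proportions, `p_S - p_C = p10 - p01`, which depends on the discordant
#' cells only. The posterior is summarized by Monte Carlo with a fixed
#' internal seed; the comparison is significant when the 95% CrI of the
#' difference excludes 0.
#'
#' @param counts Named integer vector with elements `both`,
#'   `spectralis_only`, `cirrus_only`, `neither`.
#' @param direction Which verdict is being compared, `"negative"` or
#'   `"positive"` (recorded in the output).
#' @param prior Dirichlet concentration for the four cells (default
#'   `c(1, 1, 1, 1)`, uniform).
#' @param n_draws Monte Carlo sample size.
#' @param seed Internal Monte Carlo seed.
#' @param level Credible level.
#' @param sector Optional sector label recorded in the output.
#' @return A one-row tibble of class `rnfl_mcnemar`: the four counts, the
#'   posterior mean and CrI of the proportion difference, the posterior
#'   probability that the Spectralis proportion exceeds the Cirrus
#'   proportion, and the significance verdict.
#' @export
mcnemar_from_counts <- function(counts, direction = c("negative", "positive"),
                                prior = c(1, 1, 1, 1), n_draws = 2e5,
                                seed = 20260101, level = 0.95, sector = NA) {
  direction <- match.arg(direction)
  need <- c("both", "spectralis_only", "cirrus_only", "neither")
  if (!all(need %in% names(counts))) {
    stop("counts must be named: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- counts[need]
  stopifnot(all(counts >= 0), length(prior) == 4, all(prior > 0))
  a <- as.numeric(counts) + prior
  draws <- withr::with_seed(as.integer(seed), {
    g <- matrix(stats::rgamma(4 * n_draws, shape = rep(a, each = n_draws)),
                ncol = 4)
    g / rowSums(g)
  })
  d <- draws[, 2] - draws[, 3] # p_S - p_C = p10 - p01
  ci <- cri(d, level)
  tibble::tibble(
    sector = sector, direction = direction,
    both = counts[["both"]], spectralis_only = counts[["spectralis_only"]],
    cirrus_only = counts[["cirrus_only"]], neither = counts[["neither"]],
    diff_mean = mean(d), diff_lower = ci[1], diff_upper = ci[2],
    pr_spectralis_greater = mean(draws[, 2] > draws[, 3]),
    significant = ci[1] > 0 | ci[2] < 0
  ) |>
    structure(class = c("rnfl_mcnemar", class(tibble::tibble())))
}

#' Bayesian McNemar test from a per-eye classification
#'
#' Builds the 2x2 paired-indicator table of which device classified each eye
#' in the requested direction, then calls [mcnemar_from_counts()].
#'
#' @param classification A tibble from [classify_slopes()].
#' @inheritParams mcnemar_from_counts
#' @return See [mcnemar_from_counts()].
#' @export
bayesian_mcnemar <- function(classification,
                             direction = c("negative", "positive"),
                             prior = c(1, 1, 1, 1), n_draws = 2e5,
                             seed = 20260101, level = 0.95) {
  direction <- match.arg(direction)
  wide <- classification |>
    dplyr::mutate(hit = .data$verdict == direction) |>
    dplyr::select("eye_id", "device", "hit") |>
    tidyr::pivot_wider(names_from = "device", values_from = "hit")
  if (anyNA(wide$spectralis) || anyNA(wide$cirrus)) {
    stop("classification must cover both devices for every eye",
         call. = FALSE)
  }
  counts <- c(
    both = sum(wide$spectralis & wide$cirrus),
    spectralis_only = sum(wide$spectralis & !wide$cirrus),
    cirrus_only = sum(!wide$spectralis & wide$cirrus),
    neither = sum(!wide$spectralis & !wide$cirrus)
  )
  mcnemar_from_counts(counts, direction = direction, prior = prior,
                      n_draws = n_draws, seed = seed, level = level,
                      sector = attr(classification, "sector") %||% NA)
}
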