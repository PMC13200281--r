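#' Names of the six eye-level effects
#'
#' Each eye carries six correlated latent effects: device-specific intercepts
#' (`alpha`, micrometers), rates of change (`beta`, micrometers/year), and
#' log residual standard deviations (`lambda`, log-micrometers). Ordering is
#' fixed as (alpha_S, alpha_C, beta_S, beta_C, lambda_S, lambda_C).
#'
#' @return Character vector of length 6.
#' @export
effect_names <- function() {
  c("alpha_spectralis", "alpha_cirrus",
    "beta_spectralis", "beta_cirrus",
    "lambda_spectralis", "lambda_cirrus")
}

#' Population-level parameters of the bivariate hierarchical model
#'
#' @param mu Numeric vector of 6 population means in the order of
#'   [effect_names()]: intercepts (micrometers), rates of change
#'   (micrometers/year), log residual SDs (log-micrometers).
#' @param Sigma 6x6 symmetric positive-definite covariance matrix of the
#'   eye-level effects.
#' @param rho Within-visit cross-device residual correlation, in (-1, 1).
#' @return An object of class `population_params`.
#' @export
population_params <- function(mu, Sigma, rho) {
  mu <- as.numeric(mu)
  if (length(mu) != 6 || !all(is.finite(mu))) {
    stop("mu must be 6 finite values", call. = FALSE)
  }
  Sigma <- as.matrix(Sigma)
  if (!all(dim(Sigma) == c(6, 6)) || !all(is.finite(Sigma)) ||
      max(abs(Sigma - t(Sigma))) > 1e-8) {
    stop("Sigma must be a finite symmetric 6x6 matrix", call. = FALSE)
  }
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma must be positive definite", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("rho must lie strictly inside (-1, 1)", call. = FALSE)
  }
  names(mu) <- effect_names()
  dimnames(Sigma) <- list(effect_names(), effect_names())
  structure(list(mu = mu, Sigma = Sigma, rho = rho),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n mu:\n")
  print(round(x$mu, 4))
  cat(" effect SDs:", paste(round(sqrt(diag(x$Sigma)), 3), collapse = " "),
      "\n rho:", x$rho, "\n")
  invisible(x)
}

#' Prior specification for the bivariate hierarchical model
#'
#' Priors are weakly informative on the micrometer scale of peripapillary
#' RNFL data. Population means get independent normal priors. The 6x6
#' effect covariance gets an inverse-Wishart prior, parameterized here by a
#' degrees-of-freedom `sigma_df` and a vector of prior-mean effect SDs
#' `sigma_scale`: the Wishart scale matrix is
#' `diag(sigma_scale^2) * (sigma_df - 7)`, so that the prior mean of Sigma is
#' `diag(sigma_scale^2)` whenever `sigma_df > 7`. The residual correlation
#' `rho` has a uniform prior on (-1, 1).
#'
#' @param mu_location,mu_scale Numeric vectors of 6: normal prior location
#'   and scale for each population mean, in [effect_names()] order.
#' @param sigma_df Inverse-Wishart degrees of freedom (> 7 for a finite
#'   prior mean of Sigma).
#' @param sigma_scale Numeric vector of 6 prior-mean SDs of the eye effects.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_location = c(75, 75, 0, 0, log(3), log(3)),
                       mu_scale = c(50, 50, 10, 10, 1.5, 1.5),
                       sigma_df = 8,
                       sigma_scale = c(20, 20, 2, 2, 1, 1)) {
  stopifnot(length(mu_location) == 6, length(mu_scale) == 6,
            all(is.finite(mu_location)), all(mu_scale > 0),
            length(sigma_scale) == 6, all(sigma_scale > 0),
            length(sigma_df) == 1, sigma_df > 7)
  structure(list(mu_location = as.numeric(mu_location),
                 mu_scale = as.numeric(mu_scale),
                 sigma_df = as.numeric(sigma_df),
                 sigma_scale = as.numeric(sigma_scale)),
            class = "prior_spec")
}

# Wishart scale matrix implied by a prior_spec
prior_scale_matrix <- function(priors) {
  diag(priors$sigma_scale^2) * (priors$sigma_df - 7)
}

# log of the multivariate gamma function
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# log inverse-Wishart density of Sigma with df nu and scale matrix S
dinvwishart_log <- function(Sigma, nu, S) {
  p <- nrow(Sigma)
  chS <- chol(S)
  chSig <- chol(Sigma)
  ldetS <- 2 * sum(log(diag(chS)))
  ldetSig <- 2 * sum(log(diag(chSig)))
  tr <- sum(diag(backsolve(chSig, forwardsolve(t(chSig), S))))
  nu / 2 * ldetS - nu * p / 2 * log(2) - lmvgamma(nu / 2, p) -
    (nu + p + 1) / 2 * ldetSig - tr / 2
}

# multivariate normal log density, x a matrix with one row per observation
dmvnorm_log <- function(x, mean, Sigma) {
  x <- rbind(x)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * ncol(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# bivariate normal log density of residuals (e1, e2) with sds and correlation
dbivnorm_log <- function(e1, e2, s1, s2, rho) {
  z1 <- e1 / s1
  z2 <- e2 / s2
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-rho^2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))
}

#' Joint log density of the bivariate hierarchical model
#'
#' Evaluates, for single-sector data, the exact joint log density that the
#' sampler targets: (a) the residual likelihood, bivariate normal at visits
#' where both devices measured (residual SDs `exp(lambda)` per device and
#' eye, cross-device correlation `rho`), univariate normal at single-device
#' visits; (b) the 6-dimensional multivariate normal density of the
#' eye-level effects; (c) the prior densities of `mu`, `Sigma` and `rho`.
#'
#' @param data Single-sector measurements: a data frame with columns
#'   `eye_id`, `device`, `t_years`, `thickness_um` (a `sector` column, if
#'   present, must contain exactly one sector).
#' @param effects A data frame with column `eye_id` plus the six effect
#'   columns of [effect_names()], one row per eye in `data`.
#' @param pop A [population_params()] object.
#' @param priors A [prior_spec()] object, or `NULL` to omit the prior term.
#' @param terms Which terms to include; any subset of
#'   `c("likelihood", "effects", "prior")`.
#' @return A single finite number (the log density), or `-Inf` where the
#'   likelihood is degenerate.
#' @export
bivariate_log_density <- function(data, effects, pop, priors = NULL,
                                  terms = c("likelihood", "effects", "prior")) {
  terms <- match.arg(terms, several.ok = TRUE)
  if ("sector" %in% names(data) && dplyr::n_distinct(data$sector) > 1) {
    stop("log density is defined per sector; data contains several",
         call. = FALSE)
  }
  stopifnot(inherits(pop, "population_params"))
  eff <- tibble::as_tibble(effects)
  need <- c("eye_id", effect_names())
  if (!all(need %in% names(eff))) {
    stop("effects must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  eff$eye_id <- as.character(eff$eye_id)

  total <- 0

  if ("likelihood" %in% terms) {
    wide <- tibble::as_tibble(data) |>
      dplyr::mutate(eye_id = as.character(.data$eye_id)) |>
      dplyr::select("eye_id", "device", "t_years", "thickness_um") |>
      tidyr::pivot_wider(names_from = "device",
                         values_from = "thickness_um") |>
      dplyr::left_join(eff, by = "eye_id")
    if (anyNA(wide$alpha_spectralis)) {
      stop("effects missing for eyes present in data", call. = FALSE)
    }
    if (!"spectralis" %in% names(wide)) wide$spectralis <- NA_real_
    if (!"cirrus" %in% names(wide)) wide$cirrus <- NA_real_
    eS <- wide$spectralis - wide$alpha_spectralis -
      wide$beta_spectralis * wide$t_years
    eC <- wide$cirrus - wide$alpha_cirrus - wide$beta_cirrus * wide$t_years
    sS <- exp(wide$lambda_spectralis)
    sC <- exp(wide$lambda_cirrus)
    paired <- !is.na(eS) & !is.na(eC)
    ll <- sum(dbivnorm_log(eS[paired], eC[paired], sS[paired], sC[paired],
                           pop$rho))
    only_s <- !is.na(eS) & is.na(eC)
    only_c <- is.na(eS) & !is.na(eC)
    ll <- ll + sum(stats::dnorm(eS[only_s], 0, sS[only_s], log = TRUE)) +
      sum(stats::dnorm(eC[only_c], 0, sC[only_c], log = TRUE))
    total <- total + ll
  }

  if ("effects" %in% terms) {
    bmat <- as.matrix(eff[, effect_names()])
    total <- total + sum(dmvnorm_log(bmat, pop$mu, pop$Sigma))
  }

  if ("prior" %in% terms && !is.null(priors)) {
    stopifnot(inherits(priors, "prior_spec"))
    total <- total +
      sum(stats::dnorm(pop$mu, priors$mu_location, priors$mu_scale,
                       log = TRUE)) +
      dinvwishart_log(pop$Sigma, priors$sigma_df,
                      prior_scale_matrix(priors)) +
      stats::dunif(pop$rho, -1, 1, log = TRUE)
  }

  total
}

#' Simulate single-sector data from the generative model
#'
#' The exact generative counterpart of [bivariate_log_density()]: eye
#' effects are drawn from the 6-dimensional multivariate normal
#' `(mu, Sigma)`, then each visit's residual pair from the bivariate normal
#' residual law with eye-specific SDs `exp(lambda)` and correlation `rho`.
#'
#' @param pop A [population_params()] object.
#' @param design Per-eye visit-time grids: either a data frame with columns
#'   `eye_id` and `t_years`, or a named list of numeric time vectors.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A list with `data` (tibble: `eye_id`, `device`, `t_years`,
#'   `thickness_um`) and `effects` (tibble of latent eye effects, one row
#'   per eye) for recovery testing.
#' @export
simulate_from_model <- function(pop, design, seed) {
  stopifnot(inherits(pop, "population_params"))
  if (is.list(design) && !is.data.frame(design)) {
    design <- tibble::tibble(
      eye_id = rep(names(design), lengths(design)),
      t_years = unlist(design, use.names = FALSE)
    )
  }
  design <- tibble::as_tibble(design)
  stopifnot(all(c("eye_id", "t_years") %in% names(design)),
            nrow(design) > 0)
  design$eye_id <- as.character(design$eye_id)
  eyes <- unique(design$eye_id)

  withr::with_seed(as.integer(seed), {
    L <- t(chol(pop$Sigma))
    z <- matrix(stats::rnorm(6 * length(eyes)), nrow = 6)
    b <- t(pop$mu + L %*% z)
    colnames(b) <- effect_names()
    effects <- tibble::tibble(eye_id = eyes) |>
      dplyr::bind_cols(tibble::as_tibble(b))

    data <- purrr::map_dfr(seq_along(eyes), function(i) {
      t <- sort(design$t_years[design$eye_id == eyes[i]])
      n <- length(t)
      sS <- exp(b[i, "lambda_spectralis"])
      sC <- exp(b[i, "lambda_cirrus"])
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      yS <- b[i, "alpha_spectralis"] + b[i, "beta_spectralis"] * t + sS * z1
      yC <- b[i, "alpha_cirrus"] + b[i, "beta_cirrus"] * t +
        sC * (pop$rho * z1 + sqrt(1 - pop$rho^2) * z2)
      tibble::tibble(
        eye_id = eyes[i],
        device = rep(device_levels(), each = n),
        t_years = c(t, t),
        thickness_um = c(yS, yC)
      )
    })
    list(data = data, effects = effects)
  })
}
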