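#' Sampler configuration
#'
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param adapt Adaptation iterations (step-size tuning) per chain.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Kept draws per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; mandatory, there is no silent clock seeding.
#' @param rhat_max,ess_min Convergence thresholds used by [diagnose()].
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, adapt = 1000L, warmup = 1000L,
                           draws = 1000L, thin = 1L, seed,
                           rhat_max = 1.01, ess_min = 400) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(chains >= 1, adapt >= 100, warmup >= 0, draws >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 thin = as.integer(thin), seed = as.integer(seed),
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "sampler_config")
}

# Assemble single-sector data into paired / unpaired visit structures.
prepare_sector_data <- function(cohort, sector, min_eye_visits = 2L) {
  d <- cohort |>
    dplyr::filter(.data$sector == !!sector, .data$quality_ok) |>
    dplyr::select("eye_id", "device", "t_years", "thickness_um")
  if (nrow(d) == 0) stop("no data for sector ", sector, call. = FALSE)
  wide <- tidyr::pivot_wider(d, names_from = "device",
                             values_from = "thickness_um")
  if (!"spectralis" %in% names(wide)) wide$spectralis <- NA_real_
  if (!"cirrus" %in% names(wide)) wide$cirrus <- NA_real_
  nv <- wide |> dplyr::count(.data$eye_id)
  dropped <- nv$eye_id[nv$n < min_eye_visits]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " eye(s) with fewer than ",
            min_eye_visits, " visits in sector ", sector, ": ",
            paste(utils::head(dropped, 5), collapse = ", "))
    wide <- wide[!wide$eye_id %in% dropped, , drop = FALSE]
  }
  if (nrow(wide) == 0) stop("no eyes remain for sector ", sector,
                            call. = FALSE)
  eyes <- sort(unique(wide$eye_id))
  wide$eye_idx <- match(wide$eye_id, eyes)
  paired <- wide[!is.na(wide$spectralis) & !is.na(wide$cirrus), ]
  unpaired <- wide[xor(is.na(wide$spectralis), is.na(wide$cirrus)), ]
  unpaired$dev_idx <- ifelse(is.na(unpaired$cirrus), 1L, 2L)
  unpaired$y <- ifelse(unpaired$dev_idx == 1L,
                       unpaired$spectralis, unpaired$cirrus)
  list(paired = paired, unpaired = unpaired, eyes = eyes, dropped = dropped)
}

# JAGS model code; paired / unpaired observation blocks are included only
# when the corresponding data exist (JAGS rejects empty loops).
jags_model_code <- function(has_paired, has_unpaired) {
  paired_block <- "
  for (v in 1:Np) {
    y2[v,1:2] ~ dmnorm(m2[v,1:2], P2[v,1:2,1:2])
    m2[v,1] <- b[eyeP[v],1] + b[eyeP[v],3]*tP[v]
    m2[v,2] <- b[eyeP[v],2] + b[eyeP[v],4]*tP[v]
    C2[v,1,1] <- exp(2*b[eyeP[v],5])
    C2[v,2,2] <- exp(2*b[eyeP[v],6])
    C2[v,1,2] <- rho*exp(b[eyeP[v],5]+b[eyeP[v],6])
    C2[v,2,1] <- C2[v,1,2]
    P2[v,1:2,1:2] <- inverse(C2[v,1:2,1:2])
  }"
  unpaired_block <- "
  for (u in 1:Nu) {
    y1[u] ~ dnorm(b[eyeU[u],dev[u]] + b[eyeU[u],dev[u]+2]*tU[u],
                  exp(-2*b[eyeU[u],dev[u]+4]))
  }"
  paste0(
    "model {",
    if (has_paired) paired_block else "",
    if (has_unpaired) unpaired_block else "",
    "
  for (i in 1:Ne) { b[i,1:6] ~ dmnorm(mu[1:6], Tau[1:6,1:6]) }
  for (k in 1:6) { mu[k] ~ dnorm(m0[k], pow(s0[k], -2)) }
  Tau[1:6,1:6] ~ dwish(Rw[1:6,1:6], dfw)
  Sigma[1:6,1:6] <- inverse(Tau[1:6,1:6])
  rho ~ dunif(-1, 1)
}")
}

# deterministic per-eye ordinary-least-squares starting values
ols_inits <- function(prep) {
  eyes <- prep$eyes
  long <- dplyr::bind_rows(
    prep$paired |>
      dplyr::select("eye_idx", "t_years", "spectralis", "cirrus") |>
      tidyr::pivot_longer(c("spectralis", "cirrus"),
                          names_to = "device", values_to = "y"),
    prep$unpaired |>
      dplyr::transmute(.data$eye_idx, .data$t_years,
                       device = device_levels()[.data$dev_idx], y = .data$y)
  )
  pooled_int <- mean(long$y)
  pooled_lsd <- log(max(stats::sd(long$y) / 4, 0.5))
  b <- matrix(NA_real_, length(eyes), 6)
  for (i in seq_along(eyes)) {
    for (d in 1:2) {
      di <- long[long$eye_idx == i & long$device == device_levels()[d], ]
      if (nrow(di) >= 2 && dplyr::n_distinct(di$t_years) >= 2) {
        f <- stats::lm(y ~ t_years, data = di)
        b[i, d] <- stats::coef(f)[1]
        b[i, d + 2] <- stats::coef(f)[2]
        sig <- if (nrow(di) >= 3) summary(f)$sigma else NA
        b[i, d + 4] <- log(max(sig, 0.5, na.rm = TRUE))
      } else {
        b[i, d] <- pooled_int
        b[i, d + 2] <- 0
        b[i, d + 4] <- pooled_lsd
      }
    }
  }
  mu0 <- colMeans(b)
  v <- stats::cov(b)
  v <- v + diag(pmax(0.05, 0.05 * diag(v)))
  tau0 <- tryCatch(solve(v), error = function(e) {
    diag(1 / pmax(diag(v), 0.05))
  })
  tau0 <- (tau0 + t(tau0)) / 2
  list(b = b, mu = mu0, Tau = tau0, rho = 0)
}

#' Fit the bivariate hierarchical model to one sector
#'
#' Samples the posterior implied by [bivariate_log_density()] for a single
#' sector (or the global average) using Gibbs/Metropolis sampling via JAGS.
#' Visits where both devices measured enter as bivariate observations;
#' single-device visits contribute their univariate margin. Eyes with fewer
#' than two visits in the sector are dropped with a message (their slope is
#' unidentifiable). The fit is deterministic given data, priors and config
#' (chain seeds derive from `config$seed`; starting values are per-eye
#' least-squares estimates).
#'
#' @param cohort A cohort tibble.
#' @param sector One sector label from [sector_levels()].
#' @param priors A [prior_spec()].
#' @param config A [sampler_config()].
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `rnfl_fit` holding the posterior draws
#'   (`coda::mcmc.list` of `mu`, `Sigma`, `rho` and the per-eye effects `b`),
#'   the eye index, sector, configuration and convergence diagnostics.
#' @export
fit_sector <- function(cohort, sector = "G", priors = prior_spec(), config,
                       quiet = TRUE) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "sampler_config"))
  if (!sector %in% sector_levels()) {
    stop("unknown sector: ", sector, call. = FALSE)
  }
  prep <- prepare_sector_data(cohort, sector)
  np <- nrow(prep$paired)
  nu <- nrow(prep$unpaired)

  jd <- list(Ne = length(prep$eyes),
             m0 = priors$mu_location, s0 = priors$mu_scale,
             Rw = prior_scale_matrix(priors), dfw = priors$sigma_df)
  if (np > 0) {
    jd$Np <- np
    jd$y2 <- cbind(prep$paired$spectralis, prep$paired$cirrus)
    jd$tP <- prep$paired$t_years
    jd$eyeP <- prep$paired$eye_idx
  }
  if (nu > 0) {
    jd$Nu <- nu
    jd$y1 <- prep$unpaired$y
    jd$tU <- prep$unpaired$t_years
    jd$eyeU <- prep$unpaired$eye_idx
    jd$dev <- prep$unpaired$dev_idx
  }

  start <- ols_inits(prep)
  inits <- lapply(seq_len(config$chains), function(ch) {
    c(start, list(.RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = config$seed * 1000L + ch))
  })

  code <- jags_model_code(np > 0, nu > 0)
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                            n.chains = config$chains, n.adapt = config$adapt,
                            quiet = quiet)
    if (config$warmup > 0) {
      stats::update(jm, config$warmup, progress.bar = "none")
    }
    rjags::coda.samples(jm, c("mu", "Sigma", "rho", "b"),
                        n.iter = config$draws * config$thin,
                        thin = config$thin, progress.bar = "none")
  }
  samples <- if (quiet) {
    withCallingHandlers(
      suppressWarnings(run()),
      message = function(m) invokeRestart("muffleMessage"))
  } else {
    run()
  }

  fit <- structure(
    list(samples = samples, sector = sector, eyes = prep$eyes,
         dropped_eyes = prep$dropped, n_paired = np, n_unpaired = nu,
         priors = priors, config = config),
    class = "rnfl_fit"
  )
  fit$diagnostics <- diagnose(fit)
  if (!attr(fit$diagnostics, "pass")) {
    warning("convergence diagnostics failed for sector ", sector,
            " (max split R-hat ",
            round(max(fit$diagnostics$rhat, na.rm = TRUE), 3),
            ", min bulk ESS ",
            round(min(fit$diagnostics$ess, na.rm = TRUE)), ")",
            call. = FALSE)
  }
  fit
}

#' @export
print.rnfl_fit <- function(x, ...) {
  cat("<rnfl_fit> sector ", x$sector, ": ", length(x$eyes), " eyes, ",
      x$n_paired, " paired + ", x$n_unpaired, " unpaired visits, ",
      x$config$chains, " chains x ", x$config$draws, " draws",
      if (attr(x$diagnostics, "pass")) ", converged" else
        ", CONVERGENCE FLAGGED",
      "\n", sep = "")
  invisible(x)
}

# combined-chain draw matrix for selected monitored parameters
draw_matrix <- function(fit, pattern = NULL) {
  m <- as.matrix(fit$samples)
  if (!is.null(pattern)) m <- m[, grepl(pattern, colnames(m)), drop = FALSE]
  m
}

# draws of the eye-level rate of change for one device; columns = eyes
eye_beta_draws <- function(fit, device = c("spectralis", "cirrus")) {
  device <- match.arg(device)
  k <- if (device == "spectralis") 3L else 4L
  cols <- sprintf("b[%d,%d]", seq_along(fit$eyes), k)
  m <- draw_matrix(fit)[, cols, drop = FALSE]
  colnames(m) <- fit$eyes
  m
}

# split potential-scale-reduction factor; x is an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  pieces <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(pieces)
  nn <- nrow(pieces)
  w <- mean(apply(pieces, 2, stats::var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- nn * stats::var(colMeans(pieces))
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Convergence diagnostics for a fit
#'
#' Reports split potential-scale-reduction (R-hat) and effective sample size
#' per monitored population parameter. The fit passes when all R-hat values
#' are at or below `rhat_max` and all effective sample sizes at or above
#' `ess_min` (thresholds from the fit's [sampler_config()], defaults 1.01
#' and 400). With a single chain, R-hat is not computable and only ESS is
#' reported, with a warning.
#'
#' @param fit An `rnfl_fit`.
#' @param params Regular expression selecting parameters (default: the
#'   population-level `mu`, `Sigma` diagonal, and `rho`).
#' @return A tibble with columns `term`, `rhat`, `ess`; attribute `"pass"`
#'   holds the overall verdict.
#' @export
diagnose <- function(fit, params = "^mu\\[|^Sigma\\[([1-6]),\\1\\]|^rho$") {
  sel <- grepl(params, coda::varnames(fit$samples))
  sub <- fit$samples[, sel, drop = FALSE]
  terms <- coda::varnames(sub)
  ess <- coda::effectiveSize(sub)
  single <- length(sub) < 2
  if (single) {
    warning("R-hat requires at least 2 chains; reporting ESS only",
            call. = FALSE)
    rhat <- rep(NA_real_, length(terms))
  } else {
    rhat <- vapply(terms, function(v) {
      split_rhat(sapply(sub, function(ch) as.numeric(ch[, v])))
    }, numeric(1))
  }
  out <- tibble::tibble(term = terms, rhat = unname(rhat),
                        ess = unname(ess[terms]))
  pass <- !single && all(is.finite(out$rhat)) &&
    max(out$rhat) <= fit$config$rhat_max &&
    min(out$ess) >= fit$config$ess_min
  attr(out, "pass") <- pass
  out
}

#' @exportS3Method generics::tidy
tidy.rnfl_fit <- function(x, conf_level = 0.95, ...) {
  m <- draw_matrix(x, "^mu\\[|^Sigma\\[|^rho$")
  a <- (1 - conf_level) / 2
  q <- apply(m, 2, stats::quantile, probs = c(a, 1 - a))
  tibble::tibble(
    term = colnames(m),
    estimate = colMeans(m),
    std.error = apply(m, 2, stats::sd),
    conf.low = q[1, ],
    conf.high = q[2, ]
  )
}

#' @exportS3Method generics::glance
glance.rnfl_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    sector = x$sector,
    n_eyes = length(x$eyes),
    n_paired_visits = x$n_paired,
    n_unpaired_visits = x$n_unpaired,
    chains = x$config$chains,
    draws_per_chain = x$config$draws,
    max_rhat = suppressWarnings(max(d$rhat, na.rm = TRUE)),
    min_ess = min(d$ess, na.rm = TRUE),
    converged = attr(d, "pass")
  )
}

#' Closed-form conjugate posterior for one eye's regression line
#'
#' The fixed-variance, no-hierarchy special case of the model: a single eye,
#' single device, known residual SD, and a normal prior on (intercept,
#' slope). Returns the exact normal posterior, used as an independent oracle
#' for the sampler.
#'
#' @param t,y Visit times (years) and thicknesses (micrometers).
#' @param sd Known residual SD (> 0).
#' @param prior_mean Length-2 prior mean for (intercept, slope); ignored for
#'   the flat-prior limit `prior_cov = NULL`.
#' @param prior_cov 2x2 prior covariance, or `NULL` for the flat-prior limit
#'   (requires at least two distinct times).
#' @return A list with `mean` (named length-2 vector) and `cov` (2x2 matrix).
#' @export
conjugate_slope_posterior <- function(t, y, sd, prior_mean = c(0, 0),
                                      prior_cov = NULL) {
  stopifnot(length(t) == length(y), sd > 0)
  X <- cbind(intercept = 1, slope = t)
  xtx <- crossprod(X)
  if (is.null(prior_cov)) {
    if (abs(det(xtx)) < 1e-12) {
      stop("singular design: flat prior needs two distinct times",
           call. = FALSE)
    }
    prec <- xtx / sd^2
    rhs <- crossprod(X, y) / sd^2
  } else {
    p0 <- solve(prior_cov)
    prec <- xtx / sd^2 + p0
    rhs <- crossprod(X, y) / sd^2 + p0 %*% prior_mean
  }
  cov <- solve(prec)
  cov <- (cov + t(cov)) / 2
  mean <- drop(cov %*% rhs)
  names(mean) <- c("intercept", "slope")
  dimnames(cov) <- list(names(mean), names(mean))
  list(mean = mean, cov = cov)
}

#' MCMC fit of the restricted single-line model
#'
#' Samples the same restricted model as [conjugate_slope_posterior()] with
#' independent normal priors, for sampler-vs-closed-form equivalence checks.
#'
#' @inheritParams conjugate_slope_posterior
#' @param prior_sd Length-2 prior SDs for (intercept, slope).
#' @param config A [sampler_config()].
#' @return A tibble with posterior `mean` and `sd` for `intercept` and
#'   `slope` computed from the MCMC draws.
#' @export
fit_line_mcmc <- function(t, y, sd, prior_mean = c(0, 0),
                          prior_sd = c(10, 10), config) {
  stopifnot(inherits(config, "sampler_config"))
  code <- "model {
    for (i in 1:N) { y[i] ~ dnorm(a + bb * t[i], prec) }
    a ~ dnorm(pm[1], pow(ps[1], -2))
    bb ~ dnorm(pm[2], pow(ps[2], -2))
  }"
  jd <- list(N = length(y), y = y, t = t, prec = 1 / sd^2,
             pm = prior_mean, ps = prior_sd)
  inits <- lapply(seq_len(config$chains), function(ch) {
    list(a = prior_mean[1], bb = prior_mean[2],
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed * 1000L + ch)
  })
  jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                          n.chains = config$chains, n.adapt = config$adapt,
                          quiet = TRUE)
  stats::update(jm, config$warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("a", "bb"), n.iter = config$draws,
                            progress.bar = "none")
  m <- as.matrix(sm)
  tibble::tibble(term = c("intercept", "slope"),
                 mean = c(mean(m[, "a"]), mean(m[, "bb"])),
                 sd = c(stats::sd(m[, "a"]), stats::sd(m[, "bb"])))
}
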