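make_pop <- function(rho = 0.3) {
  sds <- c(13.3, 10.5, 0.6, 0.6, 0.4, 0.4)
  R <- diag(6)
  R[1, 2] <- R[2, 1] <- 0.85
  R[3, 4] <- R[4, 3] <- 0.6
  R[5, 6] <- R[6, 5] <- 0.6
  population_params(mu = c(61.5, 65.3, -0.7, -0.45, log(1.8), log(2.5)),
                    Sigma = diag(sds) %*% R %*% diag(sds), rho = rho)
}

# independent brute-force joint log density, written from the model
# definition with no code shared with the package implementation
brute_force_logdens <- function(data, effects, pop, priors = NULL) {
  total <- 0
  eff <- as.data.frame(effects)
  for (r in seq_len(nrow(eff))) {
    e <- eff[r, ]
    rows <- data[data$eye_id == e$eye_id, ]
    for (tt in unique(rows$t_years)) {
      ys <- rows$thickness_um[rows$device == "spectralis" &
                                rows$t_years == tt]
      yc <- rows$thickness_um[rows$device == "cirrus" & rows$t_years == tt]
      ms <- e$alpha_spectralis + e$beta_spectralis * tt
      mc <- e$alpha_cirrus + e$beta_cirrus * tt
      ss <- exp(e$lambda_spectralis)
      sc <- exp(e$lambda_cirrus)
      if (length(ys) == 1 && length(yc) == 1) {
        C <- matrix(c(ss^2, pop$rho * ss * sc, pop$rho * ss * sc, sc^2), 2)
        v <- c(ys - ms, yc - mc)
        total <- total - log(2 * pi) - 0.5 * log(det(C)) -
          0.5 * drop(t(v) %*% solve(C) %*% v)
      } else if (length(ys) == 1) {
        total <- total + stats::dnorm(ys, ms, ss, log = TRUE)
      } else if (length(yc) == 1) {
        total <- total + stats::dnorm(yc, mc, sc, log = TRUE)
      }
    }
    b <- as.numeric(e[effect_names()])
    v <- b - pop$mu
    total <- total - 3 * log(2 * pi) - 0.5 * log(det(pop$Sigma)) -
      0.5 * drop(t(v) %*% solve(pop$Sigma) %*% v)
  }
  if (!is.null(priors)) {
    total <- total + sum(stats::dnorm(pop$mu, priors$mu_location,
                                      priors$mu_scale, log = TRUE))
    S <- diag(priors$sigma_scale^2) * (priors$sigma_df - 7)
    nu <- priors$sigma_df
    p <- 6
    lmg <- p * (p - 1) / 4 * log(pi) +
      sum(lgamma(nu / 2 + (1 - seq_len(p)) / 2))
    total <- total + nu / 2 * log(det(S)) - nu * p / 2 * log(2) - lmg -
      (nu + p + 1) / 2 * log(det(pop$Sigma)) -
      0.5 * sum(diag(solve(pop$Sigma) %*% S))
    total <- total + log(0.5) # uniform(-1, 1) on rho
  }
  total
}

sim_small <- function(rho = 0.3, seed = 101) {
  pop <- make_pop(rho)
  design <- list(a = c(0, 1, 2, 3.5), b = c(0, 0.8, 1.6), c = c(0, 1.2))
  sim <- simulate_from_model(pop, design, seed = seed)
  # knock out some single-device measurements to exercise unpaired terms
  sim$data <- sim$data[-c(2, 9, 15), ]
  list(pop = pop, sim = sim)
}

test_that("joint log density matches a brute-force oracle to 1e-10", {
  s <- sim_small()
  priors <- prior_spec()
  got <- bivariate_log_density(s$sim$data, s$sim$effects, s$pop, priors)
  want <- brute_force_logdens(s$sim$data, s$sim$effects, s$pop, priors)
  expect_true(is.finite(got))
  expect_lt(abs(got - want), 1e-10)
})

test_that("term subsets are consistent and sum to the total", {
  s <- sim_small()
  priors <- prior_spec()
  parts <- vapply(c("likelihood", "effects", "prior"), function(tm) {
    bivariate_log_density(s$sim$data, s$sim$effects, s$pop, priors, terms = tm)
  }, numeric(1))
  total <- bivariate_log_density(s$sim$data, s$sim$effects, s$pop, priors)
  expect_equal(sum(parts), total, tolerance = 1e-12)
})

test_that("at rho = 0 the paired likelihood factorizes into two univariate models", {
  s <- sim_small(rho = 0)
  ll <- bivariate_log_density(s$sim$data, s$sim$effects, s$pop,
                              terms = "likelihood")
  uni <- 0
  eff <- as.data.frame(s$sim$effects)
  for (r in seq_len(nrow(eff))) {
    e <- eff[r, ]
    rows <- s$sim$data[s$sim$data$eye_id == e$eye_id, ]
    for (dev in device_levels()) {
      d <- rows[rows$device == dev, ]
      a <- if (dev == "spectralis") e$alpha_spectralis else e$alpha_cirrus
      b <- if (dev == "spectralis") e$beta_spectralis else e$beta_cirrus
      s_ <- exp(if (dev == "spectralis") e$lambda_spectralis else
        e$lambda_cirrus)
      uni <- uni + sum(stats::dnorm(d$thickness_um, a + b * d$t_years, s_,
                                    log = TRUE))
    }
  }
  expect_lt(abs(ll - uni), 1e-10)
})

test_that("degenerate inputs are rejected", {
  s <- sim_small()
  expect_error(population_params(rep(0, 5), diag(6), 0.3), "6 finite values")
  expect_error(population_params(rep(0, 6), diag(-1, 6), 0.3),
               "positive definite")
  expect_error(population_params(rep(0, 6), diag(6), 1), "inside")
  expect_error(prior_spec(sigma_df = 7), "sigma_df")
  expect_error(
    bivariate_log_density(s$sim$data, s$sim$effects[, -3], s$pop),
    "effects must have columns")
  two_sec <- s$sim$data
  two_sec$sector <- rep_len(c("G", "1"), nrow(two_sec))
  expect_error(bivariate_log_density(two_sec, s$sim$effects, s$pop),
               "per sector")
})

test_that("simulate_from_model is seed-deterministic and seed-sensitive", {
  pop <- make_pop()
  design <- list(a = c(0, 1, 2), b = c(0, 0.5, 1, 1.5))
  s1 <- simulate_from_model(pop, design, seed = 5)
  s2 <- simulate_from_model(pop, design, seed = 5)
  s3 <- simulate_from_model(pop, design, seed = 6)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$data$thickness_um,
                                s3$data$thickness_um)))
})

test_that("simulated data reproduce the generating moments (property)", {
  pop <- make_pop()
  design <- stats::setNames(
    rep(list(c(0, 1, 2, 3, 4)), 600),
    sprintf("e%03d", 1:600)
  )
  sim <- simulate_from_model(pop, design, seed = 77)
  b <- as.matrix(sim$effects[, effect_names()])
  expect_lt(max(abs(colMeans(b) - pop$mu) / sqrt(diag(pop$Sigma) / 600)), 4)
  # residual correlation across paired visits
  wide <- tidyr::pivot_wider(sim$data, names_from = "device",
                             values_from = "thickness_um") |>
    dplyr::left_join(sim$effects, by = "eye_id")
  es <- (wide$spectralis - wide$alpha_spectralis -
           wide$beta_spectralis * wide$t_years) /
    exp(wide$lambda_spectralis)
  ec <- (wide$cirrus - wide$alpha_cirrus - wide$beta_cirrus * wide$t_years) /
    exp(wide$lambda_cirrus)
  expect_lt(abs(stats::cor(es, ec) - pop$rho), 0.05)
  expect_lt(abs(stats::sd(es) - 1), 0.05)
})
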