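test_that("sampler_config validates its inputs", {
  expect_error(sampler_config(), "seed is required")
  expect_error(sampler_config(seed = 1, chains = 0))
  expect_error(sampler_config(seed = 1, adapt = 10))
  cfg <- sampler_config(seed = 9)
  expect_s3_class(cfg, "sampler_config")
  expect_identical(cfg$chains, 4L)
})

test_that("sector data preparation splits paired and unpaired visits", {
  g <- tiny_cohort(seed = 12, n_eyes = 6)
  co <- g$cohort
  # remove one device at two visits of eye 1, and all but one visit of eye 2
  eyes <- sort(unique(co$eye_id))
  t1 <- sort(unique(co$t_years[co$eye_id == eyes[1]]))[1:2]
  drop1 <- co$eye_id == eyes[1] & co$device == "cirrus" & co$t_years %in% t1
  t2 <- sort(unique(co$t_years[co$eye_id == eyes[2]]))
  drop2 <- co$eye_id == eyes[2] & co$t_years != t2[1]
  co2 <- co[!(drop1 | drop2), ]
  expect_message(
    prep <- rnfltrend:::prepare_sector_data(co2, "G"),
    "fewer than 2 visits"
  )
  expect_identical(prep$dropped, eyes[2])
  expect_equal(length(prep$eyes), 5)
  expect_equal(nrow(prep$unpaired), 2)
  expect_equal(prep$unpaired$dev_idx, c(1L, 1L))
  n_visits <- co |> dplyr::distinct(eye_id, t_years) |> nrow()
  n_visits1 <- co |>
    dplyr::filter(eye_id != eyes[2]) |>
    dplyr::distinct(eye_id, t_years) |>
    nrow()
  expect_equal(nrow(prep$paired), n_visits1 - 2)
  # quality_ok gate removes rows before pairing
  co3 <- co
  co3$quality_ok[co3$eye_id == eyes[3] & co3$device == "spectralis"] <- FALSE
  prep3 <- rnfltrend:::prepare_sector_data(co3, "G")
  expect_true(all(prep3$unpaired$dev_idx == 2L))
})

test_that("conjugate posterior equals least squares in the flat-prior limit", {
  t <- c(0, 0.7, 1.5, 2.1, 3.0, 3.9)
  y <- withr::with_seed(21, 95 - 0.8 * t + stats::rnorm(6, 0, 2))
  post <- conjugate_slope_posterior(t, y, sd = 2)
  f <- stats::lm(y ~ t)
  expect_equal(unname(post$mean), unname(stats::coef(f)), tolerance = 1e-10)
  expect_equal(post$cov, 4 * solve(crossprod(cbind(intercept = 1, slope = t))),
               tolerance = 1e-10)
  expect_error(conjugate_slope_posterior(c(1, 1), c(2, 3), sd = 1),
               "singular design")
})

test_that("an informative prior shrinks the conjugate posterior", {
  t <- c(0, 1, 2, 3)
  y <- c(90, 89, 88, 87)
  tight <- conjugate_slope_posterior(t, y, sd = 1, prior_mean = c(80, 0),
                                     prior_cov = diag(c(1e-6, 1e-6)))
  expect_equal(unname(tight$mean), c(80, 0), tolerance = 1e-3)
  flat <- conjugate_slope_posterior(t, y, sd = 1, prior_mean = c(80, 0),
                                    prior_cov = diag(c(1e6, 1e6)))
  expect_equal(unname(flat$mean),
               unname(conjugate_slope_posterior(t, y, sd = 1)$mean),
               tolerance = 1e-3)
})

test_that("split R-hat detects non-mixing and passes white noise", {
  x <- withr::with_seed(31, matrix(stats::rnorm(4000), ncol = 4))
  expect_lt(abs(rnfltrend:::split_rhat(x) - 1), 0.02)
  shifted <- sweep(x, 2, c(0, 0, 0, 3), "+")
  expect_gt(rnfltrend:::split_rhat(shifted), 1.5)
  # within-chain drift (first half vs second half) is also caught
  drift <- x
  drift[501:1000, ] <- drift[501:1000, ] + 3
  expect_gt(rnfltrend:::split_rhat(drift), 1.5)
  expect_true(is.na(rnfltrend:::split_rhat(matrix(1, 100, 2))))
})

test_that("diagnose passes on independent draws and warns on one chain", {
  fit <- fake_fit(n_eyes = 2, n_draws = 600)
  d <- fit$diagnostics
  expect_true(attr(d, "pass"))
  expect_true(all(d$rhat < 1.01))
  expect_true(all(d$ess >= 400))
  expect_true(all(grepl("^mu\\[|^Sigma\\[|^rho$", d$term)))
  one <- fit
  one$samples <- coda::mcmc.list(fit$samples[[1]])
  expect_warning(d1 <- diagnose(one), "at least 2 chains")
  expect_true(all(is.na(d1$rhat)))
  expect_false(attr(d1, "pass"))
})

test_that("fit_sector returns a usable fit on a small cohort", {
  g <- tiny_cohort(seed = 14, n_eyes = 10)
  fit <- suppressWarnings(
    fit_sector(g$cohort, "G", config = quick_config(14))
  )
  expect_s3_class(fit, "rnfl_fit")
  expect_equal(fit$sector, "G")
  expect_equal(length(fit$eyes), 10)
  expect_equal(fit$n_unpaired, 0)
  expect_output(print(fit), "10 eyes")

  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_eyes, 10)
  expect_equal(gl$chains, 2)

  bs <- rnfltrend:::eye_beta_draws(fit, "spectralis")
  expect_equal(dim(bs), c(2 * 300, 10))
  expect_identical(colnames(bs), fit$eyes)
  # posterior intercept means should sit near the data scale
  expect_lt(abs(mean(rnfltrend:::draw_matrix(fit, "^mu\\[1\\]$")) - 61.5), 15)
})

test_that("fit_sector rejects unknown sectors and missing data", {
  g <- tiny_cohort(seed = 15, n_eyes = 4)
  expect_error(fit_sector(g$cohort, "13", config = quick_config(1)),
               "unknown sector")
  expect_error(
    suppressWarnings(fit_sector(g$cohort, "5", config = quick_config(1))),
    "no data for sector")
})
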