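test_that("pop_draws extracts named population draws per chain", {
  fit <- fake_fit(n_eyes = 2, n_draws = 250, n_chains = 3)
  d <- pop_draws(fit)
  expect_equal(nrow(d), 3 * 250)
  expect_equal(sort(unique(d$chain)), 1:3)
  expect_true(all(c("mu_beta_spectralis", "mu_beta_cirrus",
                    "var_lambda_spectralis", "rho") %in% names(d)))
  expect_lt(abs(mean(d$mu_beta_spectralis) + 0.7), 0.02)
  expect_lt(abs(mean(d$rho) - 0.3), 0.02)
})

test_that("summarize_sector reports exact values on degenerate draws", {
  n <- 200
  d <- tibble::tibble(
    chain = 1L, draw = seq_len(n),
    mu_alpha_spectralis = 61.5, mu_alpha_cirrus = 65.3,
    mu_beta_spectralis = -0.7, mu_beta_cirrus = -0.45,
    mu_lambda_spectralis = log(2), mu_lambda_cirrus = log(2.5),
    var_lambda_spectralis = 0.32, var_lambda_cirrus = 0.18,
    rho = 0.3
  )
  s <- summarize_sector(d, sector = "G")
  expect_s3_class(s, "rnfl_sector_summary")
  expect_equal(nrow(s), 9)
  pick <- function(q, c_) s[s$quantity == q & s$contrast == c_, ]
  expect_equal(pick("roc", "difference")$mean, -0.25)
  expect_equal(pick("roc", "difference")$verdict, "negative")
  expect_equal(pick("intercept", "difference")$verdict, "negative")
  # average residual SD is the lognormal mean exp(mu + var/2), draw-wise
  expect_equal(pick("resid_sd", "spectralis")$mean, exp(log(2) + 0.16))
  expect_equal(pick("resid_sd", "cirrus")$mean, exp(log(2.5) + 0.09))
  expect_equal(pick("resid_sd", "ratio")$mean,
               exp(log(2) + 0.16) / exp(log(2.5) + 0.09))
  expect_equal(pick("resid_sd", "ratio")$verdict, "smaller")
  expect_equal(pick("roc", "spectralis")$lower, -0.7)
  expect_equal(pick("roc", "spectralis")$upper, -0.7)
})

test_that("differences are computed draw-wise, not from marginal summaries", {
  x <- withr::with_seed(51, stats::rnorm(2000, 0, 1))
  d <- tibble::tibble(
    chain = 1L, draw = seq_along(x),
    mu_alpha_spectralis = 60, mu_alpha_cirrus = 60,
    mu_beta_spectralis = x, mu_beta_cirrus = x + 0.2,
    mu_lambda_spectralis = log(2), mu_lambda_cirrus = log(2),
    var_lambda_spectralis = 0, var_lambda_cirrus = 0, rho = 0
  )
  s <- summarize_sector(d, sector = "G")
  marg <- s[s$quantity == "roc" & s$contrast == "spectralis", ]
  diff <- s[s$quantity == "roc" & s$contrast == "difference", ]
  expect_equal(marg$verdict, "null") # wide marginal straddles 0
  expect_equal(diff$mean, -0.2)
  expect_equal(diff$lower, -0.2)
  expect_equal(diff$verdict, "negative") # exact draw-wise difference
})

test_that("summarizing a non-converged fit warns", {
  fit <- fake_fit(n_eyes = 2, n_draws = 60) # too few draws for the ESS gate
  expect_false(attr(fit$diagnostics, "pass"))
  expect_warning(summarize_sector(fit), "convergence diagnostics failed")
})

test_that("classify_slopes applies the credible-interval decision rule", {
  betas <- cbind(c(-1, 0, 1), c(-1, -1, 0))
  fit <- fake_fit(n_eyes = 3, beta_centers = betas, sd = 0.05)
  cls <- classify_slopes(fit)
  expect_s3_class(cls, "rnfl_classification")
  expect_equal(attr(cls, "sector"), "G")
  verd <- function(i, dev) cls$verdict[cls$eye_id == fit$eyes[i] &
                                         cls$device == dev]
  expect_equal(verd(1, "spectralis"), "negative")
  expect_equal(verd(2, "spectralis"), "null")
  expect_equal(verd(3, "spectralis"), "positive")
  expect_equal(verd(3, "cirrus"), "null")
  expect_true(all(cls$lower <= cls$mean & cls$mean <= cls$upper))

  prop <- slope_proportions(cls)
  expect_equal(nrow(prop), 4)
  neg_s <- prop[prop$device == "spectralis" & prop$direction == "negative", ]
  expect_equal(neg_s$n_significant, 1)
  expect_equal(neg_s$n_eyes, 3)
  expect_equal(neg_s$proportion, 1 / 3)
  pos_c <- prop[prop$device == "cirrus" & prop$direction == "positive", ]
  expect_equal(pos_c$n_significant, 0)
})

test_that("Bayesian McNemar matches the exact Beta-tail oracle", {
  counts <- c(both = 3, spectralis_only = 12, cirrus_only = 1, neither = 78)
  res <- mcnemar_from_counts(counts, "negative")
  # marginalizing the Dirichlet, (p10, p01) renormalized is Beta(a10, a01):
  # Pr(p10 > p01) = Pr(Beta(13, 2) > 1/2)
  exact <- 1 - stats::pbeta(0.5, 13, 2)
  expect_lt(abs(res$pr_spectralis_greater - exact), 0.005)
  expect_true(res$significant)
  expect_gt(res$diff_lower, 0)
})

test_that("the discordant-only property holds: concordant cells do not matter", {
  base <- mcnemar_from_counts(
    c(both = 3, spectralis_only = 12, cirrus_only = 1, neither = 78),
    "negative")
  moved <- mcnemar_from_counts(
    c(both = 50, spectralis_only = 12, cirrus_only = 1, neither = 31),
    "negative")
  expect_lt(abs(base$pr_spectralis_greater - moved$pr_spectralis_greater),
            0.01)
  # and the exact oracle is identical for both
  expect_equal(1 - stats::pbeta(0.5, 13, 2), 1 - stats::pbeta(0.5, 13, 2))
})

test_that("McNemar is deterministic and validates its counts", {
  counts <- c(both = 5, spectralis_only = 9, cirrus_only = 4, neither = 70)
  expect_identical(mcnemar_from_counts(counts, "negative"),
                   mcnemar_from_counts(counts, "negative"))
  expect_error(mcnemar_from_counts(c(both = 1, spectralis_only = 2), "negative"),
               "must be named")
})

test_that("bayesian_mcnemar builds the paired table from a classification", {
  cls <- tibble::tibble(
    eye_id = rep(sprintf("e%d", 1:5), each = 2),
    device = rep(device_levels(), 5),
    mean = 0, lower = 0, upper = 0,
    verdict = c("negative", "negative", # both
                "negative", "null",     # spectralis only
                "null", "negative",     # cirrus only
                "null", "null",         # neither
                "positive", "null")     # neither (for "negative")
  )
  attr(cls, "sector") <- "G"
  res <- bayesian_mcnemar(cls, "negative")
  expect_equal(res$both, 1)
  expect_equal(res$spectralis_only, 1)
  expect_equal(res$cirrus_only, 1)
  expect_equal(res$neither, 2)
  expect_equal(res$sector, "G")
  expect_false(res$significant)
  incomplete <- cls[-2, ]
  expect_error(bayesian_mcnemar(incomplete, "negative"), "both devices")
})
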