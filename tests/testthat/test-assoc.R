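test_that("G-test matches direct evaluation of the likelihood ratio", {
  same <- rbind(c(10, 20), c(10, 20))
  r <- g_test(same)
  expect_equal(r$G, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  r <- g_test(rbind(c(10, 20), c(20, 10)))
  expect_equal(round(r$G, 3), 6.796)
  expect_equal(r$df, 1)

  set.seed(8)
  for (i in 1:20) {
    m <- matrix(stats::rpois(12, 8) + 1, 3, 4)
    expect_equal(g_test(m)$G, g_naive(m), tolerance = 1e-9)
    # homogeneity: scaling all counts by k scales G by k
    expect_equal(g_test(m * 3)$G, 3 * g_test(m)$G, tolerance = 1e-9)
  }
  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "zero row or column")
  expect_error(g_test(matrix(1, 1, 2)), "at least 2")
})

test_that("Kruskal-Wallis statistic and invariances", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # hand evaluation of the rank-sum formula: H = 12/(6*7)*(36/3+225/3)-21
  expect_equal(round(r$H, 3), 3.857)
  expect_equal(r$df, 1)

  expect_warning(r0 <- kruskal_wallis(list(c(2, 2), c(2, 2))),
                 "identical")
  expect_equal(r0$H, 0)

  # invariance to strictly monotone transforms of the pooled data
  set.seed(13)
  g <- list(stats::rnorm(12), stats::rnorm(15, 1), stats::rnorm(9))
  a <- kruskal_wallis(g)
  b <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))
  expect_equal(a$H, b$H, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "length")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("change-model rows pair responses with year-t covariates", {
  census <- census_df(
    plot_id = "P1",
    individual_id = rep("a", 4),
    year = 2010:2013,
    sex = c("F", "F", "M", "M"),
    dbh_cm = c(3.0, 3.2, 3.5, 3.6),
    rppfd_winter = rep(0.4, 4),
    rppfd_summer = rep(0.2, 4)
  )
  md <- change_model_data(census)
  # first year lacks previous-year growth; last year lacks a response
  expect_equal(nrow(md), 2)
  expect_equal(md$year, c(2011, 2012))
  expect_equal(md$response, c(1L, 0L))
  std <- attr(md, "standardization")
  # growth is the absolute DBH difference in mm
  expect_equal(unname(md$growth * std$growth["sd"] + std$growth["mean"]),
               c(2, 3))
  # pattern-specific data: at-risk subset with focal response
  md2 <- change_model_data(census, from_state = "F", to_state = "M")
  expect_equal(nrow(md2), 1)
  expect_equal(md2$response, 1L)
  md3 <- change_model_data(census, from_state = "M")
  expect_equal(nrow(md3), 1)
  expect_equal(md3$response, 0L)
})

test_that("intercept-only logistic fit has the closed-form intercept", {
  d <- data.frame(response = rep(c(1L, 0L), c(30, 70)), plot_id = "P1")
  fit <- fit_mixed_logistic(d, terms = character(0))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(30 / 70),
               tolerance = 1e-8)
  expect_equal(fit$sigma_plot, 0)
  expect_equal(fit$AIC, -2 * fit$logLik + 2)
})

test_that("zero-variance mixed fit collapses to plain logistic regression", {
  set.seed(21)
  n <- 600
  d <- data.frame(
    x = stats::rnorm(n),
    plot_id = rep(c("P1", "P2"), each = n / 2)
  )
  d$response <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * d$x))
  mixed <- fit_mixed_logistic(d, terms = "x")
  plain <- stats::glm(response ~ x, binomial(), d)
  # true plot variance is 0, so the mixed fit must land on the glm
  expect_equal(unname(mixed$coefficients), unname(coef(plain)),
               tolerance = 0.02)
  expect_lt(mixed$sigma_plot, 0.15)
  forced <- fit_mixed_logistic(d, terms = "x", random_effect = FALSE)
  expect_equal(unname(forced$coefficients), unname(coef(plain)),
               tolerance = 1e-10)
})

test_that("quadrature log-likelihood matches dense-grid integration", {
  set.seed(33)
  n_g <- 60
  d <- data.frame(
    x = stats::rnorm(2 * n_g),
    plot_id = rep(c("P1", "P2"), each = n_g)
  )
  u_true <- c(-0.4, 0.5)
  eta <- 0.3 + 0.7 * d$x + u_true[as.integer(factor(d$plot_id))]
  d$response <- stats::rbinom(2 * n_g, 1, stats::plogis(eta))
  fit <- fit_mixed_logistic(d, terms = "x", nAGQ = 25)
  beta <- fit$coefficients
  sig <- fit$sigma_plot
  # marginal likelihood by brute-force trapezoidal integration over u
  grid <- seq(-8 * sig, 8 * sig, length.out = 20001)
  w <- stats::dnorm(grid, 0, sig)
  ll <- 0
  for (g in split(seq_len(nrow(d)), d$plot_id)) {
    lin <- beta[1] + beta[2] * d$x[g]
    contrib <- vapply(grid, function(u) {
      p <- stats::plogis(lin + u)
      exp(sum(d$response[g] * log(p) + (1 - d$response[g]) * log(1 - p)))
    }, numeric(1))
    f <- contrib * w
    lik <- sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
    ll <- ll + log(lik)
  }
  expect_equal(fit$logLik, ll, tolerance = 1e-4)
})

test_that("mixed-logistic parameter recovery on simulated censuses", {
  cfg <- sim_config(n_per_plot = rep(110, 4), years = 2010:2014,
                    mode = "covariate", p_nonflower = 0, seed = 55,
                    beta = c(intercept = -1.5, dbh = 0.3, rppfd_winter = 0,
                             rppfd_summer = 0, growth = 0.3),
                    sigma_plot = 0.5)
  md <- change_model_data(simulate_census(cfg))
  fit <- fit_mixed_logistic(md)
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))
  est <- fit$coefficients
  truth <- c(0.3, 0, 0, 0.3)
  for (k in seq_along(truth)) {
    expect_lt(abs(est[k + 1] - truth[k]), 3 * se[k + 1])
  }
  expect_true(fit$converged)
})

test_that("logLik is monotone in nesting and backward AIC behaves", {
  set.seed(99)
  n <- 800
  d <- data.frame(
    dbh = stats::rnorm(n), rppfd_winter = stats::rnorm(n),
    rppfd_summer = stats::rnorm(n), growth = stats::rnorm(n),
    plot_id = rep(paste0("P", 1:4), length.out = n)
  )
  d$response <- stats::rbinom(n, 1, stats::plogis(-1 + 0.9 * d$growth))
  full <- fit_mixed_logistic(d, random_effect = FALSE)
  red <- fit_mixed_logistic(d, terms = c("dbh", "growth"),
                            random_effect = FALSE)
  expect_gte(full$logLik, red$logLik - 1e-6)

  sel <- backward_aic(d, random_effect = FALSE)
  expect_true("growth" %in% names(sel$coefficients))
  expect_true(all(diff(sel$trace$AIC) < 0))
  expect_true(is.na(sel$trace$dropped[1]))

  # all-noise predictors: selection should strip the model down
  d$response <- stats::rbinom(n, 1, 0.3)
  sel0 <- backward_aic(d, random_effect = FALSE)
  expect_lte(length(sel0$terms), 1)

  # a model already at minimal AIC is returned unchanged
  d2 <- d
  d2$response <- stats::rbinom(n, 1, stats::plogis(-1 + 1.2 * d$dbh))
  sel1 <- backward_aic(d2, full_terms = "dbh", random_effect = FALSE)
  expect_equal(nrow(sel1$trace), 1)
  expect_equal(sel1$terms, "dbh")
})
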