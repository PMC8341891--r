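test_that("fit_ols is exact on collinear data and matches normal equations", {
  pairs <- tibble::tibble(x = 1:3, y = c(1.5, 2.5, 3.5))
  fit <- fit_ols(pairs)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$residual_sd, 0)

  # independent oracle: solve the normal equations directly
  p8 <- make_pairs(8, seed = 101)
  X <- cbind(1, p8$x)
  beta <- solve(t(X) %*% X, t(X) %*% p8$y)
  fit8 <- fit_ols(p8)
  expect_equal(fit8$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit8$slope, beta[2], tolerance = 1e-10)

  expect_error(fit_ols(tibble::tibble(x = c(1, 1, 1), y = 1:3)),
               "singular")
})

test_that("hetero_loglik matches closed-form and hand-summed values", {
  one <- tibble::tibble(x = 2, y = 2, c = 0L)
  expect_equal(hetero_loglik(one, slope = 1, intercept = 0,
                             sigma2 = 1, tau2 = 0),
               -0.5 * log(2 * pi))

  # tau2 enters only through flagged rows
  p <- make_pairs(12, seed = 3, frac_distorted = 0)
  expect_equal(hetero_loglik(p, 0.9, -0.4, 0.04, 0),
               hetero_loglik(p, 0.9, -0.4, 0.04, 5))

  # frozen term-by-term hand computation, c = (0, 1, 0)
  p3 <- tibble::tibble(x = c(1, 2, 3), y = c(1.2, 2.9, 3.1),
                       c = c(0L, 1L, 0L))
  expect_equal(hetero_loglik(p3, 0.9, 0.3, 0.04, 0.25),
               -0.147450872607, tolerance = 1e-10)
})

test_that("with no flagged rows the distortion fit collapses to OLS exactly", {
  p <- make_pairs(20, seed = 7, frac_distorted = 0)
  ols <- fit_ols(p)
  for (crit in c("ml", "reml")) {
    fit <- quiet_fit(p, criterion = crit)
    expect_identical(fit$slope, ols$slope)
    expect_identical(fit$intercept, ols$intercept)
    expect_equal(fit$distortion_sd, 0)
  }
  expect_warning(fit_distortion_model(p), "no measurements flagged")
})

test_that("profile optimum matches a staged 2-D grid search", {
  for (seed in c(11, 12, 13)) {
    p <- make_pairs(20, tau = 0.4, seed = seed)
    for (crit in c("ml", "reml")) {
      fit <- quiet_fit(p, criterion = crit)
      grid <- grid_fit_hetero(p$x, p$y, p$c, criterion = crit)
      expect_lt(abs(fit$slope - grid$slope), 1e-4)
      expect_lt(abs(fit$intercept - grid$intercept), 1e-4)
      expect_lt(abs(fit$residual_sd^2 - grid$sigma2), 1e-4)
      expect_lt(abs(fit$distortion_sd^2 - grid$tau2), 1e-4)
      expect_lt(abs(fit$criterion_value - grid$value), 1e-5)
    }
  }
})

test_that("estimates agree with nlme::gls with a two-group variance function", {
  skip_if_not_installed("nlme")
  p <- make_pairs(40, tau = 0.4, seed = 21)
  df <- data.frame(x = p$x, y = p$y, grp = factor(p$c))
  for (crit in c("REML", "ML")) {
    g <- nlme::gls(y ~ x, data = df,
                   weights = nlme::varIdent(form = ~ 1 | grp),
                   method = crit)
    fit <- quiet_fit(p, criterion = tolower(crit))
    expect_equal(fit$slope, unname(coef(g)["x"]), tolerance = 1e-5)
    expect_equal(fit$intercept, unname(coef(g)["(Intercept)"]),
                 tolerance = 1e-5)
    # per-group SDs: reference-group sigma times the variance-function
    # coefficients (allCoef includes the reference at 1)
    sds <- g$sigma * coef(g$modelStruct$varStruct,
                          unconstrained = FALSE, allCoef = TRUE)
    sigma2_gls <- unname(sds["0"]^2)
    tau2_gls <- unname(sds["1"]^2 - sds["0"]^2)
    expect_equal(fit$residual_sd^2, sigma2_gls, tolerance = 1e-4)
    expect_equal(fit$distortion_sd^2, tau2_gls, tolerance = 1e-3)
    expect_equal(fit$criterion_value, as.numeric(logLik(g)),
                 tolerance = 1e-5)
  }
})

test_that("fits are equivariant under shifts of y and x", {
  p <- make_pairs(25, tau = 0.4, seed = 31)
  base <- quiet_fit(p)
  k <- 0.7
  up <- quiet_fit(dplyr::mutate(p, y = y + k))
  expect_equal(up$slope, base$slope, tolerance = 1e-7)
  expect_equal(up$intercept, base$intercept + k, tolerance = 1e-7)
  expect_equal(up$residual_sd, base$residual_sd, tolerance = 1e-7)
  expect_equal(up$distortion_sd, base$distortion_sd, tolerance = 1e-6)

  right <- quiet_fit(dplyr::mutate(p, x = x + k))
  expect_equal(right$slope, base$slope, tolerance = 1e-7)
  expect_equal(right$intercept, base$intercept - k * base$slope,
               tolerance = 1e-6)
})

test_that("the ML distortion fit never has lower likelihood than OLS", {
  for (seed in 41:50) {
    p <- make_pairs(15, tau = if (seed %% 2) 0 else 0.4, seed = seed)
    fit <- quiet_fit(p, criterion = "ml")
    ols <- fit_ols(p)
    expect_gte(fit$log_likelihood, ols$log_likelihood - 1e-8)
  }
})

test_that("parameter recovery with balanced flags", {
  # at n = 500 the distortion variance is pinned down to +/- 0.05
  # (its sampling SD is ~0.024 there); the slope's own sampling SD is
  # ~0.12 at n = 500 under these generating values, so slope recovery
  # to +/- 0.05 is checked at a larger n where SE(slope) ~ 0.018
  ok_tau <- vapply(1:100, function(seed) {
    p <- make_pairs(500, tau = 0.4, seed = 600 + seed)
    fit <- quiet_fit(p)
    abs(fit$distortion_sd^2 - 0.16) <= 0.05
  }, logical(1))
  expect_gte(mean(ok_tau), 0.95)

  ok_both <- vapply(1:40, function(seed) {
    p <- make_pairs(20000, tau = 0.4, seed = 600 + seed)
    fit <- quiet_fit(p)
    abs(fit$slope - 0.91) <= 0.05 &&
      abs(fit$distortion_sd^2 - 0.16) <= 0.05
  }, logical(1))
  expect_gte(mean(ok_both), 0.9)
})

test_that("lrt_distortion is zero at the boundary and detects strong tau", {
  # flags carry no signal: tau optimises to 0, statistic 0, p = 1
  p0 <- make_pairs(30, tau = 0, seed = 71)
  res0 <- suppressWarnings(lrt_distortion(p0))
  if (res0$statistic == 0) expect_equal(res0$p_value, 1)
  expect_gte(res0$statistic, 0)
  expect_equal(suppressWarnings(lrt_distortion(p0, boundary_mixture = TRUE)
                                )$p_value,
               if (res0$statistic == 0) 1 else 0.5 * res0$p_value)

  # Monte-Carlo power at tau2 = 0.5, n = 40
  hits <- vapply(1:200, function(seed) {
    p <- make_pairs(40, tau = sqrt(0.5), seed = 5000 + seed)
    suppressWarnings(lrt_distortion(p))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("predict_feature follows the back-transformed power law", {
  fit <- structure(list(slope = 1, intercept = 0), class = "allom_fit")
  expect_equal(predict_feature(fit, 100), 100)
  fit$intercept <- -1.26
  expect_equal(predict_feature(fit, 100), 10^0.74, tolerance = 1e-10)
  # an intercept offset of delta multiplies every prediction by 10^delta
  fit2 <- fit; fit2$intercept <- fit$intercept + 0.25
  x <- c(10, 100, 500)
  expect_equal(predict_feature(fit2, x) / predict_feature(fit, x),
               rep(10^0.25, 3))
  expect_error(predict_feature(fit, -5), "positive")
})

test_that("small or one-sided samples warn but still fit", {
  p <- make_pairs(8, tau = 0.3, seed = 81)
  # n = 8 with a 4/4 split triggers both the size and group warnings
  expect_warning(expect_warning(fit_distortion_model(p), "unstable"),
                 "at least 5 per group")
  p2 <- make_pairs(20, tau = 0.3, frac_distorted = 0.1, seed = 82)
  expect_warning(fit_distortion_model(p2), "at least 5 per group")
  p3 <- dplyr::mutate(make_pairs(10, seed = 83), c = 1L)
  expect_warning(f3 <- fit_distortion_model(p3), "not identifiable")
  expect_equal(f3$distortion_sd, 0)
})

test_that("tidy, glance and serialisation expose the fit parameters", {
  p <- make_pairs(30, tau = 0.4, seed = 91)
  fit <- quiet_fit(p)
  td <- tidy(fit)
  expect_equal(td$term,
               c("slope", "intercept", "residual_sd", "distortion_sd"))
  expect_equal(td$estimate[1], fit$slope)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "hetero-reml")
  rec <- fit_to_record(fit)
  expect_named(rec, c("slope", "intercept", "residual_sd",
                      "distortion_sd", "log_likelihood", "method",
                      "n", "n_distorted"))
})
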