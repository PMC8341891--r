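#' @keywords internal
new_allom_fit <- function(slope, intercept, residual_sd, distortion_sd,
                          log_likelihood, method, n, n_distorted,
                          criterion_value = NA_real_, lambda = NA_real_) {
  structure(
    list(slope = slope, intercept = intercept,
         residual_sd = residual_sd, distortion_sd = distortion_sd,
         log_likelihood = log_likelihood, method = method,
         n = n, n_distorted = n_distorted,
         criterion_value = criterion_value, lambda = lambda),
    class = "allom_fit")
}

#' Ordinary least squares allometric fit
#'
#' Fits the homoscedastic log-log regression `y = slope * x + intercept`
#' by closed-form least squares, ignoring distortion flags. The slope is
#' the coefficient of allometry: 1 is isometry, above 1 positive and
#' below 1 negative allometry.
#'
#' @param pairs Data frame with numeric columns `x` and `y` (log10 mm)
#'   and optionally `c` (ignored here), e.g. from [to_log_pairs()] or
#'   [simulate_dataset()].
#'
#' @return An `"allom_fit"` object; see [fit_distortion_model()] for the
#'   fields. `residual_sd` is `sqrt(RSS / (n - 2))`; the log-likelihood
#'   is evaluated at the maximum-likelihood variance `RSS / n`.
#' @seealso [fit_distortion_model()], [tidy.allom_fit()]
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n = 25), seed = 1)
#' fit_ols(sim)
fit_ols <- function(pairs) {
  d <- .check_pairs(pairs, need_c = FALSE)
  if (d$n < 3) abort("need at least 3 pairs.")
  res <- .ols_core(d$x, d$y)
  if (is.null(res)) {
    abort("singular design: all x values are identical.")
  }
  n <- d$n
  sig2_ml <- res$rss / n
  loglik <- if (sig2_ml > 0) {
    -0.5 * n * (log(2 * pi * sig2_ml) + 1)
  } else Inf
  nd <- if ("c" %in% names(pairs)) sum(.check_pairs(pairs)$c) else 0L
  new_allom_fit(slope = res$slope, intercept = res$intercept,
                residual_sd = sqrt(res$rss / (n - 2)), distortion_sd = 0,
                log_likelihood = loglik, method = "ols",
                n = n, n_distorted = nd)
}

#' Log-likelihood of the heteroscedastic distortion model
#'
#' Evaluates the marginal Gaussian log-likelihood of the model in which
#' each observation has variance `sigma2 + c * tau2`: flagged
#' (distorted) measurements carry the extra distortion variance `tau2`,
#' unflagged ones do not.
#'
#' @inheritParams fit_ols
#' @param slope,intercept Fixed-effect coefficients.
#' @param sigma2 Residual variance (log10 scale), `>= 0`.
#' @param tau2 Distortion variance (log10 scale), `>= 0`.
#'
#' @return A single numeric log-likelihood.
#' @export
hetero_loglik <- function(pairs, slope, intercept, sigma2, tau2) {
  d <- .check_pairs(pairs)
  if (sigma2 < 0 || tau2 < 0) {
    abort("`sigma2` and `tau2` must be non-negative.")
  }
  .hetero_loglik_core(d$x, d$y, d$c, slope, intercept, sigma2, tau2)
}

#' Fit the distortion-aware allometric model
#'
#' Fits `y = slope * x + intercept + e`, `Var(e) = sigma2 + c * tau2`,
#' the marginal equivalent of a mixed model with a mean-zero random
#' distortion effect attached only to flagged measurements. When the
#' flags carry no signal the fit collapses to ordinary least squares
#' with `tau2 = 0`, so the model is safe to apply under cautious
#' over-flagging.
#'
#' Estimation profiles the variance ratio `lambda = tau2 / sigma2`: for
#' fixed `lambda` the weighted (GLS) coefficients and the residual
#' variance have closed forms, leaving a one-dimensional search over
#' `log(lambda)` on \[-12, 12\] (tolerance 1e-8) plus an explicit
#' boundary evaluation at `lambda = 0`. No random restarts are needed;
#' the profile objective is smooth in one variable.
#'
#' @inheritParams fit_ols
#' @param pairs Data frame with numeric columns `x`, `y` and a 0/1
#'   distortion flag `c`.
#' @param criterion `"reml"` (default; restricted maximum likelihood,
#'   the usual convention for variance components) or `"ml"`. Likelihood
#'   ratio tests must use `"ml"` fits; see [lrt_distortion()].
#'
#' @return An object of class `"allom_fit"`: a list with elements
#'   `slope`, `intercept`, `residual_sd` (`sigma`, log10 units),
#'   `distortion_sd` (`tau`, log10 units), `log_likelihood` (the
#'   marginal ML log-likelihood evaluated at the estimates),
#'   `method` (`"hetero-ml"` or `"hetero-reml"`), `n`, `n_distorted`,
#'   `criterion_value` (the maximised ML or REML criterion) and
#'   `lambda` (`tau2 / sigma2`).
#'
#' @details Variance-component estimation is unstable with fewer than
#'   about five specimens per flag group; the fit then proceeds with a
#'   warning rather than refusing, since with no detectable distortion
#'   variance it simply returns the OLS solution. With an empty (or
#'   full) flag group `tau2` is not identifiable and is fixed at 0 with
#'   a warning.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n = 50), seed = 1)
#' fit <- fit_distortion_model(sim)
#' tidy(fit)
fit_distortion_model <- function(pairs, criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  d <- .check_pairs(pairs)
  if (d$n < 3) abort("need at least 3 pairs.")
  if (length(unique(d$x)) < 2) {
    abort("singular design: all x values are identical.")
  }
  nd <- sum(d$c)
  if (nd == 0) {
    warn("no measurements flagged distorted; tau is fixed at 0.")
  } else if (nd == d$n) {
    warn("all measurements flagged distorted; tau is not identifiable and is fixed at 0.")
  } else {
    if (d$n < 10) {
      warn(paste0("only ", d$n, " pairs: variance-component estimates are ",
                  "unstable below ~10 specimens."))
    }
    if (min(nd, d$n - nd) < 5) {
      warn(paste0("smallest flag group has ", min(nd, d$n - nd),
                  " member(s); at least 5 per group are recommended for ",
                  "stable distortion-variance estimation."))
    }
  }
  res <- .fit_hetero_core(d$x, d$y, d$c, criterion = criterion)
  if (is.null(res)) abort("singular design.")
  new_allom_fit(slope = res$slope, intercept = res$intercept,
                residual_sd = sqrt(res$sigma2),
                distortion_sd = sqrt(res$tau2),
                log_likelihood = res$log_likelihood,
                method = paste0("hetero-", criterion),
                n = res$n, n_distorted = res$n_distorted,
                criterion_value = res$criterion_value,
                lambda = res$lambda)
}

#' Likelihood ratio test for the distortion variance component
#'
#' Compares the distortion-aware model (extra variance `tau2` on flagged
#' measurements) against plain OLS by a likelihood ratio test. Both
#' models are fitted by maximum likelihood (REML criteria are not used
#' for the test). The statistic is referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' Because the null value `tau2 = 0` lies on the boundary of the
#' parameter space, the plain 1-df reference is conservative; the
#' standard remedy is a 50:50 mixture of a point mass at 0 and
#' chi-squared(1), available with `boundary_mixture = TRUE` (the plain
#' reference is the default).
#'
#' @inheritParams fit_distortion_model
#' @param boundary_mixture Use the 50:50 boundary-mixture reference
#'   instead of plain chi-squared(1).
#'
#' @return A one-row tibble: `statistic` (`2 * delta log-likelihood`,
#'   truncated at 0), `df`, `p_value`.
#' @export
lrt_distortion <- function(pairs, boundary_mixture = FALSE) {
  fit1 <- fit_distortion_model(pairs, criterion = "ml")
  fit0 <- fit_ols(pairs)
  stat <- max(0, 2 * (fit1$log_likelihood - fit0$log_likelihood))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mixture) {
    p <- if (stat == 0) 1 else 0.5 * p
  }
  tibble(statistic = stat, df = 1, p_value = p)
}

#' Predict a feature size from an allometric fit
#'
#' Back-transforms the log-log regression to the millimetre scale:
#' `10 ^ (slope * log10(x_mm) + intercept)`.
#'
#' @param fit An `"allom_fit"`.
#' @param x_mm Reference measurement(s) in mm, strictly positive.
#' @return Predicted focal measurement(s) in mm.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n = 25), seed = 1)
#' predict_feature(fit_ols(sim), x_mm = 100)
predict_feature <- function(fit, x_mm) {
  if (!inherits(fit, "allom_fit")) abort("`fit` must be an `allom_fit`.")
  x_mm <- as.numeric(x_mm)
  if (anyNA(x_mm) || any(x_mm <= 0)) {
    abort("`x_mm` must be strictly positive.")
  }
  10 ^ (fit$slope * log10(x_mm) + fit$intercept)
}

#' @export
print.allom_fit <- function(x, digits = 4, ...) {
  cat("Allometric fit (", x$method, "), n = ", x$n,
      " (", x$n_distorted, " distorted)\n", sep = "")
  cat("  slope (coef. of allometry): ", format(x$slope, digits = digits),
      "\n  intercept:                  ", format(x$intercept, digits = digits),
      "\n  residual SD (sigma):        ", format(x$residual_sd, digits = digits),
      "\n  distortion SD (tau):        ", format(x$distortion_sd, digits = digits),
      "\n  log-likelihood:             ", format(x$log_likelihood, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an allometric fit
#'
#' @param x An `"allom_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy allom_fit
#' @export
tidy.allom_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept", "residual_sd", "distortion_sd"),
         estimate = c(x$slope, x$intercept, x$residual_sd, x$distortion_sd))
}

#' One-row summary of an allometric fit
#'
#' @param x An `"allom_fit"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance allom_fit
#' @export
glance.allom_fit <- function(x, ...) {
  tibble(method = x$method, n = x$n, n_distorted = x$n_distorted,
         slope = x$slope, intercept = x$intercept,
         residual_sd = x$residual_sd, distortion_sd = x$distortion_sd,
         log_likelihood = x$log_likelihood)
}

#' Serialise an allometric fit to a flat list
#'
#' Suitable for `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#'
#' @param fit An `"allom_fit"`.
#' @return A named list of scalars.
#' @export
fit_to_record <- function(fit) {
  if (!inherits(fit, "allom_fit")) abort("`fit` must be an `allom_fit`.")
  fit[c("slope", "intercept", "residual_sd", "distortion_sd",
        "log_likelihood", "method", "n", "n_distorted")]
}
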