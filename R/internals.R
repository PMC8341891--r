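# Internal numerical core: plain-vector fitters shared by the exported
# estimators, the study driver and the bootstrap. All validation of
# user-facing inputs happens in the exported wrappers.

# Extract and check the (x, y, c) columns of a log-pair table.
.check_pairs <- function(pairs, need_c = TRUE, call = rlang::caller_env()) {
  if (!is.data.frame(pairs)) {
    abort("`pairs` must be a data frame with columns `x`, `y` and `c`.",
          call = call)
  }
  need <- c("x", "y", if (need_c) "c")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("`pairs` is missing column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."),
          call = call)
  }
  x <- as.numeric(pairs$x)
  y <- as.numeric(pairs$y)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite and non-missing.", call = call)
  }
  c_flag <- if (need_c && "c" %in% names(pairs)) {
    cc <- pairs$c
    if (is.logical(cc)) cc <- as.integer(cc)
    cc <- as.numeric(cc)
    if (anyNA(cc) || !all(cc %in% c(0, 1))) {
      abort("distortion flag `c` must be 0 or 1.", call = call)
    }
    as.integer(cc)
  } else {
    integer(length(x))
  }
  list(x = x, y = y, c = c_flag, n = length(x))
}

# Closed-form simple least squares. Returns NULL on singular design when
# `allow_fail` (used by study/bootstrap loops, which count failures).
.ols_core <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  dx <- x - xbar
  sxx <- sum(dx^2)
  if (sxx <= 0) return(NULL)
  slope <- sum(dx * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  r <- y - intercept - slope * x
  rss <- sum(r^2)
  list(slope = slope, intercept = intercept, rss = rss, n = n)
}

# Weighted least squares with weights w (already 1/relative-variance).
.gls_core <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  dx <- x - xbar
  sxx <- sum(w * dx^2)
  if (sxx <= 0) return(NULL)
  slope <- sum(w * dx * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  r <- y - intercept - slope * x
  list(slope = slope, intercept = intercept, wrss = sum(w * r^2),
       sw = sw, sxx = sxx)
}

# Gaussian log-likelihood of the heteroscedastic model at given parameters:
# v_i = sigma2 + c_i * tau2.
.hetero_loglik_core <- function(x, y, c_flag, slope, intercept, sigma2, tau2) {
  v <- sigma2 + c_flag * tau2
  if (any(v <= 0)) {
    abort("per-observation variance sigma2 + c * tau2 must be positive.")
  }
  r <- y - intercept - slope * x
  -0.5 * sum(log(2 * pi * v) + r^2 / v)
}

# Profile objective in log(lambda), lambda = tau2 / sigma2.
# criterion "ml":    profile log-likelihood.
# criterion "reml":  restricted log-likelihood (error contrasts), i.e. the
#   weighted-coefficients log-likelihood with sigma2 profiled at wRSS/(n-2)
#   and the -1/2 log det(X' W X) adjustment folded in.
.hetero_profile_obj <- function(lambda, x, y, c_flag, criterion) {
  n <- length(x)
  w <- 1 / (1 + lambda * c_flag)
  g <- .gls_core(x, y, w)
  if (is.null(g)) return(-Inf)
  sumlog <- sum(log1p(lambda * c_flag))
  if (criterion == "ml") {
    sig2 <- g$wrss / n
    if (sig2 <= 0) return(Inf) # exact fit: unbounded likelihood
    -0.5 * (n * log(2 * pi * sig2) + sumlog + n)
  } else {
    sig2 <- g$wrss / (n - 2)
    if (sig2 <= 0) return(Inf)
    -0.5 * ((n - 2) * log(2 * pi * sig2) + sumlog +
              log(g$sw * g$sxx) + (n - 2))
  }
}

# Fit the heteroscedastic model by 1-D search over log(lambda) on
# [-12, 12] plus an explicit boundary evaluation at lambda = 0.
# Returns NULL on singular design.
.fit_hetero_core <- function(x, y, c_flag, criterion = "reml",
                             loglam_bounds = c(-12, 12), tol = 1e-8) {
  n <- length(x)
  ols <- .ols_core(x, y)
  if (is.null(ols)) return(NULL)

  nd <- sum(c_flag)
  identifiable <- nd > 0 && nd < n
  obj0 <- .hetero_profile_obj(0, x, y, c_flag, criterion)

  if (identifiable) {
    opt <- stats::optimize(
      function(ll) .hetero_profile_obj(exp(ll), x, y, c_flag, criterion),
      interval = loglam_bounds, maximum = TRUE, tol = tol)
    take_boundary <- !is.finite(opt$objective) && opt$objective < 0 ||
      obj0 >= opt$objective
  } else {
    take_boundary <- TRUE
  }

  if (take_boundary) {
    lambda <- 0
    crit_val <- obj0
    slope <- ols$slope
    intercept <- ols$intercept
    wrss <- ols$rss
  } else {
    lambda <- exp(opt$maximum)
    crit_val <- opt$objective
    g <- .gls_core(x, y, 1 / (1 + lambda * c_flag))
    slope <- g$slope
    intercept <- g$intercept
    wrss <- g$wrss
  }
  sigma2 <- if (criterion == "ml") wrss / n else wrss / (n - 2)
  tau2 <- lambda * sigma2
  loglik <- if (sigma2 > 0) {
    .hetero_loglik_core(x, y, c_flag, slope, intercept, sigma2, tau2)
  } else {
    Inf # interpolating fit: likelihood unbounded as sigma2 -> 0
  }
  list(slope = slope, intercept = intercept, sigma2 = sigma2, tau2 = tau2,
       lambda = lambda, criterion = criterion, criterion_value = crit_val,
       log_likelihood = loglik, n = n, n_distorted = nd)
}

# Quantile convention used throughout: linear interpolation (type 7).
.q95 <- function(v) {
  stats::quantile(v, probs = c(0.025, 0.975), names = FALSE, type = 7)
}
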