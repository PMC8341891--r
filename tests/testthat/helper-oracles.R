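# Shared fixtures and independent oracles for the estimator tests.

# Simulate a plain (x, y, c) tibble directly, bypassing the package's own
# generator, so estimator tests do not depend on simulate_dataset().
make_pairs <- function(n, slope = 0.91, intercept = -0.37, sigma = 0.3,
                       tau = 0, frac_distorted = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, 2.39, 0.14)
  c_flag <- as.integer(seq_len(n) %in% sample(n, round(frac_distorted * n)))
  y <- intercept + slope * x + rnorm(n, 0, sigma) +
    c_flag * rnorm(n, 0, tau)
  tibble::tibble(x = x, y = y, c = c_flag)
}

quiet_fit <- function(...) suppressWarnings(fit_distortion_model(...))

# Full-surface evaluation of the ML or REML criterion at given variance
# components (sigma2, tau2), with the coefficients at their exact GLS
# optimum for that variance structure. Written from the canonical
# matrix-free formulas, independent of the package's lambda profiling:
#   ML:    -1/2 [ n log 2pi + sum log v + sum r^2 / v ]
#   REML:  -1/2 [ (n-2) log 2pi + sum log v + log det(X' V^-1 X)
#                 + sum r^2 / v ]
criterion_at <- function(x, y, c_flag, sigma2, tau2, criterion) {
  v <- sigma2 + c_flag * tau2
  if (any(v <= 0)) return(list(value = -Inf))
  w <- 1 / v
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  r <- y - intercept - slope * x
  quad <- sum(r^2 * w)
  n <- length(x)
  value <- if (criterion == "ml") {
    -0.5 * (n * log(2 * pi) + sum(log(v)) + quad)
  } else {
    # det(X' V^-1 X) = sw * sxx for the centred 2-column design
    -0.5 * ((n - 2) * log(2 * pi) + sum(log(v)) + log(sw * sxx) + quad)
  }
  list(value = value, slope = slope, intercept = intercept)
}

# Staged 2-D grid search over (sigma2, tau2), zooming four times; the
# boundary tau2 = 0 is always a grid point in the first stage.
grid_fit_hetero <- function(x, y, c_flag, criterion = "ml",
                            sigma2_range = c(1e-4, 1), tau2_max = 1) {
  s_grid <- seq(sigma2_range[1], sigma2_range[2], length.out = 41)
  t_grid <- c(0, seq(1e-6, tau2_max, length.out = 40))
  best <- list(value = -Inf)
  for (stage in 1:4) {
    for (s2 in s_grid) for (t2 in t_grid) {
      res <- criterion_at(x, y, c_flag, s2, t2, criterion)
      if (res$value > best$value) {
        best <- c(res, list(sigma2 = s2, tau2 = t2))
      }
    }
    ds <- max(diff(s_grid[1:2]), 1e-9) * 2
    dt <- max(t_grid[3] - t_grid[2], 1e-9) * 2
    s_grid <- seq(max(1e-8, best$sigma2 - ds), best$sigma2 + ds,
                  length.out = 41)
    t_grid <- seq(max(0, best$tau2 - dt), best$tau2 + dt,
                  length.out = 41)
  }
  best
}

# Write a measurement CSV from a data frame of rows; returns the path.
write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
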