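#' Distortion assignment design
#'
#' Describes how simulated specimens are assigned the distorted flag:
#' either an independent Bernoulli draw per specimen (`"binomial"`,
#' probability `p`), or exact group counts in randomised order
#' (`"fixed"`), e.g. 5 undistorted / 5 distorted at n = 10, or the
#' largely distorted 5 / 10 design at n = 15.
#'
#' @param kind `"binomial"` or `"fixed"`.
#' @param p Distortion probability for the binomial design.
#' @param n_undistorted,n_distorted Group counts for the fixed design.
#' @return A `"distortion_scheme"` list.
#' @export
#' @examples
#' distortion_scheme("fixed", n_undistorted = 5, n_distorted = 10)
distortion_scheme <- function(kind = c("binomial", "fixed"), p = 0.5,
                              n_undistorted = NULL, n_distorted = NULL) {
  kind <- match.arg(kind)
  if (kind == "binomial") {
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
      abort("`p` must be a probability in [0, 1].")
    }
  } else {
    if (is.null(n_undistorted) || is.null(n_distorted) ||
        n_undistorted < 0 || n_distorted < 0) {
      abort("fixed design needs non-negative `n_undistorted` and `n_distorted`.")
    }
  }
  structure(list(kind = kind, p = p,
                 n_undistorted = n_undistorted, n_distorted = n_distorted),
            class = "distortion_scheme")
}

#' Draw a distortion-flag vector
#'
#' Variance-component fits need both flag groups populated (at least
#' five specimens per group for stability), so the binomial design
#' redraws until both groups have 5 or more members. That is only
#' feasible from n = 15 upwards; for n = 10 the fixed 5/5 design must be
#' used instead, and the binomial design errors below n = 15.
#'
#' @param n Number of specimens, `>= 3`.
#' @param scheme A [distortion_scheme()].
#' @return Integer 0/1 vector of length `n`. Fixed designs return the
#'   exact counts in randomised order.
#' @export
draw_design <- function(n, scheme = distortion_scheme()) {
  if (!inherits(scheme, "distortion_scheme")) {
    abort("`scheme` must be a `distortion_scheme`.")
  }
  if (n < 3) abort("`n` must be at least 3.")
  if (scheme$kind == "fixed") {
    if (scheme$n_undistorted + scheme$n_distorted != n) {
      abort(paste0("fixed design counts (", scheme$n_undistorted, " + ",
                   scheme$n_distorted, ") do not sum to n = ", n, "."))
    }
    return(sample(rep(c(0L, 1L),
                      c(scheme$n_undistorted, scheme$n_distorted))))
  }
  if (n < 15) {
    abort(paste0("binomial design requires n >= 15 (cannot reliably give ",
                 ">= 5 specimens per flag group below that); use a fixed ",
                 "design, e.g. distortion_scheme('fixed', n_undistorted = 5, ",
                 "n_distorted = 5)."))
  }
  for (i in seq_len(10000L)) {
    c_flag <- stats::rbinom(n, 1L, scheme$p)
    k <- sum(c_flag)
    if (k >= 5 && n - k >= 5) return(as.integer(c_flag))
  }
  abort("could not draw a design with >= 5 specimens per group; `p` too extreme?")
}

#' Simulation configuration
#'
#' Generative parameters of the distorted-allometry simulator. The
#' defaults emulate an empirical cynodont cranial regression of log10
#' snout length on log10 skull length: slope 0.91 (slightly negative
#' allometry), intercept -0.37, reference size log10-normal with mean
#' 2.39 (about a 245 mm skull) and SD 0.14, and distortion noise with SD
#' 0.4 -- about 1.5 times the typical residual SD, i.e. strong
#' deformation.
#'
#' Residual variation is specified as "mean 0.3, SD 0.1". Under the
#' default reading (`resid_interpretation = "sd_draw"`) each simulated
#' dataset draws its own residual SD from Normal(0.3, 0.1), truncated
#' positive by redraw, and the errors themselves are mean-zero -- so an
#' OLS fit to clean data recovers the generating slope and intercept, as
#' a validity check requires. The literal alternative
#' (`"literal_mean"`: errors drawn from Normal(0.3, 0.1), shifting every
#' response by +0.3) is provided for sensitivity analysis only.
#'
#' @param n Specimens per dataset, `>= 3`.
#' @param alpha,beta Generating slope and intercept (log10/log10 scale).
#' @param resid_sd_mean,resid_sd_sd Mean and SD of the per-dataset
#'   residual SD draw (log10 units).
#' @param gamma_sd SD of the distortion noise added to flagged
#'   measurements (log10 units), `>= 0`.
#' @param x_log_mean,x_log_sd Mean and SD of log10 reference size.
#' @param scheme A [distortion_scheme()].
#' @param resid_interpretation `"sd_draw"` (default) or `"literal_mean"`;
#'   see above.
#' @param seed Optional integer seed stored in the config and used by
#'   [simulate_dataset()] when no seed is given there.
#' @return A `"sim_config"` list.
#' @export
simulation_config <- function(n, alpha = 0.91, beta = -0.37,
                              resid_sd_mean = 0.3, resid_sd_sd = 0.1,
                              gamma_sd = 0.4,
                              x_log_mean = 2.39, x_log_sd = 0.14,
                              scheme = distortion_scheme(),
                              resid_interpretation = c("sd_draw",
                                                       "literal_mean"),
                              seed = NULL) {
  resid_interpretation <- match.arg(resid_interpretation)
  if (n < 3) abort("`n` must be at least 3.")
  if (gamma_sd < 0) abort("`gamma_sd` must be non-negative.")
  if (resid_sd_mean <= 0) abort("`resid_sd_mean` must be positive.")
  if (resid_sd_sd < 0) abort("`resid_sd_sd` must be non-negative.")
  if (x_log_sd <= 0) abort("`x_log_sd` must be positive.")
  if (!inherits(scheme, "distortion_scheme")) {
    abort("`scheme` must be a `distortion_scheme`.")
  }
  structure(list(n = as.integer(n), alpha = alpha, beta = beta,
                 resid_sd_mean = resid_sd_mean, resid_sd_sd = resid_sd_sd,
                 gamma_sd = gamma_sd,
                 x_log_mean = x_log_mean, x_log_sd = x_log_sd,
                 scheme = scheme,
                 resid_interpretation = resid_interpretation,
                 seed = seed),
            class = "sim_config")
}

#' Simulate one distorted allometric dataset
#'
#' Generates a dataset under the two-stage model: clean responses
#' `y_clean = alpha * x + beta + eps`, then distortion noise
#' `y = y_clean + c * gamma` added only to flagged rows. All draws come
#' from one seeded stream in a fixed, documented order -- x, then the
#' per-dataset residual SD, then eps, then gamma, then the flags c -- so
#' a seed pins down the whole dataset.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; overrides `config$seed`. When both
#'   are `NULL` the current RNG state is used (as inside [run_study()],
#'   which seeds once for the whole study).
#' @return A tibble of class `"allom_sim"` with columns `specimen_id`,
#'   `x`, `y`, `c`, `y_clean`, `gamma`, and attributes `config` and
#'   `resid_sd` (the drawn per-dataset residual SD, `NA` under the
#'   literal interpretation).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n = 25), seed = 42)
#' dplyr::count(sim, c)
simulate_dataset <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must come from simulation_config().")
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n

  x <- stats::rnorm(n, config$x_log_mean, config$x_log_sd)
  if (config$resid_interpretation == "sd_draw") {
    s <- stats::rnorm(1, config$resid_sd_mean, config$resid_sd_sd)
    while (s <= 0) s <- stats::rnorm(1, config$resid_sd_mean, config$resid_sd_sd)
    eps <- stats::rnorm(n, 0, s)
  } else {
    s <- NA_real_
    eps <- stats::rnorm(n, config$resid_sd_mean, config$resid_sd_sd)
  }
  gamma <- stats::rnorm(n, 0, config$gamma_sd)
  c_flag <- draw_design(n, config$scheme)

  y_clean <- config$alpha * x + config$beta + eps
  out <- tibble(
    specimen_id = sprintf("sim-%03d", seq_len(n)),
    x = x, y = y_clean + c_flag * gamma, c = c_flag,
    y_clean = y_clean, gamma = gamma)
  attr(out, "config") <- config
  attr(out, "resid_sd") <- s
  class(out) <- c("allom_sim", class(out))
  out
}

#' Convert a simulated dataset to a measurement table
#'
#' Back-transforms a simulated log-pair dataset to the millimetre-scale
#' long format used by [read_measurements()], with one reference-feature
#' row (flagged undistorted) and one focal-feature row (carrying the
#' simulated flag) per specimen. Useful for writing simulator output as
#' a CSV that the empirical pipeline can re-read.
#'
#' @param sim An `"allom_sim"` tibble from [simulate_dataset()].
#' @param x_feature,y_feature Feature names to use in the table.
#' @return A `"measurement_tbl"` tibble.
#' @export
sim_to_measurements <- function(sim, x_feature = "reference_length",
                                y_feature = "focal_length") {
  if (!inherits(sim, "allom_sim")) {
    abort("`sim` must come from simulate_dataset().")
  }
  long <- dplyr::bind_rows(
    tibble(specimen_id = sim$specimen_id, feature = x_feature,
           value_mm = 10 ^ sim$x, distorted = 0L),
    tibble(specimen_id = sim$specimen_id, feature = y_feature,
           value_mm = 10 ^ sim$y, distorted = as.integer(sim$c)))
  validate_measurements(dplyr::arrange(long, .data$specimen_id,
                                       .data$feature))
}
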