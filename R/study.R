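#' Configuration for the simulation study
#'
#' Describes a full Monte Carlo comparison of estimators: for each
#' sample size and replicate, one dataset is simulated and every
#' requested model is fitted to (a view of) that same draw, so the
#' models are compared on identical data and paired tests are
#' well-defined.
#'
#' The four models are: `ols_clean` -- OLS on the clean responses before
#' distortion noise (the idealised benchmark); `ols_full` -- OLS on the
#' distorted responses, flags ignored (the naive analysis);
#' `glmm_full` -- the distortion-aware heteroscedastic fit on the
#' distorted responses with flags; and `ols_undistorted_subset` -- OLS
#' on the distorted responses restricted to unflagged rows (the common
#' practice of excluding distorted specimens).
#'
#' @param sample_sizes Integer vector of dataset sizes.
#' @param replicates Simulated datasets per sample size.
#' @param sim A [simulation_config()] template; its `n` and `scheme` are
#'   overridden per sample size.
#' @param models Subset of the four model tags above.
#' @param criterion Criterion for the `glmm_full` fit (`"reml"` or
#'   `"ml"`).
#' @param schemes Optional named list (names = sample sizes as
#'   characters) of [distortion_scheme()] overrides. By default, sizes
#'   below 15 use a fixed near-half split (5/5 at n = 10) because a
#'   binomial draw cannot reliably populate both flag groups there;
#'   sizes 15 and above use the binomial 50% design.
#' @param seed Optional integer seed for the whole study.
#' @return A `"study_config"` list.
#' @export
study_config <- function(sample_sizes = c(10, 15, 25, 50),
                         replicates = 2000,
                         sim = simulation_config(n = 10),
                         models = c("ols_clean", "ols_full", "glmm_full",
                                    "ols_undistorted_subset"),
                         criterion = c("reml", "ml"),
                         schemes = NULL, seed = NULL) {
  criterion <- match.arg(criterion)
  models <- match.arg(models, several.ok = TRUE)
  if (replicates < 1) abort("`replicates` must be at least 1.")
  if (!inherits(sim, "sim_config")) {
    abort("`sim` must come from simulation_config().")
  }
  if ("glmm_full" %in% models && any(sample_sizes < 10)) {
    abort("`glmm_full` requires sample sizes of at least 10.")
  }
  structure(list(sample_sizes = as.integer(sample_sizes),
                 replicates = as.integer(replicates), sim = sim,
                 models = models, criterion = criterion,
                 schemes = schemes, seed = seed),
            class = "study_config")
}

.default_scheme_for_n <- function(n) {
  if (n < 15) {
    distortion_scheme("fixed", n_undistorted = floor(n / 2),
                      n_distorted = ceiling(n / 2))
  } else {
    distortion_scheme("binomial", p = 0.5)
  }
}

# Fit one model tag to one simulated dataset; NULL on failure.
.fit_study_model <- function(model, sim, criterion) {
  x <- sim$x
  switch(model,
    ols_clean = {
      f <- .ols_core(x, sim$y_clean)
      if (is.null(f)) return(NULL)
      list(slope = f$slope, intercept = f$intercept,
           resid_sd = sqrt(f$rss / (f$n - 2)), distortion_sd = 0)
    },
    ols_full = {
      f <- .ols_core(x, sim$y)
      if (is.null(f)) return(NULL)
      list(slope = f$slope, intercept = f$intercept,
           resid_sd = sqrt(f$rss / (f$n - 2)), distortion_sd = 0)
    },
    glmm_full = {
      f <- .fit_hetero_core(x, sim$y, sim$c, criterion = criterion)
      if (is.null(f)) return(NULL)
      list(slope = f$slope, intercept = f$intercept,
           resid_sd = sqrt(f$sigma2), distortion_sd = sqrt(f$tau2))
    },
    ols_undistorted_subset = {
      keep <- sim$c == 0
      if (sum(keep) < 3 || length(unique(x[keep])) < 2) return(NULL)
      f <- .ols_core(x[keep], sim$y[keep])
      if (is.null(f)) return(NULL)
      list(slope = f$slope, intercept = f$intercept,
           resid_sd = sqrt(f$rss / (f$n - 2)), distortion_sd = 0)
    })
}

#' Run the estimator-comparison simulation study
#'
#' For every sample size and replicate, simulates one dataset and fits
#' all requested models to that same draw, then summarises the replicate
#' estimate distributions (mean, median, 2.5%/97.5% quantiles, kernel
#' density grid) and runs the paired t-test of `glmm_full` against
#' `ols_clean` slopes.
#'
#' @param config A [study_config()].
#' @return An object of class `"allom_study"`: a list with tibbles
#'   `estimates` (one row per successful fit: `sample_size`, `model`,
#'   `replicate`, `slope`, `intercept`, `resid_sd`, `distortion_sd`),
#'   `summary` (per sample size x model x parameter), `densities`
#'   (kernel-density grids), `tests` (paired slope tests), `failures`
#'   (failed-fit counts), plus the `config`.
#' @export
#' @examples
#' \donttest{
#' st <- run_study(study_config(sample_sizes = 25, replicates = 100,
#'                              seed = 1))
#' dplyr::filter(st$summary, parameter == "slope")
#' }
run_study <- function(config) {
  if (!inherits(config, "study_config")) {
    abort("`config` must come from study_config().")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  models <- config$models
  reps <- config$replicates

  cells <- list()
  for (n in config$sample_sizes) {
    scheme <- config$schemes[[as.character(n)]] %||%
      .default_scheme_for_n(n)
    sim_cfg <- config$sim
    sim_cfg$n <- as.integer(n)
    sim_cfg$scheme <- scheme
    sim_cfg$seed <- NULL

    est <- array(NA_real_, dim = c(reps, length(models), 4L),
                 dimnames = list(NULL, models,
                                 c("slope", "intercept", "resid_sd",
                                   "distortion_sd")))
    for (r in seq_len(reps)) {
      sim <- simulate_dataset(sim_cfg)
      for (m in models) {
        f <- .fit_study_model(m, sim, config$criterion)
        if (!is.null(f)) {
          est[r, m, ] <- c(f$slope, f$intercept, f$resid_sd,
                           f$distortion_sd)
        }
      }
    }
    cell <- purrr::map(models, function(m) {
      tibble(sample_size = n, model = m, replicate = seq_len(reps),
             slope = est[, m, "slope"], intercept = est[, m, "intercept"],
             resid_sd = est[, m, "resid_sd"],
             distortion_sd = est[, m, "distortion_sd"])
    })
    cells[[as.character(n)]] <- dplyr::bind_rows(cell)
  }
  all_est <- dplyr::bind_rows(cells)

  failures <- all_est |>
    dplyr::group_by(.data$sample_size, .data$model) |>
    dplyr::summarise(n_failed = sum(is.na(.data$slope)), .groups = "drop")
  bad <- dplyr::filter(failures, .data$n_failed == reps)
  if (nrow(bad) > 0) {
    abort(paste0("all replicates failed for model `", bad$model[1],
                 "` at n = ", bad$sample_size[1], "."))
  }
  estimates <- dplyr::filter(all_est, !is.na(.data$slope))

  long <- estimates |>
    tidyr::pivot_longer(c("slope", "intercept"), names_to = "parameter",
                        values_to = "estimate")
  summary_tbl <- long |>
    dplyr::group_by(.data$sample_size, .data$model, .data$parameter) |>
    dplyr::summarise(
      n_ok = dplyr::n(),
      mean = mean(.data$estimate), median = stats::median(.data$estimate),
      q2.5 = .q95(.data$estimate)[1], q97.5 = .q95(.data$estimate)[2],
      .groups = "drop") |>
    dplyr::left_join(failures, by = c("sample_size", "model"))

  densities <- long |>
    dplyr::group_by(.data$sample_size, .data$model, .data$parameter) |>
    dplyr::reframe({
      d <- stats::density(.data$estimate, n = 512, cut = 3)
      tibble(grid = d$x, density = d$y)
    })

  tests <- NULL
  if (all(c("glmm_full", "ols_clean") %in% models)) {
    tests <- purrr::map(config$sample_sizes, function(n) {
      a <- all_est$slope[all_est$sample_size == n &
                           all_est$model == "glmm_full"]
      b <- all_est$slope[all_est$sample_size == n &
                           all_est$model == "ols_clean"]
      ok <- !is.na(a) & !is.na(b)
      res <- paired_slope_test(a[ok], b[ok])
      dplyr::mutate(res, sample_size = n, .before = 1)
    }) |> dplyr::bind_rows()
  }

  structure(list(estimates = estimates, summary = summary_tbl,
                 densities = densities, tests = tests,
                 failures = failures, config = config),
            class = "allom_study")
}

#' Paired t-test between two replicate estimate vectors
#'
#' Compares two estimators' slope estimates replicate by replicate (both
#' estimators having seen the same simulated draw). Delegates to
#' [stats::t.test()] with `paired = TRUE`.
#'
#' @param a,b Numeric vectors of equal length (`>= 2`), paired by
#'   replicate index.
#' @return A one-row tibble: `statistic`, `p_value`, `n`.
#' @export
paired_slope_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("need at least 2 paired values.")
  d <- a - b
  if (all(d == 0) || stats::sd(d) == 0) {
    abort("degenerate input: paired differences have zero variance.")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         n = length(a))
}

#' Summarise a replicate estimate vector
#'
#' Moments, empirical 2.5%/97.5% quantiles (linear interpolation,
#' `type = 7`), and a Gaussian kernel density on a 512-point grid
#' spanning the data plus three bandwidths each side (normal-reference
#' bandwidth).
#'
#' @param values Numeric vector of at least 10 estimates.
#' @return A one-row tibble: `n`, `mean`, `median`, `q2.5`, `q97.5`, and
#'   a `density` list-column holding a tibble with `grid` and `density`.
#' @export
summarize_estimates <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 10) abort("need at least 10 values.")
  q <- .q95(values)
  d <- stats::density(values, n = 512, cut = 3)
  tibble(n = length(values), mean = mean(values),
         median = stats::median(values), q2.5 = q[1], q97.5 = q[2],
         density = list(tibble(grid = d$x, density = d$y)))
}

#' @export
print.allom_study <- function(x, ...) {
  cat("Allometric simulation study:",
      length(x$config$sample_sizes), "sample size(s) x",
      x$config$replicates, "replicates\n")
  print(dplyr::filter(x$summary, .data$parameter == "slope"))
  if (!is.null(x$tests)) {
    cat("\nPaired t-tests, glmm_full vs ols_clean slopes:\n")
    print(x$tests)
  }
  invisible(x)
}

#' Tidy a simulation study
#'
#' @param x An `"allom_study"`.
#' @param ... Unused.
#' @return The per-cell summary tibble.
#' @method tidy allom_study
#' @export
tidy.allom_study <- function(x, ...) x$summary
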