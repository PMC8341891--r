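#' Configuration for the nonparametric bootstrap
#'
#' @param replicates Bootstrap iterations (default 5000).
#' @param models Subset of `"ols_undistorted"` (OLS on unflagged
#'   specimens only), `"ols_full"` (OLS on all specimens) and
#'   `"glmm_full"` (distortion-aware fit on all specimens).
#' @param criterion Criterion for `glmm_full` refits.
#' @param seed Optional integer seed.
#' @param min_per_group Warning threshold for the smallest flag group.
#' @param resample_full_then_subset For `ols_undistorted`: resample the
#'   full table and then keep unflagged rows (variable effective n),
#'   instead of the default of resampling the unflagged subset directly
#'   at its own size.
#' @return A `"bootstrap_config"` list.
#' @export
bootstrap_config <- function(replicates = 5000,
                             models = c("ols_undistorted", "ols_full",
                                        "glmm_full"),
                             criterion = c("reml", "ml"), seed = NULL,
                             min_per_group = 5,
                             resample_full_then_subset = FALSE) {
  criterion <- match.arg(criterion)
  models <- match.arg(models, several.ok = TRUE)
  if (replicates < 1) abort("`replicates` must be at least 1.")
  structure(list(replicates = as.integer(replicates), models = models,
                 criterion = criterion, seed = seed,
                 min_per_group = min_per_group,
                 resample_full_then_subset = resample_full_then_subset),
            class = "bootstrap_config")
}

#' Nonparametric specimen bootstrap of the allometric models
#'
#' Resamples specimens (whole rows) with replacement and refits each
#' model, giving an empirical distribution of slope and intercept from
#' which percentile 95% intervals are read. Each model resamples its own
#' data domain: the full table for `ols_full` and `glmm_full`, and the
#' unflagged subset (at its own size) for `ols_undistorted`, so every
#' distribution is an honest bootstrap of its own estimator. Degenerate
#' resamples -- fewer than two distinct x values or, for `glmm_full`, an
#' emptied flag group -- are skipped and counted, preserving replicate
#' independence.
#'
#' @param pairs Data frame with columns `x`, `y`, `c` (see
#'   [to_log_pairs()]).
#' @param config A [bootstrap_config()].
#' @return An object of class `"allom_boot"`: list with tibbles
#'   `estimates` (`model`, `replicate`, `slope`, `intercept`) and
#'   `summary` (per model: `median`, `q2.5`, `q97.5` of the slope,
#'   `median_intercept`, `n_ok`, `n_skipped`), plus the `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n = 26), seed = 7)
#' bt <- run_bootstrap(sim, bootstrap_config(replicates = 200, seed = 1))
#' bt$summary
run_bootstrap <- function(pairs, config = bootstrap_config()) {
  if (!inherits(config, "bootstrap_config")) {
    abort("`config` must come from bootstrap_config().")
  }
  d <- .check_pairs(pairs)
  n <- d$n
  if (n < 3) abort("need at least 3 pairs.")
  if ("glmm_full" %in% config$models && n < 10) {
    abort("`glmm_full` bootstrap requires at least 10 pairs.")
  }
  nd <- sum(d$c)
  if ("glmm_full" %in% config$models &&
      min(nd, n - nd) < config$min_per_group) {
    warn(paste0("smallest flag group has ", min(nd, n - nd),
                " member(s); distortion-variance estimates from ",
                "`glmm_full` resamples will be unstable."))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  reps <- config$replicates
  idx_und <- which(d$c == 0)

  one_model <- function(model) {
    slope <- rep(NA_real_, reps)
    intercept <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      if (model == "ols_undistorted" && !config$resample_full_then_subset) {
        if (length(idx_und) < 3) break
        take <- sample(idx_und, length(idx_und), replace = TRUE)
      } else {
        take <- sample.int(n, n, replace = TRUE)
        if (model == "ols_undistorted") {
          take <- take[d$c[take] == 0]
          if (length(take) < 3) next
        }
      }
      x <- d$x[take]; y <- d$y[take]; cc <- d$c[take]
      if (length(unique(x)) < 2) next
      f <- if (model == "glmm_full") {
        k <- sum(cc)
        if (k == 0 || k == length(cc)) NULL
        else .fit_hetero_core(x, y, cc, criterion = config$criterion)
      } else {
        .ols_core(x, y)
      }
      if (is.null(f)) next
      slope[r] <- f$slope
      intercept[r] <- f$intercept
    }
    tibble(model = model, replicate = seq_len(reps),
           slope = slope, intercept = intercept)
  }

  est <- dplyr::bind_rows(purrr::map(config$models, one_model))
  skip <- est |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_skipped = sum(is.na(.data$slope)), .groups = "drop")
  too_many <- dplyr::filter(skip, .data$n_skipped > reps / 2)
  if (nrow(too_many) > 0) {
    abort(paste0("more than half of the bootstrap resamples were ",
                 "degenerate for model `", too_many$model[1], "`."))
  }
  estimates <- dplyr::filter(est, !is.na(.data$slope))
  summary_tbl <- estimates |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_ok = dplyr::n(),
      median = stats::median(.data$slope),
      q2.5 = .q95(.data$slope)[1], q97.5 = .q95(.data$slope)[2],
      median_intercept = stats::median(.data$intercept),
      intercept_q2.5 = .q95(.data$intercept)[1],
      intercept_q97.5 = .q95(.data$intercept)[2],
      .groups = "drop") |>
    dplyr::left_join(skip, by = "model")

  structure(list(estimates = estimates, summary = summary_tbl,
                 config = config, n = n, n_distorted = nd),
            class = "allom_boot")
}

#' @export
print.allom_boot <- function(x, ...) {
  cat("Nonparametric bootstrap:", x$config$replicates,
      "replicates, n =", x$n, "pairs (", x$n_distorted, "distorted)\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x An `"allom_boot"`.
#' @param ... Unused.
#' @return The per-model summary tibble.
#' @method tidy allom_boot
#' @export
tidy.allom_boot <- function(x, ...) x$summary
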