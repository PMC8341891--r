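test_that("a clean CSV round-trips through read_measurements", {
  df <- tibble::tibble(
    specimen_id = c("A", "A", "B", "B"),
    feature = rep(c("skull_length", "snout_length"), 2),
    value_mm = c(100, 10, 200, 18),
    distorted = c(0, 1, 0, 0))
  tab <- read_measurements(write_measurement_csv(df))
  expect_s3_class(tab, "measurement_tbl")
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "n_dropped"), 0)
  expect_type(tab$distorted, "integer")
})

test_that("schema maps arbitrary column names", {
  df <- tibble::tibble(id = c("A", "B", "C"), meas = "skull",
                       mm = c(10, 20, 30), deformed = c(0, 0, 1))
  tab <- read_measurements(
    write_measurement_csv(df),
    schema = measurement_schema(specimen_id = "id", feature = "meas",
                                value = "mm", distorted = "deformed"))
  expect_equal(tab$value_mm, c(10, 20, 30))
  expect_error(read_measurements(write_measurement_csv(df)), "schema")
})

test_that("validation rejects bad values and names the offender", {
  df <- tibble::tibble(specimen_id = c("A", "B"), feature = "skull",
                       value_mm = c(100, 0), distorted = c(0, 0))
  expect_error(read_measurements(write_measurement_csv(df)),
               "specimen `B`")
  df$value_mm <- c(100, 90)
  df$distorted <- c(0, 2)
  expect_error(read_measurements(write_measurement_csv(df)),
               "0 or 1")
  dup <- df[c(1, 1), ]
  dup$distorted <- c(0L, 0L)
  expect_error(validate_measurements(dup), "duplicate")
})

test_that("blank measurement cells are dropped and counted", {
  df <- tibble::tibble(
    specimen_id = c("A", "B", "C", "D", "E"),
    feature = "snout_length",
    value_mm = c(10, NA, 12, 14, 16), distorted = 0)
  expect_message(tab <- read_measurements(write_measurement_csv(df)),
                 "Dropped 1")
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "n_dropped"), 1)
})

test_that("to_log_pairs takes log10 values and the focal flag", {
  df <- tibble::tibble(
    specimen_id = rep(c("A", "B", "C"), each = 2),
    feature = rep(c("skull_length", "snout_length"), 3),
    value_mm = c(100, 10, 1000, 100, 10, 1),
    distorted = c(0, 1, 0, 0, 0, 1))
  pairs <- to_log_pairs(validate_measurements(df),
                        "skull_length", "snout_length")
  expect_equal(pairs$x, c(2, 3, 1))
  expect_equal(pairs$y, c(1, 2, 0))
  expect_equal(pairs$c, c(1L, 0L, 1L))
})

test_that("pairing is per specimen and drops incomplete specimens", {
  df <- tibble::tibble(
    specimen_id = c("A", "A", "B", "B", "C", "C", "D"),
    feature = c(rep(c("skull", "snout"), 3), "skull"),
    value_mm = c(100, 10, 150, 14, 210, 20, 250),
    distorted = 0)
  pairs <- to_log_pairs(validate_measurements(df), "skull", "snout")
  expect_equal(pairs$specimen_id, c("A", "B", "C"))

  # distorted reference measurements keep the focal flag, with a warning
  df$distorted[1] <- 1
  expect_warning(
    pairs2 <- to_log_pairs(validate_measurements(df), "skull", "snout"),
    "reference")
  expect_equal(pairs2$c, c(0L, 0L, 0L))

  # fewer than 3 shared specimens is insufficient
  expect_error(
    to_log_pairs(validate_measurements(df[1:4, ]), "skull", "snout"),
    "insufficient")
})

test_that("the bundled synthetic table pairs 15 of 16 specimens", {
  path <- system.file("extdata", "synthetic_cranial_measurements.csv",
                      package = "distallom")
  tab <- read_measurements(path)
  expect_equal(length(unique(tab$specimen_id)), 16)
  pairs <- to_log_pairs(tab, "skull_length", "snout_length")
  expect_equal(nrow(pairs), 15)
  expect_equal(sum(pairs$c), 8)
})

test_that("rescaling mm by 10 shifts log pairs by exactly +1", {
  df <- tibble::tibble(
    specimen_id = rep(c("A", "B", "C", "D"), each = 2),
    feature = rep(c("skull", "snout"), 4),
    value_mm = c(100, 10, 150, 14, 210, 20, 250, 23),
    distorted = rep(c(0, 1), 4))
  p1 <- to_log_pairs(validate_measurements(df), "skull", "snout")
  df2 <- dplyr::mutate(df, value_mm = value_mm * 10)
  p2 <- to_log_pairs(validate_measurements(df2), "skull", "snout")
  expect_equal(p2$x, p1$x + 1)
  expect_equal(p2$y, p1$y + 1)
  expect_identical(p2$c, p1$c)
})

test_that("file -> pairs is deterministic", {
  df <- tibble::tibble(
    specimen_id = rep(c("A", "B", "C"), each = 2),
    feature = rep(c("skull", "snout"), 3),
    value_mm = c(103.7, 11.2, 151.9, 14.8, 212.4, 19.9),
    distorted = c(0, 1, 0, 0, 0, 1))
  path <- write_measurement_csv(df)
  p1 <- to_log_pairs(read_measurements(path), "skull", "snout")
  p2 <- to_log_pairs(read_measurements(path), "skull", "snout")
  expect_identical(p1, p2)
})

test_that("normality_check matches an independent implementation", {
  # reference values from scipy.stats.shapiro on the same vector
  v <- c(2.3, 3.1, 1.8, 2.9, 3.4, 2.2, 2.7, 3.0, 1.9, 2.5)
  res <- normality_check(v)
  expect_equal(res$statistic, 0.9668678177, tolerance = 1e-6)
  expect_equal(res$p_value, 0.8603832536, tolerance = 1e-5)
  expect_error(normality_check(c(5, 5, 5, 5)), "identical")
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
})

test_that("normality screening flags skewed measurements", {
  # detection rates measured a priori by Monte Carlo for Exp(1) draws:
  # ~0.84 at n = 20, ~0.99 at n = 35
  rate_at <- function(n, trials = 100) {
    hits <- vapply(seq_len(trials), function(i) {
      set.seed(1000 + i)
      normality_check(rexp(n))$p_value < 0.05
    }, logical(1))
    mean(hits)
  }
  expect_gte(rate_at(20), 0.7)
  expect_gte(rate_at(35), 0.9)
})

test_that("normality_screen reports per-feature results", {
  path <- system.file("extdata", "synthetic_cranial_measurements.csv",
                      package = "distallom")
  scr <- normality_screen(read_measurements(path))
  expect_equal(nrow(scr), 2)
  expect_true(all(scr$p_value > 0 & scr$p_value <= 1))
  expect_equal(scr$n, c(16, 15))
})
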