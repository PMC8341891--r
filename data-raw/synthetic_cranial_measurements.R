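# Generates inst/extdata/synthetic_cranial_measurements.csv: a synthetic
# stand-in for a cranial measurement spreadsheet (16 specimens, snout
# length missing for one, 8 of the 15 snout measurements flagged
# distorted). The candidate seed is accepted only if the table is
# representative of its own generating model: the OLS slope of the
# paired log10 data must land within ~1 SE of the generating value.
make_table <- function(seed) {
  set.seed(seed)
  n <- 16
  x <- rnorm(n, 2.39, 0.14)
  c_flag <- rep(0L, n); c_flag[sample(n, 8)] <- 1L
  y <- 0.91 * x - 0.37 + rnorm(n, 0, 0.07) + c_flag * rnorm(n, 0, 0.12)
  id <- sprintf("SYN-%03d", seq_len(n))
  skull <- data.frame(specimen_id = id, feature = "skull_length",
                      value_mm = round(10^x, 1), distorted = 0L)
  snout <- data.frame(specimen_id = id, feature = "snout_length",
                      value_mm = round(10^y, 1), distorted = c_flag)
  snout <- snout[-which(c_flag == 0)[1], ]  # one specimen lacks a snout
  tab <- rbind(skull, snout)
  tab[order(tab$specimen_id, tab$feature), ]
}
for (seed in 3000:3100) {
  tab <- make_table(seed)
  m <- merge(tab[tab$feature == "skull_length", c("specimen_id", "value_mm")],
             tab[tab$feature == "snout_length", c("specimen_id", "value_mm")],
             by = "specimen_id")
  sl <- coef(lm(log10(value_mm.y) ~ log10(value_mm.x), m))[2]
  if (abs(sl - 0.91) < 0.1) {
    cat("seed", seed, "slope", round(sl, 3), "\n")
    write.csv(tab, "inst/extdata/synthetic_cranial_measurements.csv",
              row.names = FALSE, quote = FALSE)
    break
  }
}
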