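#!/usr/bin/env Rscript
# Builds the packaged synthetic growth and IGF-1 reference tables under
# inst/extdata/. Both are smooth, clearly non-clinical stand-ins: logistic-
# in-age median weight/height channels with constant coefficient of
# variation, and a log-normal IGF-1 reference with log-linear age trend and
# constant log-scale SD. Re-run from the repository root after editing.

ages <- seq(3, 16, by = 0.5)

logistic <- function(a, base, span, mid, scale) base + span / (1 + exp(-(a - mid) / scale))

growth <- do.call(rbind, lapply(c("M", "F"), function(sex) {
  if (sex == "M") {
    wm <- logistic(ages, 11, 75, 13.5, 3.2)
    hm <- logistic(ages, 60, 140, 10.0, 7.0)
  } else {
    wm <- logistic(ages, 10.5, 70, 13.0, 3.1)
    hm <- logistic(ages, 59, 136, 9.8, 6.9)
  }
  data.frame(age = ages, sex = sex,
             weight_median = round(wm, 3), weight_cv = 0.13,
             height_median = round(hm, 3), height_cv = 0.04)
}))

igf1 <- do.call(rbind, lapply(c("M", "F"), function(sex) {
  base <- if (sex == "M") 120 else 130
  data.frame(age = ages, sex = sex,
             mu_ln = round(log(base) + 0.08 * (ages - 3), 5),
             sd_ln = 0.4)
}))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(growth, "inst/extdata/growth_reference_synthetic.csv", row.names = FALSE, quote = FALSE)
write.csv(igf1, "inst/extdata/igf1_reference_synthetic.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(growth), "growth rows and", nrow(igf1), "IGF-1 rows\n")
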