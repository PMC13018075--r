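# Packaged synthetic references: growth channels (weight/height medians by
# age and sex) and the log-normal IGF-1 standardisation table. Both ship as
# plain CSVs under inst/extdata and are labelled synthetic: they carry the
# *interface* of a pediatric reference, not clinical values.

.pegsim_env <- new.env(parent = emptyenv())

#' Load the synthetic growth reference
#'
#' Age- and sex-specific median weight and height channels (ages 3-16 years,
#' half-year grid) with constant coefficients of variation. Lookups
#' interpolate linearly in age. The table is a smooth synthetic stand-in for
#' a national pediatric growth reference.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (`age`, `sex`, `weight_median`, `weight_cv`, `height_median`,
#'   `height_cv`).
#' @return A data.frame of class `growth_reference`.
#' @export
growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pegsim_env$growth_ref)) return(.pegsim_env$growth_ref)
    path <- system.file("extdata", "growth_reference_synthetic.csv",
                        package = "pegsim", mustWork = TRUE)
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "weight_median", "weight_cv",
                  "height_median", "height_cv") %in% names(ref)))
  for (s in unique(ref$sex)) {
    sub <- ref[ref$sex == s, ]
    sub <- sub[order(sub$age), ]
    if (any(diff(sub$weight_median) <= 0) || any(diff(sub$height_median) <= 0))
      stop("growth reference medians must increase with age within sex")
  }
  ref <- structure(ref, class = c("growth_reference", "data.frame"))
  .pegsim_env$growth_ref <- ref
  ref
}

#' Load the synthetic IGF-1 standardisation reference
#'
#' Per age (years) and sex: mean and SD of log IGF-1 in the reference
#' population, so that `SDS = (log(igf1) - mu_ln) / sd_ln`. Linear
#' interpolation in age; no extrapolation outside the tabulated 3-16 year
#' span.
#'
#' @param path Optional path to an alternative CSV with columns `age`,
#'   `sex`, `mu_ln`, `sd_ln`.
#' @return A data.frame of class `igf1_reference`.
#' @export
igf1_reference <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pegsim_env$igf1_ref)) return(.pegsim_env$igf1_ref)
    path <- system.file("extdata", "igf1_reference_synthetic.csv",
                        package = "pegsim", mustWork = TRUE)
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "mu_ln", "sd_ln") %in% names(ref)),
            all(ref$sd_ln > 0))
  ref <- structure(ref, class = c("igf1_reference", "data.frame"))
  .pegsim_env$igf1_ref <- ref
  ref
}

ref_interp <- function(ref, sex, column, age, clamp = FALSE) {
  sub <- ref[ref$sex == sex, ]
  if (nrow(sub) == 0L) stop("unknown sex code: ", sex)
  rng <- range(sub$age)
  if (clamp) {
    age <- pmin(pmax(age, rng[1]), rng[2])
  } else if (any(age < rng[1] | age > rng[2])) {
    stop(sprintf("age outside reference span [%g, %g]", rng[1], rng[2]))
  }
  stats::approx(sub$age, sub[[column]], xout = age, rule = 1)$y
}

ref_invert <- function(ref, sex, column, value, what = "value") {
  sub <- ref[ref$sex == sex, ]
  rng <- range(sub[[column]])
  if (any(value < rng[1] | value > rng[2]))
    stop(sprintf("%s outside reference span [%g, %g]", what, rng[1], rng[2]))
  stats::approx(sub[[column]], sub$age, xout = value, rule = 1)$y
}

#' Growth-channel lookups
#'
#' Median weight or height at a given age, and the inverse lookups giving
#' the age at which the median channel attains a given weight or height.
#'
#' @param age Age in years (vectorised).
#' @param sex `"M"` or `"F"`.
#' @param ref A [growth_reference()] table.
#' @param clamp Clamp ages to the tabulated span instead of erroring.
#' @return Numeric vector.
#' @export
ref_weight_median <- function(age, sex, ref = growth_reference(), clamp = FALSE) {
  ref_interp(ref, sex, "weight_median", age, clamp)
}

#' @rdname ref_weight_median
#' @export
ref_height_median <- function(age, sex, ref = growth_reference(), clamp = FALSE) {
  ref_interp(ref, sex, "height_median", age, clamp)
}

#' @rdname ref_weight_median
#' @param weight Median weight (kg) to invert.
#' @export
age_for_weight <- function(weight, sex, ref = growth_reference()) {
  ref_invert(ref, sex, "weight_median", weight, "weight")
}

#' @rdname ref_weight_median
#' @param height Median height (cm) to invert.
#' @export
age_for_height <- function(height, sex, ref = growth_reference()) {
  ref_invert(ref, sex, "height_median", height, "height")
}
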