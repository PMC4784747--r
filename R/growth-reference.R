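#' Growth reference of median body weights
#'
#' Builds a sex-by-age table of median body weights covering ages 0 to 18 in
#' half-year steps, used to back-project a child's clinic-visit weight to
#' the end of the incident via the growth-rate coefficient (GRC). The table
#' is a synthetic approximation of Taiwanese growth medians, anchored to the
#' two published values: boys weigh 18.3 kg at age 5 and 15.3 kg at age 3.5.
#' Weights are monotone non-decreasing in age within each sex.
#'
#' @param config ignored; accepted so the generator surface is uniform.
#' @return An object of class `growth_reference`: a data frame with columns
#'   `sex` ("male"/"female"), `age` (years) and `weight_kg`.
#' @export
#' @examples
#' ref <- generate_growth_reference()
#' lookup_median_weight(ref, "male", 5)    # 18.3
#' lookup_median_weight(ref, "male", 3.5)  # 15.3
generate_growth_reference <- function(config = NULL) {
  ages <- seq(0, 18, by = 0.5)
  boys_knots <- c(
    3.3, 7.7, 9.8, 11.0, 12.2, 13.2, 14.3, 15.3, 16.3, 17.3, 18.3,
    19.3, 20.4, 21.5, 22.7, 24.0, 25.3, 26.8, 28.3, 30.0, 31.7, 33.5,
    35.5, 37.6, 39.8, 42.2, 44.6, 47.2, 49.7, 52.0, 54.2, 55.9, 57.5,
    58.5, 59.5, 60.2, 60.8
  )
  girls_knots <- c(
    3.2, 7.1, 9.2, 10.4, 11.6, 12.6, 13.7, 14.7, 15.7, 16.7, 17.7,
    18.7, 19.7, 20.8, 22.0, 23.3, 24.7, 26.3, 28.0, 29.9, 31.9, 34.0,
    36.2, 38.4, 40.6, 42.6, 44.5, 46.0, 47.3, 48.3, 49.2, 49.9, 50.5,
    51.0, 51.4, 51.7, 52.0
  )
  stopifnot(length(boys_knots) == length(ages),
            length(girls_knots) == length(ages))
  ref <- data.frame(
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, times = 2),
    weight_kg = c(boys_knots, girls_knots),
    stringsAsFactors = FALSE
  )
  class(ref) <- c("growth_reference", "data.frame")
  ref
}

#' Median body weight at a given age
#'
#' Linear interpolation of the growth-reference table; ages outside the
#' table range are clamped to its ends.
#'
#' @param ref a [generate_growth_reference()] table.
#' @param sex "male" or "female".
#' @param age age in years (vectorised).
#' @return Median weight(s) in kg.
#' @export
lookup_median_weight <- function(ref, sex, age) {
  sex <- match.arg(sex, c("male", "female"))
  tab <- ref[ref$sex == sex, ]
  stats::approx(tab$age, tab$weight_kg, xout = age, rule = 2)$y
}

#' Growth-rate coefficient (GRC)
#'
#' The median GRC gamma_j(a, t) = median_weight(a) / median_weight(a - t):
#' the factor by which a child of current age `a` has grown over the last
#' `t` years according to the reference medians. Returns 1 for participants
#' aged 18 or older. Ages `a - t` below the table range are clamped to the
#' youngest tabulated age with a warning.
#'
#' @param ref a [generate_growth_reference()] table.
#' @param sex "male" or "female".
#' @param age current age in years.
#' @param lag_years elapsed time t in years (>= 0).
#' @return The GRC (scalar, >= 1 for growing ages).
#' @export
#' @examples
#' ref <- generate_growth_reference()
#' growth_rate_coefficient(ref, "male", 5, 1.5)  # 18.3/15.3 ~ 1.2
growth_rate_coefficient <- function(ref, sex, age, lag_years) {
  if (lag_years < 0) stop("lag_years must be >= 0", call. = FALSE)
  if (age >= 18 || lag_years == 0) return(1)
  a0 <- age - lag_years
  amin <- min(ref$age)
  if (a0 < amin) {
    warning(sprintf("age - lag (%.2f) below table range; clamped to %.1f",
                    a0, amin))
    a0 <- amin
  }
  lookup_median_weight(ref, sex, age) / lookup_median_weight(ref, sex, a0)
}
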