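# Median age-associated hearing loss (AAHL) reference values.
#
# Two interchangeable backends:
#  * "per_frequency" (default): AAHL(f) = alpha(f, sex) * (age - 18)^2, the
#    standard ISO 7029 functional form for the median, with alpha calibrated
#    so the age-52 male surface reproduces the published reference row
#    (4.6, 7.5, 10.1, 12.4, 15.9, 18.6) dB at (1, 2, 3, 4, 6, 8) kHz, i.e.
#    alpha = value / (52 - 18)^2 = value / 1156.
#  * "fixture": values served from a user-supplied lookup table, for users
#    who want to plug in their own tabulated medians.
#
# A separate quadratic backend (aahl_quadratic) evaluates the published
# best-fitting quadratics for the summed/averaged AAHL measures. Those
# coefficients are rounded fits and are NOT used by the diagnosis; see the
# methods vignette for how far they diverge from the per-frequency surface
# away from age 52.

# age-52 male reference AAHL row (dB HL) at 1,2,3,4,6,8 kHz
AAHL_MALE_52 <- c(4.6, 7.5, 10.1, 12.4, 15.9, 18.6)

AAHL_ALPHA_MALE <- AAHL_MALE_52 / (52 - 18)^2

# Best-fitting quadratic coefficients y = a + b*age + c*age^2 for the
# summed (Mag(Notch)) and averaged (Mag(ExcessHF)) AAHL measures.
AAHL_QUAD <- list(
  male = list(
    sum_6k8k = c(a = 22.212, b = -1.895, c = 0.041),
    sum_4k8k = c(a = 20.080, b = -1.713, c = 0.037),
    sum_3k8k = c(a = 18.596, b = -1.590, c = 0.034),
    pta_468k = c(a = 9.636,  b = -0.837, c = 0.018)
  ),
  female = list(
    sum_6k8k = c(a = 20.507, b = -1.665, c = 0.034),
    sum_4k8k = c(a = 20.397, b = -1.617, c = 0.032),
    sum_3k8k = c(a = 18.957, b = -1.506, c = 0.030),
    pta_468k = c(a = 9.907,  b = -0.792, c = 0.016)
  )
)

#' Median age-associated hearing loss surface
#'
#' Returns the median AAHL (dB) at each of 1, 2, 3, 4, 6 and 8 kHz for a
#' given age and sex. The default `per_frequency` backend uses the
#' ISO-7029-style model AAHL(f) = alpha(f) * (age - 18)^2, zero at the
#' reference age 18 and non-decreasing in age. Male alphas are built in
#' (calibrated to the published age-52 row); no female per-frequency
#' calibration row is published, so for `sex = "female"` the `alpha` vector
#' must be supplied by the user (the female quadratics of
#' [aahl_quadratic()] are available as printed).
#'
#' Only 3-8 kHz enter the diagnostic formulas; 1 and 2 kHz are included for
#' display and validation.
#'
#' @param age age in years, >= 18.
#' @param sex `"male"` or `"female"`.
#' @param backend `"per_frequency"` (model) or `"fixture"` (lookup table).
#' @param alpha optional named per-frequency alpha overrides
#'   (dB / year^2), names `"1","2","3","4","6","8"`.
#' @param fixture for the fixture backend: a data frame with columns `age`,
#'   `sex` and `f1k, f2k, f3k, f4k, f6k, f8k`; the row matching (age, sex)
#'   exactly is served.
#' @return object of class `aahl_surface`: named numeric vector of AAHL by
#'   frequency, with `age` and `sex` attributes.
#' @examples
#' aahl_surface(52, "male")   # reproduces the published age-52 row
#' @export
aahl_surface <- function(age, sex = c("male", "female"),
                         backend = c("per_frequency", "fixture"),
                         alpha = NULL, fixture = NULL) {
  sex <- match.arg(sex)
  backend <- match.arg(backend)
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age))
    stop("age must be a single finite number", call. = FALSE)
  if (age < 18)
    stop("age < 18: the AAHL reference starts at age 18", call. = FALSE)

  if (backend == "fixture") {
    if (is.null(fixture))
      stop("fixture backend requires a fixture table", call. = FALSE)
    hit <- which(fixture$age == age & fixture$sex == sex)
    if (length(hit) != 1L)
      stop("fixture table has no unique row for age ", age, ", ", sex,
           call. = FALSE)
    vals <- as.numeric(fixture[hit, paste0("f", NIHL_FREQS, "k")])
  } else {
    if (is.null(alpha)) {
      if (sex == "female")
        stop("no built-in female per-frequency calibration; supply `alpha` ",
             "or use aahl_quadratic()", call. = FALSE)
      alpha <- setNames(AAHL_ALPHA_MALE, freq_key(NIHL_FREQS))
    } else {
      want <- freq_key(NIHL_FREQS)
      if (is.null(names(alpha)) && length(alpha) == 6L)
        names(alpha) <- want
      if (!all(want %in% names(alpha)))
        stop("alpha must be named by frequency (kHz): ",
             paste(want, collapse = ", "), call. = FALSE)
      alpha <- alpha[want]
    }
    vals <- as.numeric(alpha) * (age - 18)^2
  }
  structure(setNames(as.numeric(vals), freq_key(NIHL_FREQS)),
            age = age, sex = sex, class = "aahl_surface")
}

#' @export
print.aahl_surface <- function(x, ...) {
  cat("Median AAHL (dB HL), age ", attr(x, "age"), ", ", attr(x, "sex"),
      ":\n", sep = "")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Published quadratic fits for summed/averaged AAHL measures
#'
#' Evaluates y = a + b*age + c*age^2 with the published coefficients for
#' the four AAHL measures used in computing Mag(Notch) (pairwise sums of
#' AAHL at 6+8, 4+8 and 3+8 kHz) and Mag(ExcessHF) (mean AAHL over 4, 6,
#' 8 kHz). These are rounded best fits: they agree with the per-frequency
#' surface near age 52 but drift away from it at younger and older ages, so
#' the diagnosis uses [aahl_surface()] instead.
#'
#' @param age age in years, >= 18.
#' @param sex `"male"` or `"female"`.
#' @param measure one of `"sum_6k8k"`, `"sum_4k8k"`, `"sum_3k8k"`,
#'   `"pta_468k"`.
#' @return the quadratic's value (dB) as exact arithmetic on the printed
#'   coefficients.
#' @examples
#' aahl_quadratic(52, "male", "sum_6k8k")
#' @export
aahl_quadratic <- function(age, sex = c("male", "female"),
                           measure = c("sum_6k8k", "sum_4k8k",
                                       "sum_3k8k", "pta_468k")) {
  sex <- match.arg(sex)
  measure <- match.arg(measure)
  if (any(age < 18)) stop("age < 18", call. = FALSE)
  co <- AAHL_QUAD[[sex]][[measure]]
  unname(co["a"] + co["b"] * age + co["c"] * age^2)
}
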