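# Synthetic audiogram cohorts with the marginal structure of the study's
# noise-exposed (MilDB) and screened-control (ContDB) databases. Only
# per-ear per-frequency means/SDs and age moments are published; the joint
# correlation structure is a modelling choice (exchangeable, default
# rho = 0.7), so simulated diagnostic performance is indicative only.

# Published per-group moments: age mean (SD) and per-ear per-frequency HTL
# mean (SD) at 1,2,3,4,6,8 kHz. Both study populations were men aged 29-60.
TABLE2_SPECS <- list(
  mildb1 = list(
    n = 143, age_mean = 45.4, age_sd = 8.9,
    R_mean = c(16.9, 22.8, 32.7, 41.0, 44.7, 42.2),
    R_sd   = c(11, 15, 18, 21, 22, 24),
    L_mean = c(19.2, 25.8, 41.8, 50.4, 53.2, 51.0),
    L_sd   = c(12, 16, 21, 21, 23, 23),
    control_screening = FALSE),
  mildb2 = list(
    n = 142, age_mean = 44.7, age_sd = 9.6,
    R_mean = c(16.7, 22.6, 33.4, 41.3, 44.6, 41.4),
    R_sd   = c(11, 15, 19, 20, 22, 24),
    L_mean = c(17.9, 25.3, 39.9, 48.1, 52.6, 50.0),
    L_sd   = c(11, 17, 20, 21, 23, 24),
    control_screening = FALSE),
  contdb1 = list(
    n = 93, age_mean = 41.8, age_sd = 12,
    R_mean = c(4.4, 5.6, 7.7, 9.7, 13.4, 20.2),
    R_sd   = c(5.2, 6.5, 7.7, 9.1, 12, 15),
    L_mean = c(3.1, 5.1, 9.4, 12.7, 14.7, 19.9),
    L_sd   = c(5.1, 7.6, 10, 11, 11, 14),
    control_screening = TRUE),
  contdb2 = list(
    n = 92, age_mean = 41.2, age_sd = 11,
    R_mean = c(3.8, 4.3, 8.0, 9.2, 11.5, 18.1),
    R_sd   = c(4.6, 5.4, 7.7, 10, 11, 13),
    L_mean = c(2.6, 4.1, 7.9, 10.4, 14.9, 19.9),
    L_sd   = c(5.2, 6.0, 7.7, 11, 12, 16),
    control_screening = TRUE)
)

#' Specification of a synthetic audiogram cohort
#'
#' Captures everything the simulator needs: sample size, age distribution
#' (truncated normal), per-ear per-frequency HTL means and SDs (dB) at 1,
#' 2, 3, 4, 6, 8 kHz, an exchangeable inter-frequency/inter-ear correlation
#' `rho`, an optional audiometric quantization step, and whether subjects
#' are screened with the control asymmetry filter.
#'
#' @param label cohort label.
#' @param n number of subjects (> 0).
#' @param age_mean,age_sd age distribution parameters (years).
#' @param age_range ages are truncated to this (min, max) interval.
#' @param L_mean,L_sd,R_mean,R_sd numeric length-6 vectors: HTL mean and SD
#'   per frequency (1, 2, 3, 4, 6, 8 kHz) for the left and right ear.
#' @param rho exchangeable correlation between all 12 HTLs, in \[0, 1).
#' @param quantize_step round HTLs to this step (dB; clinical audiometry
#'   uses 5); `NULL` keeps them continuous.
#' @param control_screening apply the control inclusion filter (reject and
#'   redraw subjects with cross-ear asymmetry >= 10 dB averaged over 1, 2,
#'   3, 4, 6 kHz)?
#' @param sex subject sex (the study populations were male).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, n, age_mean, age_sd, age_range = c(29, 60),
                        L_mean, L_sd, R_mean, R_sd, rho = 0.7,
                        quantize_step = 5, control_screening = FALSE,
                        sex = "male") {
  stopifnot(n > 0, age_sd >= 0, length(age_range) == 2,
            length(L_mean) == 6, length(L_sd) == 6,
            length(R_mean) == 6, length(R_sd) == 6,
            all(L_sd >= 0), all(R_sd >= 0), rho >= 0, rho < 1)
  structure(list(label = label, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 age_range = as.numeric(age_range),
                 L_mean = as.numeric(L_mean), L_sd = as.numeric(L_sd),
                 R_mean = as.numeric(R_mean), R_sd = as.numeric(R_sd),
                 rho = rho, quantize_step = quantize_step,
                 control_screening = isTRUE(control_screening), sex = sex),
            class = "cohort_spec")
}

#' Built-in cohort specifications from the published group moments
#'
#' The four study databases as shipped constants: noise-exposed `"mildb1"`
#' (n = 143) and `"mildb2"` (n = 142), and screened controls `"contdb1"`
#' (n = 93) and `"contdb2"` (n = 92). Control specs have
#' `control_screening = TRUE`. The exposed specs reproduce, on average, the
#' left-worse-than-right high-frequency asymmetry of the real databases.
#'
#' @param db one of `"mildb1"`, `"mildb2"`, `"contdb1"`, `"contdb2"`.
#' @param ... overrides passed to [cohort_spec()] (e.g. `n`, `rho`,
#'   `quantize_step`, `control_screening`).
#' @return a `cohort_spec`.
#' @export
builtin_cohort_spec <- function(db = c("mildb1", "mildb2",
                                       "contdb1", "contdb2"), ...) {
  db <- match.arg(db)
  s <- TABLE2_SPECS[[db]]
  args <- list(label = db, n = s$n, age_mean = s$age_mean,
               age_sd = s$age_sd, L_mean = s$L_mean, L_sd = s$L_sd,
               R_mean = s$R_mean, R_sd = s$R_sd,
               control_screening = s$control_screening)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

#' Read a cohort spec from a YAML or JSON file
#'
#' The file is a flat mapping of [cohort_spec()] arguments.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(cohort_spec, vals)
}

#' Cross-ear asymmetry screen
#'
#' The control inclusion filter: a subject passes when the absolute
#' difference between the left- and right-ear mean HTLs over the screening
#' frequencies (1, 2, 3, 4, 6 kHz) is strictly below the threshold; an
#' asymmetry of exactly 10 dB fails (">= 10 dB" excluded).
#'
#' @param left,right `ear_audiogram`s (or coercible vectors).
#' @param freqs screening frequencies in kHz.
#' @param threshold exclusion threshold (dB).
#' @return TRUE when the subject passes the screen.
#' @export
asymmetry_screen <- function(left, right, freqs = c(1, 2, 3, 4, 6),
                             threshold = 10) {
  left <- as_ear(left); right <- as_ear(right)
  k <- freq_key(freqs)
  if (!all(k %in% names(left)))
    stop("screening frequency not in audiogram", call. = FALSE)
  abs(mean(unclass(left)[k]) - mean(unclass(right)[k])) < threshold
}

# truncated-normal ages by rejection (the truncation range is a few SDs
# wide for all builtin specs, so rejection is cheap)
draw_ages <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(pmin(pmax(mean, range[1]), range[2]), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Simulate a synthetic audiogram cohort
#'
#' Ages are drawn from a normal truncated to `age_range`. The twelve HTLs
#' (two ears x six frequencies) are drawn from a multivariate normal with
#' the spec's marginal means/SDs and exchangeable correlation `rho` between
#' every pair (within and across ears), then clipped to the audiometer
#' range \[-10, 120\] dB HL and optionally quantized to `quantize_step`.
#' With `control_screening`, subjects failing [asymmetry_screen()] are
#' rejected and redrawn (screening never alters HTL values); an error is
#' raised if the rejection rate exceeds 99%.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional integer; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a `nihl_cohort` with `exposure_evidence = TRUE` (cohort-level
#'   scoring convention; flip the column for other uses).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  mu <- c(spec$L_mean, spec$R_mean)
  sdv <- c(spec$L_sd, spec$R_sd)
  corr <- matrix(spec$rho, 12, 12); diag(corr) <- 1
  sigma <- diag(sdv) %*% corr %*% diag(sdv)

  draw_batch <- function(m) {
    htl <- MASS::mvrnorm(m, mu = mu, Sigma = sigma)
    if (m == 1L) htl <- matrix(htl, nrow = 1)
    htl <- pmin(pmax(htl, HTL_MIN), HTL_MAX)
    if (!is.null(spec$quantize_step))
      htl <- round(htl / spec$quantize_step) * spec$quantize_step
    htl
  }

  kept <- matrix(numeric(0), 0, 12)
  drawn <- 0L
  while (nrow(kept) < spec$n) {
    m <- max(spec$n - nrow(kept), 16L)
    htl <- draw_batch(m)
    drawn <- drawn + m
    if (spec$control_screening) {
      sel <- c("1", "2", "3", "4", "6")
      idx <- match(sel, freq_key(NIHL_FREQS))
      asym <- abs(rowMeans(htl[, idx, drop = FALSE]) -
                    rowMeans(htl[, idx + 6L, drop = FALSE]))
      htl <- htl[asym < 10, , drop = FALSE]
    }
    kept <- rbind(kept, htl)
    if (drawn > 100L * spec$n && nrow(kept) < drawn / 100)
      stop("screening rejection rate > 99%: spec infeasible", call. = FALSE)
  }
  kept <- kept[seq_len(spec$n), , drop = FALSE]

  df <- data.frame(
    id = sprintf("%s_%04d", spec$label, seq_len(spec$n)),
    age = round(draw_ages(spec$n, spec$age_mean, spec$age_sd,
                          spec$age_range), 1),
    sex = spec$sex, exposure_evidence = TRUE,
    stringsAsFactors = FALSE)
  cols <- c(ear_cols("L"), ear_cols("R"))
  for (j in seq_along(cols)) df[[cols[j]]] <- round(kept[, j], 1)
  nihl_cohort(df, label = spec$label)
}
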