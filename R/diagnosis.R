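# Ear-level and individual-level diagnosis.
#
# M-NIHL (original): positive ear  <=>  R1 and (R2a or R2b).
# rM-NIHL (revised): positive ear  <=>  R1 and (Mag(Notch) >= 14.5 dB or
#                                               Mag(ExcessHF) >= 19 dB).
# R0 (documented noise exposure) gates the individual-level call for both
# methods; it is an input assertion carried on the subject, not computed.
#
# All threshold comparisons ("at least", ">=") are inclusive, and all
# comparisons are made on exact unrounded dB values; rounding to 1 decimal
# is display-only.

#' Diagnostic criterion thresholds for the rM-NIHL method
#'
#' The defaults (14.5 dB for Mag(Notch), 19.0 dB for Mag(ExcessHF)) are the
#' published values chosen to balance sensitivity and specificity.
#'
#' @param mag_notch_min minimum notch/bulge depth (dB), > 0.
#' @param mag_excess_hf_min minimum mean high-frequency excess (dB), > 0.
#' @return object of class `nihl_criteria`.
#' @export
nihl_criteria <- function(mag_notch_min = 14.5, mag_excess_hf_min = 19.0) {
  if (!is.numeric(mag_notch_min) || mag_notch_min <= 0 ||
      !is.numeric(mag_excess_hf_min) || mag_excess_hf_min <= 0)
    stop("criterion thresholds must be strictly positive", call. = FALSE)
  structure(list(mag_notch_min = as.numeric(mag_notch_min),
                 mag_excess_hf_min = as.numeric(mag_excess_hf_min)),
            class = "nihl_criteria")
}

#' @export
print.nihl_criteria <- function(x, ...) {
  cat("rM-NIHL criteria: Mag(Notch) >= ", x$mag_notch_min,
      " dB or Mag(ExcessHF) >= ", x$mag_excess_hf_min, " dB\n", sep = "")
  invisible(x)
}

#' Requirement R1: high-frequency loss relative to 1/2 kHz
#'
#' R1 is met when any single HTL at 3, 4, 6 or 8 kHz is at least 10 dB
#' higher than the HTL at 1 or 2 kHz. "At 1 or 2 kHz" is read as the more
#' permissive reference, min(HTL(1), HTL(2)) — either low frequency
#' suffices — consistent with the method's high-sensitivity intent; the
#' stricter max reference is available via `reference = "max"`.
#'
#' @param ear an `ear_audiogram` (or coercible numeric vector).
#' @param reference `"min"` (default) or `"max"` of HTL(1), HTL(2).
#' @return list with `met` (logical) and `magnitudes` (dB, named by
#'   frequency 3, 4, 6, 8).
#' @export
r1_check <- function(ear, reference = c("min", "max")) {
  ear <- as_ear(ear)
  reference <- match.arg(reference)
  ref <- if (reference == "min") min(ear["1"], ear["2"])
         else max(ear["1"], ear["2"])
  mags <- ear[freq_key(c(3, 4, 6, 8))] - ref
  list(met = any(mags >= 10), magnitudes = unclass(mags))
}

#' Notch/bulge depth Mag(Notch)
#'
#' For each candidate notch center f in {6, 4, 3} kHz the age-corrected
#' excess over 8 kHz is computed as
#' \deqn{[HTL(f) - HTL(8)] - [AAHL(f) - AAHL(8)]}
#' and Mag(Notch) is the maximum of the three. The maximum allows for the
#' notch being centered at 3 or 6 kHz rather than the classic 4 kHz.
#'
#' @param ear an `ear_audiogram`.
#' @param aahl an `aahl_surface` for the subject's age and sex.
#' @return list with `components` (dB, named by center frequency 3, 4, 6)
#'   and `mag_notch` (their maximum, dB).
#' @export
mag_notch <- function(ear, aahl) {
  ear <- as_ear(ear)
  comp <- vapply(freq_key(c(3, 4, 6)), function(f) {
    (ear[[f]] - ear[["8"]]) - (aahl[[f]] - aahl[["8"]])
  }, numeric(1))
  list(components = comp, mag_notch = max(comp))
}

#' Mean high-frequency excess Mag(ExcessHF)
#'
#' \deqn{Mag(ExcessHF) = [HTL(4)+HTL(6)+HTL(8)]/3 - [AAHL(4)+AAHL(6)+AAHL(8)]/3}
#' the amount by which the average measured loss over 4, 6 and 8 kHz
#' exceeds the median loss expected from age alone.
#'
#' @inheritParams mag_notch
#' @return Mag(ExcessHF) in dB.
#' @export
mag_excess_hf <- function(ear, aahl) {
  ear <- as_ear(ear)
  hf <- freq_key(c(4, 6, 8))
  mean(unclass(ear)[hf]) - mean(unclass(aahl)[hf])
}

#' Requirement R2a (M-NIHL): slope flatter than expected from age
#'
#' Met when the 8-minus-6 kHz HTL difference is at least 5 dB smaller than
#' expected from age alone, or the 8-minus-4 or 8-minus-3 kHz difference is
#' at least 10 dB smaller than expected from age alone. Boundaries are
#' inclusive.
#'
#' @inheritParams mag_notch
#' @return logical; attribute `by_pair` holds the three sub-conditions
#'   (named by the lower frequency 3, 4, 6).
#' @export
r2a_check <- function(ear, aahl) {
  ear <- as_ear(ear)
  d <- function(f) (ear[["8"]] - ear[[f]]) - (aahl[["8"]] - aahl[[f]])
  by_pair <- c("3" = d("3") <= -10, "4" = d("4") <= -10, "6" = d("6") <= -5)
  structure(any(by_pair), by_pair = by_pair)
}

#' Requirement R2b (M-NIHL): absolute high-frequency excess
#'
#' Met when the HTL at any one of 4, 6 or 8 kHz is at least 20 dB above the
#' median expected for that age. Boundary inclusive.
#'
#' @inheritParams mag_notch
#' @return logical; attribute `by_freq` holds the per-frequency conditions.
#' @export
r2b_check <- function(ear, aahl) {
  ear <- as_ear(ear)
  hf <- freq_key(c(4, 6, 8))
  by_freq <- vapply(hf, function(f) ear[[f]] >= aahl[[f]] + 20, logical(1))
  structure(any(by_freq), by_freq = by_freq)
}

#' Diagnose one ear under the M-NIHL or rM-NIHL method
#'
#' Computes all requirement booleans and magnitudes for the ear, then the
#' positive/negative call for both methods (`method` selects which call is
#' reported as `positive`). The two methods can disagree: an ear that just
#' meets the original R2a slope test can still have Mag(Notch) below 14.5
#' dB and be rM-NIHL-negative.
#'
#' @param ear an `ear_audiogram`.
#' @param age subject age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param method `"rmnihl"` (default) or `"mnihl"`.
#' @param criteria an [nihl_criteria()] object.
#' @param aahl optionally a precomputed `aahl_surface`; otherwise built via
#'   [aahl_surface()] with `...` passed through (backend, alpha, fixture).
#' @param r1_reference passed to [r1_check()].
#' @param ... further arguments to [aahl_surface()].
#' @return object of class `ear_diagnosis`: a list with `r1_met`,
#'   `r1_magnitudes`, `r2a_met`, `r2b_met`, `mag_notch_components`,
#'   `mag_notch`, `mag_excess_hf`, `positive_mnihl`, `positive_rmnihl`,
#'   `method`, `positive`.
#' @examples
#' diagnose_ear(c(10, 10, 10, 10, 20, 15), age = 52, sex = "male")
#' @export
diagnose_ear <- function(ear, age, sex, method = c("rmnihl", "mnihl"),
                         criteria = nihl_criteria(), aahl = NULL,
                         r1_reference = c("min", "max"), ...) {
  method <- match.arg(method)
  ear <- as_ear(ear)
  if (is.null(aahl)) aahl <- aahl_surface(age, sex, ...)
  r1 <- r1_check(ear, reference = r1_reference)
  r2a <- r2a_check(ear, aahl)
  r2b <- r2b_check(ear, aahl)
  mn <- mag_notch(ear, aahl)
  me <- mag_excess_hf(ear, aahl)
  pos_m <- r1$met && (as.logical(r2a) || as.logical(r2b))
  pos_r <- r1$met && (mn$mag_notch >= criteria$mag_notch_min ||
                        me >= criteria$mag_excess_hf_min)
  structure(list(
    r1_met = r1$met, r1_magnitudes = r1$magnitudes,
    r2a_met = as.logical(r2a), r2b_met = as.logical(r2b),
    mag_notch_components = mn$components, mag_notch = mn$mag_notch,
    mag_excess_hf = me,
    positive_mnihl = pos_m, positive_rmnihl = pos_r,
    method = method,
    positive = if (method == "rmnihl") pos_r else pos_m
  ), class = "ear_diagnosis")
}

#' @export
print.ear_diagnosis <- function(x, ...) {
  cat("Ear diagnosis (", x$method, "): ",
      if (x$positive) "POSITIVE" else "negative", "\n", sep = "")
  cat("  R1 met: ", x$r1_met, "  (magnitudes ",
      paste(sprintf("%.1f", x$r1_magnitudes), collapse = ", "),
      " dB at 3,4,6,8 kHz)\n", sep = "")
  cat("  Mag(Notch): ", sprintf("%.1f", x$mag_notch), " dB  (components ",
      paste(sprintf("%.1f", x$mag_notch_components), collapse = ", "),
      " at 3,4,6 kHz)\n", sep = "")
  cat("  Mag(ExcessHF): ", sprintf("%.1f", x$mag_excess_hf), " dB\n", sep = "")
  cat("  M-NIHL: R2a ", x$r2a_met, ", R2b ", x$r2b_met, " -> ",
      if (x$positive_mnihl) "POSITIVE" else "negative", "\n", sep = "")
  invisible(x)
}

#' Diagnose an individual (both ears)
#'
#' Applies [diagnose_ear()] to both ears and combines: `positive_either`
#' (one or both ears positive) and `positive_both` (both positive). If the
#' R0 precondition `exposure_evidence` is FALSE, both individual-level
#' calls are negative regardless of the audiometry and the result is
#' flagged (`r0_asserted = FALSE`); the ear-level audiometric results are
#' still reported.
#'
#' @param left,right `ear_audiogram`s for the left and right ears.
#' @param age,sex,method,criteria,aahl,r1_reference,... as in
#'   [diagnose_ear()].
#' @param exposure_evidence logical R0 assertion (default TRUE, matching
#'   how noise-exposed/control databases are scored at cohort level).
#' @return object of class `individual_diagnosis` with fields `left`,
#'   `right`, `positive_either`, `positive_both`, `method`, `r0_asserted`.
#' @export
diagnose_individual <- function(left, right, age, sex,
                                method = c("rmnihl", "mnihl"),
                                criteria = nihl_criteria(),
                                exposure_evidence = TRUE,
                                aahl = NULL, r1_reference = c("min", "max"),
                                ...) {
  method <- match.arg(method)
  if (is.null(aahl)) aahl <- aahl_surface(age, sex, ...)
  dl <- diagnose_ear(left, age, sex, method, criteria, aahl = aahl,
                     r1_reference = r1_reference)
  dr <- diagnose_ear(right, age, sex, method, criteria, aahl = aahl,
                     r1_reference = r1_reference)
  either <- exposure_evidence && (dl$positive || dr$positive)
  both <- exposure_evidence && (dl$positive && dr$positive)
  structure(list(left = dl, right = dr,
                 positive_either = either, positive_both = both,
                 method = method, r0_asserted = isTRUE(exposure_evidence)),
            class = "individual_diagnosis")
}

#' @export
print.individual_diagnosis <- function(x, ...) {
  cat("Individual diagnosis (", x$method, "):\n", sep = "")
  if (!x$r0_asserted)
    cat("  R0 not asserted (no documented noise exposure): calls negative\n")
  cat("  left ear:  ", if (x$left$positive) "POSITIVE" else "negative", "\n",
      "  right ear: ", if (x$right$positive) "POSITIVE" else "negative", "\n",
      "  either-ear rule: ", x$positive_either,
      " | both-ears rule: ", x$positive_both, "\n", sep = "")
  invisible(x)
}

# Per-ear magnitudes/requirements for every ear in a cohort, computed once
# so criterion sweeps can threshold without re-deriving audiometry.
# Returns a data.frame with one row per ear.
ear_magnitudes <- function(cohort, r1_reference = "min", ...) {
  stopifnot(inherits(cohort, "nihl_cohort"))
  rows <- vector("list", 2L * nrow(cohort))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    aahl <- aahl_surface(cohort$age[i], cohort$sex[i], ...)
    for (side in c("L", "R")) {
      ear <- cohort_ear(cohort, i, side)
      r1 <- r1_check(ear, reference = r1_reference)
      mn <- mag_notch(ear, aahl)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = i, id = cohort$id[i], side = side,
        exposure_evidence = cohort$exposure_evidence[i],
        r1_met = r1$met,
        r2a_met = as.logical(r2a_check(ear, aahl)),
        r2b_met = as.logical(r2b_check(ear, aahl)),
        mag_notch = mn$mag_notch,
        mag_excess_hf = mag_excess_hf(ear, aahl),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Ear-level positivity from precomputed magnitudes, vectorized over ears.
ear_positive <- function(mags, method, criteria) {
  if (method == "mnihl") {
    mags$r1_met & (mags$r2a_met | mags$r2b_met)
  } else {
    mags$r1_met & (mags$mag_notch >= criteria$mag_notch_min |
                     mags$mag_excess_hf >= criteria$mag_excess_hf_min)
  }
}

#' Diagnose every subject in a cohort
#'
#' @param cohort a `nihl_cohort`.
#' @param method `"rmnihl"` or `"mnihl"`.
#' @param criteria an [nihl_criteria()].
#' @param r1_reference passed to [r1_check()].
#' @param ... further arguments to [aahl_surface()].
#' @return data frame, one row per subject: per-ear magnitudes and
#'   requirement booleans (`L_`/`R_` prefixes), and `positive_left`,
#'   `positive_right`, `positive_either`, `positive_both` (the latter two
#'   gated by `exposure_evidence`, the R0 assertion).
#' @export
diagnose_cohort <- function(cohort, method = c("rmnihl", "mnihl"),
                            criteria = nihl_criteria(),
                            r1_reference = c("min", "max"), ...) {
  method <- match.arg(method)
  r1_reference <- match.arg(r1_reference)
  mags <- ear_magnitudes(cohort, r1_reference = r1_reference, ...)
  mags$positive <- ear_positive(mags, method, criteria)
  L <- mags[mags$side == "L", ]
  R <- mags[mags$side == "R", ]
  keep <- c("r1_met", "r2a_met", "r2b_met", "mag_notch", "mag_excess_hf")
  out <- data.frame(id = cohort$id, age = cohort$age, sex = cohort$sex,
                    exposure_evidence = cohort$exposure_evidence,
                    method = method, stringsAsFactors = FALSE)
  for (col in keep) {
    out[[paste0("L_", col)]] <- L[[col]]
    out[[paste0("R_", col)]] <- R[[col]]
  }
  out$positive_left <- L$positive
  out$positive_right <- R$positive
  out$positive_either <- out$exposure_evidence &
    (L$positive | R$positive)
  out$positive_both <- out$exposure_evidence &
    (L$positive & R$positive)
  out
}
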