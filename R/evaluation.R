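# Diagnostic performance of a method on a labelled case/control cohort
# pair: sensitivity, specificity, d-prime, ROC-style criterion sweeps, and
# the balanced criterion-selection procedure.

#' Signal-detection d-prime from sensitivity and specificity
#'
#' \deqn{d' = Z(hit rate) - Z(false alarm rate)}
#' where Z is the inverse of the cumulative Gaussian distribution, the hit
#' rate is the sensitivity and the false-alarm rate is 1 - specificity.
#' Degenerate proportions (0 or 1) would give infinite Z; when the
#' underlying counts are known they are clamped with the standard 1/(2n)
#' continuity correction, otherwise with a fixed small epsilon.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @param n_cases,n_controls optional counts behind the two proportions,
#'   used for the 1/(2n) clamp.
#' @return d-prime (dimensionless).
#' @examples
#' d_prime(0.972, 0.613)  # 2.20 to 2 d.p.
#' @export
d_prime <- function(sensitivity, specificity,
                    n_cases = NULL, n_controls = NULL) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  clamp <- function(p, n) {
    eps <- if (is.null(n)) 1e-4 else 1 / (2 * n)
    pmin(pmax(p, eps), 1 - eps)
  }
  qnorm(clamp(sensitivity, n_cases)) -
    qnorm(1 - clamp(specificity, n_controls))
}

# individual/ear-level positivity under one decision rule
rule_positive <- function(mags, method, criteria,
                          rule = c("either", "both", "each_ear")) {
  rule <- match.arg(rule)
  pos <- ear_positive(mags, method, criteria)
  if (rule == "each_ear") return(pos & mags$exposure_evidence)
  byL <- pos[mags$side == "L"]
  byR <- pos[mags$side == "R"]
  r0 <- mags$exposure_evidence[mags$side == "L"]
  if (rule == "either") r0 & (byL | byR) else r0 & (byL & byR)
}

#' Sensitivity, specificity and d-prime for a case/control cohort pair
#'
#' The case cohort is assumed truly affected and the control cohort truly
#' unaffected, so sensitivity is the proportion of cases called positive
#' and specificity the proportion of controls called negative. Under
#' `rule = "each_ear"` ears are counted independently (denominator 2 x
#' subjects); `"either"` and `"both"` count individuals.
#'
#' @param cases,controls `nihl_cohort`s (non-empty).
#' @param method `"rmnihl"` or `"mnihl"`.
#' @param criteria an [nihl_criteria()].
#' @param rule `"either"`, `"both"` or `"each_ear"`.
#' @param r1_reference passed to [r1_check()].
#' @param ... further arguments to [aahl_surface()].
#' @return object of class `nihl_performance`: list with counts,
#'   `sensitivity`, `specificity`, `d_prime`, `rule`, `method`, `criteria`.
#' @export
evaluate_cohorts <- function(cases, controls, method = c("rmnihl", "mnihl"),
                             criteria = nihl_criteria(),
                             rule = c("either", "both", "each_ear"),
                             r1_reference = c("min", "max"), ...) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  r1_reference <- match.arg(r1_reference)
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("empty cohort", call. = FALSE)
  m_cases <- ear_magnitudes(cases, r1_reference = r1_reference, ...)
  m_controls <- ear_magnitudes(controls, r1_reference = r1_reference, ...)
  performance_from_magnitudes(m_cases, m_controls, method, criteria, rule)
}

# core computation, reusable by sweeps without recomputing magnitudes
performance_from_magnitudes <- function(m_cases, m_controls, method,
                                        criteria, rule) {
  pos_cases <- rule_positive(m_cases, method, criteria, rule)
  pos_controls <- rule_positive(m_controls, method, criteria, rule)
  n_cases <- length(pos_cases)
  n_controls <- length(pos_controls)
  sens <- sum(pos_cases) / n_cases
  spec <- sum(!pos_controls) / n_controls
  structure(list(
    rule = rule, method = method, criteria = criteria,
    n_positive_cases = sum(pos_cases), n_cases = n_cases,
    n_negative_controls = sum(!pos_controls), n_controls = n_controls,
    sensitivity = sens, specificity = spec,
    d_prime = d_prime(sens, spec, n_cases, n_controls)
  ), class = "nihl_performance")
}

#' @export
print.nihl_performance <- function(x, ...) {
  cat("Diagnostic performance (", x$method, ", rule = ", x$rule, ")\n",
      sep = "")
  cat(sprintf("  sensitivity %.3f (%d/%d)  specificity %.3f (%d/%d)  d' %.2f\n",
              x$sensitivity, x$n_positive_cases, x$n_cases,
              x$specificity, x$n_negative_controls, x$n_controls,
              x$d_prime))
  invisible(x)
}

#' ROC-style sweep over one criterion threshold
#'
#' Holds one of the two rM-NIHL criterion thresholds fixed and sweeps the
#' other over a grid, recording (sensitivity, 1 - specificity) for each of
#' the three decision rules at every grid value — the construction behind
#' the method's ROC curves (e.g. Mag(Notch) fixed at 14.5 dB while
#' Mag(ExcessHF) runs from 13 to 25 dB).
#'
#' @param cases,controls `nihl_cohort`s.
#' @param sweep which threshold to sweep: `"mag_notch_min"` or
#'   `"mag_excess_hf_min"`.
#' @param lo,hi,step sweep grid (dB); `lo <= hi`, `step > 0`.
#' @param fixed value (dB) for the other threshold.
#' @param method,r1_reference,... as in [evaluate_cohorts()].
#' @return data frame of class `nihl_roc`: one row per (grid value, rule)
#'   with `mag_notch_min`, `mag_excess_hf_min`, `rule`, `sensitivity`,
#'   `specificity`, `fpr` (= 1 - specificity), `d_prime`.
#' @export
roc_sweep <- function(cases, controls,
                      sweep = c("mag_excess_hf_min", "mag_notch_min"),
                      lo, hi, step = 1, fixed,
                      method = c("rmnihl", "mnihl"),
                      r1_reference = c("min", "max"), ...) {
  sweep <- match.arg(sweep)
  method <- match.arg(method)
  r1_reference <- match.arg(r1_reference)
  if (!(lo <= hi) || step <= 0) stop("invalid sweep range", call. = FALSE)
  grid <- seq(lo, hi, by = step)
  m_cases <- ear_magnitudes(cases, r1_reference = r1_reference, ...)
  m_controls <- ear_magnitudes(controls, r1_reference = r1_reference, ...)
  rows <- list()
  for (v in grid) {
    crit <- if (sweep == "mag_excess_hf_min")
      nihl_criteria(mag_notch_min = fixed, mag_excess_hf_min = v)
    else
      nihl_criteria(mag_notch_min = v, mag_excess_hf_min = fixed)
    for (rule in c("either", "both", "each_ear")) {
      p <- performance_from_magnitudes(m_cases, m_controls, method, crit,
                                       rule)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_notch_min = crit$mag_notch_min,
        mag_excess_hf_min = crit$mag_excess_hf_min,
        rule = rule, sensitivity = p$sensitivity,
        specificity = p$specificity, fpr = 1 - p$specificity,
        d_prime = p$d_prime, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nihl_roc", "data.frame")
  out
}

#' Iso-d-prime ROC curve
#'
#' The ROC curve traced by a fixed d-prime as the decision criterion
#' varies: sensitivity = Phi(d' + Z(false-alarm rate)) pointwise. Used as a
#' reference curve against which swept (1 - specificity, sensitivity)
#' points can be compared.
#'
#' @param d d-prime value (finite).
#' @param fpr grid of false-alarm rates in (0, 1).
#' @return data frame with columns `fpr` and `sensitivity`.
#' @export
iso_dprime_curve <- function(d, fpr = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(is.finite(d), all(fpr > 0 & fpr < 1))
  data.frame(fpr = fpr, sensitivity = pnorm(d + qnorm(fpr)))
}

#' Select balanced criterion thresholds
#'
#' Implements the published selection procedure over a grid of candidate
#' (Mag(Notch), Mag(ExcessHF)) threshold pairs:
#' \enumerate{
#'   \item on the controls, each ear considered separately (R1 still
#'     required), the proportion of false positives triggered by
#'     Mag(Notch) alone should be similar to the proportion triggered by
#'     Mag(ExcessHF) alone — operationalized as minimizing their absolute
#'     difference;
#'   \item specificity under the either-ear rule must exceed
#'     `spec_either_min` (default 0.6);
#'   \item sensitivity under the both-ears rule must exceed
#'     `sens_both_min` (default 0.75).
#' }
#' The feasible pair minimizing the balance gap is returned; if no pair is
#' feasible an error is raised reporting the best infeasible pair.
#'
#' @param cases,controls `nihl_cohort`s (development databases).
#' @param notch_grid,excess_grid numeric vectors of candidate thresholds
#'   (dB); defaults are 0.5-dB grids over the plausible published ranges.
#' @param spec_either_min,sens_both_min the two constraint bounds.
#' @param r1_reference,... as in [evaluate_cohorts()].
#' @return an [nihl_criteria()] with attribute `diagnostics`: a data frame
#'   over the whole grid with `fp_notch_only`, `fp_excess_only`,
#'   `balance_gap`, `spec_either`, `sens_both`, `feasible`.
#' @export
select_criteria <- function(cases, controls,
                            notch_grid = seq(7.5, 20.5, by = 0.5),
                            excess_grid = seq(13, 25, by = 0.5),
                            spec_either_min = 0.6, sens_both_min = 0.75,
                            r1_reference = c("min", "max"), ...) {
  r1_reference <- match.arg(r1_reference)
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("empty cohort", call. = FALSE)
  m_cases <- ear_magnitudes(cases, r1_reference = r1_reference, ...)
  m_controls <- ear_magnitudes(controls, r1_reference = r1_reference, ...)
  n_ctrl_ears <- nrow(m_controls)

  grid <- expand.grid(mag_notch_min = notch_grid,
                      mag_excess_hf_min = excess_grid)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    crit <- nihl_criteria(grid$mag_notch_min[k], grid$mag_excess_hf_min[k])
    # single-trigger false-positive proportions, per control ear, R1 gated
    fp_notch <- sum(m_controls$r1_met &
                      m_controls$mag_notch >= crit$mag_notch_min) /
      n_ctrl_ears
    fp_excess <- sum(m_controls$r1_met &
                       m_controls$mag_excess_hf >= crit$mag_excess_hf_min) /
      n_ctrl_ears
    spec_either <- performance_from_magnitudes(
      m_cases, m_controls, "rmnihl", crit, "either")$specificity
    sens_both <- performance_from_magnitudes(
      m_cases, m_controls, "rmnihl", crit, "both")$sensitivity
    data.frame(mag_notch_min = crit$mag_notch_min,
               mag_excess_hf_min = crit$mag_excess_hf_min,
               fp_notch_only = fp_notch, fp_excess_only = fp_excess,
               balance_gap = abs(fp_notch - fp_excess),
               spec_either = spec_either, sens_both = sens_both,
               feasible = spec_either > spec_either_min &
                 sens_both > sens_both_min)
  })
  diag <- do.call(rbind, res)
  if (!any(diag$feasible)) {
    best <- diag[which.min(diag$balance_gap), ]
    stop("no criterion pair satisfies the constraints ",
         "(specificity(either) > ", spec_either_min,
         ", sensitivity(both) > ", sens_both_min, "); ",
         "best infeasible pair: (", best$mag_notch_min, ", ",
         best$mag_excess_hf_min, ") with spec ",
         round(best$spec_either, 3), ", sens ", round(best$sens_both, 3),
         call. = FALSE)
  }
  feas <- diag[diag$feasible, ]
  best <- feas[which.min(feas$balance_gap), ]
  out <- nihl_criteria(best$mag_notch_min, best$mag_excess_hf_min)
  attr(out, "diagnostics") <- diag
  attr(out, "selected") <- best
  out
}
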