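# Shared fixtures, all built in code.

# Published worked example: age-52 male ear and its AAHL row.
WE_HTL <- c(10, 10, 10, 10, 20, 15)          # 1,2,3,4,6,8 kHz
WE_AAHL <- c(4.6, 7.5, 10.1, 12.4, 15.9, 18.6)
WE_AGE <- 52

# The twelve published (sensitivity, specificity, d') triples:
# rM-NIHL and M-NIHL on the development and evaluation database pairs,
# under the either / both / each-ear rules.
PUBLISHED_TRIPLES <- data.frame(
  sens = c(0.972, 0.769, 0.871, 0.993, 0.930, 0.961,
           0.979, 0.761, 0.870, 0.993, 0.880, 0.940),
  spec = c(0.613, 0.914, 0.763, 0.344, 0.828, 0.586,
           0.630, 0.946, 0.788, 0.402, 0.815, 0.609),
  d    = c(2.20, 2.10, 1.85, 2.06, 2.42, 1.99,
           2.37, 2.32, 1.92, 2.21, 2.07, 1.83))

# --- constructed age-18 ears (AAHL = 0, so magnitudes are direct) -------

# Mag(Notch) = m (notch centered at 6 kHz), Mag(ExcessHF) = (20 + m)/3,
# R1 met via the 3 kHz value.
notch_ear <- function(m) c(0, 0, 10, 0, 10 + m, 10)

# Mag(ExcessHF) = e (flat high-frequency elevation), Mag(Notch) = 0 for
# e >= 10, R1 met.
excess_ear <- function(e) c(0, 0, 10, e, e, e)

# R1 met but both magnitudes harmless.
neg_ear <- function() notch_ear(0)

# R1 fails outright.
flat_ear <- function(htl = 0) rep(htl, 6)

# --- cohort assembly ----------------------------------------------------

subject_row <- function(id, left, right, age = 18, sex = "male",
                        exposure_evidence = TRUE) {
  row <- data.frame(id = id, age = age, sex = sex,
                    exposure_evidence = exposure_evidence,
                    stringsAsFactors = FALSE)
  for (j in 1:6) row[[paste0("L_", c(1, 2, 3, 4, 6, 8)[j], "k")]] <- left[j]
  for (j in 1:6) row[[paste0("R_", c(1, 2, 3, 4, 6, 8)[j], "k")]] <- right[j]
  row
}

make_cohort <- function(rows, label = NULL) {
  nihl_cohort(do.call(rbind, rows), label = label)
}

# Hand-counted toy pair: under the both-ears rule sensitivity is 7/10 and
# specificity 9/10 (under either: 10/10 and 9/10).
toy_case_cohort <- function() {
  rows <- c(
    lapply(1:7, function(i) subject_row(paste0("case_bb", i),
                                        notch_ear(20), notch_ear(20))),
    lapply(1:3, function(i) subject_row(paste0("case_lo", i),
                                        notch_ear(20), neg_ear())))
  make_cohort(rows, "toy_cases")
}
toy_control_cohort <- function() {
  rows <- c(
    lapply(1:9, function(i) subject_row(paste0("ctl_neg", i),
                                        neg_ear(), neg_ear())),
    list(subject_row("ctl_pos", notch_ear(20), notch_ear(20))))
  make_cohort(rows, "toy_controls")
}

# Cohort pair constructed so that, on a 0.5-dB grid, the threshold pair
# (14.5, 19.0) uniquely satisfies the three selection conditions:
# sens(both) > 0.75 forces Mag(Notch) <= 14.5 (case ears carry exactly
# 14.5-dB notches), spec(either) > 0.6 forces thresholds above the 14.2-dB
# notch / 18.7-dB excess control ears, and the 14.7 / 19.2 singleton
# control ears make the single-trigger false-positive proportions balance
# (1/24 each) only at (14.5, 19.0).
selection_case_cohort <- function() {
  rows <- c(
    lapply(1:8, function(i) subject_row(paste0("c", i),
                                        notch_ear(14.5), notch_ear(14.5))),
    lapply(9:10, function(i) subject_row(paste0("c", i),
                                         neg_ear(), neg_ear())))
  make_cohort(rows, "sel_cases")
}
selection_control_cohort <- function() {
  rows <- c(
    lapply(1:5, function(i) subject_row(paste0("n", i),
                                        notch_ear(14.2), flat_ear())),
    lapply(6:10, function(i) subject_row(paste0("n", i),
                                         excess_ear(18.7), flat_ear())),
    list(subject_row("n11", notch_ear(14.7), flat_ear()),
         subject_row("n12", excess_ear(19.2), flat_ear())))
  make_cohort(rows, "sel_controls")
}

# Random valid ears for property tests (uniform HTLs over a wide range).
random_ears <- function(n, seed = 1) {
  set.seed(seed)
  matrix(round(runif(6 * n, -10, 90), 1), ncol = 6,
         dimnames = list(NULL, c("1", "2", "3", "4", "6", "8")))
}
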