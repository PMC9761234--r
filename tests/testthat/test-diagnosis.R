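we_aahl_surface <- function() aahl_surface(WE_AGE, "male")

test_that("R1 reproduces the worked-example magnitudes", {
  r1 <- r1_check(WE_HTL)
  expect_true(r1$met)
  expect_equal(unname(r1$magnitudes), c(0, 0, 10, 5))

  flat <- r1_check(flat_ear(20))
  expect_false(flat$met)
  expect_equal(unname(flat$magnitudes), rep(0, 4))
})

test_that("R1 reference choice: min of 1/2 kHz is the default, max optional", {
  # HTL(1)=5, HTL(2)=15, HTL(4)=15: magnitude 10 under min reference
  ear <- c(5, 15, 5, 15, 5, 5)
  r_min <- r1_check(ear, reference = "min")
  r_max <- r1_check(ear, reference = "max")
  expect_equal(unname(r_min$magnitudes[["4"]]), 10)
  expect_true(r_min$met)
  expect_false(r_max$met)  # against max(5,15) the excess is only 0
  # enumeration: min reference is never stricter than max reference
  ears <- random_ears(200, seed = 5)
  for (i in seq_len(nrow(ears))) {
    if (r1_check(ears[i, ], reference = "max")$met)
      expect_true(r1_check(ears[i, ], reference = "min")$met)
  }
})

test_that("Mag(Notch) matches the worked example and degenerate cases", {
  mn <- mag_notch(WE_HTL, we_aahl_surface())
  expect_equal(unname(mn$components), c(3.5, 1.2, 7.7))
  expect_equal(mn$mag_notch, 7.7)

  # HTL equal to AAHL everywhere: all components zero
  aahl <- we_aahl_surface()
  mn0 <- mag_notch(ear_audiogram(as.numeric(aahl)), aahl)
  expect_equal(unname(mn0$components), rep(0, 3))

  # age 18 (AAHL = 0): components reduce to HTL differences vs 8 kHz
  mn18 <- mag_notch(c(0, 0, 10, 20, 30, 20), aahl_surface(18, "male"))
  expect_equal(unname(mn18$components), c(-10, 0, 10))
  expect_equal(mn18$mag_notch, 10)
})

test_that("Mag(Notch) sign convention: left-to-right parse agrees with the
           bracketed-difference form on random ears", {
  aahl <- we_aahl_surface()
  ears <- random_ears(300, seed = 7)
  for (i in seq_len(nrow(ears))) {
    h <- ears[i, ]
    comp <- mag_notch(h, aahl)$components
    for (f in c("3", "4", "6")) {
      left_to_right <- h[[f]] - h[["8"]] - aahl[[f]] + aahl[["8"]]
      expect_equal(unname(comp[[f]]), unname(left_to_right))
    }
  }
})

test_that("Mag(ExcessHF) matches the worked example, is linear in HTL", {
  me <- mag_excess_hf(WE_HTL, we_aahl_surface())
  expect_equal(me, (10 + 20 + 15) / 3 - (12.4 + 15.9 + 18.6) / 3)
  expect_equal(round(me, 1), -0.6)

  expect_equal(mag_excess_hf(c(0, 0, 0, 19, 19, 19),
                             aahl_surface(18, "male")), 19)

  # shift invariance: HTL = AAHL + delta everywhere gives exactly delta
  aahl <- we_aahl_surface()
  for (delta in c(-5, 0, 7.3)) {
    expect_equal(mag_excess_hf(as.numeric(aahl) + delta, aahl), delta)
  }
})

test_that("R2a matches the worked example with inclusive boundaries", {
  aahl <- we_aahl_surface()
  r2a <- r2a_check(WE_HTL, aahl)
  expect_true(as.logical(r2a))
  expect_equal(unname(attr(r2a, "by_pair")), c(FALSE, FALSE, TRUE))

  # HTL(8)-HTL(6) exactly equal to the age expectation: not met
  h <- c(0, 0, 0, 0, 10, 10 + (aahl[["8"]] - aahl[["6"]]))
  expect_false(as.logical(r2a_check(h, aahl)))

  # exactly 10 dB smaller on the 8/4 pair: met ("at least" is inclusive);
  # at age 18 the expectation is 0, so the boundary sits at -10 exactly
  a18 <- aahl_surface(18, "male")
  r2a_b <- r2a_check(c(0, 0, 0, 20, 10, 10), a18)
  expect_true(as.logical(r2a_b))
  expect_equal(unname(attr(r2a_b, "by_pair")), c(FALSE, TRUE, FALSE))
})

test_that("R2b matches the worked example with inclusive boundaries", {
  expect_false(as.logical(r2b_check(WE_HTL, we_aahl_surface())))
  a18 <- aahl_surface(18, "male")
  expect_true(as.logical(r2b_check(c(0, 0, 0, 20, 0, 0), a18)))
  expect_false(as.logical(r2b_check(c(0, 0, 0, 19.9, 19.9, 19.9), a18)))
})

test_that("the worked-example ear is M-NIHL positive but rM-NIHL negative", {
  d <- diagnose_ear(WE_HTL, WE_AGE, "male")
  expect_true(d$r1_met)
  expect_true(d$r2a_met)
  expect_false(d$r2b_met)
  expect_true(d$positive_mnihl)
  expect_equal(d$mag_notch, 7.7)
  expect_equal(round(d$mag_excess_hf, 1), -0.6)
  expect_false(d$positive_rmnihl)
  expect_false(d$positive)  # default method is rmnihl
  expect_true(diagnose_ear(WE_HTL, WE_AGE, "male", method = "mnihl")$positive)
})

test_that("criterion boundaries are inclusive and flat ears are negative", {
  # mag_notch exactly 14.5 with R1 met: positive
  d <- diagnose_ear(notch_ear(14.5), 18, "male")
  expect_equal(d$mag_notch, 14.5)
  expect_true(d$positive_rmnihl)
  # just below: negative
  expect_false(diagnose_ear(notch_ear(14.49), 18, "male")$positive_rmnihl)
  # mag_excess exactly 19: positive
  expect_true(diagnose_ear(excess_ear(19), 18, "male")$positive_rmnihl)
  # flat 0-dB audiogram: R1 fails, both methods negative at any age
  for (age in c(18, 40, 65)) {
    d0 <- diagnose_ear(flat_ear(), age, "male")
    expect_false(d0$positive_mnihl)
    expect_false(d0$positive_rmnihl)
  }
})

test_that("raising criteria never flips an ear negative-to-positive", {
  ears <- random_ears(150, seed = 9)
  grid <- expand.grid(mn = c(8, 12, 14.5, 18), me = c(14, 19, 23))
  for (i in seq_len(nrow(ears))) {
    calls <- mapply(function(mn, me)
      diagnose_ear(ears[i, ], 45, "male",
                   criteria = nihl_criteria(mn, me))$positive_rmnihl,
      grid$mn, grid$me)
    # positivity must be monotone non-increasing in both thresholds
    for (a in seq_len(nrow(grid))) for (b in seq_len(nrow(grid))) {
      if (grid$mn[b] >= grid$mn[a] && grid$me[b] >= grid$me[a])
        expect_true(calls[a] || !calls[b])
    }
  }
})

test_that("monotonicity of the magnitudes in single HTLs", {
  aahl <- we_aahl_surface()
  ears <- random_ears(60, seed = 13)
  for (i in seq_len(nrow(ears))) {
    h <- ears[i, ]
    for (delta in c(2, 10)) {
      h6 <- h; h6[["6"]] <- min(h6[["6"]] + delta, 120)
      expect_gte(mag_notch(h6, aahl)$mag_notch,
                 mag_notch(h, aahl)$mag_notch)
      hf <- h; hf[c("4", "6", "8")] <- hf[c("4", "6", "8")] + delta
      expect_equal(mag_excess_hf(hf, aahl),
                   mag_excess_hf(h, aahl) + delta)
    }
  }
})

test_that("individual diagnosis combines ears and gates on R0", {
  pos <- notch_ear(20); neg <- neg_ear()
  d1 <- diagnose_individual(pos, neg, 18, "male")
  expect_true(d1$left$positive); expect_false(d1$right$positive)
  expect_true(d1$positive_either); expect_false(d1$positive_both)

  d2 <- diagnose_individual(pos, pos, 18, "male")
  expect_true(d2$positive_either); expect_true(d2$positive_both)

  # R0 false: audiometrically positive ears, but individual calls negative
  d3 <- diagnose_individual(pos, pos, 18, "male",
                            exposure_evidence = FALSE)
  expect_true(d3$left$positive)   # ear-level audiometry still reported
  expect_false(d3$positive_either)
  expect_false(d3$positive_both)
  expect_false(d3$r0_asserted)
})

test_that("diagnose_cohort agrees with per-ear diagnosis", {
  cohort <- make_cohort(list(
    subject_row("s1", WE_HTL, notch_ear(20), age = 52),
    subject_row("s2", neg_ear(), neg_ear()),
    subject_row("s3", notch_ear(20), notch_ear(20),
                exposure_evidence = FALSE)))
  res <- diagnose_cohort(cohort)
  expect_equal(res$positive_left, c(FALSE, FALSE, TRUE))
  expect_equal(res$positive_right, c(TRUE, FALSE, TRUE))
  expect_equal(res$positive_either, c(TRUE, FALSE, FALSE))  # s3 gated by R0
  expect_equal(res$positive_both, c(FALSE, FALSE, FALSE))
  expect_equal(res$L_mag_notch[1], 7.7)
  expect_equal(round(res$L_mag_excess_hf[1], 1), -0.6)
})
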