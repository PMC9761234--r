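#' @importFrom stats qnorm pnorm rnorm setNames
#' @importFrom utils read.csv write.csv
NULL

# The six frequencies (kHz) the diagnostic method consumes. 0.5 kHz appears
# in the control-screening narrative but never enters the method, so it is
# deliberately not part of the data model.
NIHL_FREQS <- c(1, 2, 3, 4, 6, 8)

# Audiometer range sanity bounds (dB HL)
HTL_MIN <- -10
HTL_MAX <- 120

freq_key <- function(f) as.character(f)

ear_cols <- function(side) paste0(side, "_", NIHL_FREQS, "k")

#' Construct a validated single-ear audiogram
#'
#' An ear audiogram is a named numeric vector of hearing threshold levels
#' (dB HL) at the six frequencies the diagnostic method uses: 1, 2, 3, 4, 6
#' and 8 kHz. All six must be present and finite; values outside the
#' audiometer sanity range \[-10, 120\] dB HL are rejected. HTLs are kept as
#' supplied (real-valued); they are not forced onto a 5-dB grid.
#'
#' @param htl numeric vector of length 6. Either named with the frequencies
#'   in kHz (`"1"`, `"2"`, `"3"`, `"4"`, `"6"`, `"8"`) or unnamed and given
#'   in that order.
#' @return named numeric vector of class `ear_audiogram`.
#' @examples
#' ear_audiogram(c(10, 10, 10, 10, 20, 15))
#' @export
ear_audiogram <- function(htl) {
  if (!is.numeric(htl) || length(htl) != 6L)
    stop("an ear audiogram needs exactly 6 numeric HTLs (1,2,3,4,6,8 kHz)",
         call. = FALSE)
  if (is.null(names(htl))) {
    names(htl) <- freq_key(NIHL_FREQS)
  } else {
    want <- freq_key(NIHL_FREQS)
    if (!all(want %in% names(htl)))
      stop("missing frequency: ",
           paste(setdiff(want, names(htl)), collapse = ", "), " kHz",
           call. = FALSE)
    htl <- htl[want]
  }
  if (any(!is.finite(htl)))
    stop("non-finite HTL at ",
         paste(names(htl)[!is.finite(htl)], collapse = ", "), " kHz",
         call. = FALSE)
  if (any(htl < HTL_MIN | htl > HTL_MAX))
    stop("HTL outside [", HTL_MIN, ", ", HTL_MAX, "] dB HL at ",
         paste(names(htl)[htl < HTL_MIN | htl > HTL_MAX], collapse = ", "),
         " kHz", call. = FALSE)
  structure(as.numeric(setNames(htl, names(htl))),
            names = names(htl), class = "ear_audiogram")
}

as_ear <- function(x) {
  if (inherits(x, "ear_audiogram")) x else ear_audiogram(x)
}

#' Construct a cohort of audiogram subjects
#'
#' A cohort is a validated data frame, one row per subject, with columns
#' `id`, `age`, `sex`, `exposure_evidence` and twelve HTL columns
#' `L_1k ... L_8k`, `R_1k ... R_8k` (dB HL at 1, 2, 3, 4, 6, 8 kHz).
#' `exposure_evidence` records the R0 precondition of the M-NIHL method:
#' documented exposure to noise of sufficient intensity and duration. It is
#' an input assertion, never computed from the audiometry.
#'
#' @param df data frame in the wide cohort schema.
#' @param label optional cohort label, kept as an attribute.
#' @return `df` with class `nihl_cohort` prepended, after validation.
#' @export
nihl_cohort <- function(df, label = NULL) {
  required <- c("id", "age", "sex", "exposure_evidence",
                ear_cols("L"), ear_cols("R"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("no subjects", call. = FALSE)

  df$id <- as.character(df$id)
  df$sex <- tolower(as.character(df$sex))
  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex token in row(s) ", paste(bad_sex, collapse = ", "),
         call. = FALSE)

  for (col in c("age", ear_cols("L"), ear_cols("R"))) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column ", col, ", row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      v <- v2
    }
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("missing/non-finite value in column ", col, ", row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    df[[col]] <- as.numeric(v)
  }

  bad_age <- which(df$age < 18)
  if (length(bad_age))
    stop("age < 18 in row(s) ", paste(bad_age, collapse = ", "),
         " (the AAHL reference starts at 18)", call. = FALSE)

  for (col in c(ear_cols("L"), ear_cols("R"))) {
    bad <- which(df[[col]] < HTL_MIN | df[[col]] > HTL_MAX)
    if (length(bad))
      stop("HTL outside [", HTL_MIN, ", ", HTL_MAX, "] dB HL in column ",
           col, ", row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }

  if (is.logical(df$exposure_evidence)) {
    ee <- df$exposure_evidence
  } else {
    ee <- toupper(as.character(df$exposure_evidence))
    if (!all(ee %in% c("TRUE", "FALSE")))
      stop("exposure_evidence must be TRUE/FALSE", call. = FALSE)
    ee <- ee == "TRUE"
  }
  df$exposure_evidence <- ee

  df <- df[, required]
  attr(df, "label") <- label
  class(df) <- c("nihl_cohort", "data.frame")
  df
}

#' @export
print.nihl_cohort <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Audiogram cohort", if (!is.null(lab)) paste0("'", lab, "'"),
      "with", nrow(x), "subjects\n")
  cat("  ages ", round(min(x$age), 1), "-", round(max(x$age), 1),
      "; sex: ", paste(names(table(x$sex)), table(x$sex),
                       sep = "=", collapse = ", "), "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Extract one ear of one subject as an `ear_audiogram`
#'
#' @param cohort a `nihl_cohort`.
#' @param row subject row index.
#' @param side `"L"` or `"R"`.
#' @return an `ear_audiogram`.
#' @export
cohort_ear <- function(cohort, row, side = c("L", "R")) {
  side <- match.arg(side)
  ear_audiogram(setNames(as.numeric(cohort[row, ear_cols(side)]),
                         freq_key(NIHL_FREQS)))
}

#' Read a cohort CSV
#'
#' The schema is wide-format, one subject per row: `id, age, sex,
#' exposure_evidence, L_1k, L_2k, L_3k, L_4k, L_6k, L_8k, R_1k, ..., R_8k`.
#' Header required; UTF-8; "." decimal separator. Every malformed row is a
#' diagnostic error naming the row and column; rows are never silently
#' dropped.
#'
#' @param path path to the CSV file.
#' @param label optional cohort label.
#' @return a `nihl_cohort`; row order preserved.
#' @export
read_cohort <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no subjects in ", path, call. = FALSE)
  nihl_cohort(df, label = label)
}

#' Write a cohort CSV
#'
#' HTLs and age are serialized at 0.1-dB / 0.1-year precision, which makes
#' `read_cohort(write_cohort(x))` the identity on any cohort whose values
#' carry at most one decimal (the simulator and the clinical 5-dB grid both
#' satisfy this).
#'
#' @param cohort a `nihl_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nihl_cohort"))
  out <- as.data.frame(cohort)
  num_cols <- c("age", ear_cols("L"), ear_cols("R"))
  for (col in num_cols) out[[col]] <- sprintf("%.1f", out[[col]])
  out$exposure_evidence <- ifelse(cohort$exposure_evidence, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
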