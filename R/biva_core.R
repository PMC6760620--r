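#' Quality-control thresholds for duplicate impedance readings
#'
#' Plausibility and repeatability limits applied before analysis: records with
#' an averaged phase angle above `pa_max` are implausible (healthy values lie
#' between 5 and 7 degrees), and records whose duplicate readings disagree by
#' more than `pa_dup_max` degrees (phase angle) or by at least `rh_dup_max` /
#' `xch_dup_max` ohm/m after height adjustment (resistance / reactance) fail
#' repeatability.
#'
#' @param pa_max Maximum plausible averaged phase angle, degrees.
#' @param pa_dup_max Maximum allowed absolute difference between phase-angle
#'   duplicates, degrees (strict `>` excludes).
#' @param rh_dup_max,xch_dup_max Duplicate-difference limits for R/H and Xc/H,
#'   ohm/m (`>=` excludes).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(pa_max = 8.0, pa_dup_max = 0.5,
                          rh_dup_max = 6.0, xch_dup_max = 6.0) {
  stopifnot(pa_max > 0, pa_dup_max > 0, rh_dup_max > 0, xch_dup_max > 0)
  structure(list(pa_max = pa_max, pa_dup_max = pa_dup_max,
                 rh_dup_max = rh_dup_max, xch_dup_max = xch_dup_max),
            class = "qc_thresholds")
}

#' Height-adjusted impedance vector components
#'
#' Averages the duplicate 50 kHz readings and standardises resistance and
#' reactance for height: `r_h = mean(r1, r2)/height`, `xc_h = mean(xc1,
#' xc2)/height` (ohm/m). Phase angle is the average of the instrument-reported
#' duplicates; `pa_consistency` re-derives the angle as
#' `atan(xc_h/r_h) * 180/pi` from the averaged components as an internal
#' self-consistency check, and `z` is the impedance magnitude
#' `sqrt(R^2 + Xc^2)`.
#'
#' @param x A `cohort` object or data frame with the canonical duplicate
#'   reading and height columns.
#' @return Data frame with `subject_id`, `r_h`, `xc_h`, `pa`,
#'   `pa_consistency` and `z`.
#' @examples
#' coh <- generate_cohort(generator_config(n = 5, seed = 1))$cohort
#' compute_vectors(coh)
#' @export
compute_vectors <- function(x) {
  need <- c("height_m", "r1_ohm", "r2_ohm", "xc1_ohm", "xc2_ohm",
            "pa1_deg", "pa2_deg")
  miss <- need[!need %in% names(x)]
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(x)
  if (anyNA(df[, need]))
    stop("incomplete record: duplicate readings or height missing")
  if (any(df$height_m <= 0)) stop("nonpositive height")
  if (any(df[, c("r1_ohm", "r2_ohm", "xc1_ohm", "xc2_ohm",
                 "pa1_deg", "pa2_deg")] <= 0))
    stop("nonpositive impedance reading")
  r <- (df$r1_ohm + df$r2_ohm) / 2
  xc <- (df$xc1_ohm + df$xc2_ohm) / 2
  data.frame(
    subject_id = if ("subject_id" %in% names(df)) df$subject_id
                 else as.character(seq_len(nrow(df))),
    r_h = r / df$height_m,
    xc_h = xc / df$height_m,
    pa = (df$pa1_deg + df$pa2_deg) / 2,
    pa_consistency = atan2(xc, r) * 180 / pi,
    z = sqrt(r^2 + xc^2),
    stringsAsFactors = FALSE
  )
}

#' Partition a cohort into QC-kept and QC-excluded records
#'
#' Applies the exclusion rules of [qc_thresholds()] to every record. A record
#' is excluded iff its averaged phase angle exceeds `pa_max`, or any duplicate
#' pair fails repeatability; each excluded record carries exactly the reasons
#' that fired (a record can fail several rules). Records with missing
#' duplicates or height are excluded with reason `"incomplete"`. Kept and
#' excluded sets are disjoint and together contain every input record, and the
#' filter is idempotent: re-filtering the kept set removes nothing.
#'
#' @param x A `cohort` object.
#' @param thresholds A [qc_thresholds()] object.
#' @return Object of class `biva_qc`: list with `kept` (a `cohort`),
#'   `excluded` (data frame `subject_id`, `reasons`), `thresholds`, `n_input`.
#' @examples
#' coh <- generate_cohort(generator_config(n = 50, seed = 1,
#'   contamination = c(pa_implausible = 0.1)))$cohort
#' qc_filter(coh)
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  df <- as.data.frame(x)
  n <- nrow(df)
  need <- c("height_m", "r1_ohm", "r2_ohm", "xc1_ohm", "xc2_ohm",
            "pa1_deg", "pa2_deg")
  complete <- stats::complete.cases(df[, need, drop = FALSE]) &
    df$height_m > 0
  complete[is.na(complete)] <- FALSE

  reasons <- vector("list", n)
  for (i in which(!complete)) reasons[[i]] <- "incomplete"

  ok <- which(complete)
  pa_mean <- (df$pa1_deg + df$pa2_deg) / 2
  pa_gap <- abs(df$pa1_deg - df$pa2_deg)
  rh_gap <- abs(df$r1_ohm - df$r2_ohm) / df$height_m
  xch_gap <- abs(df$xc1_ohm - df$xc2_ohm) / df$height_m

  for (i in ok) {
    r <- character(0)
    if (pa_mean[i] > thresholds$pa_max) r <- c(r, "implausible PA")
    if (pa_gap[i] > thresholds$pa_dup_max) r <- c(r, "PA repeatability")
    if (rh_gap[i] >= thresholds$rh_dup_max) r <- c(r, "R/H repeatability")
    if (xch_gap[i] >= thresholds$xch_dup_max) r <- c(r, "Xc/H repeatability")
    if (length(r)) reasons[[i]] <- r
  }

  bad <- which(vapply(reasons, length, 1L) > 0L)
  kept_rows <- setdiff(seq_len(n), bad)
  kept <- df[kept_rows, , drop = FALSE]
  rownames(kept) <- NULL
  report <- attr(x, "parse_report")
  kept <- .new_cohort(kept, report)
  excluded <- data.frame(
    subject_id = df$subject_id[bad],
    reasons = vapply(reasons[bad], paste, "", collapse = "; "),
    stringsAsFactors = FALSE
  )
  structure(list(kept = kept, excluded = excluded, thresholds = thresholds,
                 n_input = n),
            class = "biva_qc")
}

#' @export
print.biva_qc <- function(x, ...) {
  cat(sprintf("<biva_qc> %d record(s) in: %d kept, %d excluded\n",
              x$n_input, nrow(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    tab <- sort(table(unlist(strsplit(x$excluded$reasons, "; ", fixed = TRUE))),
                decreasing = TRUE)
    for (nm in names(tab)) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}
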