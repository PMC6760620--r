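#' Total body water from deuterium dilution space
#'
#' Deuterium overestimates body water through proton exchange; the dilution
#' space is divided by 1.044 to obtain total body water (TBW).
#'
#' @param dilution_space_kg Deuterium dilution space, kg. Must be positive.
#' @param correction Proton-exchange overestimation factor (default 1.044).
#' @return TBW in kg.
#' @export
tbw_from_dilution <- function(dilution_space_kg, correction = 1.044) {
  if (any(!is.finite(dilution_space_kg) | dilution_space_kg <= 0))
    stop("dilution space must be positive")
  stopifnot(correction > 0)
  dilution_space_kg / correction
}

#' Default 4-component model coefficients
#'
#' Fuller-type linear combination of body volume (L), total body water (kg),
#' bone mineral content (kg) and body weight (kg) yielding fat mass:
#' `fm = 2.747*bv - 0.710*tbw + 1.460*bmc - 2.050*weight`. The coefficient set
#' is a configuration item; alternative published sets can be supplied to
#' [four_component()] and are recorded in its output.
#'
#' @return Named numeric vector with elements `bv`, `tbw`, `bmc`, `weight`.
#' @export
four_component_coefficients <- function() {
  c(bv = 2.747, tbw = -0.710, bmc = 1.460, weight = -2.050)
}

#' Fat and fat-free mass from the 4-component model
#'
#' Computes fat mass from weight, body volume (air-displacement
#' plethysmography), total body water (deuterium) and bone mineral content
#' (DXA); fat-free mass is the complement `ffm = weight - fm`, so mass closure
#' `fm + ffm = weight` holds exactly. Physiologically impossible combinations
#' (`fm < 0` or `fm > weight`) are flagged, not rejected.
#'
#' @param weight_kg,body_volume_l,tbw_kg,bmc_kg Vectors of positive inputs;
#'   `tbw_kg < weight_kg` and `bmc_kg < weight_kg` required.
#' @param coefficients Named vector as in [four_component_coefficients()].
#' @return Data frame with `fm_kg`, `ffm_kg`, logical `flag_fm_range`, and
#'   the coefficient set in attribute `"coefficients"`.
#' @examples
#' four_component(40, 38.3, 22, 1.7)
#' @export
four_component <- function(weight_kg, body_volume_l, tbw_kg, bmc_kg,
                           coefficients = four_component_coefficients()) {
  stopifnot(all(c("bv", "tbw", "bmc", "weight") %in% names(coefficients)))
  if (any(weight_kg <= 0 | body_volume_l <= 0 | tbw_kg <= 0 | bmc_kg <= 0,
          na.rm = TRUE))
    stop("all 4-component inputs must be positive")
  if (any(tbw_kg >= weight_kg, na.rm = TRUE))
    stop("total body water must be below body weight")
  if (any(bmc_kg >= weight_kg, na.rm = TRUE))
    stop("bone mineral content must be below body weight")
  fm <- coefficients[["bv"]] * body_volume_l +
    coefficients[["tbw"]] * tbw_kg +
    coefficients[["bmc"]] * bmc_kg +
    coefficients[["weight"]] * weight_kg
  out <- data.frame(
    fm_kg = fm,
    ffm_kg = weight_kg - fm,
    flag_fm_range = !is.na(fm) & (fm < 0 | fm > weight_kg)
  )
  attr(out, "coefficients") <- coefficients
  out
}

#' Hydration of fat-free mass
#'
#' `h_ffm = tbw/ffm`, the water fraction of fat-free mass. Values outside the
#' plausibility band for healthy children (0.70--0.80) are flagged via the
#' `"flag"` attribute, not rejected; hydration declines with chemical
#' maturation through childhood.
#'
#' @param tbw_kg Total body water, kg.
#' @param ffm_kg Fat-free mass, kg (must be positive).
#' @param band Plausibility band, fraction.
#' @return Numeric vector of hydration fractions with logical attribute
#'   `"flag"` marking values outside `band`.
#' @export
hydration <- function(tbw_kg, ffm_kg, band = c(0.70, 0.80)) {
  if (any(ffm_kg <= 0, na.rm = TRUE)) stop("fat-free mass must be positive")
  h <- tbw_kg / ffm_kg
  structure(h, flag = !is.na(h) & (h < band[1] | h > band[2]))
}

#' Per-subject body composition for a cohort
#'
#' Convenience wrapper running [tbw_from_dilution()], [four_component()] and
#' [hydration()] over a cohort, plus BMI (`weight/height^2`). Subjects with
#' any 4-component input missing get `NA` composition (BMI is always
#' computed).
#'
#' @param x A `cohort` object.
#' @param coefficients 4-component coefficient set.
#' @param tbw_correction Proton-exchange factor for [tbw_from_dilution()].
#' @return Data frame: `subject_id`, `tbw_kg`, `fm_kg`, `ffm_kg`, `h_ffm`,
#'   `bmi`, `flag_fm_range`, `flag_h_ffm`.
#' @export
body_composition <- function(x, coefficients = four_component_coefficients(),
                             tbw_correction = 1.044) {
  df <- as.data.frame(x)
  n <- nrow(df)
  out <- data.frame(
    subject_id = df$subject_id,
    tbw_kg = NA_real_, fm_kg = NA_real_, ffm_kg = NA_real_,
    h_ffm = NA_real_, bmi = df$weight_kg / df$height_m^2,
    flag_fm_range = NA, flag_h_ffm = NA,
    stringsAsFactors = FALSE
  )
  have <- stats::complete.cases(
    df[, c("weight_kg", "dilution_space_kg", "body_volume_l", "bmc_kg")])
  if (any(have)) {
    tbw <- tbw_from_dilution(df$dilution_space_kg[have], tbw_correction)
    fc <- four_component(df$weight_kg[have], df$body_volume_l[have],
                         tbw, df$bmc_kg[have], coefficients)
    h <- hydration(tbw, fc$ffm_kg)
    out$tbw_kg[have] <- tbw
    out$fm_kg[have] <- fc$fm_kg
    out$ffm_kg[have] <- fc$ffm_kg
    out$h_ffm[have] <- as.numeric(h)
    out$flag_fm_range[have] <- fc$flag_fm_range
    out$flag_h_ffm[have] <- attr(h, "flag")
  }
  attr(out, "coefficients") <- coefficients
  out
}
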