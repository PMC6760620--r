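# Synthetic cohorts with the statistical structure the analysis assumes:
# age/sex growth of every trait, a configurable SDS correlation structure,
# duplicate-measurement noise, and QC-violating contaminants. The generator
# draws one 7-dimensional standard-normal SDS vector per child (trait order
# pa, rh, xch, bmi, ffm, fm, hffm) from the positive-definite projection of
# the target correlation matrix and back-transforms each score through that
# sex's median/spread curves using log-normal spreads (L = 0); the LMS fitter
# must then recover approximately N(0,1) scores, deliberately testing its
# skewness selection toward zero.

.sds_traits <- c("pa", "rh", "xch", "bmi", "ffm", "fm", "hffm")

#' Published whole-cohort SDS correlation targets
#'
#' The symmetric 7x7 correlation matrix among PA, R/H, Xc/H, BMI, FFM, FM
#' and FFM-hydration standard deviation scores used as the generator's
#' default target structure. As printed, the matrix is not positive definite
#' (its FFM-FM entry is inconsistent with the BMI rows), so the generator
#' always projects it with [nearest_pd()] before sampling.
#'
#' @return 7x7 symmetric matrix with unit diagonal, dimnames
#'   `pa, rh, xch, bmi, ffm, fm, hffm`.
#' @export
default_sds_correlation <- function() {
  C <- diag(7)
  dimnames(C) <- list(.sds_traits, .sds_traits)
  set <- function(a, b, v) { C[a, b] <<- v; C[b, a] <<- v }
  set("pa", "rh", -0.32); set("pa", "xch", 0.40); set("pa", "bmi", 0.20)
  set("pa", "ffm", 0.29); set("pa", "fm", 0.01); set("pa", "hffm", -0.07)
  set("rh", "xch", 0.73); set("rh", "bmi", -0.72); set("rh", "ffm", -0.89)
  set("rh", "fm", -0.58); set("rh", "hffm", -0.32)
  set("xch", "bmi", -0.55); set("xch", "ffm", -0.65); set("xch", "fm", -0.54)
  set("xch", "hffm", -0.35)
  set("bmi", "ffm", 0.74); set("bmi", "fm", 0.92); set("bmi", "hffm", 0.45)
  set("ffm", "fm", -0.61); set("ffm", "hffm", 0.31)
  set("fm", "hffm", 0.52)
  C
}

#' Nearest positive-definite correlation matrix
#'
#' Returns the input unchanged when it is already positive definite (minimum
#' eigenvalue at least `eig_tol`); otherwise projects it to the nearest
#' positive-definite correlation matrix (Higham alternating projections, unit
#' diagonal restored) and reports the largest entry-wise adjustment in the
#' `"adjustment"` attribute. Idempotent.
#'
#' @param x Symmetric matrix with unit diagonal.
#' @param eig_tol Minimum eigenvalue below which projection is triggered.
#' @return Positive-definite correlation matrix with attribute
#'   `"adjustment"` (0 when unchanged).
#' @export
nearest_pd <- function(x, eig_tol = 1e-8) {
  x <- as.matrix(x)
  attr(x, "adjustment") <- NULL
  if (!isSymmetric(x, tol = 1e-10)) stop("matrix must be symmetric")
  if (any(abs(diag(x) - 1) > 1e-10)) stop("matrix must have unit diagonal")
  if (min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) >= eig_tol)
    return(structure(x, adjustment = 0))
  out <- as.matrix(Matrix::nearPD(x, corr = TRUE, eig.tol = eig_tol,
                                  posd.tol = eig_tol)$mat)
  dimnames(out) <- dimnames(x)
  structure(out, adjustment = max(abs(out - x)))
}

# Per-sex median anchor tables at ages 4, 12 and 20 y. Invented fixtures
# constrained by the qualitative shape statements: R/H and Xc/H decline with
# age curvilinearly, PA rises roughly linearly and stays within the healthy
# 5-7 degree band, hydration of FFM declines with chemical maturation.
# fm_frac is the median fat fraction of weight; ffm/fm medians are derived
# from bmi and height so that weight, BMI and height stay mutually
# consistent at the median.
.default_anchors <- function() {
  list(
    male = data.frame(
      age = c(4, 12, 20),
      height = c(1.06, 1.50, 1.77),
      rh = c(590, 375, 290), xch = c(64, 44, 34),
      pa = c(5.1, 5.9, 6.6),
      bmi = c(15.8, 17.8, 22.0), fm_frac = c(0.17, 0.15, 0.14),
      hffm = c(0.766, 0.750, 0.736)),
    female = data.frame(
      age = c(4, 12, 20),
      height = c(1.05, 1.51, 1.64),
      rh = c(610, 390, 320), xch = c(66, 46, 37),
      pa = c(5.0, 5.7, 6.3),
      bmi = c(15.5, 18.0, 21.5), fm_frac = c(0.20, 0.22, 0.26),
      hffm = c(0.768, 0.752, 0.740))
  )
}

.median_at <- function(anchors, sex, what, age) {
  a <- anchors[[sex]]
  stats::splinefun(a$age, a[[what]], method = "monoH.FC")(age)
}

#' Generator configuration
#'
#' @param n Cohort size.
#' @param seed RNG seed (all draws flow from it; the caller's RNG state is
#'   restored afterwards).
#' @param sds_correlation 7x7 target SDS correlation matrix, trait order
#'   `pa, rh, xch, bmi, ffm, fm, hffm`; projected with [nearest_pd()] before
#'   sampling.
#' @param anchors Per-sex median anchor tables (see the package defaults).
#' @param spread_cv Named coefficient-of-variation (sigma) per trait used for
#'   the log-normal back-transformation.
#' @param duplicate_noise_sd Measurement noise SD for the duplicate readings:
#'   `r` (ohm), `xc` (ohm), `pa` (degrees).
#' @param contamination Named fractions in `[0, 1)` of records made to
#'   violate QC: `pa_implausible`, `pa_repeat`, `rh_repeat`, `xch_repeat`.
#' @param age_range Age span in years (ages drawn uniformly; sexes balanced).
#' @param bmc_frac Bone mineral content as a fraction of fat-free mass.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n = 1000, seed = 0,
                             sds_correlation = default_sds_correlation(),
                             anchors = .default_anchors(),
                             spread_cv = c(pa = 0.07, rh = 0.11, xch = 0.12,
                                           bmi = 0.13, ffm = 0.11, fm = 0.35,
                                           hffm = 0.012),
                             duplicate_noise_sd = c(r = 2, xc = 1, pa = 0.1),
                             contamination = c(pa_implausible = 0,
                                               pa_repeat = 0, rh_repeat = 0,
                                               xch_repeat = 0),
                             age_range = c(4, 20),
                             bmc_frac = 0.045) {
  stopifnot(n > 0, length(age_range) == 2, age_range[1] < age_range[2])
  sds_correlation <- as.matrix(sds_correlation)
  stopifnot(nrow(sds_correlation) == 7, ncol(sds_correlation) == 7,
            isSymmetric(sds_correlation, tol = 1e-10),
            all(abs(diag(sds_correlation) - 1) < 1e-10),
            all(abs(sds_correlation) <= 1))
  full_cont <- c(pa_implausible = 0, pa_repeat = 0, rh_repeat = 0,
                 xch_repeat = 0)
  full_cont[names(contamination)] <- contamination
  stopifnot(all(full_cont >= 0), sum(full_cont) < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sds_correlation = sds_correlation, anchors = anchors,
                 spread_cv = spread_cv,
                 duplicate_noise_sd = duplicate_noise_sd,
                 contamination = full_cont, age_range = age_range,
                 bmc_frac = bmc_frac),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_config <- function() generator_config()

#' Generate a synthetic cohort with known truth
#'
#' Draws ages uniformly over the configured range with balanced sexes, one
#' correlated 7-trait SDS vector per child, and back-transforms the scores
#' through the per-sex median curves (log-normal spreads). Weight is the sum
#' of the intended fat and fat-free mass; height is derived from weight and
#' the BMI score so BMI, weight and height stay exactly consistent; the
#' deuterium dilution space, body volume and bone mineral content are derived
#' so that the 4-component equation reproduces the intended FM/FFM and
#' hydration exactly. Duplicate R/Xc/PA readings carry the configured
#' measurement noise, and the configured fractions of records are turned into
#' QC violators. Identical config and seed give identical output.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (a `cohort` object) and `truth` (one row per
#'   subject: true SDS vector, true composition, QC-violation label, and the
#'   positive-definite correlation actually sampled in attribute
#'   `"sds_correlation_pd"`).
#' @examples
#' g <- generate_cohort(generator_config(n = 100, seed = 42))
#' head(g$truth)
#' @export
generate_cohort <- function(config = default_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  n <- config$n
  Cpd <- nearest_pd(config$sds_correlation)
  R <- chol(Cpd)
  Z <- matrix(stats::rnorm(n * 7), n, 7) %*% R
  colnames(Z) <- .sds_traits

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- rep(c("male", "female"), length.out = n)
  cv <- config$spread_cv

  med <- function(what) {
    out <- numeric(n)
    for (sx in c("male", "female")) {
      i <- sex == sx
      out[i] <- .median_at(config$anchors, sx, what, age[i])
    }
    out
  }
  raw <- function(trait, what = trait) med(what) * exp(cv[[trait]] * Z[, trait])

  pa <- raw("pa")
  rh <- raw("rh")
  xch <- raw("xch")
  bmi <- raw("bmi")
  hffm <- raw("hffm")
  h_med <- med("height")
  bmi_med <- med("bmi")
  ff <- med("fm_frac")
  ffm <- (bmi_med * h_med^2 * (1 - ff)) * exp(cv[["ffm"]] * Z[, "ffm"])
  fm <- (bmi_med * h_med^2 * ff) * exp(cv[["fm"]] * Z[, "fm"])

  weight <- ffm + fm
  height <- sqrt(weight / bmi)
  tbw <- hffm * ffm
  dilution <- tbw * 1.044
  bmc <- config$bmc_frac * ffm
  cf <- four_component_coefficients()
  bv <- (fm - cf[["tbw"]] * tbw - cf[["bmc"]] * bmc -
           cf[["weight"]] * weight) / cf[["bv"]]

  nz <- config$duplicate_noise_sd
  r_mean <- rh * height
  xc_mean <- xch * height
  r1 <- r_mean + stats::rnorm(n, 0, nz[["r"]])
  r2 <- r_mean + stats::rnorm(n, 0, nz[["r"]])
  xc1 <- xc_mean + stats::rnorm(n, 0, nz[["xc"]])
  xc2 <- xc_mean + stats::rnorm(n, 0, nz[["xc"]])
  pa1 <- pa + stats::rnorm(n, 0, nz[["pa"]])
  pa2 <- pa + stats::rnorm(n, 0, nz[["pa"]])

  # contamination: disjoint random subsets made to violate one QC rule each
  qc_violation <- rep("none", n)
  fr <- config$contamination
  k <- round(fr * n)
  pool <- sample.int(n)
  take <- function(m) {
    idx <- utils::head(pool, m)
    pool <<- utils::tail(pool, length(pool) - m)
    idx
  }
  i <- take(k[["pa_implausible"]])
  if (length(i)) {
    v <- stats::runif(length(i), 8.2, 9.5)
    pa1[i] <- v + stats::runif(length(i), -0.1, 0.1)
    pa2[i] <- v + stats::runif(length(i), -0.1, 0.1)
    qc_violation[i] <- "pa_implausible"
  }
  i <- take(k[["pa_repeat"]])
  if (length(i)) {
    gap <- stats::runif(length(i), 0.6, 1.2)
    pa1[i] <- pa[i] - gap / 2
    pa2[i] <- pa[i] + gap / 2
    qc_violation[i] <- "pa_repeat"
  }
  i <- take(k[["rh_repeat"]])
  if (length(i)) {
    gap <- stats::runif(length(i), 6.5, 10) * height[i]
    r1[i] <- r_mean[i] - gap / 2
    r2[i] <- r_mean[i] + gap / 2
    qc_violation[i] <- "rh_repeat"
  }
  i <- take(k[["xch_repeat"]])
  if (length(i)) {
    gap <- stats::runif(length(i), 6.5, 10) * height[i]
    xc1[i] <- xc_mean[i] - gap / 2
    xc2[i] <- xc_mean[i] + gap / 2
    qc_violation[i] <- "xch_repeat"
  }

  id <- sprintf("S%0*d", nchar(n), seq_len(n))
  cohort <- as_cohort(data.frame(
    subject_id = id, sex = sex, age_y = age, height_m = height,
    weight_kg = weight, r1_ohm = r1, r2_ohm = r2, xc1_ohm = xc1,
    xc2_ohm = xc2, pa1_deg = pa1, pa2_deg = pa2,
    dilution_space_kg = dilution, body_volume_l = bv, bmc_kg = bmc,
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(
    subject_id = id, sex = sex, age_y = age,
    sds_pa = Z[, "pa"], sds_rh = Z[, "rh"], sds_xch = Z[, "xch"],
    sds_bmi = Z[, "bmi"], sds_ffm = Z[, "ffm"], sds_fm = Z[, "fm"],
    sds_hffm = Z[, "hffm"],
    pa = pa, r_h = rh, xc_h = xch, bmi = bmi,
    ffm_kg = ffm, fm_kg = fm, tbw_kg = tbw, h_ffm = hffm,
    weight_kg = weight, height_m = height,
    qc_violation = qc_violation,
    stringsAsFactors = FALSE
  )
  attr(truth, "sds_correlation_pd") <- Cpd
  attr(truth, "seed") <- config$seed
  list(cohort = cohort, truth = truth)
}
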