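# Fixtures are built in code at test time.

# A well-formed cohort data frame with n plausible children.
toy_cohort_df <- function(n = 6, seed = 101) {
  set.seed(seed)
  age <- runif(n, 5, 18)
  height <- 0.9 + 0.045 * age
  r <- 700 - 20 * age + rnorm(n, 0, 10)
  xc <- 70 - 1.5 * age + rnorm(n, 0, 2)
  pa <- 5 + 0.08 * age
  weight <- 16 * height^2
  ffm <- 0.8 * weight
  tbw <- 0.75 * ffm
  data.frame(
    subject_id = sprintf("C%03d", seq_len(n)),
    sex = rep(c("male", "female"), length.out = n),
    age_y = age, height_m = height, weight_kg = weight,
    r1_ohm = r, r2_ohm = r + 1, xc1_ohm = xc, xc2_ohm = xc + 0.5,
    pa1_deg = pa, pa2_deg = pa + 0.05,
    dilution_space_kg = tbw * 1.044, body_volume_l = weight / 1.05,
    bmc_kg = 0.045 * ffm,
    stringsAsFactors = FALSE
  )
}

# Six-record QC fixture: rows 1-3 clean, row 4 implausible PA (duplicates
# 8.2/8.4), row 5 PA repeatability (6.0/6.6, gap 0.6), row 6 R/H
# repeatability (duplicate gap of 7 ohm/m after height adjustment).
qc_fixture_cohort <- function() {
  df <- toy_cohort_df(6)
  df$pa1_deg[4] <- 8.2; df$pa2_deg[4] <- 8.4
  df$pa1_deg[5] <- 6.0; df$pa2_deg[5] <- 6.6
  gap <- 7 * df$height_m[6]
  df$r1_ohm[6] <- 500 - gap / 2; df$r2_ohm[6] <- 500 + gap / 2
  as_cohort(df)
}

write_tmp_cohort <- function(df, ...) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}
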