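# reference values for the Box-Cox z-score used as an independent check
bc_z <- function(value, L, M, S) {
  if (abs(L) < 1e-12) log(value / M) / S
  else ((value / M)^L - 1) / (L * S)
}

# hand-built reference on a two-point grid with constant curves
flat_ref <- function(L, M, S) {
  structure(list(trait = "t", sex = NA_character_, age_grid = c(4, 20),
                 L = c(L, L), M = c(M, M), S = c(S, S), data = NULL),
            class = "lms")
}

test_that("near-constant data collapse to a flat median and minimal complexity", {
  set.seed(21)
  age <- runif(300, 4, 20)
  y <- 50 * exp(0.001 * rnorm(300))
  fit <- lms_fit(y, age)
  expect_equal(unname(fit$edf), c(1, 1, 1))
  expect_equal(fit$M, rep(fit$M[1], length(fit$M)))
  expect_lt(max(abs(fit$M / 50 - 1)), 0.001)
  expect_equal(fit$S[1], sd(log(y)), tolerance = 0.1)
})

test_that("simulated smooth curves are recovered and SDS self-calibrate", {
  set.seed(22)
  n <- 5000
  age <- runif(n, 4, 20)
  Mstar <- function(t) 600 * exp(-0.055 * (t - 4)) + 20
  Sstar <- function(t) 0.08 + 0.002 * (t - 4)
  y <- Mstar(age) * exp(Sstar(age) * rnorm(n))
  fit <- lms_fit(y, age, trait = "r_h")
  interior <- fit$age_grid >= 5 & fit$age_grid <= 19
  expect_lt(max(abs(fit$M[interior] / Mstar(fit$age_grid[interior]) - 1)),
            0.02)
  z <- residuals(fit)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_lt(abs(mean(z < 0) - 0.5), 0.03)
  # fitted S within 15% of truth at interior ages
  expect_lt(max(abs(fit$S[interior] / Sstar(fit$age_grid[interior]) - 1)),
            0.15)
})

test_that("median recovery stays below 2% across replicates", {
  Mstar <- function(t) 22 - 0.9 * t + 0.035 * t^2
  errs <- vapply(1:8, function(rep) {
    set.seed(100 + rep)
    age <- runif(2000, 4, 20)
    y <- Mstar(age) * exp(0.1 * rnorm(2000))
    fit <- lms_fit(y, age, edf = c(M = 4, S = 1, L = 1))
    interior <- fit$age_grid >= 5 & fit$age_grid <= 19
    stats::median(abs(fit$M[interior] / Mstar(fit$age_grid[interior]) - 1))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("a single-entry complexity grid is selected as-is", {
  set.seed(23)
  age <- runif(200, 4, 20)
  y <- (100 - 2 * age) * exp(0.1 * rnorm(200))
  fit <- lms_fit(y, age, edf = c(M = 2, S = 1, L = 1))
  expect_equal(unname(fit$edf), c(2, 1, 1))
  expect_equal(nrow(fit$trace), 1L)
})

test_that("SDS conversion matches the Box-Cox closed form", {
  # the median maps to zero for any L, S
  for (L in c(-1, 0, 0.5, 2))
    expect_equal(to_sds(50, 10, flat_ref(L, 50, 0.1)), 0)
  # linear case L = 1
  expect_equal(to_sds(55, 10, flat_ref(1, 50, 0.10)), 1.0, tolerance = 1e-12)
  # general L against the closed form
  expect_equal(to_sds(63, 12, flat_ref(-0.7, 50, 0.12)),
               bc_z(63, -0.7, 50, 0.12), tolerance = 1e-12)
  # continuity across the L -> 0 limit
  expect_lt(abs(to_sds(55, 10, flat_ref(0.001, 50, 0.1)) -
                  to_sds(55, 10, flat_ref(-0.001, 50, 0.1))), 1e-4)
  expect_error(to_sds(-5, 10, flat_ref(1, 50, 0.1)), "positive")
})

test_that("centile curves invert the SDS transform and never cross", {
  set.seed(24)
  age <- runif(1000, 4, 20)
  y <- (30 + age) * exp((0.1 + 0.003 * age) * rnorm(1000))
  fit <- lms_fit(y, age, edf = c(M = 2, S = 2, L = 2))
  expect_equal(centile_curve(fit, 50), fit$M, tolerance = 1e-12)
  z91 <- to_sds(centile_curve(fit, 91), fit$age_grid, fit)
  expect_equal(z91, rep(qnorm(0.91), length(z91)), tolerance = 1e-8)
  cc <- centile_curve(fit, c(3, 10, 25, 50, 75, 90, 97))
  expect_true(all(diff(t(cc)) > 0))
  expect_error(centile_curve(fit, 0), "percentile")
  expect_error(centile_curve(fit, 100), "percentile")
})

test_that("undefined centile regions flag a gap instead of crashing", {
  ref <- flat_ref(-3, 50, 0.3) # L*S*z_p <= -1 for high percentiles
  expect_warning(v <- predict(ref, age = 10, type = "centile", p = 95),
                 "undefined")
  expect_true(is.na(v))
})

test_that("evaluation refuses extrapolation outside the age support", {
  ref <- flat_ref(1, 50, 0.1)
  expect_error(to_sds(50, 25, ref), "extrapolation")
  expect_error(predict(ref, age = 3, type = "centile", p = 50),
               "extrapolation")
})

test_that("references round-trip through the CSV format", {
  set.seed(25)
  age <- runif(500, 4, 20)
  fits <- list(
    lms_fit((60 - 2 * age) * exp(0.1 * rnorm(500)), age, sex = "male",
            trait = "xch", edf = c(M = 2, S = 1, L = 1)),
    lms_fit((5 + 0.1 * age) * exp(0.05 * rnorm(500)), age, sex = "female",
            trait = "pa", edf = c(M = 2, S = 1, L = 1))
  )
  path <- tempfile(fileext = ".csv")
  write_lms_reference(fits, path)
  back <- read_lms_reference(path)
  expect_length(back, 2)
  ref <- back[["xch.male"]]
  expect_equal(ref$age_grid, fits[[1]]$age_grid, tolerance = 1e-9)
  expect_equal(ref$M, fits[[1]]$M, tolerance = 1e-9)
  expect_equal(ref$L, fits[[1]]$L, tolerance = 1e-9)
  expect_equal(ref$S, fits[[1]]$S, tolerance = 1e-9)
})

test_that("malformed reference tables raise parse errors", {
  df <- data.frame(trait = "t", sex = "male", age_y = c(4, 6, 5),
                   L = 0, M = 50, S = 0.1)
  p <- tempfile(fileext = ".csv"); write.csv(df, p, row.names = FALSE)
  expect_error(read_lms_reference(p), "non-monotone")
  df$age_y <- c(4, 5, 6); df$S <- c(0.1, -0.1, 0.1)
  write.csv(df, p, row.names = FALSE)
  expect_error(read_lms_reference(p), "S <= 0")
  df$S <- 0.1
  write.csv(df[, -3], p, row.names = FALSE)
  expect_error(read_lms_reference(p), "lacks column")
})

test_that("fitting preconditions are enforced", {
  expect_error(lms_fit(rep(50, 10), runif(10, 4, 20)), "at least 50")
  expect_error(lms_fit(c(rep(50, 60), -1), runif(61, 4, 20)), "positive")
})

test_that("simulate() draws values whose SDS are standard normal", {
  set.seed(26)
  age <- runif(2000, 4, 20)
  y <- (600 - 20 * age) * exp(0.1 * rnorm(2000))
  fit <- lms_fit(y, age, edf = c(M = 2, S = 1, L = 1))
  sim <- simulate(fit, nsim = 1, seed = 99)
  z <- to_sds(sim$sim_1, fit$data$age, fit)
  expect_lt(abs(mean(z)), 0.08)
  expect_lt(abs(sd(z) - 1), 0.08)
})
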