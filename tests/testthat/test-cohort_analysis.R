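test_that("category schemes partition every subject by the boundary rule", {
  expect_equal(as.character(categorize(data.frame(ffm_sds = -1.2),
                                       ffm_scheme())), "G1")
  # right-closed intervals: a value exactly on a break joins the lower group
  expect_equal(as.character(categorize(data.frame(hffm_sds = -0.5),
                                       hffm_scheme())), "G2")
  expect_equal(as.character(categorize(data.frame(ffm_sds = 0),
                                       ffm_scheme())), "G2")
  # all values below the first break: one group holds everything
  g <- categorize(rep(-5, 10), ffm_scheme())
  expect_equal(unname(attr(g, "counts")["G1"]), 10L)
  expect_equal(sum(attr(g, "counts")), 10L)
  # random fixtures always partition
  set.seed(41)
  for (k in 1:5) {
    v <- rnorm(200)
    g <- categorize(v, ffm_scheme())
    expect_equal(sum(attr(g, "counts")), 200L)
    expect_false(anyNA(g))
  }
})

test_that("scheme construction validates breaks and labels", {
  expect_error(category_scheme("x", c(1, 0)), "diff")
  expect_error(category_scheme("x", c(0, 1), labels = c("a", "b")), "labels")
  s <- category_scheme("x", c(-1, 1), labels = c("low", "mid", "high"))
  expect_equal(as.character(categorize(c(-2, 0, 2), s)),
               c("low", "mid", "high"))
})

test_that("correlation matrices are symmetric with exact structural entries", {
  set.seed(42)
  df <- data.frame(a = rnorm(100))
  df$b <- 2 * df$a
  df$c <- rnorm(100)
  cm <- correlation_matrix(df)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 1.0, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$p, t(cm$p))
  # p-values agree with cor.test
  ct <- cor.test(df$a, df$c)
  expect_equal(cm$p["a", "c"], ct$p.value, tolerance = 1e-10)
})

test_that("correlation matrices flag undefined entries and honour subgroups", {
  df <- data.frame(a = rnorm(50), b = rep(1, 50))
  cm <- correlation_matrix(df)
  expect_true(is.na(cm$r["a", "b"]))
  expect_equal(cm$undefined["a", "b"], "zero variance")
  set.seed(43)
  df2 <- data.frame(a = rnorm(200), g = rep(1:2, each = 100))
  df2$b <- ifelse(df2$g == 1, df2$a, -df2$a)
  cm1 <- correlation_matrix(df2, columns = c("a", "b"), subgroup = df2$g == 1)
  expect_equal(cm1$r["a", "b"], 1.0, tolerance = 1e-12)
  expect_equal(cm1$n["a", "b"], 100L)
})

test_that("a generated correlation is recovered from a large sample", {
  set.seed(44)
  n <- 50000
  z1 <- rnorm(n); z2 <- rnorm(n)
  df <- data.frame(x = z1, y = 0.73 * z1 + sqrt(1 - 0.73^2) * z2)
  cm <- correlation_matrix(df)
  expect_equal(cm$r["x", "y"], 0.73, tolerance = 0.015)
})

test_that("regression on standardised columns matches the normal equations", {
  set.seed(45)
  n <- 10
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  y <- X %*% c(0.5, -0.8, 0.3) + rnorm(n, 0, 0.1)
  df <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3])
  fit <- sds_regression(df, "y", c("x1", "x2"))
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(fit$terms$estimate, drop(beta), tolerance = 1e-10)
  # r2 equals 1 - SSE/SST computed independently
  sse <- sum((y - X %*% beta)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(fit$r2, 1 - sse / sst, tolerance = 1e-10)
})

test_that("standardised simple regression returns the Pearson correlation", {
  set.seed(46)
  a <- as.numeric(scale(rnorm(80)))
  b <- as.numeric(scale(0.6 * a + rnorm(80)))
  df <- data.frame(a = a, b = b)
  fit <- sds_regression(df, "b", "a")
  expect_equal(fit$terms$estimate[2], cor(a, b), tolerance = 1e-12)
})

test_that("orthogonal predictors keep their marginal correlations as coefficients", {
  set.seed(47)
  x1 <- as.numeric(scale(rnorm(100)))
  x2 <- as.numeric(scale(residuals(lm(rnorm(100) ~ x1))))
  y <- as.numeric(scale(0.5 * x1 - 0.3 * x2 + rnorm(100, 0, 0.5)))
  df <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- sds_regression(df, "y", c("x1", "x2"))
  expect_equal(fit$terms$estimate[2], cor(y, x1), tolerance = 1e-10)
  expect_equal(fit$terms$estimate[3], cor(y, x2), tolerance = 1e-10)
})

test_that("collinear designs raise an informative error", {
  df <- data.frame(y = rnorm(20), x1 = 1:20)
  df$x2 <- 2 * df$x1
  expect_error(sds_regression(df, "y", c("x1", "x2")), "collinear")
})

test_that("group contrasts cover all pairs with Bonferroni adjustment", {
  set.seed(48)
  df <- data.frame(y = rnorm(200), g = rep(paste0("G", 1:5), each = 40))
  ct <- group_contrasts(df, "y", "g")
  expect_equal(nrow(ct), choose(5, 2))
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-15))
  expect_true(all(ct$p_adj <= 1))
  # identical groups: zero difference, p = 1
  df2 <- data.frame(y = rep(rnorm(20), 2), g = rep(c("a", "b"), each = 20))
  ct2 <- group_contrasts(df2, "y", "g")
  expect_equal(ct2$mean_diff, 0)
  expect_equal(ct2$p_adj, 1)
  expect_false(ct2$significant)
})

test_that("singleton groups are flagged undefined, not dropped", {
  df <- data.frame(y = c(rnorm(10), 5), g = c(rep("a", 10), "b"))
  ct <- group_contrasts(df, "y", "g")
  expect_true(ct$undefined)
  expect_true(is.na(ct$p_raw))
})

test_that("a 2 SD shifted group is detected and null groups stay quiet", {
  set.seed(49)
  flagged_shift <- 0; false_flags <- 0; null_pairs <- 0
  for (rep in 1:10) {
    df <- data.frame(
      y = c(rnorm(40, 2), rnorm(40), rnorm(40), rnorm(40)),
      g = rep(paste0("G", 1:4), each = 40))
    ct <- group_contrasts(df, "y", "g")
    shift <- ct$group1 == "G1" | ct$group2 == "G1"
    flagged_shift <- flagged_shift + sum(ct$significant[shift])
    false_flags <- false_flags + sum(ct$significant[!shift])
    null_pairs <- null_pairs + sum(!shift)
  }
  expect_equal(flagged_shift, 30) # every contrast against the shifted group
  expect_lte(false_flags / null_pairs, 0.05)
})

test_that("slope heterogeneity finds a divergent slope and respects nesting", {
  set.seed(50)
  hits <- 0
  for (rep in 1:8) {
    x <- rnorm(180)
    g <- factor(rep(c("ref", "same", "diff"), each = 60),
                levels = c("ref", "same", "diff"))
    slope <- ifelse(g == "diff", 0.8, 0.3)
    df <- data.frame(y = slope * x + rnorm(180, 0, 0.3), x = x, g = g)
    fit <- slope_heterogeneity(df, "y", "x", "g")
    pv <- fit$terms$p_value[fit$terms$term == "x:gsame"]
    hits <- hits + (fit$terms$p_value[fit$terms$term == "x:gdiff"] < 0.05)
  }
  expect_gte(hits, 7)

  # no group structure: model r2 matches the simple fit's r2
  set.seed(51)
  x <- rnorm(300)
  df <- data.frame(y = 0.87 * x + rnorm(300, 0, 0.5), x = x,
                   g = sample(c("a", "b", "c"), 300, replace = TRUE))
  fit <- slope_heterogeneity(df, "y", "x", "g")
  simple <- summary(lm(y ~ x, data = df))$r.squared
  expect_equal(fit$r2, simple, tolerance = 0.02)
})

test_that("null groups produce no excess dummy/interaction significance", {
  set.seed(52)
  n_sig <- 0; n_terms <- 0
  for (rep in 1:15) {
    x <- rnorm(240)
    df <- data.frame(y = 0.8 * x + rnorm(240, 0, 0.5), x = x,
                     g = rep(paste0("G", 1:4), each = 60))
    fit <- slope_heterogeneity(df, "y", "x", "g")
    tt <- fit$terms[grepl("^g|^x:g", fit$terms$term), ]
    n_sig <- n_sig + sum(tt$p_value < 0.05)
    n_terms <- n_terms + nrow(tt)
  }
  expect_lte(n_sig / n_terms, 0.10)
})

test_that("tiny groups are excluded from the interaction model and noted", {
  set.seed(53)
  df <- data.frame(y = rnorm(63), x = rnorm(63),
                   g = c(rep("a", 30), rep("b", 31), rep("tiny", 2)))
  fit <- slope_heterogeneity(df, "y", "x", "g")
  expect_equal(fit$excluded_groups, "tiny")
  expect_equal(fit$n, 61)
})
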