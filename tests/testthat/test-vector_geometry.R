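# independent brute-force evaluation of the two-sample T2 closed form
brute_t2 <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  ma <- colSums(A) / n1; mb <- colSums(B) / n2
  ca <- matrix(0, 2, 2); cb <- matrix(0, 2, 2)
  for (i in seq_len(n1)) ca <- ca + tcrossprod(A[i, ] - ma)
  for (i in seq_len(n2)) cb <- cb + tcrossprod(B[i, ] - mb)
  sp <- (ca + cb) / (n1 + n2 - 2)
  d <- ma - mb
  drop(n1 * n2 / (n1 + n2) * t(d) %*% solve(sp) %*% d)
}

test_that("an isotropic sample gives a circle with canonical orientation", {
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- confidence_ellipse(pts, 0.95)
  expect_equal(e$semi_major, e$semi_minor, tolerance = 1e-12)
  expect_equal(e$orientation, 0)
  expect_equal(unname(e$center), c(0, 0))
})

test_that("ellipse area grows with level and tolerance dwarfs confidence", {
  set.seed(31)
  x <- matrix(rnorm(400), ncol = 2)
  expect_lt(ellipse_area(confidence_ellipse(x, 0.50)),
            ellipse_area(confidence_ellipse(x, 0.95)))
  expect_lt(ellipse_area(tolerance_ellipse(x, 0.50)),
            ellipse_area(tolerance_ellipse(x, 0.95)))
  expect_gt(ellipse_area(tolerance_ellipse(x, 0.95)),
            10 * ellipse_area(confidence_ellipse(x, 0.95)))
})

test_that("confidence ellipse area shrinks roughly as 1/n", {
  set.seed(32)
  big <- matrix(rnorm(4000), ncol = 2)
  a_small <- ellipse_area(confidence_ellipse(big[1:100, ], 0.95))
  a_big <- ellipse_area(confidence_ellipse(big, 0.95))
  expect_lt(a_big, a_small)
})

test_that("strong correlation with equal variances orients the axis at 45 degrees", {
  set.seed(33)
  n <- 20000
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- cbind(z1, 0.9 * z1 + sqrt(1 - 0.9^2) * z2)
  e <- tolerance_ellipse(x, 0.95)
  expect_lt(abs(e$orientation - 45), 1.5)
  expect_gt(e$semi_major, e$semi_minor)
})

test_that("ellipse membership matches the Mahalanobis inequality", {
  set.seed(34)
  x <- matrix(rnorm(200, sd = 2), ncol = 2)
  e <- tolerance_ellipse(x, 0.5)
  expect_true(ellipse_contains(e, matrix(e$center, ncol = 2)))
  expect_false(ellipse_contains(e, matrix(c(100, 100), ncol = 2)))
  # boundary points are on the ellipse
  b <- ellipse_boundary(e)
  expect_true(all(ellipse_contains(e, b)))
  expect_true(all(!ellipse_contains(e, sweep(sweep(b, 2, e$center), 1, 1.01,
                                             "*") + rep(e$center, each = nrow(b)))))
})

test_that("degenerate covariance raises a geometry error", {
  x <- cbind(1:10, 2 * (1:10))
  expect_error(confidence_ellipse(x), "singular")
  expect_error(hotelling_test(x, x + 1), "singular")
})

test_that("identical groups give T2 = 0 and p = 1", {
  set.seed(35)
  A <- matrix(rnorm(40), ncol = 2)
  h <- hotelling_test(A, A)
  expect_equal(unname(h$statistic), 0, tolerance = 1e-12)
  expect_equal(h$p.value, 1)
})

test_that("T2 on the toy fixture equals a brute-force evaluation", {
  A <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 1))
  B <- rbind(c(5, 5), c(6, 7), c(7, 6), c(6, 6))
  h <- hotelling_test(A, B)
  expect_equal(unname(h$statistic), brute_t2(A, B), tolerance = 1e-10)
  p <- 2; n1 <- 4; n2 <- 4
  f_hand <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * brute_t2(A, B)
  expect_equal(unname(h$parameter[["F"]]), f_hand, tolerance = 1e-10)
  expect_equal(h$p.value, pf(f_hand, 2, 5, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("T2 is invariant under common full-rank affine transformations", {
  set.seed(36)
  A <- matrix(rnorm(60), ncol = 2)
  B <- matrix(rnorm(80, mean = 0.5), ncol = 2)
  t2_0 <- unname(hotelling_test(A, B)$statistic)
  for (k in 1:3) {
    Mx <- matrix(rnorm(4, sd = 2), 2, 2)
    while (abs(det(Mx)) < 0.1) Mx <- matrix(rnorm(4, sd = 2), 2, 2)
    b <- rnorm(2)
    t2_k <- unname(hotelling_test(sweep(A %*% Mx, 2, b, "+"),
                                  sweep(B %*% Mx, 2, b, "+"))$statistic)
    expect_equal(t2_k, t2_0, tolerance = 1e-8)
  }
})

test_that("in a 1-D embedding T2 collapses to the squared t statistic", {
  set.seed(37)
  a <- rnorm(25); b <- rnorm(30, 0.8)
  # second coordinate: tiny jitter with its group-mean difference removed, so
  # only the first coordinate carries signal
  ja <- rnorm(25, 0, 1e-6); jb <- rnorm(30, 0, 1e-6)
  A <- cbind(a, 1 + ja - mean(ja))
  B <- cbind(b, 1 + jb - mean(jb))
  t2 <- unname(hotelling_test(A, B)$statistic)
  t_sq <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
  expect_equal(t2, t_sq, tolerance = 0.05)
  expect_gte(t2, t_sq * (1 - 1e-9))
})

test_that("rxc_plot validates input and returns a deterministic payload", {
  expect_error(rxc_plot(list()), "non-empty")
  set.seed(38)
  groups <- lapply(setNames(1:5, paste0("G", 1:5)), function(i)
    matrix(rnorm(60, mean = i), ncol = 2))
  f <- tempfile(fileext = ".pdf")
  pdf(f)
  s1 <- rxc_plot(groups, level = 0.95)
  s2 <- rxc_plot(groups, level = 0.95)
  dev.off()
  expect_length(s1, 5)
  expect_identical(s1, s2)
  expect_s3_class(s1[[1]], "biva_ellipse")
})
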