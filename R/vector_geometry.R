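# Bivariate statistics on the RXc plane (R/H on x, Xc/H on y), in raw ohm/m
# or SDS units. Exact small-sample F-based ellipse scalings are used, suited
# to group sizes of a few dozen; the large-sample chi-square variant is
# available behind `scaling = "chisq"` for cross-checks with other BIVA
# software.

.ellipse_spec <- function(center, cov, scale2, level, kind, n) {
  eg <- eigen(cov, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop("degenerate geometry: sample covariance is singular")
  ax <- sqrt(eg$values * scale2)
  v <- eg$vectors[, 1]
  orient <- if (abs(eg$values[1] - eg$values[2]) < 1e-12 * eg$values[1]) 0
  else (atan2(v[2], v[1]) * 180 / pi) %% 180
  structure(list(center = center, semi_major = ax[1], semi_minor = ax[2],
                 orientation = orient, level = level, kind = kind, n = n,
                 cov = cov, scale2 = scale2),
            class = "biva_ellipse")
}

.check_biv <- function(x, min_n = 4) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("a bivariate sample (two columns) is required")
  if (anyNA(x)) stop("missing values in bivariate sample")
  if (nrow(x) < min_n) stop("at least ", min_n, " points are required")
  x
}

#' Confidence ellipse for a bivariate mean vector
#'
#' Ellipse containing the group's true mean vector with the stated
#' probability: axes along the sample-covariance eigenvectors with semi-axis
#' lengths `sqrt(lambda_i * p(n-1)/(n(n-p)) * F_{p,n-p}(level))`, `p = 2`.
#'
#' @param x Two-column matrix or data frame (e.g. R/H, Xc/H).
#' @param level Coverage probability in (0, 1).
#' @param scaling `"f"` (exact small-sample, default) or `"chisq"`
#'   (large-sample approximation).
#' @return A `biva_ellipse`: `center`, `semi_major`, `semi_minor` (axis
#'   units), `orientation` (degrees in \[0, 180), 0 for the circular tie),
#'   `level`, `kind`, `n`.
#' @examples
#' set.seed(1)
#' confidence_ellipse(matrix(rnorm(100), ncol = 2))
#' @export
confidence_ellipse <- function(x, level = 0.95, scaling = c("f", "chisq")) {
  scaling <- match.arg(scaling)
  x <- .check_biv(x)
  stopifnot(level > 0, level < 1)
  n <- nrow(x); p <- 2
  s2 <- if (scaling == "f")
    p * (n - 1) / (n * (n - p)) * stats::qf(level, p, n - p)
  else stats::qchisq(level, p) / n
  .ellipse_spec(colMeans(x), stats::cov(x), s2, level, "confidence", n)
}

#' Tolerance ellipse for bivariate individuals
#'
#' Ellipse expected to contain the stated fraction of individual vectors:
#' semi-axes `sqrt(lambda_i * p(n^2-1)/(n(n-p)) * F_{p,n-p}(level))`. On
#' large normal samples it contains approximately `level` of the points.
#'
#' @inheritParams confidence_ellipse
#' @return A `biva_ellipse` with `kind = "tolerance"`.
#' @export
tolerance_ellipse <- function(x, level = 0.95, scaling = c("f", "chisq")) {
  scaling <- match.arg(scaling)
  x <- .check_biv(x)
  stopifnot(level > 0, level < 1)
  n <- nrow(x); p <- 2
  s2 <- if (scaling == "f")
    p * (n^2 - 1) / (n * (n - p)) * stats::qf(level, p, n - p)
  else stats::qchisq(level, p)
  .ellipse_spec(colMeans(x), stats::cov(x), s2, level, "tolerance", n)
}

#' Area of an ellipse
#'
#' @param e A `biva_ellipse`.
#' @return `pi * semi_major * semi_minor`.
#' @export
ellipse_area <- function(e) {
  stopifnot(inherits(e, "biva_ellipse"))
  pi * e$semi_major * e$semi_minor
}

#' Point membership in an ellipse
#'
#' @param e A `biva_ellipse`.
#' @param points Two-column matrix of points.
#' @return Logical vector: `TRUE` where the point lies inside or on `e`.
#' @export
ellipse_contains <- function(e, points) {
  stopifnot(inherits(e, "biva_ellipse"))
  pts <- matrix(as.matrix(points), ncol = 2)
  d <- sweep(pts, 2, e$center)
  q <- rowSums((d %*% solve(e$cov)) * d)
  q <= e$scale2 * (1 + 1e-12)
}

#' Boundary coordinates of an ellipse
#'
#' @param e A `biva_ellipse`.
#' @param n_points Number of boundary points.
#' @return Two-column matrix tracing the boundary (closed).
#' @export
ellipse_boundary <- function(e, n_points = 181) {
  stopifnot(inherits(e, "biva_ellipse"))
  th <- seq(0, 2 * pi, length.out = n_points)
  a <- e$orientation * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- cbind(e$semi_major * cos(th), e$semi_minor * sin(th)) %*% t(rot)
  sweep(xy, 2, e$center, "+")
}

#' @export
print.biva_ellipse <- function(x, ...) {
  cat(sprintf(
    "%d%% %s ellipse (n = %d)\n  center (%.3f, %.3f); semi-axes %.3f x %.3f; orientation %.1f deg\n",
    round(100 * x$level), x$kind, x$n, x$center[1], x$center[2],
    x$semi_major, x$semi_minor, x$orientation))
  invisible(x)
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares two independent bivariate mean vectors with pooled covariance:
#' `T2 = (n1 n2/(n1+n2)) d' S_pooled^-1 d` with `d` the mean difference,
#' transformed to `F = ((n1+n2-p-1)/(p(n1+n2-2))) T2` on
#' `(p, n1+n2-p-1)` degrees of freedom, `p = 2`. The statistic is invariant
#' under any common full-rank affine transformation of both samples.
#'
#' @param x,y Two-column matrices (the two groups), `n >= 3` each.
#' @return An object of classes `hotelling_test` and `htest` with `statistic`
#'   (`T2`), `parameter` (`F`, `df1`, `df2`), `p.value` and `estimate` (the
#'   bivariate mean difference `x - y`).
#' @examples
#' set.seed(1)
#' hotelling_test(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 1), ncol = 2))
#' @export
hotelling_test <- function(x, y) {
  x <- .check_biv(x, min_n = 3)
  y <- .check_biv(y, min_n = 3)
  n1 <- nrow(x); n2 <- nrow(y); p <- 2
  d <- colMeans(x) - colMeans(y)
  sp <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n1 + n2 - 2)
  si <- tryCatch(solve(sp), error = function(e)
    stop("degenerate geometry: pooled covariance is singular"))
  t2 <- as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% si %*% d)
  df2 <- n1 + n2 - p - 1
  f <- df2 / (p * (n1 + n2 - 2)) * t2
  pv <- stats::pf(f, p, df2, lower.tail = FALSE)
  structure(list(
    statistic = c(T2 = t2),
    parameter = c(F = f, df1 = p, df2 = df2),
    p.value = pv,
    estimate = c(d1 = d[1], d2 = d[2]),
    method = "Two-sample Hotelling's T-squared test",
    data.name = sprintf("two bivariate samples (n = %d, %d)", n1, n2),
    alternative = "two-sided"
  ), class = c("hotelling_test", "htest"))
}

#' Plot groups and their ellipses on the RXc plane
#'
#' Draws group mean markers and confidence or tolerance ellipses over the
#' R/H--Xc/H plane, in raw ohm/m or SDS units. Output is deterministic given
#' the inputs.
#'
#' @param groups Named list of two-column matrices, one per group. Must be
#'   non-empty and share `axes_mode`.
#' @param level Ellipse level(s); for `kind = "tolerance"` the BIVA
#'   convention is `c(0.5, 0.75, 0.95)`.
#' @param kind `"confidence"` (group means) or `"tolerance"` (individuals).
#' @param axes_mode `"raw"` (ohm/m axis labels) or `"sds"`.
#' @param col Colours, recycled over groups.
#' @param points Overlay the individual points.
#' @param main Title.
#' @return Invisibly, a named list of the `biva_ellipse` objects drawn
#'   (`<group>@<level>`).
#' @export
rxc_plot <- function(groups, level = 0.95, kind = c("confidence", "tolerance"),
                     axes_mode = c("raw", "sds"), col = NULL, points = FALSE,
                     main = NULL) {
  kind <- match.arg(kind)
  axes_mode <- match.arg(axes_mode)
  if (!is.list(groups) || length(groups) == 0)
    stop("'groups' must be a non-empty named list of bivariate samples")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("every group needs a name")
  maker <- if (kind == "confidence") confidence_ellipse else tolerance_ellipse
  specs <- list()
  for (g in names(groups)) for (lv in level)
    specs[[sprintf("%s@%g", g, lv)]] <- maker(groups[[g]], lv)
  if (is.null(col)) col <- grDevices::hcl.colors(length(groups), "Dark 3")
  col <- rep_len(col, length(groups))

  bounds <- lapply(specs, ellipse_boundary)
  all_xy <- do.call(rbind, c(bounds, lapply(groups, as.matrix)))
  labs <- if (axes_mode == "raw")
    c("R/H (ohm/m)", "Xc/H (ohm/m)") else c("R/H-SDS", "Xc/H-SDS")
  graphics::plot(range(all_xy[, 1]), range(all_xy[, 2]), type = "n",
                 xlab = labs[1], ylab = labs[2],
                 main = if (is.null(main))
                   sprintf("%d%% %s ellipses", round(100 * level[1]), kind)
                 else main)
  for (i in seq_along(groups)) {
    g <- names(groups)[i]
    if (points)
      graphics::points(groups[[g]], pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor(col[i], 0.3))
    for (lv in level) {
      sp <- specs[[sprintf("%s@%g", g, lv)]]
      graphics::lines(ellipse_boundary(sp), col = col[i])
      graphics::points(sp$center[1], sp$center[2], pch = 3, col = col[i])
    }
  }
  graphics::legend("topright", legend = names(groups), col = col, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(specs)
}
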