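# Cohort-level statistical surface on SDS data: category construction,
# correlation matrices (whole cohort or subgroups), multiple regression on
# SDS columns (already standardised by construction, so coefficients are on
# the SDS scale), pairwise group contrasts with Bonferroni correction, and a
# dummy-variable/interaction test of slope heterogeneity.

#' Category scheme over an SDS column
#'
#' Defines ordered groups by cut points, e.g. the five fat-free-mass SDS
#' bands `< -1, -1 to 0, 0 to 0.75, 0.75 to 1.5, > 1.5`. Intervals are
#' left-open/right-closed (`(a, b]`) by default (`right = TRUE`), with the
#' outermost intervals open-ended; a value exactly on a break is assigned by
#' this rule, never dropped.
#'
#' @param variable SDS column name the scheme applies to.
#' @param breaks Strictly increasing cut points.
#' @param labels Group labels, `length(breaks) + 1` of them (default
#'   `"G1"..`).
#' @param right Do intervals close on the right?
#' @return A `category_scheme` object.
#' @export
category_scheme <- function(variable, breaks, labels = NULL, right = TRUE) {
  stopifnot(is.character(variable), length(variable) == 1,
            all(diff(breaks) > 0))
  if (is.null(labels)) labels <- paste0("G", seq_len(length(breaks) + 1))
  stopifnot(length(labels) == length(breaks) + 1)
  structure(list(variable = variable, breaks = breaks, labels = labels,
                 right = right),
            class = "category_scheme")
}

#' Published category schemes for fat-free mass and hydration SDS
#'
#' The five-group schemes over FFM-SDS (cuts -1, 0, 0.75, 1.5) and
#' H_FFM-SDS (cuts -1, -0.5, 0, 1), chosen so that each group keeps a sample
#' size above roughly forty in a cohort of ~290 while spanning the trait's
#' range evenly.
#'
#' @return A `category_scheme`.
#' @export
ffm_scheme <- function() category_scheme("ffm_sds", c(-1, 0, 0.75, 1.5))

#' @rdname ffm_scheme
#' @export
hffm_scheme <- function() category_scheme("hffm_sds", c(-1, -0.5, 0, 1))

#' Assign subjects to categories
#'
#' @param x Data frame holding the scheme's variable (an SDS table), or a
#'   numeric vector.
#' @param scheme A [category_scheme()].
#' @return Ordered factor of group labels with a `"counts"` attribute
#'   (per-group counts, summing to the number of non-missing values).
#' @examples
#' categorize(data.frame(ffm_sds = c(-1.2, 0.3, 2)), ffm_scheme())
#' @export
categorize <- function(x, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  v <- if (is.data.frame(x)) {
    if (!scheme$variable %in% names(x))
      stop("column '", scheme$variable, "' not found")
    x[[scheme$variable]]
  } else as.numeric(x)
  g <- cut(v, breaks = c(-Inf, scheme$breaks, Inf), labels = scheme$labels,
           right = scheme$right, ordered_result = TRUE)
  structure(g, counts = table(g))
}

#' Pearson correlation matrix with pairwise p-values
#'
#' Whole-cohort or subgroup correlation matrix over SDS columns, with
#' two-sided p-values from the t transform of r. Pairs with fewer than three
#' complete rows or a zero-variance column are flagged (`NA` plus an entry in
#' `$undefined`), never silently dropped.
#'
#' @param x Data frame (e.g. an SDS table).
#' @param columns Columns to correlate (default: all numeric).
#' @param subgroup Optional logical row filter (e.g. an age band).
#' @return A `biva_corr` object: list with symmetric matrices `r` and
#'   `p`, pairwise-complete counts `n`, and `undefined` (character matrix of
#'   flags).
#' @export
correlation_matrix <- function(x, columns = NULL, subgroup = NULL) {
  df <- as.data.frame(x)
  if (!is.null(subgroup)) df <- df[which(subgroup), , drop = FALSE]
  if (is.null(columns))
    columns <- names(df)[vapply(df, is.numeric, TRUE)]
  df <- df[, columns, drop = FALSE]
  k <- length(columns)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  nmat <- matrix(0L, k, k, dimnames = list(columns, columns))
  undef <- matrix("", k, k, dimnames = list(columns, columns))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(i)) {
    cc <- stats::complete.cases(df[[i]], df[[j]])
    nmat[i, j] <- nmat[j, i] <- sum(cc)
    if (i == j) next
    if (sum(cc) < 3) { undef[i, j] <- undef[j, i] <- "n < 3"; next }
    xi <- df[[i]][cc]; xj <- df[[j]][cc]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      undef[i, j] <- undef[j, i] <- "zero variance"; next
    }
    rij <- stats::cor(xi, xj)
    r[i, j] <- r[j, i] <- rij
    n <- sum(cc)
    tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, p = p, n = nmat, undefined = undef),
            class = "biva_corr")
}

#' @export
print.biva_corr <- function(x, digits = 2, ...) {
  cat("Pearson correlations (pairwise complete):\n")
  print(round(x$r, digits))
  if (any(nzchar(x$undefined)))
    cat("undefined entries flagged:",
        sum(nzchar(x$undefined[upper.tri(x$undefined)])), "\n")
  invisible(x)
}

#' Multiple regression on SDS columns
#'
#' Ordinary least squares of one SDS outcome on SDS predictors, used as-is
#' (they are standardised by construction, so coefficients are on the SDS
#' scale). Rows with missing values in any used column are excluded
#' (row-complete per analysis).
#'
#' @param x Data frame.
#' @param outcome Outcome column name.
#' @param predictors Predictor column names.
#' @return A `sds_regression` object: `terms` data frame (term, estimate,
#'   std_error, p_value), `r2`, `n`, `outcome`, and the underlying `lm` fit.
#' @export
sds_regression <- function(x, outcome, predictors) {
  df <- as.data.frame(x)[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(predictors) + 1)
    stop("too few complete rows for the requested model")
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(predictors) + 1) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear predictors (rank-deficient design): ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    outcome = outcome,
    terms = data.frame(term = rownames(co), estimate = co[, 1],
                       std_error = co[, 2], p_value = co[, 4],
                       row.names = NULL, stringsAsFactors = FALSE),
    r2 = sm$r.squared, n = nrow(df), fit = fit
  ), class = "sds_regression")
}

#' @export
print.sds_regression <- function(x, ...) {
  cat(sprintf("Regression of %s (n = %d, r2 = %.3f)\n", x$outcome, x$n, x$r2))
  print(transform(x$terms, estimate = round(estimate, 3),
                  std_error = round(std_error, 3),
                  p_value = signif(p_value, 2)), row.names = FALSE)
  invisible(x)
}

#' Pairwise group contrasts with Bonferroni correction
#'
#' All pairwise two-sample t contrasts of group means of one outcome, with
#' Bonferroni adjustment over the number of pairs (`p_adj = min(1, p *
#' n_pairs)`) and a significance flag at `alpha`. Pairs involving a singleton
#' group are reported with an undefined p-value and flagged, not dropped.
#'
#' @param x Data frame.
#' @param outcome Outcome column name.
#' @param groups Factor (or column name in `x`) of group labels.
#' @param pooled_variance Use the pooled-variance t-test (default, matching
#'   ANOVA-style contrasts); `FALSE` gives Welch.
#' @param alpha Significance level for the flag.
#' @return Data frame: `group1`, `group2`, `mean_diff`, `p_raw`, `p_adj`,
#'   `significant`, `undefined`.
#' @export
group_contrasts <- function(x, outcome, groups, pooled_variance = TRUE,
                            alpha = 0.05) {
  df <- as.data.frame(x)
  g <- if (is.character(groups) && length(groups) == 1) df[[groups]]
  else groups
  y <- df[[outcome]]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(factor(g[keep]))
  lev <- levels(g)
  if (length(lev) < 2) stop("at least two groups are required")
  pairs <- utils::combn(lev, 2)
  np <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    mean_diff = NA_real_, p_raw = NA_real_,
                    p_adj = NA_real_, significant = NA,
                    undefined = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(np)) {
    a <- y[g == pairs[1, k]]; b <- y[g == pairs[2, k]]
    out$mean_diff[k] <- mean(a) - mean(b)
    if (length(a) < 2 || length(b) < 2) { out$undefined[k] <- TRUE; next }
    tt <- stats::t.test(a, b, var.equal = pooled_variance)
    out$p_raw[k] <- tt$p.value
  }
  out$p_adj <- pmin(1, out$p_raw * np)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Slope heterogeneity across groups (dummy + interaction regression)
#'
#' Fits `y ~ x + group + x:group` with the first group level as reference, to
#' test whether the x--y relationship (e.g. Xc/H on R/H) differs across
#' categories: dummy terms test level shifts, interaction terms test slope
#' differences. Groups with fewer than 3 members are excluded from the fit
#' and listed in `$excluded_groups`.
#'
#' @param x Data frame.
#' @param y_col,x_col Outcome and predictor column names.
#' @param groups Factor (or column name) of group labels; the first level is
#'   the reference.
#' @return A `sds_regression` object with extra fields `reference` and
#'   `excluded_groups`.
#' @export
slope_heterogeneity <- function(x, y_col, x_col, groups) {
  df <- as.data.frame(x)
  g <- if (is.character(groups) && length(groups) == 1) df[[groups]]
  else groups
  dat <- data.frame(y = df[[y_col]], x = df[[x_col]], g = factor(g))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  cnt <- table(dat$g)
  small <- names(cnt)[cnt < 3]
  if (length(small)) dat <- dat[!dat$g %in% small, , drop = FALSE]
  dat$g <- droplevels(dat$g)
  if (nlevels(dat$g) < 2)
    stop("fewer than two usable groups for the interaction model")
  fit <- stats::lm(y ~ x * g, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    outcome = y_col,
    terms = data.frame(term = rownames(co), estimate = co[, 1],
                       std_error = co[, 2], p_value = co[, 4],
                       row.names = NULL, stringsAsFactors = FALSE),
    r2 = sm$r.squared, n = nrow(dat), fit = fit,
    reference = levels(dat$g)[1], excluded_groups = small
  ), class = "sds_regression")
}
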