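# LMS (Box-Cox) age-conditional reference fitting.
#
# Model: at age t, a positive trait y follows
#   z = ((y/M(t))^L(t) - 1) / (L(t) S(t)),  z ~ N(0,1)
# (log form in the L -> 0 limit), with L, M, S smooth in age. Fitting is
# penalised maximum likelihood via Fisher-scoring backfitting: each curve is
# updated by smoothing its working residual (score / expected information)
# against age at fixed effective degrees of freedom (edf), with step-halving
# on the deviance. Curve complexity is chosen greedily (M, then S, then L),
# accepting one extra edf only if it reduces the deviance by more than ln(N).

.lms_loglik <- function(y, u, m, s, lam) {
  S <- exp(s)
  z <- ifelse(lam == 0, u / S, expm1(lam * u) / (lam * S))
  sum(-0.5 * z^2 - 0.5 * log(2 * pi) + (lam - 1) * log(y) - lam * m - s)
}

# One weighted smooth at fixed edf. edf 1 = constant, 2 = linear, >2 = cubic
# smoothing spline. Returns fitted values at x and a predictor function.
.fit_curve <- function(x, target, w, edf) {
  if (edf <= 1) {
    v <- sum(w * target) / sum(w)
    list(fit = rep(v, length(x)), predict = function(xx) rep(v, length(xx)))
  } else if (edf <= 2) {
    fit <- stats::lm.wfit(cbind(1, x), target, w)
    b <- fit$coefficients
    list(fit = b[1] + b[2] * x, predict = function(xx) b[1] + b[2] * xx)
  } else {
    sp <- stats::smooth.spline(x, target, w = w, df = edf)
    list(fit = stats::predict(sp, x)$y,
         predict = function(xx) stats::predict(sp, xx)$y)
  }
}

# Penalised-likelihood backfitting at fixed edf = c(M, S, L).
.lms_engine <- function(y, age, edf, maxit = 50, tol = 1e-3) {
  n <- length(y)
  ly <- log(y)

  cm <- .fit_curve(age, ly, rep(1, n), edf[["M"]])
  m <- cm$fit
  s0 <- log(max(stats::sd(ly - m), 1e-6))
  cs <- list(fit = rep(s0, n), predict = function(xx) rep(s0, length(xx)))
  s <- cs$fit
  cl <- list(fit = rep(1, n), predict = function(xx) rep(1, length(xx)))
  lam <- cl$fit

  dev <- -2 * .lms_loglik(y, ly - m, m, s, lam)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

  # propose a new curve, step-halve if the deviance worsens
  try_update <- function(which, target, w, edf1) {
    old <- switch(which, m = cm, s = cs, l = cl)
    lim <- switch(which, m = c(-Inf, Inf), s = c(log(1e-5), log(2)),
                  l = c(-4, 4))
    new <- .fit_curve(age, target, w, edf1)
    step <- 1
    for (k in 1:6) {
      damped <- local({
        op <- old$predict; np <- new$predict; st <- step
        lo <- lim[1]; hi <- lim[2]
        fn <- function(xx) clamp(op(xx) + st * (np(xx) - op(xx)), lo, hi)
        list(fit = fn(age), predict = fn)
      })
      fit <- damped$fit
      cand_m <- if (which == "m") fit else m
      cand_s <- if (which == "s") fit else s
      cand_l <- if (which == "l") fit else lam
      d <- -2 * .lms_loglik(y, ly - cand_m, cand_m, cand_s, cand_l)
      if (is.finite(d) && d <= dev + 1e-9) {
        if (which == "m") { m <<- fit; cm <<- damped }
        if (which == "s") { s <<- fit; cs <<- damped }
        if (which == "l") { lam <<- fit; cl <<- damped }
        dev <<- d
        return(TRUE)
      }
      step <- step / 2
    }
    FALSE
  }

  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    dev_start <- dev
    S <- exp(s)
    u <- ly - m
    lamc <- ifelse(abs(lam) < 1e-5, ifelse(lam < 0, -1e-5, 1e-5), lam)
    e <- exp(lamc * u)
    z <- expm1(lamc * u) / (lamc * S)

    g_m <- -lam + z * e / S
    w_m <- (1 + 2 * lam^2 * S^2) / S^2
    try_update("m", m + g_m / w_m, w_m, edf[["M"]])

    S <- exp(s); u <- ly - m
    z <- expm1(lamc * u) / (lamc * S)
    g_s <- z^2 - 1
    try_update("s", s + g_s / 2, rep(2, n), edf[["S"]])

    S <- exp(s)
    z <- expm1(lamc * u) / (lamc * S)
    e <- exp(lamc * u)
    dz <- (u * e) / (lamc * S) - z / lamc
    g_l <- u - z * dz
    w_l <- 7 * S^2 / 4
    try_update("l", lam + g_l / w_l, w_l, edf[["L"]])

    if (dev_start - dev < tol) { converged <- TRUE; break }
  }

  list(predict_m = cm$predict, predict_s = cs$predict, predict_l = cl$predict,
       deviance = dev, iter = iter, converged = converged)
}

#' Fit an LMS (Box-Cox) age-reference model
#'
#' Fits three smooth curves against age -- the Box-Cox skewness L (lambda),
#' the median M (mu, trait units) and the coefficient of variation S (sigma)
#' -- by penalised maximum likelihood, so that the standard deviation score
#' (SDS) of a measurement `y` at age `t` is
#' `z = ((y/M(t))^L(t) - 1)/(L(t) S(t))` (log form as `L -> 0`). Each sex is
#' fitted separately by calling `lms_fit()` on that sex's data.
#'
#' Curve complexity is measured in effective degrees of freedom (edf; 1 =
#' constant, 2 = linear, >2 = cubic smoothing spline) and chosen greedily in
#' the order M, S, L: one extra edf on a curve is accepted only if it reduces
#' the penalised deviance by more than `ln(N)`, the Schwarz (BIC) step. The
#' full selection trace is kept in the fitted object. Supplying `edf` skips
#' selection and fits that single complexity.
#'
#' @param y Positive trait measurements.
#' @param age Decimal ages, same length as `y`.
#' @param sex Optional label (`"male"`/`"female"`) stored with the fit; the
#'   function never pools sexes.
#' @param trait Trait name stored with the fit.
#' @param edf Optional named vector `c(M=,S=,L=)` fixing the complexity.
#' @param max_edf Named vector of maximum edf per curve for the greedy search.
#' @param age_grid Ages at which the fitted curves are tabulated (default: 101
#'   equally spaced points over the observed age range). Evaluation between
#'   grid points uses monotone (Fritsch-Carlson) cubic interpolation;
#'   extrapolation outside the grid is refused.
#' @param maxit,tol Backfitting iteration cap and deviance tolerance.
#' @return An object of class `"lms"` with components `age_grid`, `L`, `M`,
#'   `S`, `edf`, `deviance`, `n`, `trace`, `data` (ages, values and their
#'   SDS). Methods: [predict.lms()], [plot.lms()], [coef.lms()],
#'   [simulate.lms()], `residuals`, `fitted`, `print`, `summary`.
#' @examples
#' set.seed(1)
#' age <- runif(500, 4, 20)
#' y <- 600 * exp(-0.05 * (age - 4)) * exp(0.1 * rnorm(500))
#' fit <- lms_fit(y, age, trait = "r_h", edf = c(M = 4, S = 1, L = 1))
#' fit
#' mean(residuals(fit)); sd(residuals(fit))
#' @export
lms_fit <- function(y, age, sex = NA_character_, trait = "value",
                    edf = NULL, max_edf = c(M = 6, S = 6, L = 6),
                    age_grid = NULL, maxit = 50, tol = 1e-3) {
  stopifnot(length(y) == length(age))
  ok <- is.finite(y) & is.finite(age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 50)
    stop("reference fitting needs at least 50 observations")
  if (any(y <= 0)) stop("Box-Cox reference fitting requires positive values")
  n <- length(y)

  trace <- data.frame(edf_M = integer(), edf_S = integer(), edf_L = integer(),
                      deviance = double(), accepted = logical(),
                      stringsAsFactors = FALSE)
  push <- function(e, d, acc)
    trace[nrow(trace) + 1L, ] <<- list(e[["M"]], e[["S"]], e[["L"]], d, acc)

  if (!is.null(edf)) {
    edf <- c(M = unname(edf[["M"]]), S = unname(edf[["S"]]), L = unname(edf[["L"]]))
    eng <- .lms_engine(y, age, edf, maxit, tol)
    push(edf, eng$deviance, TRUE)
  } else {
    edf <- c(M = 1, S = 1, L = 1)
    eng <- .lms_engine(y, age, edf, maxit, tol)
    push(edf, eng$deviance, TRUE)
    for (curve in c("M", "S", "L")) {
      repeat {
        if (edf[[curve]] + 1 > max_edf[[curve]]) break
        cand <- edf
        cand[[curve]] <- cand[[curve]] + 1
        eng_c <- .lms_engine(y, age, cand, maxit, tol)
        accept <- (eng$deviance - eng_c$deviance) > log(n)
        push(cand, eng_c$deviance, accept)
        if (!accept) break
        edf <- cand
        eng <- eng_c
      }
    }
  }

  if (is.null(age_grid))
    age_grid <- seq(min(age), max(age), length.out = 101)
  stopifnot(all(diff(age_grid) > 0))

  obj <- structure(list(
    trait = trait, sex = sex,
    age_grid = age_grid,
    L = eng$predict_l(age_grid),
    M = exp(eng$predict_m(age_grid)),
    S = exp(eng$predict_s(age_grid)),
    edf = edf, deviance = eng$deviance, n = n,
    converged = eng$converged, iterations = eng$iter,
    trace = trace,
    data = list(age = age, y = y)
  ), class = "lms")
  obj$data$sds <- predict(obj, age = age, value = y, type = "sds")
  obj
}

# Monotone-safe interpolation of a tabulated curve; refuses extrapolation.
.lms_interp <- function(grid, vals, age) {
  rng <- range(grid)
  eps <- 1e-8 * max(1, abs(rng))
  if (any(age < rng[1] - eps | age > rng[2] + eps))
    stop(sprintf(
      "age outside the reference support [%.3g, %.3g]; extrapolation refused",
      rng[1], rng[2]))
  f <- stats::splinefun(grid, vals, method = "monoH.FC")
  f(pmin(pmax(age, rng[1]), rng[2]))
}

#' Evaluate an LMS reference
#'
#' @param object An `"lms"` fit or ingested reference.
#' @param age Ages at which to evaluate (inside the reference support).
#' @param value Measurements to standardise (`type = "sds"`), recycled
#'   against `age`.
#' @param type `"sds"` converts `value` to standard deviation scores;
#'   `"centile"` returns the trait value at percentile `p`; `"curves"`
#'   returns the interpolated L, M, S.
#' @param p Percentile in (0, 100) for `type = "centile"`.
#' @param ... Unused.
#' @return Numeric vector (`"sds"`, `"centile"`) or data frame (`"curves"`).
#'   Centile values where `1 + L*S*z_p <= 0` (the Box-Cox domain boundary)
#'   are returned as `NA` with a warning, marking a gap in the curve.
#' @export
predict.lms <- function(object, age, value = NULL,
                        type = c("sds", "centile", "curves"), p = 50, ...) {
  type <- match.arg(type)
  L <- .lms_interp(object$age_grid, object$L, age)
  M <- .lms_interp(object$age_grid, object$M, age)
  S <- .lms_interp(object$age_grid, object$S, age)
  if (type == "curves")
    return(data.frame(age = age, L = L, M = M, S = S))
  if (type == "sds") {
    if (is.null(value)) stop("'value' is required for type = \"sds\"")
    if (any(value <= 0, na.rm = TRUE))
      stop("values must be positive for SDS conversion")
    r <- value / M
    return(ifelse(abs(L) < 1e-7, log(r) / S, (r^L - 1) / (L * S)))
  }
  # centile
  if (any(p <= 0 | p >= 100)) stop("percentile must lie strictly in (0, 100)")
  zp <- stats::qnorm(p / 100)
  base <- 1 + L * S * zp
  out <- ifelse(abs(L) < 1e-7, M * exp(S * zp),
                ifelse(base > 0, M * base^(1 / L), NA_real_))
  if (anyNA(out) && !anyNA(c(L, M, S)))
    warning("centile undefined where 1 + L*S*z_p <= 0; returned NA")
  out
}

#' Convert a measurement to a standard deviation score
#'
#' @param value Positive measurement(s).
#' @param age Age(s) in years, inside the reference support.
#' @param ref An `"lms"` reference.
#' @return SDS (z-score) values.
#' @export
to_sds <- function(value, age, ref) {
  predict(ref, age = age, value = value, type = "sds")
}

#' Centile curve of an LMS reference
#'
#' @param ref An `"lms"` reference.
#' @param p Single percentile in (0, 100), or a vector (one column each).
#' @param ages Evaluation grid (default: the reference's own grid).
#' @return Numeric vector for one `p`; otherwise a matrix with one column per
#'   percentile, named `p<percentile>`.
#' @export
centile_curve <- function(ref, p, ages = ref$age_grid) {
  if (length(p) == 1L)
    return(predict(ref, age = ages, type = "centile", p = p))
  out <- vapply(p, function(pp)
    predict(ref, age = ages, type = "centile", p = pp), numeric(length(ages)))
  colnames(out) <- paste0("p", p)
  out
}

#' @export
#' @method residuals lms
residuals.lms <- function(object, ...) {
  if (is.null(object$data)) stop("ingested references carry no fitting data")
  object$data$sds
}

#' @export
#' @method fitted lms
fitted.lms <- function(object, ...) {
  if (is.null(object$data)) stop("ingested references carry no fitting data")
  .lms_interp(object$age_grid, object$M, object$data$age)
}

#' Tabulated L, M and S curves of a reference
#'
#' @param object An `"lms"` object.
#' @param ... Unused.
#' @return Data frame `age`, `L`, `M`, `S` on the reference grid.
#' @export
#' @method coef lms
coef.lms <- function(object, ...) {
  data.frame(age = object$age_grid, L = object$L, M = object$M, S = object$S)
}

#' Simulate measurements from an LMS reference
#'
#' Draws standard-normal SDS and inverts the Box-Cox transform at the given
#' ages; used for parameter-recovery checks and synthetic data.
#'
#' @param object An `"lms"` object.
#' @param nsim Number of replicate columns.
#' @param seed Optional seed (restores the RNG state on exit).
#' @param ages Ages at which to simulate (default: the fitting ages).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated trait values.
#' @export
#' @method simulate lms
simulate.lms <- function(object, nsim = 1, seed = NULL,
                         ages = object$data$age, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  cur <- predict(object, age = ages, type = "curves")
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    z <- stats::rnorm(length(ages))
    ifelse(abs(cur$L) < 1e-7, cur$M * exp(cur$S * z),
           cur$M * pmax(1 + cur$L * cur$S * z, 1e-12)^(1 / cur$L))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.lms <- function(x, ...) {
  cat(sprintf("LMS reference for '%s'%s\n", x$trait,
              if (is.na(x$sex)) "" else paste0(" (", x$sex, ")")))
  cat(sprintf("  n = %s, age support [%.2f, %.2f] y\n",
              ifelse(is.na(x$n), "?", x$n),
              min(x$age_grid), max(x$age_grid)))
  if (!is.null(x$edf))
    cat(sprintf("  edf: M = %d, S = %d, L = %d; deviance = %.2f\n",
                x$edf[["M"]], x$edf[["S"]], x$edf[["L"]], x$deviance))
  invisible(x)
}

#' @export
summary.lms <- function(object, ...) {
  cal <- if (!is.null(object$data))
    c(mean = mean(object$data$sds), sd = stats::sd(object$data$sds),
      below_median = mean(object$data$sds < 0))
  structure(list(fit = object, calibration = cal, trace = object$trace),
            class = "summary.lms")
}

#' @export
print.summary.lms <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$calibration))
    cat(sprintf(
      "  SDS calibration: mean %.4f, sd %.4f, fraction below median %.3f\n",
      x$calibration[["mean"]], x$calibration[["sd"]],
      x$calibration[["below_median"]]))
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("  complexity selection trace:\n")
    print(x$trace, row.names = FALSE)
  }
  invisible(x)
}

#' Centile chart for an LMS reference
#'
#' Draws the classical growth-chart centiles (3rd, 10th, 25th, 50th, 75th,
#' 90th, 97th by default) over the reference's age support, with the fitting
#' sample optionally overplotted.
#'
#' @param x An `"lms"` object.
#' @param p Percentiles to draw.
#' @param points Overlay the fitting sample, if available.
#' @param xlab,ylab,main Axis labels and title.
#' @param ... Passed to [graphics::matplot()].
#' @return The matrix of centile values, invisibly.
#' @export
plot.lms <- function(x, p = c(3, 10, 25, 50, 75, 90, 97), points = TRUE,
                     xlab = "age (y)", ylab = x$trait, main = NULL, ...) {
  cc <- centile_curve(x, p)
  if (is.null(dim(cc))) cc <- matrix(cc, ncol = 1)
  graphics::matplot(x$age_grid, cc, type = "l", lty = 1,
                    col = grDevices::grey(0.3),
                    xlab = xlab, ylab = ylab,
                    main = if (is.null(main)) sprintf(
                      "%s%s centiles", x$trait,
                      if (is.na(x$sex)) "" else paste0(" (", x$sex, ")"))
                    else main, ...)
  if (points && !is.null(x$data))
    graphics::points(x$data$age, x$data$y, pch = ".", col = "steelblue")
  graphics::text(max(x$age_grid), cc[nrow(cc), ], labels = paste0("p", p),
                 pos = 4, cex = 0.6, xpd = NA)
  invisible(cc)
}

#' Write LMS references to a CSV table
#'
#' One row per (trait, sex, grid age) with columns
#' `trait, sex, age_y, L, M, S`; the layout expected by
#' [read_lms_reference()] and suitable for publishing a fitted reference.
#'
#' @param x An `"lms"` object or a (possibly nested) list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lms_reference <- function(x, path) {
  flat <- list()
  collect <- function(o) {
    if (inherits(o, "lms")) flat[[length(flat) + 1L]] <<- o
    else if (is.list(o)) lapply(o, collect)
    else stop("not an 'lms' object")
  }
  collect(x)
  rows <- do.call(rbind, lapply(flat, function(o)
    data.frame(trait = o$trait, sex = as.character(o$sex),
               age_y = o$age_grid, L = o$L, M = o$M, S = o$S,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read LMS references from a CSV table
#'
#' Validates each (trait, sex) block: strictly increasing ages, `M > 0`,
#' `S > 0`; malformed blocks raise a parse error naming the offending rows.
#'
#' @param path CSV with columns `trait, sex, age_y, L, M, S`.
#' @return A single `"lms"` object if the file holds one (trait, sex) block,
#'   otherwise a named list of them (`"<trait>.<sex>"`).
#' @export
read_lms_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "sex", "age_y", "L", "M", "S")
  miss <- need[!need %in% names(df)]
  if (length(miss)) stop("reference table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$age_y) | !is.finite(df$L) |
                 !is.finite(df$M) | !is.finite(df$S) | df$M <= 0 | df$S <= 0)
  if (length(bad))
    stop("malformed reference rows (non-finite, M <= 0 or S <= 0): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  key <- interaction(df$trait, df$sex, drop = TRUE)
  out <- lapply(split(df, key), function(b) {
    if (any(diff(b$age_y) <= 0))
      stop(sprintf("non-monotone age grid for trait '%s', sex '%s'",
                   b$trait[1], b$sex[1]))
    structure(list(trait = b$trait[1], sex = b$sex[1], age_grid = b$age_y,
                   L = b$L, M = b$M, S = b$S,
                   edf = NULL, deviance = NA_real_, n = NA_integer_,
                   converged = NA, iterations = NA_integer_,
                   trace = NULL, data = NULL),
              class = "lms")
  })
  if (length(out) == 1L) out[[1L]] else out
}
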