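# End-to-end orchestration: QC -> vector components -> 4-component
# composition -> per-sex LMS references (fitted from the cohort, or ingested
# from a published reference table) -> SDS -> categories, correlations,
# regressions, contrasts, ellipses and centile charts, with a JSON run
# report. Every step is deterministic given its inputs.

.trait_map <- data.frame(
  trait = c("pa", "rh", "xch", "bmi", "ffm", "fm", "hffm"),
  column = c("pa", "r_h", "xc_h", "bmi", "ffm_kg", "fm_kg", "h_ffm"),
  sds = c("pa_sds", "rh_sds", "xch_sds", "bmi_sds", "ffm_sds", "fm_sds",
          "hffm_sds"),
  stringsAsFactors = FALSE
)

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the core SDS pipeline in memory
#'
#' Applies QC, computes the height-adjusted vector components and the
#' 4-component body composition, fits (or applies) per-sex LMS references for
#' the seven traits (phase angle, R/H, Xc/H, BMI, FFM, FM, FFM-hydration),
#' and returns the per-subject SDS table. Sexes are always standardised
#' separately.
#'
#' @param x A `cohort` object.
#' @param thresholds [qc_thresholds()] applied before any analysis.
#' @param references Optional ingested references (output of
#'   [read_lms_reference()], or a nested list `ref[[trait]][[sex]]`); when
#'   `NULL` (default) references are fitted from the QC-kept cohort itself.
#' @param edf,max_edf Passed to [lms_fit()] when fitting.
#' @return A `biva_pipeline` object: list with `sds` (data frame of the
#'   seven `*_sds` columns plus id, sex, age), `references` (nested list),
#'   `qc`, `vectors`, `composition`, `warnings`.
#' @examples
#' g <- generate_cohort(generator_config(n = 400, seed = 1))
#' pl <- sds_pipeline(g$cohort, edf = c(M = 3, S = 1, L = 1))
#' round(cor(pl$sds[, c("rh_sds", "ffm_sds")]), 2)
#' @export
sds_pipeline <- function(x, thresholds = qc_thresholds(), references = NULL,
                         edf = NULL, max_edf = c(M = 6, S = 6, L = 6)) {
  qc <- .stage("qc", qc_filter(x, thresholds))
  kept <- qc$kept
  vec <- .stage("vectors", {
    if (nrow(kept) == 0) stop("no records survived quality control")
    compute_vectors(kept)
  })
  comp <- .stage("composition", body_composition(kept))

  raw <- data.frame(
    subject_id = kept$subject_id, sex = kept$sex, age_y = kept$age_y,
    pa = vec$pa, r_h = vec$r_h, xc_h = vec$xc_h,
    bmi = comp$bmi, ffm_kg = comp$ffm_kg, fm_kg = comp$fm_kg,
    h_ffm = comp$h_ffm, stringsAsFactors = FALSE
  )

  warns <- character(0)
  refs <- .stage("reference", {
    if (!is.null(references)) .normalise_refs(references)
    else {
      out <- list()
      for (k in seq_len(nrow(.trait_map))) {
        tr <- .trait_map$trait[k]; col <- .trait_map$column[k]
        out[[tr]] <- list()
        for (sx in c("male", "female")) {
          i <- raw$sex == sx & is.finite(raw[[col]]) & raw[[col]] > 0
          if (sum(i) == 0) next
          out[[tr]][[sx]] <- lms_fit(raw[[col]][i], raw$age_y[i], sex = sx,
                                     trait = tr, edf = edf,
                                     max_edf = max_edf)
        }
      }
      out
    }
  })

  sds <- raw[, c("subject_id", "sex", "age_y")]
  .stage("sds", {
    for (k in seq_len(nrow(.trait_map))) {
      tr <- .trait_map$trait[k]; col <- .trait_map$column[k]
      z <- rep(NA_real_, nrow(raw))
      for (sx in c("male", "female")) {
        ref <- refs[[tr]][[sx]]
        if (is.null(ref)) next
        i <- which(raw$sex == sx & is.finite(raw[[col]]) & raw[[col]] > 0)
        if (!length(i)) next
        sup <- range(ref$age_grid)
        eps <- 1e-8 * max(1, abs(sup))
        ok <- raw$age_y[i] >= sup[1] - eps & raw$age_y[i] <= sup[2] + eps
        if (any(!ok))
          warns <- c(warns, sprintf(
            "%d record(s) outside the %s/%s reference support left NA",
            sum(!ok), tr, sx))
        i <- i[ok]
        z[i] <- predict(ref, age = raw$age_y[i], value = raw[[col]][i],
                        type = "sds")
      }
      sds[[.trait_map$sds[k]]] <- z
    }
    if (all(is.na(sds[, .trait_map$sds])))
      stop("no usable SDS could be computed")
  })

  structure(list(sds = sds, references = refs, qc = qc, vectors = vec,
                 composition = comp, warnings = warns),
            class = "biva_pipeline")
}

# accept read_lms_reference() output (flat "trait.sex" list or single) or an
# already-nested ref[[trait]][[sex]] list
.normalise_refs <- function(references) {
  if (inherits(references, "lms"))
    references <- stats::setNames(list(references),
                                  paste(references$trait, references$sex,
                                        sep = "."))
  if (all(vapply(references, inherits, TRUE, what = "lms"))) {
    out <- list()
    for (o in references) out[[o$trait]][[as.character(o$sex)]] <- o
    return(out)
  }
  references
}

#' @export
print.biva_pipeline <- function(x, ...) {
  cat(sprintf(
    "<biva_pipeline> %d record(s) in, %d kept after QC, %d excluded\n",
    x$qc$n_input, nrow(x$qc$kept), nrow(x$qc$excluded)))
  cal <- round(colMeans(x$sds[, .trait_map$sds], na.rm = TRUE), 3)
  cat("  SDS column means:", paste(names(cal), cal, collapse = ", "), "\n")
  invisible(x)
}

.open_device <- function(path_base) {
  if (capabilities("png")) {
    path <- paste0(path_base, ".png")
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 700, res = 110)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(path)
  }
  path <- paste0(path_base, ".pdf")
  grDevices::pdf(path, width = 8, height = 6)
  path
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Executes [sds_pipeline()] and the cohort-level analyses (category
#' construction over FFM and hydration SDS, whole-cohort correlation matrix,
#' multiple regressions of body composition on the impedance scores and the
#' reverse models, pairwise group contrasts, confidence ellipses per group,
#' centile charts), writing tidy CSVs, figures and a machine-readable JSON
#' run report to `out_dir`. Rerunning with identical inputs reproduces
#' identical numbers.
#'
#' @param cohort A `cohort` object or path to a cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param config Optional nested list of settings: `qc` (arguments to
#'   [qc_thresholds()]), `lms` (`edf`, `max_edf`), `reference_path` (ingest a
#'   published LMS reference table instead of fitting), `ellipse_level`
#'   (default 0.95), `charts` (logical, default TRUE).
#' @return The run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(cohort, out_dir, config = list()) {
  if (is.character(cohort)) cohort <- .stage("read", read_cohort(cohort))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths[[name]] <<- p
    p
  }

  thr <- do.call(qc_thresholds, config$qc %||% list())
  refs <- if (!is.null(config$reference_path))
    .stage("reference", read_lms_reference(config$reference_path))
  pl <- sds_pipeline(cohort, thresholds = thr, references = refs,
                     edf = config$lms$edf,
                     max_edf = config$lms$max_edf %||% c(M = 6, S = 6, L = 6))
  sds <- pl$sds

  emit(sds, "sds.csv")
  if (nrow(pl$qc$excluded)) emit(pl$qc$excluded, "qc_excluded.csv")
  if (is.null(refs)) {
    p <- file.path(out_dir, "lms_reference.csv")
    write_lms_reference(pl$references, p)
    paths[["lms_reference.csv"]] <- p
  }

  # correlations (long form)
  cm <- .stage("correlations",
               correlation_matrix(sds, columns = .trait_map$sds))
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  emit(data.frame(var1 = rownames(cm$r)[idx[, 1]],
                  var2 = colnames(cm$r)[idx[, 2]],
                  r = cm$r[idx], p = cm$p[idx], n = cm$n[idx]),
       "correlations.csv")

  # regressions: body composition from BIVA scores, and the reverse
  reg_spec <- list(
    c("ffm_sds", "rh_sds", "xch_sds", "pa_sds"),
    c("hffm_sds", "rh_sds", "xch_sds", "pa_sds"),
    c("rh_sds", "ffm_sds", "fm_sds", "hffm_sds"),
    c("xch_sds", "ffm_sds", "fm_sds", "hffm_sds"),
    c("pa_sds", "ffm_sds", "fm_sds", "hffm_sds")
  )
  regs <- .stage("regressions", lapply(reg_spec, function(sp)
    sds_regression(sds, sp[1], sp[-1])))
  emit(do.call(rbind, lapply(regs, function(r)
    cbind(outcome = r$outcome, r$terms, r2 = r$r2, n = r$n))),
    "regressions.csv")

  # categories, contrasts, ellipses
  schemes <- list(ffm = ffm_scheme(), hffm = hffm_scheme())
  contrasts_out <- list(); ellipse_rows <- list()
  lvl <- config$ellipse_level %||% 0.95
  for (nm in names(schemes)) {
    g <- .stage("categories", categorize(sds, schemes[[nm]]))
    for (out_col in c("rh_sds", "xch_sds", "pa_sds")) {
      ct <- .stage("contrasts", group_contrasts(sds, out_col, g))
      contrasts_out[[length(contrasts_out) + 1L]] <-
        cbind(scheme = nm, outcome = out_col, ct)
    }
    for (lev in levels(g)) {
      i <- which(g == lev & stats::complete.cases(sds[, c("rh_sds", "xch_sds")]))
      if (length(i) < 4) next
      e <- confidence_ellipse(sds[i, c("rh_sds", "xch_sds")], lvl)
      ellipse_rows[[length(ellipse_rows) + 1L]] <- data.frame(
        scheme = nm, group = lev, n = e$n,
        center_rh = e$center[1], center_xch = e$center[2],
        semi_major = e$semi_major, semi_minor = e$semi_minor,
        orientation = e$orientation, level = e$level)
    }
  }
  emit(do.call(rbind, contrasts_out), "contrasts.csv")
  emit(do.call(rbind, ellipse_rows), "ellipses.csv")

  # figures + centile table
  if (isTRUE(config$charts %||% TRUE)) {
    cent_rows <- list()
    pp <- c(3, 10, 25, 50, 75, 90, 97)
    for (tr in names(pl$references)) for (sx in names(pl$references[[tr]])) {
      ref <- pl$references[[tr]][[sx]]
      cc <- centile_curve(ref, pp)
      cent_rows[[paste(tr, sx)]] <- data.frame(
        trait = tr, sex = sx, age = ref$age_grid,
        as.data.frame(cc, check.names = FALSE))
      p <- .open_device(file.path(out_dir, sprintf("chart_%s_%s", tr, sx)))
      plot(ref)
      grDevices::dev.off()
      paths[[basename(p)]] <- p
    }
    emit(do.call(rbind, cent_rows), "centiles.csv")
    ok <- stats::complete.cases(sds[, c("rh_sds", "xch_sds", "ffm_sds")])
    grp <- split(as.matrix(sds[ok, c("rh_sds", "xch_sds")]),
                 categorize(sds[ok, ], schemes$ffm))
    grp <- lapply(grp, matrix, ncol = 2)
    grp <- grp[vapply(grp, nrow, 1L) >= 4]
    if (length(grp)) {
      p <- .open_device(file.path(out_dir, "rxc_ellipses_ffm"))
      rxc_plot(grp, level = lvl, axes_mode = "sds")
      grDevices::dev.off()
      paths[[basename(p)]] <- p
    }
  }

  reasons <- table(unlist(strsplit(pl$qc$excluded$reasons, "; ", fixed = TRUE)))
  report <- list(
    counts = list(
      rows_read = parse_report(cohort)$rows_read,
      parse_rejected = nrow(parse_report(cohort)$rejected),
      qc_input = pl$qc$n_input,
      qc_kept = nrow(pl$qc$kept),
      qc_excluded = nrow(pl$qc$excluded),
      qc_excluded_by_reason = as.list(reasons)
    ),
    settings = list(
      thresholds = unclass(thr),
      reference_mode = if (is.null(refs)) "fitted" else "ingested",
      lms_edf = config$lms$edf,
      ellipse_level = lvl
    ),
    outputs = lapply(paths, normalizePath),
    warnings = pl$warnings
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
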