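#' @keywords internal
"_PACKAGE"

# Canonical cohort columns. Mandatory columns must parse for a row to be kept;
# optional 4-component inputs may be missing (empty cells, never "0").
.cohort_mandatory <- c(
  "subject_id", "sex", "age_y", "height_m", "weight_kg",
  "r1_ohm", "r2_ohm", "xc1_ohm", "xc2_ohm", "pa1_deg", "pa2_deg"
)
.cohort_optional <- c("dilution_space_kg", "body_volume_l", "bmc_kg")
.cohort_columns <- c(.cohort_mandatory, .cohort_optional)

.default_sex_codes <- c(
  male = "male", female = "female", M = "male", F = "female",
  m = "male", f = "female", "1" = "male", "2" = "female"
)

#' Canonical cohort column names
#'
#' @return Character vector of the canonical cohort CSV column names, in
#'   order: identifiers, anthropometry, duplicate impedance readings at
#'   50 kHz, then the optional 4-component inputs.
#' @export
cohort_columns <- function() .cohort_columns

# Validate raw rows (character or numeric data.frame with canonical names).
# Returns list(records = data.frame, rejects = data.frame(row, subject_id, reason)).
.validate_rows <- function(df, sex_codes) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(i, msg) reasons[[i]] <<- c(reasons[[i]], msg)

  num_cols <- setdiff(.cohort_columns, c("subject_id", "sex"))
  out <- data.frame(subject_id = as.character(df$subject_id),
                    stringsAsFactors = FALSE)

  raw_sex <- as.character(df$sex)
  mapped <- unname(sex_codes[raw_sex])
  for (i in seq_len(n)) {
    if (is.na(raw_sex[i]) || !nzchar(raw_sex[i])) add(i, "missing sex")
    else if (is.na(mapped[i])) add(i, sprintf("unknown sex code '%s'", raw_sex[i]))
  }
  out$sex <- mapped

  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      blank <- is.na(v) | !nzchar(trimws(v))
      vn <- suppressWarnings(as.numeric(v))
      bad <- !blank & is.na(vn)
      for (i in which(bad)) add(i, sprintf("non-numeric %s", cc))
      vn[blank] <- NA_real_
    } else {
      vn <- as.numeric(v)
    }
    out[[cc]] <- vn
  }

  for (i in which(is.na(out$subject_id) | !nzchar(out$subject_id)))
    add(i, "missing subject_id")
  for (cc in .cohort_mandatory[-(1:2)])
    for (i in which(is.na(out[[cc]]) & !vapply(reasons, function(r)
      any(grepl(cc, r, fixed = TRUE)), TRUE)))
      add(i, sprintf("missing %s", cc))

  chk_pos <- function(col, label) {
    bad <- which(!is.na(out[[col]]) & out[[col]] <= 0)
    for (i in bad) add(i, label)
  }
  chk_pos("height_m", "nonpositive height")
  chk_pos("weight_kg", "nonpositive weight")
  for (cc in c("r1_ohm", "r2_ohm", "xc1_ohm", "xc2_ohm", "pa1_deg", "pa2_deg"))
    chk_pos(cc, sprintf("nonpositive impedance reading (%s)", cc))
  for (cc in .cohort_optional) chk_pos(cc, sprintf("nonpositive %s", cc))

  # duplicate ids: first occurrence kept, later ones rejected
  dup <- duplicated(out$subject_id) & nzchar(out$subject_id)
  for (i in which(dup)) add(i, "duplicate subject_id")

  bad <- which(vapply(reasons, length, 1L) > 0L)
  rejects <- data.frame(
    row = bad,
    subject_id = out$subject_id[bad],
    reason = vapply(reasons[bad], paste, "", collapse = "; "),
    stringsAsFactors = FALSE
  )
  records <- out[setdiff(seq_len(n), bad), , drop = FALSE]
  rownames(records) <- NULL

  # ages outside the reference-fitting range are flagged, never dropped
  records$flag_age_range <- !is.na(records$age_y) &
    (records$age_y < 4 | records$age_y > 20)
  list(records = records, rejects = rejects)
}

.new_cohort <- function(records, report) {
  structure(records, parse_report = report, class = c("cohort", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated cohort file (UTF-8, header row, `.` decimal
#' separator, empty cells for missing values) into a `cohort` object: one row
#' per child with anthropometry, duplicate 50 kHz impedance readings and
#' optional 4-component body-composition inputs. Malformed rows are never
#' silently dropped: each one is recorded, with its reason, in the parse
#' report attached to the returned object (see [parse_report()]).
#'
#' @param path Path to a CSV file.
#' @param columns Optional named character vector mapping canonical column
#'   names (see [cohort_columns()]) to the names used in the file, e.g.
#'   `c(age_y = "age.years")`. Unmapped canonical names are looked up as-is.
#' @param sex_codes Named character vector mapping the file's sex codes to
#'   `"male"`/`"female"`. The default accepts `male/female`, `M/F`, `m/f`
#'   and `1/2`.
#' @return A `cohort` data frame (canonical columns plus `flag_age_range`,
#'   marking ages outside 4--20 y) with a `parse_report` attribute.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(generator_config(n = 20, seed = 1))$cohort, path)
#' coh <- read_cohort(path)
#' parse_report(coh)$rows_read
#' @export
read_cohort <- function(path, columns = NULL, sex_codes = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(sex_codes)) sex_codes <- .default_sex_codes
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("empty or unreadable cohort file: ", path,
                             call. = FALSE))

  name_of <- function(canon)
    if (!is.null(columns) && canon %in% names(columns)) columns[[canon]] else canon
  file_names <- vapply(.cohort_columns, name_of, "")
  missing_mand <- .cohort_mandatory[!file_names[.cohort_mandatory] %in% names(raw)]
  if (length(missing_mand))
    stop("mandatory column(s) absent from header: ",
         paste(missing_mand, collapse = ", "))
  if (nrow(raw) == 0L) stop("cohort file has a header but no rows: ", path)

  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in .cohort_columns) {
    fn <- file_names[[canon]]
    df[[canon]] <- if (fn %in% names(raw)) raw[[fn]] else NA_character_
  }
  v <- .validate_rows(df, sex_codes)
  report <- list(
    source = path,
    rows_read = nrow(raw),
    records = nrow(v$records),
    rejected = v$rejects
  )
  .new_cohort(v$records, report)
}

#' Build a cohort object from an in-memory data frame
#'
#' Applies the same row validation as [read_cohort()]. Invalid rows raise an
#' error by default (in-memory tables are programmer-built), or are routed to
#' the parse report when `drop_invalid = TRUE`.
#'
#' @param df Data frame with canonical cohort columns.
#' @param sex_codes As in [read_cohort()].
#' @param drop_invalid Route invalid rows to the parse report instead of
#'   raising an error.
#' @return A `cohort` object.
#' @export
as_cohort <- function(df, sex_codes = NULL, drop_invalid = FALSE) {
  if (is.null(sex_codes)) sex_codes <- .default_sex_codes
  for (cc in setdiff(.cohort_columns, names(df))) df[[cc]] <- NA_real_
  v <- .validate_rows(df[, .cohort_columns, drop = FALSE], sex_codes)
  if (!drop_invalid && nrow(v$rejects))
    stop("invalid cohort rows: ",
         paste(utils::head(v$rejects$reason, 5L), collapse = " | "))
  report <- list(source = "<in-memory>", rows_read = nrow(df),
                 records = nrow(v$records), rejected = v$rejects)
  .new_cohort(v$records, report)
}

#' Parse report of a cohort
#'
#' @param x A `cohort` object.
#' @return List with `source`, `rows_read`, `records` and a `rejected` data
#'   frame (`row`, `subject_id`, `reason`); `rows_read = records + nrow(rejected)`.
#' @export
parse_report <- function(x) {
  stopifnot(inherits(x, "cohort"))
  attr(x, "parse_report")
}

#' Write a cohort table to CSV
#'
#' Writes the canonical columns (missing optional values as empty cells, never
#' zero) so that `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param x A `cohort` object (or data frame with canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  if (nrow(x) == 0L) stop("refusing to write an empty cohort")
  df <- as.data.frame(x)[, .cohort_columns, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  rep <- attr(x, "parse_report")
  cat(sprintf("<cohort> %d record(s)", nrow(x)))
  if (!is.null(rep))
    cat(sprintf(" [%d row(s) read, %d rejected]", rep$rows_read,
                nrow(rep$rejected)))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more row(s)\n", sep = "")
  invisible(x)
}
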