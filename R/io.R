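# Readers and writers for the flat rectangular files the pipeline exchanges:
# diary CSV, SFQ definition CSV, mapping-table CSV, augmented-database CSV.
# Dialect everywhere: UTF-8, comma separated, quoted fields, mandatory header.

diary_columns <- function() {
  c(
    "subject_id", "day_index", "weekday", "meal_type", "food_code",
    "food_name", "food_description", "cooking_method", "food_group",
    "amount_g"
  )
}

mapping_columns <- function() {
  c(
    "food_code", "status", "target_group", "coverage_fraction",
    "match_step", "similarity", "needs_review"
  )
}

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

blank_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

#' Read a food-diary datafile
#'
#' One row of the diary is one eating occasion: who ate what, on which survey
#' day, and how many grams. Column names in the file are adapted through an
#' explicit `schema` map, since detailed-survey datafiles do not share a
#' published header convention.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping the canonical column names
#'   (`subject_id`, `day_index`, `weekday`, `meal_type`, `food_code`,
#'   `food_name`, `food_description`, `cooking_method`, `food_group`,
#'   `amount_g`) to the column names used in the file. Defaults to the
#'   canonical names themselves. Columns not mentioned in the schema are
#'   passed through untouched.
#' @param on_error `"stop"` (default) aborts on the first invalid row(s),
#'   naming them; `"report"` drops invalid rows, warns, and attaches the error
#'   table as attribute `"row_errors"` so that
#'   `rows in = rows out + rows reported`.
#'
#' @return A tibble of consumptions in file order, one row per eating
#'   occasion, with `day_index` integer, `amount_g` double, `weekday` one of
#'   `"Mon"`..`"Sun"`, and empty text fields as `""` (never `NA`).
#' @export
read_food_diary <- function(path, schema = NULL, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) abort_dietmap("diary file not found: %s", path)
  canonical <- diary_columns()
  schema <- schema %||% stats::setNames(canonical, canonical)
  if (!all(canonical %in% names(schema))) {
    abort_dietmap(
      "schema must map every canonical column; missing: %s",
      paste(setdiff(canonical, names(schema)), collapse = ", ")
    )
  }
  raw <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(unname(schema[canonical]), names(raw))
  if (length(missing) > 0) {
    abort_dietmap("diary file lacks column(s): %s", paste(missing, collapse = ", "))
  }
  # rename file columns to canonical names, keep extras untouched
  for (cn in canonical) {
    fn <- unname(schema[[cn]])
    if (fn != cn) names(raw)[names(raw) == fn] <- cn
  }
  out <- raw
  out$day_index <- suppressWarnings(as.integer(out$day_index))
  out$amount_g <- suppressWarnings(as.numeric(out$amount_g))
  out$weekday <- canonical_weekday(out$weekday)
  for (cn in c("meal_type", "food_name", "food_description", "cooking_method", "food_group")) {
    out[[cn]] <- blank_text(out[[cn]])
  }

  problems <- character(0)
  bad <- rep(FALSE, nrow(out))
  flag <- function(cond, what) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      problems <<- c(problems, sprintf("row %d: %s", which(cond), what))
      bad <<- bad | cond
    }
  }
  flag(is.na(out$amount_g), "amount_g is missing or non-numeric")
  flag(!is.na(out$amount_g) & out$amount_g < 0, "amount_g is negative")
  flag(is.na(out$day_index) | out$day_index < 1, "day_index is missing or < 1")
  flag(is.na(out$weekday), "weekday is not a day name")
  flag(is.na(out$subject_id) | !nzchar(blank_text(out$subject_id)), "subject_id is empty")
  flag(is.na(out$food_code) | !nzchar(blank_text(out$food_code)), "food_code is empty")

  if (length(problems) > 0) {
    if (on_error == "stop") {
      abort_dietmap(
        "invalid diary rows:\n%s",
        paste(head(unique(problems), 20), collapse = "\n")
      )
    }
    err_tbl <- tibble::tibble(row = which(bad))
    warning(sprintf("dropped %d invalid diary row(s)", nrow(err_tbl)), call. = FALSE)
    out <- out[!bad, , drop = FALSE]
    attr(out, "row_errors") <- err_tbl
  }
  attr(out, "n_read") <- nrow(raw)
  tibble::as_tibble(out)
}

#' Write a food diary CSV
#'
#' @param diary Tibble of consumptions (canonical columns, see
#'   [read_food_diary()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_diary <- function(diary, path) {
  missing <- setdiff(diary_columns(), names(diary))
  if (length(missing) > 0) {
    abort_dietmap("diary lacks column(s): %s", paste(missing, collapse = ", "))
  }
  readr::write_csv(diary, path, na = "")
  invisible(path)
}

#' Read a short-food-questionnaire definition
#'
#' The definition file lists one questionnaire food group per row with columns
#' `group_code`, `label`, `polarity` (`healthy`/`unhealthy`),
#' `include_keywords`, and `exclude_keywords`; the keyword columns hold
#' semicolon-separated phrases, which are normalized on read (see
#' [normalize_text()]).
#'
#' @param path Path to the CSV definition.
#' @return A tibble with one row per group, keyword columns as list columns of
#'   normalized phrases, in file order.
#' @export
read_sfq_definition <- function(path) {
  if (!file.exists(path)) abort_dietmap("SFQ definition file not found: %s", path)
  raw <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("group_code", "label", "polarity", "include_keywords", "exclude_keywords")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort_dietmap("SFQ definition lacks column(s): %s", paste(missing, collapse = ", "))
  }
  split_kw <- function(x) {
    x <- blank_text(x)
    lapply(strsplit(x, ";", fixed = TRUE), function(ph) {
      ph <- normalize_join(ph)
      unique(ph[nzchar(ph)])
    })
  }
  out <- tibble::tibble(
    group_code = blank_text(raw$group_code),
    label = blank_text(raw$label),
    polarity = blank_text(raw$polarity),
    include_keywords = split_kw(raw$include_keywords),
    exclude_keywords = split_kw(raw$exclude_keywords)
  )
  if (anyDuplicated(out$group_code) > 0) {
    dups <- unique(out$group_code[duplicated(out$group_code)])
    abort_dietmap("duplicate group_code(s) in SFQ definition: %s", paste(dups, collapse = ", "))
  }
  if (!all(out$polarity %in% c("healthy", "unhealthy"))) {
    abort_dietmap("polarity must be 'healthy' or 'unhealthy'")
  }
  n_inc <- vapply(out$include_keywords, length, integer(1))
  if (any(n_inc == 0)) {
    abort_dietmap(
      "group(s) with empty include_keywords: %s",
      paste(out$group_code[n_inc == 0], collapse = ", ")
    )
  }
  overlap <- mapply(
    function(i, e) length(intersect(i, e)) > 0,
    out$include_keywords, out$exclude_keywords
  )
  if (any(overlap)) {
    abort_dietmap(
      "group(s) with a keyword in both include and exclude sets: %s",
      paste(out$group_code[overlap], collapse = ", ")
    )
  }
  out
}

#' Write a short-food-questionnaire definition CSV
#'
#' Inverse of [read_sfq_definition()] (keyword phrases re-joined with `;`).
#'
#' @param groups SFQ definition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfq_definition <- function(groups, path) {
  flat <- tibble::tibble(
    group_code = groups$group_code,
    label = groups$label,
    polarity = groups$polarity,
    include_keywords = vapply(groups$include_keywords, paste, character(1), collapse = ";"),
    exclude_keywords = vapply(groups$exclude_keywords, paste, character(1), collapse = ";")
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' The bundled 15-group questionnaire definition
#'
#' The questionnaire groups of the source national infant-cohort instrument
#' (8 "healthy" and 7 "unhealthy" groups), with include/exclude keyword sets
#' curated so that the token-search step resolves unambiguously (e.g. the
#' fresh-fruit group excludes `juice`/`juices`, so fruit juices stay
#' non-covered).
#'
#' @return SFQ definition tibble, see [read_sfq_definition()].
#' @export
gui_sfq_groups <- function() {
  read_sfq_definition(
    system.file("extdata", "gui_sfq_definition.csv", package = "dietmap", mustWork = TRUE)
  )
}

#' Write / read a mapping table
#'
#' The mapping table holds one verdict per catalogue food code. Entries are
#' validated against the verdict invariants before writing (see
#' [build_mapping_table()]); `read_mapping_table(write_mapping_table(x)) == x`.
#'
#' @param entries Mapping-entry tibble (`food_code`, `status`, `target_group`,
#'   `coverage_fraction`, `match_step`, `similarity`, `needs_review`).
#' @param path File path.
#' @return `write_mapping_table()` returns `path` invisibly;
#'   `read_mapping_table()` returns the validated tibble.
#' @export
write_mapping_table <- function(entries, path) {
  validate_mapping_entries(entries)
  readr::write_csv(entries[, mapping_columns()], path, na = "")
  invisible(path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) abort_dietmap("mapping table not found: %s", path)
  out <- read_csv_quiet(path, col_types = readr::cols(
    food_code = readr::col_character(),
    status = readr::col_character(),
    target_group = readr::col_character(),
    coverage_fraction = readr::col_double(),
    match_step = readr::col_character(),
    similarity = readr::col_double(),
    needs_review = readr::col_logical()
  ))
  missing <- setdiff(mapping_columns(), names(out))
  if (length(missing) > 0) {
    abort_dietmap("mapping table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  validate_mapping_entries(out)
  out
}

#' Write / read the augmented database
#'
#' The augmented database is the diary with four mapping columns appended
#' (`status`, `target_group`, `coverage_fraction`, `match_step`) plus the two
#' derived weights; see [apply_mapping()].
#'
#' @param augmented Augmented-record tibble.
#' @param path File path.
#' @return `write_augmented_db()` returns `path` invisibly;
#'   `read_augmented_db()` the tibble.
#' @export
write_augmented_db <- function(augmented, path) {
  need <- c(diary_columns(), "status", "target_group", "coverage_fraction", "match_step")
  missing <- setdiff(need, names(augmented))
  if (length(missing) > 0) {
    abort_dietmap("augmented database lacks column(s): %s", paste(missing, collapse = ", "))
  }
  readr::write_csv(augmented, path, na = "")
  invisible(path)
}

#' @rdname write_augmented_db
#' @export
read_augmented_db <- function(path) {
  if (!file.exists(path)) abort_dietmap("augmented database not found: %s", path)
  out <- read_csv_quiet(path, col_types = readr::cols(
    .default = readr::col_character(),
    day_index = readr::col_integer(),
    amount_g = readr::col_double(),
    coverage_fraction = readr::col_double(),
    covered_weight = readr::col_double(),
    noncov_weight = readr::col_double()
  ))
  for (cn in c("meal_type", "food_name", "food_description", "cooking_method", "food_group")) {
    if (cn %in% names(out)) out[[cn]] <- blank_text(out[[cn]])
  }
  out
}

#' Write / read per-subject-day coverage records
#'
#' @param coverage Coverage-record tibble, see [daily_coverage_ratios()].
#' @param path File path.
#' @return `write_coverage_records()` returns `path` invisibly;
#'   `read_coverage_records()` the tibble.
#' @export
write_coverage_records <- function(coverage, path) {
  readr::write_csv(coverage, path, na = "")
  invisible(path)
}

#' @rdname write_coverage_records
#' @export
read_coverage_records <- function(path) {
  if (!file.exists(path)) abort_dietmap("coverage file not found: %s", path)
  read_csv_quiet(path, col_types = readr::cols(
    .default = readr::col_double(),
    subject_id = readr::col_character(),
    weekday = readr::col_character(),
    day_index = readr::col_integer(),
    total_freq = readr::col_integer(),
    amount_ratio_missing = readr::col_logical()
  ))
}
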