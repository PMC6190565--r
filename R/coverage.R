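# Quantitative aggregation of the augmented database: per-subject-day
# coverage ratios, mean daily intakes, consumption frequencies, and summary
# statistics. Survey days are treated as independent days throughout.

#' Per-subject-day coverage ratios
#'
#' For every subject-day present in the augmented database, computes the
#' non-covered share of consumptions and of grams:
#' `noncov_freq = sum(1 - coverage_fraction)` over the day's eating
#' occasions, `noncov_amount_g = sum(amount_g * (1 - coverage_fraction))`,
#' and the two ratios against the day's totals. A zero-intake day has an
#' undefined amount ratio; the record is still emitted, with
#' `amount_ratio = NA` and `amount_ratio_missing = TRUE`.
#'
#' @param augmented Augmented tibble from [apply_mapping()].
#' @return Tibble with one row per (subject, day): `subject_id`, `day_index`,
#'   `weekday`, `total_freq`, `noncov_freq`, `total_amount_g`,
#'   `noncov_amount_g`, `freq_ratio`, `amount_ratio`,
#'   `amount_ratio_missing`.
#' @export
daily_coverage_ratios <- function(augmented) {
  if (nrow(augmented) == 0) abort_dietmap("augmented database is empty")
  if (any(is.na(augmented$amount_g)) || any(augmented$amount_g < 0)) {
    abort_dietmap("augmented records must have non-negative amount_g")
  }
  out <- augmented |>
    dplyr::group_by(.data$subject_id, .data$day_index, .data$weekday) |>
    dplyr::summarise(
      total_freq = dplyr::n(),
      noncov_freq = sum(1 - .data$coverage_fraction),
      total_amount_g = sum(.data$amount_g),
      noncov_amount_g = sum(.data$amount_g * (1 - .data$coverage_fraction)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      freq_ratio = .data$noncov_freq / .data$total_freq,
      amount_ratio = ifelse(
        .data$total_amount_g > 0,
        .data$noncov_amount_g / .data$total_amount_g,
        NA_real_
      ),
      amount_ratio_missing = .data$total_amount_g == 0
    ) |>
    dplyr::arrange(.data$subject_id, .data$day_index)
  out$total_freq <- as.integer(out$total_freq)
  out
}

#' Mean daily intake of a catalogue food group
#'
#' For each subject, the group's amounts are summed per day and averaged over
#' the `n_days` survey days (absent days count as zero); the sample mean and
#' SD are taken across subjects. The paper-style table pairs eating-occasion
#' counts with amounts, so the default denominator is the consumers of the
#' group; `denominator = "all"` averages over every surveyed subject instead.
#'
#' @param augmented Augmented tibble.
#' @param food_group A catalogue `food_group` label present in the data.
#' @param n_days Number of survey days (default 4).
#' @param denominator `"consumers"` (subjects with any consumption of the
#'   group; default) or `"all"` subjects.
#' @return A list: `per_subject` tibble (`subject_id`, `g_per_day`), `mean`,
#'   `sd`, `n`.
#' @export
mean_daily_intake <- function(augmented, food_group, n_days = 4,
                              denominator = c("consumers", "all")) {
  denominator <- match.arg(denominator)
  if (!food_group %in% augmented$food_group) {
    abort_dietmap("unknown food group: %s", food_group)
  }
  subjects <- unique(augmented$subject_id)
  g <- augmented[augmented$food_group == food_group, , drop = FALSE]
  totals <- g |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(g_per_day = sum(.data$amount_g) / n_days, .groups = "drop")
  per_subject <- tibble::tibble(subject_id = subjects) |>
    dplyr::left_join(totals, by = "subject_id") |>
    dplyr::mutate(g_per_day = dplyr::coalesce(.data$g_per_day, 0))
  if (denominator == "consumers") {
    per_subject <- per_subject[per_subject$g_per_day > 0, , drop = FALSE]
  }
  vals <- per_subject$g_per_day
  list(
    per_subject = per_subject,
    mean = if (length(vals)) mean(vals) else 0,
    sd = if (length(vals) >= 2) sd(vals) else NA_real_,
    n = length(vals)
  )
}

#' Consumption frequency per day
#'
#' Number of diary appearances of a food code (or a whole catalogue food
#' group) divided by the number of survey days, per subject and sample-wide.
#'
#' @param augmented Augmented tibble.
#' @param target Food code or food-group label to count.
#' @param by `"food_code"` (default) or `"food_group"`.
#' @param n_days Number of survey days (default 4).
#' @return A list: `per_subject` tibble (`subject_id`, `per_day`; subjects
#'   never consuming the target appear with 0), `sample_total_per_day`
#'   (total appearances / `n_days`) and `sample_mean_per_day` (mean of the
#'   per-subject values).
#' @export
consumption_frequency <- function(augmented, target, by = c("food_code", "food_group"),
                                  n_days = 4) {
  by <- match.arg(by)
  if (n_days < 1) abort_dietmap("n_days must be >= 1")
  subjects <- unique(augmented$subject_id)
  hit <- augmented[augmented[[by]] == target, , drop = FALSE]
  counts <- hit |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(per_day = dplyr::n() / n_days, .groups = "drop")
  per_subject <- tibble::tibble(subject_id = subjects) |>
    dplyr::left_join(counts, by = "subject_id") |>
    dplyr::mutate(per_day = dplyr::coalesce(.data$per_day, 0))
  list(
    per_subject = per_subject,
    sample_total_per_day = nrow(hit) / n_days,
    sample_mean_per_day = mean(per_subject$per_day)
  )
}

#' Summary statistics of a numeric vector
#'
#' Mean, sample standard deviation (n-1 denominator), standard error of the
#' mean, interquartile range bounds (linear-interpolation quantiles, R type
#' 7), minimum and maximum. With a single value, `sd` and `sem` are `NA`.
#'
#' @param values Non-empty numeric vector (no `NA`).
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`, `q25`, `q75`, `min`,
#'   `max`.
#' @export
aggregate_summary <- function(values) {
  if (length(values) == 0) abort_dietmap("aggregate_summary() needs at least one value")
  if (any(is.na(values))) abort_dietmap("aggregate_summary() does not accept NA values")
  n <- length(values)
  s <- if (n >= 2) sd(values) else NA_real_
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    n = n,
    mean = mean(values),
    sd = s,
    sem = s / sqrt(n),
    q25 = q[1],
    q75 = q[2],
    min = min(values),
    max = max(values)
  )
}

#' Per-group report of non-covered consumption
#'
#' One row per catalogue food group with any non-covered consumption: eating
#' occasion count, mean daily amount (g/day) with SD, and the group's
#' non-covered percentages (count-based and amount-weighted). Rows are sorted
#' by eating-occasion count, descending. Mean amounts use
#' [mean_daily_intake()] restricted to consumers of the group by default.
#'
#' @param augmented Augmented tibble.
#' @param n_days Number of survey days (default 4).
#' @param denominator Passed to [mean_daily_intake()].
#' @return Tibble: `food_group`, `n_eo`, `mean_g_day`, `sd_g_day`,
#'   `pct_noncov_freq`, `pct_noncov_amount`, sorted by `n_eo` descending.
#' @export
group_noncovered_report <- function(augmented, n_days = 4,
                                    denominator = c("consumers", "all")) {
  denominator <- match.arg(denominator)
  if (nrow(augmented) == 0) abort_dietmap("augmented database is empty")
  stats <- augmented |>
    dplyr::group_by(.data$food_group) |>
    dplyr::summarise(
      n_eo = dplyr::n(),
      pct_noncov_freq = 100 * mean(1 - .data$coverage_fraction),
      pct_noncov_amount = if (sum(.data$amount_g) > 0) {
        100 * sum(.data$amount_g * (1 - .data$coverage_fraction)) / sum(.data$amount_g)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$pct_noncov_freq > 0)
  amounts <- lapply(stats$food_group, function(g) {
    mi <- mean_daily_intake(augmented, g, n_days = n_days, denominator = denominator)
    tibble::tibble(food_group = g, mean_g_day = mi$mean, sd_g_day = mi$sd)
  })
  stats |>
    dplyr::left_join(dplyr::bind_rows(amounts), by = "food_group") |>
    dplyr::select(
      "food_group", "n_eo", "mean_g_day", "sd_g_day",
      "pct_noncov_freq", "pct_noncov_amount"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_eo))
}

#' Pooled (sample-level) non-covered fractions
#'
#' The per-subject-day ratios of [daily_coverage_ratios()] average the ratio
#' over days ("ratio of means per day, then mean"); this helper instead pools
#' all eating occasions before dividing. The two differ in general and are
#' deliberately labelled apart.
#'
#' @param augmented Augmented tibble.
#' @return One-row tibble: `freq_fraction_pooled`, `amount_fraction_pooled`.
#' @export
pooled_noncovered_fractions <- function(augmented) {
  if (nrow(augmented) == 0) abort_dietmap("augmented database is empty")
  tibble::tibble(
    freq_fraction_pooled = mean(1 - augmented$coverage_fraction),
    amount_fraction_pooled = if (sum(augmented$amount_g) > 0) {
      sum(augmented$amount_g * (1 - augmented$coverage_fraction)) / sum(augmented$amount_g)
    } else {
      NA_real_
    }
  )
}
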