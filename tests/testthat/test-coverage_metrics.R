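# Per-subject-day ratios, intakes, frequencies and summaries.

mini_augmented <- function(noncov_weights, amounts, subject = "S1", day = 1L,
                           weekday = "Mon", group = "g") {
  tibble::tibble(
    subject_id = subject, day_index = day, weekday = weekday,
    meal_type = "snack", food_code = as.character(seq_along(amounts)),
    food_name = "x", food_description = "", cooking_method = "",
    food_group = group, amount_g = amounts,
    status = ifelse(noncov_weights == 0, "covered",
      ifelse(noncov_weights == 1, "non_covered", "partial")
    ),
    target_group = ifelse(noncov_weights == 1, NA_character_, "G1"),
    coverage_fraction = 1 - noncov_weights,
    match_step = ifelse(noncov_weights == 1, "none", "manual"),
    covered_weight = 1 - noncov_weights,
    noncov_weight = noncov_weights
  )
}

test_that("daily ratios follow the per-subject-day definition", {
  a <- mini_augmented(c(rep(1, 4), rep(0, 6)), rep(10, 10))
  cv <- daily_coverage_ratios(a)
  expect_equal(cv$freq_ratio, 0.4)
  expect_equal(cv$total_freq, 10L)

  a0 <- mini_augmented(rep(0, 5), rep(20, 5))
  cv0 <- daily_coverage_ratios(a0)
  expect_equal(cv0$freq_ratio, 0)
  expect_equal(cv0$amount_ratio, 0)

  # partial weights: (0, 1, 0.63) over (50, 100, 80) grams
  ap <- mini_augmented(c(0, 1, 0.63), c(50, 100, 80))
  cvp <- daily_coverage_ratios(ap)
  expect_equal(cvp$noncov_freq, 1.63)
  expect_equal(cvp$freq_ratio, 1.63 / 3)
  expect_equal(cvp$noncov_amount_g, 100 + 0.63 * 80)
  expect_equal(cvp$amount_ratio, (100 + 50.4) / 230)
})

test_that("zero-intake days keep their record with a flagged missing amount ratio", {
  a <- mini_augmented(c(1, 0), c(0, 0))
  cv <- daily_coverage_ratios(a)
  expect_equal(nrow(cv), 1)
  expect_true(is.na(cv$amount_ratio))
  expect_true(cv$amount_ratio_missing)
  expect_equal(cv$freq_ratio, 0.5) # frequency ratio still defined
})

test_that("frequency and grams are conserved on generated data", {
  st <- small_study(seed = 19)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  a <- apply_mapping(st$diary, m)
  cv <- daily_coverage_ratios(a)
  covered_freq <- cv$total_freq - cv$noncov_freq
  expect_identical(covered_freq + cv$noncov_freq, as.numeric(cv$total_freq))
  covered_amt <- cv$total_amount_g - cv$noncov_amount_g
  expect_equal(covered_amt + cv$noncov_amount_g, cv$total_amount_g, tolerance = 1e-12)
  expect_true(all(cv$freq_ratio >= 0 & cv$freq_ratio <= 1))
  expect_true(all(is.na(cv$amount_ratio) | (cv$amount_ratio >= 0 & cv$amount_ratio <= 1)))
})

test_that("all-covered and none-covered mappings pin the ratios to 0 and 1", {
  st <- small_study(seed = 20)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  m_all <- m
  m_all$status <- "covered"
  m_all$target_group <- "C25a"
  m_all$coverage_fraction <- 1
  m_all$match_step <- "manual"
  m_all$similarity <- NA_real_
  cv1 <- daily_coverage_ratios(apply_mapping(st$diary, m_all))
  expect_true(all(cv1$freq_ratio == 0) && all(cv1$amount_ratio == 0))

  m_none <- m
  m_none$status <- "non_covered"
  m_none$target_group <- NA_character_
  m_none$coverage_fraction <- 0
  m_none$match_step <- "none"
  m_none$similarity <- NA_real_
  cv0 <- daily_coverage_ratios(apply_mapping(st$diary, m_none))
  expect_true(all(cv0$freq_ratio == 1) && all(cv0$amount_ratio == 1))
})

test_that("mean daily intake averages day sums over the survey days", {
  mk <- function(subject, sums) {
    dplyr::bind_rows(lapply(seq_along(sums), function(d) {
      mini_augmented(0, sums[d], subject = subject, day = as.integer(d))
    }))
  }
  a <- mk("S1", c(10, 20, 30, 40))
  mi <- mean_daily_intake(a, "g", n_days = 4)
  expect_equal(mi$mean, 25)

  # a subject never consuming the group scores 0 under the all-subjects rule
  b <- dplyr::bind_rows(a, mk("S2", c(5, 5, 5, 5)) |> dplyr::mutate(food_group = "other"))
  mi_all <- mean_daily_intake(b, "g", n_days = 4, denominator = "all")
  expect_equal(sort(mi_all$per_subject$g_per_day), c(0, 25))
  expect_equal(mi_all$mean, 12.5)

  # two consumers with day sums (10,20,30,40) and (0,0,0,40)
  c2 <- dplyr::bind_rows(a, mk("S2", c(0, 0, 0, 40)))
  mi2 <- mean_daily_intake(c2, "g", n_days = 4, denominator = "all")
  expect_equal(mi2$mean, (25 + 10) / 2)

  expect_error(mean_daily_intake(a, "no such group"), "unknown food group")
})

test_that("consumption frequency is appearances divided by survey days", {
  rows <- mini_augmented(rep(0, 6), rep(10, 6))
  rows$day_index <- as.integer(c(1, 1, 2, 3, 4, 4))
  cf <- consumption_frequency(rows, "1", by = "food_code", n_days = 4)
  expect_equal(cf$per_subject$per_day, 0.25)
  cf_g <- consumption_frequency(rows, "g", by = "food_group", n_days = 4)
  expect_equal(cf_g$per_subject$per_day, 1.5) # 6 appearances over 4 days
  expect_equal(cf_g$sample_total_per_day, 6 / 4)
  cf_0 <- consumption_frequency(rows, "absent", by = "food_group", n_days = 4)
  expect_equal(cf_0$per_subject$per_day, 0)

  st <- small_study(seed = 23)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  a <- apply_mapping(st$diary, m)
  gname <- a$food_group[1]
  cf_s <- consumption_frequency(a, gname, by = "food_group", n_days = 4)
  expect_equal(cf_s$sample_total_per_day, sum(a$food_group == gname) / 4)
})

test_that("aggregate_summary reports the standard seven statistics", {
  s <- aggregate_summary(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)

  s2 <- aggregate_summary(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s2$sem, sqrt(5 / 3) / 2, tolerance = 1e-12)
  expect_equal(s2$q25, 1.75) # type-7 linear interpolation
  expect_equal(s2$q75, 3.25)
  expect_equal(c(s2$min, s2$max), c(1, 4))

  expect_error(aggregate_summary(numeric()), "at least one")
  s1 <- aggregate_summary(7)
  expect_true(is.na(s1$sd) && is.na(s1$sem))
})

test_that("the group report lists non-covered groups by consumption count", {
  st <- small_study(seed = 25)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  a <- apply_mapping(st$diary, m)
  rep_tbl <- group_noncovered_report(a, n_days = 4)
  # fully covered groups are excluded from the non-covered view
  expect_true(all(rep_tbl$pct_noncov_freq > 0))
  expect_equal(rep_tbl$n_eo, sort(rep_tbl$n_eo, decreasing = TRUE))
  # EO counts agree with a direct recount
  for (i in seq_len(min(3, nrow(rep_tbl)))) {
    expect_equal(rep_tbl$n_eo[i], sum(a$food_group == rep_tbl$food_group[i]))
  }
})

test_that("averaged subject-day ratios and pooled fractions are distinct statistics", {
  a <- dplyr::bind_rows(
    mini_augmented(c(1, 0), c(10, 10), day = 1L), # day ratio 0.5 over 2 EOs
    mini_augmented(rep(0, 8), rep(10, 8), day = 2L) # day ratio 0 over 8 EOs
  )
  cv <- daily_coverage_ratios(a)
  expect_equal(mean(cv$freq_ratio), 0.25)
  expect_equal(pooled_noncovered_fractions(a)$freq_fraction_pooled, 0.1)
})
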