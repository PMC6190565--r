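# The seeded generator: structure, determinism, planted truth, calibration.

test_that("default dimensions reproduce the source-survey structure", {
  cfg <- synth_config(seed = 1)
  co <- generate_catalogue(cfg)
  expect_equal(nrow(co$catalogue), 1652)
  expect_equal(length(unique(co$catalogue$food_group)), 77)
  expect_equal(nrow(co$sfq), 15)
  expect_false(anyDuplicated(co$catalogue$food_code) > 0)
  expect_equal(co$truth$food_code, co$catalogue$food_code)
})

test_that("the generator is deterministic given its seed", {
  cfg <- synth_config(n_codes = 150, n_groups = 25, n_subjects = 10, seed = 77)
  co1 <- generate_catalogue(cfg)
  co2 <- generate_catalogue(cfg)
  expect_identical(co1$catalogue, co2$catalogue)
  expect_identical(co1$truth, co2$truth)
  d1 <- generate_diary(cfg, co1)
  d2 <- generate_diary(cfg, co2)
  expect_identical(d1, d2)
  # a different seed changes the draw
  co3 <- generate_catalogue(synth_config(n_codes = 150, n_groups = 25, n_subjects = 10, seed = 78))
  expect_false(identical(co1$catalogue$food_name, co3$catalogue$food_name))
})

test_that("without typos every mappable name is built verbatim from its templates", {
  cfg <- synth_config(n_codes = 200, n_groups = 25, typo_rate = 0, seed = 5)
  co <- generate_catalogue(cfg)
  phrases <- unlist(co$sfq$include_keywords)
  quals <- dietmap:::synth_qualifiers()
  templates <- c(phrases, as.vector(outer(phrases, quals, paste)))
  mappable <- !is.na(co$truth$true_group)
  expect_true(all(co$catalogue$food_name[mappable] %in% templates))
})

test_that("the diary covers every subject-day with valid weekday windows", {
  st <- small_study(seed = 9)
  d <- st$diary
  sd_tbl <- unique(d[, c("subject_id", "day_index")])
  expect_equal(nrow(sd_tbl), 15 * 4)
  expect_true(all(d$amount_g > 0))
  # weekend guarantee: every subject sees Sat or Sun
  by_subj <- split(d$weekday, d$subject_id)
  expect_true(all(vapply(by_subj, function(w) any(w %in% c("Sat", "Sun")), logical(1))))
})

test_that("all seven weekdays occur at the full sample size", {
  cfg <- synth_config(n_codes = 100, n_groups = 20, n_subjects = 126, seed = 2)
  co <- generate_catalogue(cfg)
  d <- generate_diary(cfg, co)
  expect_setequal(unique(d$weekday), weekday_levels())
})

test_that("extreme design fractions produce all-mappable or all-non-covered diaries", {
  cfg0 <- synth_config(
    n_codes = 100, n_groups = 20, n_subjects = 8,
    target_noncov_freq = 0, seed = 3
  )
  co0 <- generate_catalogue(cfg0)
  d0 <- generate_diary(cfg0, co0)
  gt0 <- ground_truth_coverage(co0, d0)
  expect_equal(gt0$freq_fraction, 0)
  expect_equal(gt0$amount_fraction, 0)

  cfg1 <- synth_config(
    n_codes = 100, n_groups = 20, n_subjects = 8,
    target_noncov_freq = 1, seed = 3
  )
  co1 <- generate_catalogue(cfg1)
  d1 <- generate_diary(cfg1, co1)
  gt1 <- ground_truth_coverage(co1, d1)
  expect_equal(gt1$freq_fraction, 1)
  expect_equal(gt1$amount_fraction, 1)
})

test_that("ground-truth coverage equals a direct recount over diary rows", {
  st <- small_study(seed = 4)
  gt <- ground_truth_coverage(st$cat, st$diary)
  noncov <- is.na(st$cat$truth$true_group[match(st$diary$food_code, st$cat$truth$food_code)])
  expect_equal(gt$freq_fraction, mean(noncov))
  expect_equal(
    gt$amount_fraction,
    sum(st$diary$amount_g[noncov]) / sum(st$diary$amount_g)
  )
  expect_error(
    ground_truth_coverage(st$cat, dplyr::mutate(st$diary, food_code = "nope")),
    "unknown"
  )
})

test_that("per-group amounts converge to the configured moments", {
  # crank the eating-occasion volume up to pin the lognormal moments down
  cfg <- synth_config(
    n_codes = 60, n_groups = 16, n_subjects = 40, eo_mean = 60,
    target_noncov_freq = 0.5, seed = 6
  )
  co <- generate_catalogue(cfg)
  d <- generate_diary(cfg, co)
  am <- co$amount_model
  big <- names(sort(table(d$food_group), decreasing = TRUE))[1:3]
  for (g in big) {
    v <- d$amount_g[d$food_group == g]
    i <- match(g, am$food_group)
    se <- am$sd_g[i] / sqrt(length(v))
    expect_lt(abs(mean(v) - am$mean_g[i]), 5 * se)
    expect_lt(abs(sd(v) - am$sd_g[i]) / am$sd_g[i], 0.25)
  }
})

test_that("the pipeline reproduces planted coverage exactly when names are faithful", {
  st <- small_study(seed = 10)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  a <- apply_mapping(st$diary, m)
  cv <- daily_coverage_ratios(a)
  gt <- ground_truth_coverage(st$cat, st$diary)
  expect_identical(mean(cv$freq_ratio), gt$mean_day_freq_ratio)
  expect_equal(cv$freq_ratio, gt$per_day$freq_ratio)
  expect_equal(cv$amount_ratio, gt$per_day$amount_ratio)
})

test_that("typos degrade mapping accuracy, and the fuzzy step only helps", {
  rates <- c(0, 0.1, 0.3)
  acc <- vapply(rates, function(r) {
    mean(vapply(1:3, function(s) {
      cfg <- synth_config(n_codes = 300, n_groups = 30, typo_rate = r, seed = s)
      co <- generate_catalogue(cfg)
      m <- build_mapping_table(co$catalogue, co$sfq)
      mapping_accuracy(m, co$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) < 0)) # decreasing in the typo rate

  with_without <- vapply(1:3, function(s) {
    cfg <- synth_config(n_codes = 300, n_groups = 30, typo_rate = 0.1, seed = s)
    co <- generate_catalogue(cfg)
    mf <- build_mapping_table(co$catalogue, co$sfq, match_config(use_fuzzy = TRUE))
    mn <- build_mapping_table(co$catalogue, co$sfq, match_config(use_fuzzy = FALSE))
    c(mapping_accuracy(mf, co$truth), mapping_accuracy(mn, co$truth))
  }, numeric(2))
  expect_gte(mean(with_without[1, ]), mean(with_without[2, ]))
})

test_that("invalid configurations are rejected up front", {
  expect_error(synth_config(n_groups = 0), ">= 1")
  expect_error(synth_config(n_codes = 10, n_groups = 20), "may not exceed")
  expect_error(synth_config(typo_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(eo_mean = -1), "positive")
})
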