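# The stepwise mapping algorithm: normalization, similarity, the four
# matching steps, table construction, partial fractions, repeatability.

test_that("normalization lowercases, strips punctuation and honours stopwords", {
  expect_equal(
    normalize_text("Full fat cheese/yogurt/fromage frais"),
    c("full", "fat", "cheese", "yogurt", "fromage", "frais")
  )
  expect_equal(normalize_text(""), character())
  expect_equal(normalize_text(NA_character_), character())
  expect_equal(
    normalize_text("Hot chips or French fries!", stopwords = "or"),
    c("hot", "chips", "french", "fries")
  )
})

test_that("similarity follows the normalized-Levenshtein formula", {
  expect_equal(similarity("chips", "chips"), 1)
  expect_equal(similarity("chips", ""), 0)
  expect_equal(similarity("", ""), 1)
  expect_equal(similarity("hot chips", "hot chps"), 1 - 1 / 9)
  expect_equal(similarity("a b", "b a"), similarity("b a", "a b")) # symmetric
})

test_that("similarity agrees with an independent DP oracle on random pairs", {
  set.seed(2024)
  for (i in 1:200) {
    a <- random_food_string()
    b <- if (runif(1) < 0.3) a else random_food_string()
    expect_equal(similarity(a, b), sim_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("the exact step matches labels and include phrases only", {
  g <- gui_sfq_groups()
  expect_equal(exact_match_step("sweets", g), "C25m")
  expect_equal(exact_match_step("SWEETS!", g), "C25m") # normalization first
  expect_true(is.na(exact_match_step("Ready-to-eat breakfast cereals", g)))
  expect_true(is.na(exact_match_step("", g)))
})

test_that("the fuzzy step scores against labels and phrases with review flags", {
  g <- tiny_sfq()
  g$label[1] <- "Crisps or savor snacks"
  g$include_keywords[[1]] <- "crisps"
  hit <- fuzzy_match_step("crisps or savoury snacks", g, match_config())
  expect_equal(hit$group_code, "G1")
  expect_equal(hit$similarity, 1 - 2 / 24) # "savoury" -> "savor" is 2 edits
  expect_true(hit$needs_review) # inside the (0.85, 0.95) band

  exact <- fuzzy_match_step("Crisps or savor snacks", g, match_config())
  expect_equal(exact$similarity, 1)
  expect_false(exact$needs_review)

  expect_null(fuzzy_match_step("eggs", g, match_config()))
})

test_that("token search walks name then description and honours exclusions", {
  g <- gui_sfq_groups()
  expect_equal(token_search_step("side dish", "with sausage", g), "C25i")
  expect_true(is.na(token_search_step("fruit juices", "", g))) # juice excluded
  expect_true(is.na(token_search_step("porridge", "oats", g)))
  # exclusion looks at all input tokens, including the description
  expect_true(is.na(token_search_step("fruit", "pressed juices", g)))
  # hot chips must not fall into the hot-dog group
  expect_equal(token_search_step("hot chips", "", g), "C25j")
  expect_equal(token_search_step("hot dog", "", g), "C25i")
})

test_that("map_food_code applies the steps strictly in order", {
  g <- gui_sfq_groups()
  e <- map_food_code(list(food_code = "17377", food_name = "sweets"), g)
  expect_equal(e$status, "covered")
  expect_equal(e$target_group, "C25m")
  expect_equal(e$match_step, "exact_name")
  expect_equal(e$coverage_fraction, 1)
  expect_false(e$needs_review)

  # exact name wins even when another group would match fuzzily
  e2 <- map_food_code(
    list(food_code = "1", food_name = "sweets", food_description = "hot chips"),
    g
  )
  expect_equal(e2$match_step, "exact_name")
  expect_equal(e2$target_group, "C25m")

  # no step matches: non-covered with no target
  e3 <- map_food_code(list(food_code = "11453", food_name = "ready to eat breakfast cereals"), g)
  expect_equal(e3$status, "non_covered")
  expect_equal(e3$match_step, "none")
  expect_true(is.na(e3$target_group))
  expect_equal(e3$coverage_fraction, 0)

  # cooking-method tokens take part in the token search
  e4 <- map_food_code(
    list(food_code = "2", food_name = "side dish", cooking_method = "fried sausage"),
    g
  )
  expect_equal(e4$target_group, "C25i")
  expect_equal(e4$match_step, "token")
  expect_true(e4$needs_review)

  expect_error(map_food_code(list(food_code = "3", food_name = ""), g), "empty name")
})

test_that("build_mapping_table yields one verdict per code and applies overrides", {
  g <- tiny_sfq()
  cat10 <- tibble::tibble(
    food_code = as.character(1:10),
    food_name = c(
      "sweets", "jellies toffee", "hamburger", "fresh fruit", "banana split",
      "porridge", "white bread", "meat pie special", "rice cakes plain", "yeast extract"
    ),
    food_group = rep(c("confectionery", "other"), each = 5)
  )
  m <- build_mapping_table(cat10, g)
  expect_equal(nrow(m), 10)
  expect_equal(sum(m$status == "non_covered"), 4)

  ov <- tibble::tibble(
    food_code = "6", status = "covered", target_group = "G3", coverage_fraction = 1
  )
  m2 <- build_mapping_table(cat10, g, manual_overrides = ov)
  expect_equal(m2$status[m2$food_code == "6"], "covered")
  expect_equal(m2$match_step[m2$food_code == "6"], "manual")

  ov_bad <- tibble::tibble(
    food_code = "99", status = "covered", target_group = "G3", coverage_fraction = 1
  )
  expect_error(build_mapping_table(cat10, g, manual_overrides = ov_bad), "unknown food code")

  expect_error(
    build_mapping_table(cat10[c(1, 1, 2), ], g), "duplicate food_code"
  )
})

test_that("the mapping is deterministic and vectorization matches the row-wise path", {
  st <- small_study(seed = 21, typo_rate = 0.1)
  m1 <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  m2 <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  expect_identical(m1, m2)

  rows <- dplyr::bind_rows(lapply(
    seq_len(nrow(st$cat$catalogue)),
    function(i) map_food_code(st$cat$catalogue[i, ], st$cat$sfq)
  ))
  expect_equal(as.data.frame(rows), as.data.frame(m1))
})

test_that("exact matches keep precedence whatever the other steps would say", {
  st <- small_study(seed = 8, typo_rate = 0.2)
  m <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  g <- st$cat$sfq
  for (i in seq_len(nrow(st$cat$catalogue))) {
    hit <- exact_match_step(st$cat$catalogue$food_name[i], g)
    if (!is.na(hit)) {
      expect_equal(m$match_step[i], "exact_name")
      expect_equal(m$target_group[i], hit)
    }
  }
})

test_that("raising the fuzzy threshold never turns non-covered into covered", {
  st <- small_study(seed = 13, typo_rate = 0.15)
  lo <- build_mapping_table(st$cat$catalogue, st$cat$sfq, match_config(fuzzy_threshold = 0.7))
  hi <- build_mapping_table(st$cat$catalogue, st$cat$sfq, match_config(fuzzy_threshold = 0.9))
  covered_hi <- hi$food_code[hi$status == "covered"]
  covered_lo <- lo$food_code[lo$status == "covered"]
  expect_true(all(covered_hi %in% covered_lo))
})

test_that("group-level partial fractions count member codes, optionally weighted", {
  g <- tiny_sfq()
  cat8 <- tibble::tibble(
    food_code = as.character(1:8),
    food_name = c("fresh fruit", "banana", "fruit", rep("stewed compote", 5)),
    food_group = "other fruit"
  )
  m <- build_mapping_table(cat8, g)
  res <- assign_partial_fraction("other fruit", cat8, m)
  expect_equal(res$n_codes, 8)
  expect_equal(res$n_covered, 3)
  expect_equal(res$noncov_fraction_count, 5 / 8)

  # consumption-weighted variant: unmapped codes eaten more often
  diary <- tibble::tibble(food_code = c("1", "4", "4", "5", "6"))
  res_w <- assign_partial_fraction("other fruit", cat8, m, diary = diary)
  expect_equal(res_w$noncov_fraction_weighted, 4 / 5)

  # stamping mixed codes produces valid partial entries
  res_m <- assign_partial_fraction("other fruit", cat8, m, mixed_codes = c("4", "5"))
  stamped <- res_m$mapping[res_m$mapping$food_code %in% c("4", "5"), ]
  expect_true(all(stamped$status == "partial"))
  expect_equal(stamped$coverage_fraction, rep(3 / 8, 2))
  expect_silent(dietmap:::validate_mapping_entries(res_m$mapping))

  # degenerate groups: none or all mapped
  cat_none <- tibble::tibble(
    food_code = as.character(1:5), food_name = "porridge", food_group = "cereal"
  )
  m_none <- build_mapping_table(cat_none, g)
  expect_equal(assign_partial_fraction("cereal", cat_none, m_none)$noncov_fraction_count, 1)
  cat_all <- tibble::tibble(
    food_code = as.character(1:4), food_name = "banana", food_group = "fruit"
  )
  m_all <- build_mapping_table(cat_all, g)
  expect_equal(assign_partial_fraction("fruit", cat_all, m_all)$noncov_fraction_count, 0)

  expect_error(assign_partial_fraction("no such group", cat8, m), "unknown")
})

test_that("mapping comparison reports discordant codes symmetrically", {
  st <- small_study(seed = 31)
  a <- build_mapping_table(st$cat$catalogue, st$cat$sfq)
  expect_equal(compare_mappings(a, a)$n_discordant, 0)

  b <- a
  i <- which(b$status == "covered")[1]
  b$status[i] <- "non_covered"
  b$target_group[i] <- NA_character_
  b$coverage_fraction[i] <- 0
  b$match_step[i] <- "none"
  b$similarity[i] <- NA_real_
  cmp <- compare_mappings(a, b)
  expect_equal(cmp$n_discordant, 1)
  expect_equal(cmp$discordant_codes, a$food_code[i])
  cmp_rev <- compare_mappings(b, a)
  expect_equal(cmp_rev$n_discordant, 1)

  expect_error(compare_mappings(a, a[-1, ]), "different code sets")
})
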