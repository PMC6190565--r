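# Seeded synthetic-data generator: food catalogues, questionnaire
# definitions and multi-day weighed diaries with planted ground truth, so
# every pipeline stage can be validated without the access-restricted survey
# microdata. Defaults emulate the source surveys' structure: 1,652 food codes
# in 77 catalogue groups, 15 questionnaire groups, 126 subjects keeping a
# 4-day diary with at least one weekend day.

#' Synthetic-study configuration
#'
#' @param n_codes Number of catalogue food codes (default 1652).
#' @param n_groups Number of catalogue food groups (default 77).
#' @param n_sfq_groups Number of questionnaire groups used, taken in order
#'   from the bundled definition (default 15, the full instrument).
#' @param n_subjects Number of diary subjects (default 126).
#' @param n_days Diary days per subject (default 4).
#' @param typo_rate Probability that a mappable food name receives one
#'   character-level perturbation (substitution or deletion); default 0
#'   (faithful names — typos are the perturbation that exercises the fuzzy
#'   step).
#' @param target_noncov_freq Design probability that an eating occasion draws
#'   a truly non-covered food (default 0.44).
#' @param eo_mean,eo_dispersion Mean and negative-binomial size of the
#'   eating-occasions count per subject-day (defaults 12 and 8: overdispersed
#'   counts typical of diary data).
#' @param p_exact_name Probability a mappable food name is the bare keyword
#'   phrase (exactly matchable) rather than phrase plus a qualifier word
#'   (token-matchable); default 0.5.
#' @param prop_groups_mappable Share of catalogue groups whose codes are
#'   truly mappable to a questionnaire group (default 0.5; never below
#'   `n_sfq_groups` groups).
#' @param weekday_assignment `"consecutive"` (each subject records
#'   `n_days` consecutive weekdays from a random start; default) or
#'   `"random"` (independent weekday per day).
#' @param weekend_guarantee With consecutive assignment, restrict starts so
#'   every subject's window includes a weekend day (default `TRUE`, as the
#'   source survey required).
#' @param amount_model Optional tibble (`food_group`, `mean_g`, `sd_g`)
#'   overriding the per-group eating-occasion amount distribution; by default
#'   non-covered groups follow the published per-group means/SDs and
#'   questionnaire-mappable groups use typical preschool portion sizes.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_codes = 1652, n_groups = 77, n_sfq_groups = 15,
                         n_subjects = 126, n_days = 4,
                         typo_rate = 0, target_noncov_freq = 0.44,
                         eo_mean = 12, eo_dispersion = 8,
                         p_exact_name = 0.5, prop_groups_mappable = 0.5,
                         weekday_assignment = c("consecutive", "random"),
                         weekend_guarantee = TRUE,
                         amount_model = NULL, seed = 1) {
  weekday_assignment <- match.arg(weekday_assignment)
  counts <- c(
    n_codes = n_codes, n_groups = n_groups, n_sfq_groups = n_sfq_groups,
    n_subjects = n_subjects, n_days = n_days
  )
  if (any(counts < 1)) abort_dietmap("all counts must be >= 1")
  if (n_groups > n_codes) abort_dietmap("n_groups (%d) may not exceed n_codes (%d)", n_groups, n_codes)
  probs <- c(
    typo_rate = typo_rate, target_noncov_freq = target_noncov_freq,
    p_exact_name = p_exact_name, prop_groups_mappable = prop_groups_mappable
  )
  if (any(probs < 0 | probs > 1)) abort_dietmap("probabilities must lie in [0, 1]")
  if (eo_mean <= 0 || eo_dispersion <= 0) abort_dietmap("eo_mean and eo_dispersion must be positive")
  if (!is.null(amount_model) && any(amount_model$mean_g <= 0)) {
    abort_dietmap("amount_model means must be positive")
  }
  structure(
    list(
      n_codes = as.integer(n_codes), n_groups = as.integer(n_groups),
      n_sfq_groups = as.integer(n_sfq_groups),
      n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
      typo_rate = typo_rate, target_noncov_freq = target_noncov_freq,
      eo_mean = eo_mean, eo_dispersion = eo_dispersion,
      p_exact_name = p_exact_name, prop_groups_mappable = prop_groups_mappable,
      weekday_assignment = weekday_assignment,
      weekend_guarantee = isTRUE(weekend_guarantee),
      amount_model = amount_model, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf(
    "  catalogue: %d codes in %d groups (%d SFQ groups)\n",
    x$n_codes, x$n_groups, x$n_sfq_groups
  ))
  cat(sprintf("  diary:     %d subjects x %d days\n", x$n_subjects, x$n_days))
  cat(sprintf(
    "  design:    noncov freq %.2f, typo rate %.2f, seed %d\n",
    x$target_noncov_freq, x$typo_rate, x$seed
  ))
  invisible(x)
}

# Vocabulary of truly non-covered catalogue groups. The first rows carry the
# published per-group eating-occasion counts and daily amounts of the most
# commonly consumed non-covered items; the remainder are realistic filler
# groups with a common weight. Tokens are chosen so no name can reach a
# questionnaire group through the token step (the fresh-fruit exclusion of
# "juice"/"juices" blocks fruit juices).
noncov_vocabulary <- function() {
  tibble::tribble(
    ~label, ~eo_weight, ~mean_g, ~sd_g,
    "ready to eat breakfast cereals", 351, 31, 17,
    "white sliced bread and rolls", 239, 61, 34,
    "other spreading fats", 224, 8, 5,
    "wholemeal and brown bread and rolls", 192, 50, 29,
    "fruit juices", 190, 173, 123,
    "soups sauces and miscellaneous foods", 190, 52, 71,
    "potatoes", 163, 79, 46,
    "sugars syrups preserves and sweeteners", 158, 12, 13,
    "bacon and ham", 148, 30, 25,
    "rice and pasta flours grains and starch", 131, 86, 57,
    "supplements", 124, 106, 60,
    "butter", 90, 9, 8,
    "ice creams", 89, 57, 25,
    "beef and veal dishes", 88, 129, 82,
    "chicken turkey and game", 87, 44, 26,
    "other breakfast cereals", 83, 130, 83,
    "eggs and egg dishes", 64, 60, 30,
    "fish and fish products", 62, 62, 32,
    "tea and coffee", 50, 50, 30,
    "herbs and spices", 50, 50, 30,
    "nuts and seeds", 50, 50, 30,
    "baby foods", 50, 50, 30,
    "pizza and garlic bread", 50, 50, 30,
    "noodle dishes", 50, 50, 30,
    "couscous and bulgur", 50, 50, 30,
    "crackers and crispbreads", 50, 50, 30,
    "scones and pastries", 50, 50, 30,
    "jams and marmalades", 50, 50, 30,
    "honey", 50, 50, 30,
    "raisins and sultanas", 50, 50, 30,
    "smoothies", 50, 50, 30,
    "porridge oats", 50, 50, 30,
    "yeast extract", 50, 50, 30,
    "custard and jelly", 50, 50, 30,
    "stuffing and dumplings", 50, 50, 30,
    "gravies and stocks", 50, 50, 30,
    "pickles and chutneys", 50, 50, 30,
    "breakfast bars", 50, 50, 30,
    "rusks", 50, 50, 30
  )
}

# Typical preschool eating-occasion portion sizes (grams) per questionnaire
# group, for the truly mappable catalogue groups.
mappable_amounts <- function() {
  tibble::tribble(
    ~group_code, ~mean_g, ~sd_g,
    "C25a", 80, 40,
    "C25b", 60, 30,
    "C25c", 40, 25,
    "C25d", 60, 35,
    "C25e", 60, 35,
    "C25f", 150, 70,
    "C25g", 150, 70,
    "C25h", 180, 90,
    "C25i", 70, 40,
    "C25j", 90, 50,
    "C25k", 25, 12,
    "C25l", 35, 20,
    "C25m", 20, 12,
    "C25n", 150, 80,
    "C25o", 150, 80
  )
}

# Qualifier words and cooking methods usable in any generated name without
# ever hitting an include or exclude keyword of the questionnaire fixture.
synth_qualifiers <- function() {
  c(
    "homemade", "tinned", "frozen", "grilled", "baked", "boiled",
    "steamed", "fried", "toasted", "organic", "mashed", "chilled"
  )
}

synth_cooking_methods <- function() {
  c("grilled", "baked", "boiled", "steamed", "fried", "roasted", "microwaved")
}

# One character-level perturbation: substitution or deletion at a random
# position (the minimal family that exercises the fuzzy step).
perturb_name <- function(s) {
  nc <- nchar(s)
  if (nc < 2) {
    return(s)
  }
  pos <- sample.int(nc, 1)
  if (runif(1) < 0.5) {
    substr(s, pos, pos) <- sample(letters, 1)
    s
  } else {
    paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nc))
  }
}

sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1, prob = prob)]

#' Generate a synthetic food catalogue with planted ground truth
#'
#' Partitions `n_codes` food codes into `n_groups` catalogue groups. A
#' configured share of groups is truly mappable to a questionnaire group
#' (member names built from that group's include-keyword phrases, optionally
#' with a neutral qualifier word, optionally perturbed by a typo); the rest
#' are truly non-covered, named from a disjoint vocabulary of
#' detailed-survey food groups (breakfast cereals, fruit juices, ...).
#' Deterministic given the configuration seed.
#'
#' @param cfg A [synth_config()].
#' @param sfq Questionnaire definition tibble (default [gui_sfq_groups()]);
#'   the first `cfg$n_sfq_groups` groups are used.
#' @return A list of class `synth_catalogue`: `catalogue` (tibble
#'   `food_code`, `food_name`, `food_description`, `cooking_method`,
#'   `food_group`), `truth` (tibble `food_code`, `true_group` — `NA` for
#'   truly non-covered codes — and `food_group`), `amount_model` (per-group
#'   `mean_g`, `sd_g`, `eo_weight`, `mappable`), and the `sfq` definition
#'   used.
#' @export
generate_catalogue <- function(cfg, sfq = gui_sfq_groups()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_sfq_groups > nrow(sfq)) {
    abort_dietmap(
      "n_sfq_groups (%d) exceeds the supplied SFQ definition (%d groups)",
      cfg$n_sfq_groups, nrow(sfq)
    )
  }
  sfq <- sfq[seq_len(cfg$n_sfq_groups), , drop = FALSE]
  n_map_groups <- max(cfg$n_sfq_groups, round(cfg$n_groups * cfg$prop_groups_mappable))
  n_map_groups <- min(n_map_groups, cfg$n_groups)
  n_nc_groups <- cfg$n_groups - n_map_groups

  vocab <- noncov_vocabulary()
  if (n_nc_groups > nrow(vocab)) { # recycle with a distinguishing suffix
    reps <- ceiling(n_nc_groups / nrow(vocab))
    vocab <- dplyr::bind_rows(lapply(seq_len(reps), function(r) {
      v <- noncov_vocabulary()
      if (r > 1) v$label <- paste(v$label, "variant", r)
      v
    }))
  }
  vocab <- vocab[seq_len(n_nc_groups), , drop = FALSE]

  qualifiers <- synth_qualifiers()
  cooking <- synth_cooking_methods()

  local_seed(cfg$seed, {
    # group scaffolding: mappable groups cycle through the SFQ groups
    sfq_idx <- ((seq_len(n_map_groups) - 1) %% cfg$n_sfq_groups) + 1
    map_labels <- sprintf(
      "%s [catalogue group %02d]",
      tolower(sfq$label[sfq_idx]), seq_len(n_map_groups)
    )
    group_labels <- c(map_labels, vocab$label)
    group_true <- c(sfq$group_code[sfq_idx], rep(NA_character_, n_nc_groups))

    # code counts per group: as even as possible
    base <- cfg$n_codes %/% cfg$n_groups
    counts <- rep(base, cfg$n_groups)
    rem <- cfg$n_codes - base * cfg$n_groups
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1

    rows <- vector("list", cfg$n_groups)
    code_no <- 0
    for (g in seq_len(cfg$n_groups)) {
      k <- counts[g]
      mappable <- !is.na(group_true[g])
      if (mappable) {
        phrases <- sfq$include_keywords[[match(group_true[g], sfq$group_code)]]
        base_names <- vapply(seq_len(k), function(i) sample1(phrases), character(1))
      } else {
        base_names <- rep(vocab$label[g - n_map_groups], k)
      }
      with_qual <- runif(k) >= cfg$p_exact_name
      names_k <- ifelse(
        with_qual,
        paste(base_names, vapply(seq_len(k), function(i) sample1(qualifiers), character(1))),
        base_names
      )
      if (mappable && cfg$typo_rate > 0) {
        hit <- runif(k) < cfg$typo_rate
        names_k[hit] <- vapply(names_k[hit], perturb_name, character(1), USE.NAMES = FALSE)
      }
      desc_k <- ifelse(
        runif(k) < 0.3,
        vapply(seq_len(k), function(i) sample1(qualifiers), character(1)),
        ""
      )
      cook_k <- ifelse(
        runif(k) < 0.5,
        vapply(seq_len(k), function(i) sample1(cooking), character(1)),
        ""
      )
      rows[[g]] <- tibble::tibble(
        food_code = as.character(10000 + code_no + seq_len(k)),
        food_name = names_k,
        food_description = desc_k,
        cooking_method = cook_k,
        food_group = group_labels[g],
        true_group = group_true[g]
      )
      code_no <- code_no + k
    }
    cat_full <- dplyr::bind_rows(rows)

    map_am <- mappable_amounts()
    am_idx <- match(sfq$group_code[sfq_idx], map_am$group_code)
    amount_model <- dplyr::bind_rows(
      tibble::tibble(
        food_group = map_labels,
        mean_g = ifelse(is.na(am_idx), 60, map_am$mean_g[am_idx]),
        sd_g = ifelse(is.na(am_idx), 30, map_am$sd_g[am_idx]),
        eo_weight = 1,
        mappable = TRUE
      ),
      tibble::tibble(
        food_group = vocab$label,
        mean_g = vocab$mean_g,
        sd_g = vocab$sd_g,
        eo_weight = vocab$eo_weight,
        mappable = FALSE
      )
    )
    if (!is.null(cfg$amount_model)) {
      ov <- cfg$amount_model
      idx <- match(ov$food_group, amount_model$food_group)
      if (any(is.na(idx))) {
        abort_dietmap(
          "amount_model overrides unknown group(s): %s",
          paste(ov$food_group[is.na(idx)], collapse = ", ")
        )
      }
      amount_model$mean_g[idx] <- ov$mean_g
      amount_model$sd_g[idx] <- ov$sd_g
    }

    structure(
      list(
        catalogue = cat_full[, c(
          "food_code", "food_name", "food_description",
          "cooking_method", "food_group"
        )],
        truth = cat_full[, c("food_code", "true_group", "food_group")],
        amount_model = amount_model,
        sfq = sfq
      ),
      class = "synth_catalogue"
    )
  })
}

#' @export
print.synth_catalogue <- function(x, ...) {
  cat("<synth_catalogue>\n")
  cat(sprintf(
    "  %d codes in %d groups; %d codes truly mappable to %d SFQ groups\n",
    nrow(x$catalogue), length(unique(x$catalogue$food_group)),
    sum(!is.na(x$truth$true_group)), nrow(x$sfq)
  ))
  invisible(x)
}

#' Generate a synthetic multi-day weighed food diary
#'
#' For each subject-day, draws an eating-occasion count (negative binomial),
#' samples each occasion's food code — truly non-covered with probability
#' `cfg$target_noncov_freq`, with group weights inside each stratum — and
#' samples the amount from the group's lognormal model (moment-matched to
#' the configured mean/SD, so amounts are positive). Weekdays follow the
#' configured layout; with the weekend guarantee every subject's consecutive
#' window contains Saturday or Sunday, and all seven weekdays occur
#' sample-wide. Deterministic given the configuration seed (which is also
#' used, offset, by [generate_catalogue()]; the two draws are independent).
#'
#' @param cfg A [synth_config()].
#' @param catalogue A `synth_catalogue` from [generate_catalogue()] built
#'   from the same `cfg`.
#' @return Diary tibble in the canonical layout of [read_food_diary()].
#' @export
generate_diary <- function(cfg, catalogue) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!inherits(catalogue, "synth_catalogue")) {
    abort_dietmap("generate_diary() expects the list returned by generate_catalogue()")
  }
  cat_tbl <- catalogue$catalogue
  if (nrow(cat_tbl) == 0) abort_dietmap("catalogue is empty")
  am <- catalogue$amount_model

  codes_by_group <- split(cat_tbl$food_code, cat_tbl$food_group)
  map_groups <- am$food_group[am$mappable]
  nc_groups <- am$food_group[!am$mappable]
  w_map <- am$eo_weight[am$mappable]
  w_nc <- am$eo_weight[!am$mappable]
  # lognormal parameters moment-matched to (mean, sd)
  cv2 <- (am$sd_g / am$mean_g)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(am$mean_g) - sdlog^2 / 2
  names(sdlog) <- names(meanlog) <- am$food_group

  lvls <- weekday_levels()
  window_starts <- if (cfg$weekend_guarantee && cfg$weekday_assignment == "consecutive") {
    ok <- vapply(
      1:7,
      function(st) any(((((st - 1) + seq_len(cfg$n_days) - 1) %% 7) + 1) %in% c(6, 7)),
      logical(1)
    )
    which(ok)
  } else {
    1:7
  }

  local_seed(cfg$seed + 1, {
    subj_rows <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      sid <- sprintf("S%03d", s)
      wdays <- if (cfg$weekday_assignment == "consecutive") {
        st <- sample1(window_starts)
        lvls[(((st - 1) + seq_len(cfg$n_days) - 1) %% 7) + 1]
      } else {
        lvls[sample.int(7, cfg$n_days, replace = TRUE)]
      }
      day_rows <- vector("list", cfg$n_days)
      for (d in seq_len(cfg$n_days)) {
        k <- max(1L, rnbinom(1, size = cfg$eo_dispersion, mu = cfg$eo_mean))
        is_nc <- runif(k) < cfg$target_noncov_freq
        grp <- character(k)
        if (any(is_nc)) {
          grp[is_nc] <- nc_groups[sample.int(length(nc_groups), sum(is_nc),
            replace = TRUE, prob = w_nc
          )]
        }
        if (any(!is_nc)) {
          grp[!is_nc] <- map_groups[sample.int(length(map_groups), sum(!is_nc),
            replace = TRUE, prob = w_map
          )]
        }
        code <- vapply(grp, function(g) sample1(codes_by_group[[g]]), character(1),
          USE.NAMES = FALSE
        )
        amt <- rlnorm(k, meanlog = meanlog[grp], sdlog = sdlog[grp])
        day_rows[[d]] <- tibble::tibble(
          subject_id = sid,
          day_index = d,
          weekday = wdays[d],
          meal_type = sample(c("breakfast", "lunch", "dinner", "snack"), k,
            replace = TRUE, prob = c(0.2, 0.25, 0.25, 0.3)
          ),
          food_code = code,
          food_group = grp,
          amount_g = amt
        )
      }
      subj_rows[[s]] <- dplyr::bind_rows(day_rows)
    }
    diary <- dplyr::bind_rows(subj_rows)
    idx <- match(diary$food_code, cat_tbl$food_code)
    diary$food_name <- cat_tbl$food_name[idx]
    diary$food_description <- cat_tbl$food_description[idx]
    diary$cooking_method <- cat_tbl$cooking_method[idx]
    diary$day_index <- as.integer(diary$day_index)
    diary[, diary_columns()]
  })
}

#' Ground-truth coverage of a synthetic diary
#'
#' Recomputes, directly from the planted truth labels, the non-covered
#' fractions a perfect mapping would yield: pooled over all eating occasions
#' and as per-subject-day ratios (the recovery oracle for the pipeline).
#'
#' @param truth Truth tibble from [generate_catalogue()] (or the
#'   `synth_catalogue` itself).
#' @param diary Diary generated from the same truth.
#' @return A list: `freq_fraction`, `amount_fraction` (pooled),
#'   `mean_day_freq_ratio`, `mean_day_amount_ratio` (means of the
#'   per-subject-day ratios), and the `per_day` tibble.
#' @export
ground_truth_coverage <- function(truth, diary) {
  if (inherits(truth, "synth_catalogue")) truth <- truth$truth
  idx <- match(diary$food_code, truth$food_code)
  if (any(is.na(idx))) {
    abort_dietmap(
      "diary contains food code(s) unknown to the ground truth: %s",
      paste(head(unique(diary$food_code[is.na(idx)]), 10), collapse = ", ")
    )
  }
  noncov <- as.numeric(is.na(truth$true_group[idx]))
  per_day <- tibble::tibble(
    subject_id = diary$subject_id,
    day_index = diary$day_index,
    noncov = noncov,
    amount_g = diary$amount_g
  ) |>
    dplyr::group_by(.data$subject_id, .data$day_index) |>
    dplyr::summarise(
      freq_ratio = mean(.data$noncov),
      amount_ratio = ifelse(
        sum(.data$amount_g) > 0,
        sum(.data$amount_g * .data$noncov) / sum(.data$amount_g),
        NA_real_
      ),
      .groups = "drop"
    )
  list(
    freq_fraction = mean(noncov),
    amount_fraction = sum(diary$amount_g * noncov) / sum(diary$amount_g),
    mean_day_freq_ratio = mean(per_day$freq_ratio),
    mean_day_amount_ratio = mean(per_day$amount_ratio, na.rm = TRUE),
    per_day = per_day
  )
}
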