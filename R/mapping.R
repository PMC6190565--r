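# The stepwise unidirectional mapping algorithm: assign each catalogue food
# code to a questionnaire group, a partial coverage fraction, or non-covered.
# Steps are tried strictly in order: exact name match, exact description
# match, fuzzy match, token search; the first match wins.

#' Matching configuration
#'
#' @param fuzzy_threshold Minimum [similarity()] for the fuzzy step to accept
#'   a match, in `(0, 1]`. Default 0.85: a single-character typo in a short
#'   group label (~7+ characters) still matches, while unrelated labels do
#'   not.
#' @param stopwords Tokens removed during normalization (default none).
#' @param review_band Closed similarity interval `(lo, hi)` whose fuzzy
#'   matches are additionally flagged for human review (default
#'   `c(0.85, 0.95)`), standing in for the annotator verification of each
#'   matching step.
#' @param use_fuzzy Set `FALSE` to disable the fuzzy step entirely (ablation;
#'   the token step still runs).
#' @param tie_break Tie-breaking rule; only
#'   `"highest_similarity_then_group_order"` is defined: the highest
#'   similarity wins, and among equals the group listed first in the SFQ
#'   definition.
#'
#' @return An object of class `match_config`.
#' @export
match_config <- function(fuzzy_threshold = 0.85,
                         stopwords = character(),
                         review_band = c(0.85, 0.95),
                         use_fuzzy = TRUE,
                         tie_break = "highest_similarity_then_group_order") {
  if (!is.numeric(fuzzy_threshold) || length(fuzzy_threshold) != 1 ||
    fuzzy_threshold <= 0 || fuzzy_threshold > 1) {
    abort_dietmap("fuzzy_threshold must be a single number in (0, 1]")
  }
  if (length(review_band) != 2 || review_band[1] > review_band[2]) {
    abort_dietmap("review_band must be c(lo, hi) with lo <= hi")
  }
  tie_break <- match.arg(tie_break, "highest_similarity_then_group_order")
  structure(
    list(
      fuzzy_threshold = fuzzy_threshold,
      stopwords = as.character(stopwords),
      review_band = as.numeric(review_band),
      use_fuzzy = isTRUE(use_fuzzy),
      tie_break = tie_break
    ),
    class = "match_config"
  )
}

#' @export
print.match_config <- function(x, ...) {
  cat("<match_config>\n")
  cat("  fuzzy_threshold:", x$fuzzy_threshold, if (!x$use_fuzzy) "(fuzzy step disabled)", "\n")
  cat("  review_band:    [", x$review_band[1], ",", x$review_band[2], "]\n")
  cat("  stopwords:      ", if (length(x$stopwords)) paste(x$stopwords, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Precompute normalized labels, phrases and token sets for a set of SFQ
# groups; done once per mapping run.
prepare_groups <- function(groups, stopwords = character()) {
  n <- nrow(groups)
  labels_norm <- normalize_join(groups$label, stopwords)
  phrases <- groups$include_keywords
  include_tokens <- lapply(phrases, function(ph) {
    unique(unlist(strsplit(ph, " ", fixed = TRUE)))
  })
  exclude_tokens <- lapply(groups$exclude_keywords, function(ph) {
    unique(unlist(strsplit(ph, " ", fixed = TRUE)))
  })
  # exact-match dictionary: normalized label or include phrase -> first group
  keys <- c(labels_norm, unlist(phrases))
  key_group <- c(seq_len(n), rep(seq_len(n), vapply(phrases, length, integer(1))))
  keep <- !duplicated(keys)
  list(
    codes = groups$group_code,
    n = n,
    labels_norm = labels_norm,
    phrases = phrases,
    include_tokens = include_tokens,
    exclude_tokens = exclude_tokens,
    exact_keys = keys[keep],
    exact_group = key_group[keep],
    # per-group candidate strings for the fuzzy step (label + phrases)
    fuzzy_cand = lapply(seq_len(n), function(i) unique(c(labels_norm[i], phrases[[i]]))),
    stopwords = stopwords
  )
}

as_prepared <- function(groups, stopwords) {
  if (!is.data.frame(groups) && is.list(groups) && !is.null(groups[["exact_keys"]])) {
    groups
  } else {
    prepare_groups(groups, stopwords)
  }
}

#' Exact-match step
#'
#' Returns the code of the first group whose label or include phrase equals
#' the normalized input exactly, or `NA` if none does (empty input never
#' matches).
#'
#' @param text Food name or description.
#' @param groups SFQ definition tibble (see [read_sfq_definition()]).
#' @param stopwords Normalization stopwords.
#' @return Group code or `NA_character_`.
#' @export
exact_match_step <- function(text, groups, stopwords = character()) {
  prep <- as_prepared(groups, stopwords)
  key <- normalize_join(text, prep$stopwords)
  if (!nzchar(key)) {
    return(NA_character_)
  }
  i <- match(key, prep$exact_keys)
  if (is.na(i)) NA_character_ else prep$codes[prep$exact_group[i]]
}

#' Fuzzy-match step
#'
#' Computes [similarity()] between the input and every group label and
#' include phrase; returns the best-scoring group if its similarity reaches
#' the threshold, with ties broken by higher similarity then SFQ-definition
#' order. A winning similarity inside the review band carries
#' `needs_review = TRUE`.
#'
#' @param text Food name or description.
#' @param groups SFQ definition tibble.
#' @param cfg A [match_config()].
#' @return `NULL` if no candidate reaches the threshold, otherwise a list
#'   with `group_code`, `similarity`, `needs_review`.
#' @export
fuzzy_match_step <- function(text, groups, cfg = match_config()) {
  prep <- as_prepared(groups, cfg$stopwords)
  key <- normalize_join(text, prep$stopwords)
  if (!nzchar(key)) {
    return(NULL)
  }
  best_per_group <- vapply(
    prep$fuzzy_cand,
    function(cand) max(similarity_norm(key, cand)),
    numeric(1)
  )
  best <- max(best_per_group)
  if (best < cfg$fuzzy_threshold) {
    return(NULL)
  }
  winner <- which(best_per_group == best)[1] # earlier group wins ties
  list(
    group_code = prep$codes[winner],
    similarity = best,
    needs_review = best >= cfg$review_band[1] && best <= cfg$review_band[2]
  )
}

#' Token-search step
#'
#' Walks the tokens of the food name, then of the description, in order; for
#' each token, scans the groups in definition order and returns the first
#' group whose include-keyword tokens contain it, provided no input token
#' (from name or description) appears among that group's exclude keywords.
#'
#' @param name Food name.
#' @param desc Food description (cooking-method text may be appended by the
#'   caller).
#' @param groups SFQ definition tibble.
#' @param stopwords Normalization stopwords.
#' @return Group code or `NA_character_`.
#' @export
token_search_step <- function(name, desc, groups, stopwords = character()) {
  prep <- as_prepared(groups, stopwords)
  toks <- c(
    normalize_text(name, prep$stopwords),
    normalize_text(desc, prep$stopwords)
  )
  if (length(toks) == 0) {
    return(NA_character_)
  }
  blocked <- vapply(
    prep$exclude_tokens,
    function(ex) length(ex) > 0 && any(toks %in% ex),
    logical(1)
  )
  for (tok in toks) {
    for (g in seq_len(prep$n)) {
      if (!blocked[g] && tok %in% prep$include_tokens[[g]]) {
        return(prep$codes[g])
      }
    }
  }
  NA_character_
}

new_mapping_entry <- function(food_code, status, target_group, coverage_fraction,
                              match_step, similarity = NA_real_, needs_review = FALSE) {
  tibble::tibble(
    food_code = as.character(food_code),
    status = status,
    target_group = target_group,
    coverage_fraction = coverage_fraction,
    match_step = match_step,
    similarity = similarity,
    needs_review = needs_review
  )
}

# Verdict invariants shared by every producer/consumer of mapping entries.
validate_mapping_entries <- function(entries) {
  need <- mapping_columns()
  missing <- setdiff(need, names(entries))
  if (length(missing) > 0) {
    abort_dietmap("mapping entries lack column(s): %s", paste(missing, collapse = ", "))
  }
  if (nrow(entries) == 0) {
    return(invisible(entries))
  }
  bad <- function(cond, what) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      abort_dietmap(
        "invalid mapping entries (%s): %s", what,
        paste(head(entries$food_code[cond], 10), collapse = ", ")
      )
    }
  }
  bad(!nzchar(blank_text(entries$food_code)), "empty food_code")
  bad(duplicated(entries$food_code), "duplicate food_code")
  bad(!entries$status %in% c("covered", "partial", "non_covered"), "unknown status")
  f <- entries$coverage_fraction
  bad(is.na(f) | f < 0 | f > 1, "coverage_fraction outside [0,1]")
  bad(entries$status == "covered" & f != 1, "status covered requires coverage_fraction 1")
  bad(entries$status == "non_covered" & f != 0, "status non_covered requires coverage_fraction 0")
  bad(entries$status == "partial" & (f <= 0 | f >= 1), "status partial requires fraction in (0,1)")
  bad(entries$status == "non_covered" & !is.na(entries$target_group),
    "non_covered entries must have no target_group")
  bad(entries$status != "non_covered" & is.na(entries$target_group),
    "covered/partial entries need a target_group")
  bad(entries$status == "non_covered" & entries$match_step != "none",
    "non_covered entries must have match_step 'none'")
  steps <- c("exact_name", "exact_description", "fuzzy", "token", "manual", "none")
  bad(!entries$match_step %in% steps, "unknown match_step")
  bad(entries$match_step == "fuzzy" & is.na(entries$similarity),
    "fuzzy entries must carry a similarity")
  bad(entries$match_step != "fuzzy" & !is.na(entries$similarity),
    "similarity is only defined for fuzzy entries")
  invisible(entries)
}

map_one <- function(food_code, name, description, cooking_method, prep, cfg) {
  name <- blank_text(name)
  if (!nzchar(name)) abort_dietmap("food code %s has an empty name", food_code)
  description <- blank_text(description)
  cooking_method <- blank_text(cooking_method)

  g <- exact_match_step(name, prep)
  if (!is.na(g)) {
    return(new_mapping_entry(food_code, "covered", g, 1, "exact_name"))
  }
  if (nzchar(description)) {
    g <- exact_match_step(description, prep)
    if (!is.na(g)) {
      return(new_mapping_entry(food_code, "covered", g, 1, "exact_description"))
    }
  }
  if (cfg$use_fuzzy) {
    hit <- fuzzy_match_step(name, prep, cfg)
    if (is.null(hit) && nzchar(description)) {
      hit <- fuzzy_match_step(description, prep, cfg)
    }
    if (!is.null(hit)) {
      return(new_mapping_entry(
        food_code, "covered", hit$group_code, 1, "fuzzy",
        similarity = hit$similarity, needs_review = TRUE
      ))
    }
  }
  # cooking-method tokens take part in the token search as description text
  desc_full <- trimws(paste(description, cooking_method))
  g <- token_search_step(name, desc_full, prep)
  if (!is.na(g)) {
    return(new_mapping_entry(food_code, "covered", g, 1, "token", needs_review = TRUE))
  }
  new_mapping_entry(food_code, "non_covered", NA_character_, 0, "none")
}

# Vectorized twin of map_one() for whole catalogues: identical verdicts,
# computed column-wise (exact matches via one dictionary lookup, fuzzy
# similarities via one edit-distance matrix per text field). Equality with
# the row-wise path is property-tested.
map_vectorized <- function(codes, name, desc, cook, prep, cfg) {
  n <- length(codes)
  name <- blank_text(name)
  if (any(!nzchar(name))) {
    abort_dietmap(
      "food code(s) with empty name: %s",
      paste(head(codes[!nzchar(name)], 10), collapse = ", ")
    )
  }
  desc <- blank_text(desc)
  cook <- blank_text(cook)
  nn <- normalize_join(name, prep$stopwords)
  nd <- normalize_join(desc, prep$stopwords)

  status <- rep("non_covered", n)
  target <- rep(NA_character_, n)
  step <- rep("none", n)
  simv <- rep(NA_real_, n)
  review <- rep(FALSE, n)

  assign_hit <- function(idx, grp, st, sim = NULL, flag_review = FALSE) {
    status[idx] <<- "covered"
    target[idx] <<- prep$codes[grp]
    step[idx] <<- st
    if (!is.null(sim)) simv[idx] <<- sim
    review[idx] <<- flag_review
  }

  # exact name, then exact description
  i1 <- match(nn, prep$exact_keys)
  hit <- which(!is.na(i1) & nzchar(nn))
  if (length(hit)) assign_hit(hit, prep$exact_group[i1[hit]], "exact_name")
  open <- which(status == "non_covered")
  i2 <- match(nd[open], prep$exact_keys)
  hit <- open[!is.na(i2) & nzchar(nd[open])]
  if (length(hit)) {
    assign_hit(hit, prep$exact_group[match(nd[hit], prep$exact_keys)], "exact_description")
  }

  # fuzzy: one similarity matrix per text field over label + phrase candidates
  if (cfg$use_fuzzy) {
    cand <- unlist(prep$fuzzy_cand)
    cand_grp <- rep(seq_len(prep$n), vapply(prep$fuzzy_cand, length, integer(1)))
    clen <- nchar(cand)
    fuzzy_pass <- function(texts) {
      # best candidate per row; candidates are in group order so which.max
      # breaks ties toward the earlier group
      d <- adist(texts, cand)
      sims <- 1 - d / outer(nchar(texts), clen, pmax)
      best_j <- apply(sims, 1, which.max)
      best <- sims[cbind(seq_along(texts), best_j)]
      list(grp = cand_grp[best_j], sim = best)
    }
    open <- which(status == "non_covered" & nzchar(nn))
    if (length(open)) {
      fp <- fuzzy_pass(nn[open])
      ok <- fp$sim >= cfg$fuzzy_threshold
      if (any(ok)) {
        assign_hit(open[ok], fp$grp[ok], "fuzzy", sim = fp$sim[ok], flag_review = TRUE)
      }
    }
    open <- which(status == "non_covered" & nzchar(nd))
    if (length(open)) {
      fp <- fuzzy_pass(nd[open])
      ok <- fp$sim >= cfg$fuzzy_threshold
      if (any(ok)) {
        assign_hit(open[ok], fp$grp[ok], "fuzzy", sim = fp$sim[ok], flag_review = TRUE)
      }
    }
  }

  # token search, cooking-method text joined to the description
  open <- which(status == "non_covered")
  for (i in open) {
    g <- token_search_step(name[i], trimws(paste(desc[i], cook[i])), prep)
    if (!is.na(g)) {
      grp <- match(g, prep$codes)
      assign_hit(i, grp, "token", flag_review = TRUE)
    }
  }

  tibble::tibble(
    food_code = as.character(codes),
    status = status,
    target_group = target,
    coverage_fraction = as.numeric(status == "covered"),
    match_step = step,
    similarity = simv,
    needs_review = review
  )
}

#' Map a single catalogue food code
#'
#' Applies the matching steps strictly in order — exact name, exact
#' description, fuzzy, token search — and returns the verdict of the first
#' step that matches. A code no step can place is `non_covered`. Matches
#' found by the fuzzy or token step are flagged `needs_review = TRUE`,
#' standing in for the human-annotator verification of the original
#' protocol.
#'
#' @param entry A list or one-row data frame with `food_code`, `food_name`
#'   and optionally `food_description`, `cooking_method`.
#' @param groups SFQ definition tibble.
#' @param cfg A [match_config()].
#' @return One-row mapping-entry tibble (`food_code`, `status`,
#'   `target_group`, `coverage_fraction`, `match_step`, `similarity`,
#'   `needs_review`).
#' @export
map_food_code <- function(entry, groups, cfg = match_config()) {
  entry <- as.list(entry)
  name <- entry$food_name %||% entry$name
  fc <- blank_text(entry$food_code)
  if (!nzchar(fc)) abort_dietmap("entry has an empty food_code")
  prep <- as_prepared(groups, cfg$stopwords)
  map_one(
    fc, name, entry$food_description %||% entry$description %||% "",
    entry$cooking_method %||% "", prep, cfg
  )
}

#' Build the full mapping table for a catalogue
#'
#' Runs [map_food_code()] over every food code of the catalogue, then applies
#' any manual overrides (the nutritionist-check channel): an override replaces
#' the algorithmic verdict for its code and is recorded with
#' `match_step = "manual"`.
#'
#' @param catalogue Tibble with one row per food code: `food_code`,
#'   `food_name`, optionally `food_description`, `cooking_method`,
#'   `food_group`.
#' @param groups SFQ definition tibble.
#' @param cfg A [match_config()].
#' @param manual_overrides Optional tibble with `food_code`, `status`,
#'   `target_group`, `coverage_fraction` for the codes to overrule.
#' @return Mapping-entry tibble, one row per catalogue code, in catalogue
#'   order; identical inputs and configuration give identical output.
#' @export
build_mapping_table <- function(catalogue, groups, cfg = match_config(),
                                manual_overrides = NULL) {
  if (nrow(catalogue) == 0) abort_dietmap("catalogue is empty")
  codes <- blank_text(catalogue$food_code)
  if (anyDuplicated(codes) > 0) {
    abort_dietmap(
      "duplicate food_code(s) in catalogue: %s",
      paste(unique(codes[duplicated(codes)]), collapse = ", ")
    )
  }
  prep <- as_prepared(groups, cfg$stopwords)
  pick <- function(...) {
    for (cn in c(...)) if (cn %in% names(catalogue)) return(catalogue[[cn]])
    rep("", nrow(catalogue))
  }
  out <- map_vectorized(
    codes, pick("food_name", "name"), pick("food_description", "description"),
    pick("cooking_method"), prep, cfg
  )

  if (!is.null(manual_overrides) && nrow(manual_overrides) > 0) {
    unknown <- setdiff(manual_overrides$food_code, out$food_code)
    if (length(unknown) > 0) {
      abort_dietmap(
        "override(s) reference unknown food code(s): %s",
        paste(unknown, collapse = ", ")
      )
    }
    idx <- match(manual_overrides$food_code, out$food_code)
    out$status[idx] <- manual_overrides$status
    out$target_group[idx] <- manual_overrides$target_group
    out$coverage_fraction[idx] <- manual_overrides$coverage_fraction
    out$match_step[idx] <- ifelse(manual_overrides$status == "non_covered", "none", "manual")
    out$similarity[idx] <- NA_real_
    out$needs_review[idx] <- FALSE
  }
  validate_mapping_entries(out)
  out
}

#' Group-level partial-coverage fraction
#'
#' For a catalogue food group mapped at sub-code granularity, reports which
#' share of the group is non-covered: count-based (unweighted over member
#' codes) and, when a diary is supplied, consumption-weighted (over eating
#' occasions). Codes explicitly declared "mixed" may be stamped with the
#' uniform group-level covered fraction, turning them into `partial`
#' verdicts.
#'
#' @param food_group_label A `food_group` label present in the catalogue.
#' @param catalogue Catalogue tibble (see [build_mapping_table()]).
#' @param mapping Mapping-entry tibble covering the catalogue.
#' @param diary Optional diary tibble; enables the consumption-weighted
#'   variant.
#' @param mixed_codes Optional character vector of member food codes to stamp
#'   with the group's covered fraction (only applied when that fraction is
#'   strictly between 0 and 1).
#' @return A list: `food_group`, `n_codes`, `n_covered`,
#'   `noncov_fraction_count`, `noncov_fraction_weighted` (`NA` without a
#'   diary), and the (possibly updated) `mapping`.
#' @export
assign_partial_fraction <- function(food_group_label, catalogue, mapping,
                                    diary = NULL, mixed_codes = NULL) {
  members <- catalogue$food_code[catalogue$food_group == food_group_label]
  if (length(members) == 0) {
    abort_dietmap("unknown catalogue food group: %s", food_group_label)
  }
  m <- mapping[mapping$food_code %in% members, , drop = FALSE]
  if (nrow(m) != length(members)) {
    abort_dietmap("mapping does not cover all member codes of group %s", food_group_label)
  }
  covered_share <- mean(m$coverage_fraction)
  weighted <- NA_real_
  if (!is.null(diary)) {
    d <- diary[diary$food_code %in% members, , drop = FALSE]
    if (nrow(d) > 0) {
      weighted <- 1 - mean(m$coverage_fraction[match(d$food_code, m$food_code)])
    }
  }
  if (!is.null(mixed_codes) && covered_share > 0 && covered_share < 1) {
    unknown <- setdiff(mixed_codes, members)
    if (length(unknown) > 0) {
      abort_dietmap(
        "mixed code(s) not members of group %s: %s",
        food_group_label, paste(unknown, collapse = ", ")
      )
    }
    idx <- match(mixed_codes, mapping$food_code)
    covered_targets <- m$target_group[!is.na(m$target_group)]
    if (length(covered_targets) == 0) {
      abort_dietmap("group %s has no mapped member to supply a target group", food_group_label)
    }
    target <- names(sort(table(covered_targets), decreasing = TRUE))[1]
    mapping$status[idx] <- "partial"
    mapping$coverage_fraction[idx] <- covered_share
    mapping$target_group[idx] <- target
    mapping$match_step[idx] <- "manual"
    mapping$similarity[idx] <- NA_real_
    mapping$needs_review[idx] <- FALSE
    validate_mapping_entries(mapping)
  }
  list(
    food_group = food_group_label,
    n_codes = length(members),
    n_covered = sum(m$status == "covered"),
    noncov_fraction_count = 1 - covered_share,
    noncov_fraction_weighted = weighted,
    mapping = mapping
  )
}

#' Compare two mapping tables (annotator repeatability)
#'
#' Two independently produced mapping tables over the same food codes are
#' compared code by code; a code is discordant when its `(status,
#' target_group)` pair differs. The comparison is symmetric.
#'
#' @param table_a,table_b Mapping-entry tibbles over the identical food-code
#'   set.
#' @return A list: `n_codes`, `n_discordant`, `discordant_codes`.
#' @export
compare_mappings <- function(table_a, table_b) {
  only_a <- setdiff(table_a$food_code, table_b$food_code)
  only_b <- setdiff(table_b$food_code, table_a$food_code)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort_dietmap(
      "mapping tables cover different code sets; only in A: %s; only in B: %s",
      paste(head(only_a, 10), collapse = ", "),
      paste(head(only_b, 10), collapse = ", ")
    )
  }
  idx <- match(table_a$food_code, table_b$food_code)
  key <- function(status, target) paste(status, ifelse(is.na(target), "<none>", target))
  discord <- key(table_a$status, table_a$target_group) !=
    key(table_b$status[idx], table_b$target_group[idx])
  list(
    n_codes = nrow(table_a),
    n_discordant = sum(discord),
    discordant_codes = table_a$food_code[discord]
  )
}
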