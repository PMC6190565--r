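# Independent oracles, written from first principles and kept apart from the
# package's implementation paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook two-row dynamic-programming Levenshtein distance.
lev_dp <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca)
  nb <- length(cb)
  if (na == 0) return(nb)
  if (nb == 0) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0 else 1
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[nb + 1]
}

# The normalized-similarity formula recomputed independently (own
# normalization, own DP distance).
sim_oracle <- function(a, b) {
  norm <- function(s) {
    s <- trimws(gsub("[^a-z0-9]+", " ", tolower(s)))
    s
  }
  na <- norm(a)
  nb <- norm(b)
  if (!nzchar(na) && !nzchar(nb)) return(1)
  if (!nzchar(na) || !nzchar(nb)) return(0)
  1 - lev_dp(na, nb) / max(nchar(na), nchar(nb))
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n+m, n)
# assignments of the pooled mid-ranks, measuring extremeness as distance of
# the rank sum from its null mean.
enum_wilcoxon_p <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x)
  N <- n + length(y)
  sums <- utils::combn(N, n, FUN = function(i) sum(r[i]))
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  mean(abs(sums - mu) >= obs - 1e-9)
}

random_food_string <- function(max_words = 4) {
  words <- c(
    "milk", "bread", "cheese", "apple", "stew", "grilled", "sauce", "rice",
    "oat", "berry", "roll", "cream", "soup", "bar", "juice", "pie", "snack"
  )
  k <- sample.int(max_words, 1)
  paste(sample(words, k, replace = TRUE), collapse = " ")
}

# A tiny questionnaire definition built in code for unit tests.
tiny_sfq <- function() {
  tibble::tibble(
    group_code = c("G1", "G2", "G3"),
    label = c("Sweets", "Hamburger, hot dog, sausage or meat pie", "Fresh fruit"),
    polarity = c("unhealthy", "unhealthy", "healthy"),
    include_keywords = list(
      c("sweets", "jellies"),
      c("hamburger", "hot dog", "sausage", "meat pie"),
      c("fresh fruit", "fruit", "banana")
    ),
    exclude_keywords = list(character(), character(), c("juice", "juices"))
  )
}

# Accuracy of a mapping table against planted truth labels.
mapping_accuracy <- function(mapping, truth) {
  idx <- match(mapping$food_code, truth$food_code)
  tg <- truth$true_group[idx]
  mean((is.na(tg) & mapping$status == "non_covered") |
    (!is.na(tg) & !is.na(mapping$target_group) & mapping$target_group == tg))
}

# Small synthetic study used by several suites (kept light).
small_study <- function(seed = 42, ...) {
  cfg <- synth_config(
    n_codes = 120, n_groups = 20, n_sfq_groups = 15,
    n_subjects = 15, n_days = 4, seed = seed, ...
  )
  co <- generate_catalogue(cfg)
  list(cfg = cfg, cat = co, diary = generate_diary(cfg, co))
}
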