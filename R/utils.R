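# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never clobbers the user's random stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Days of the week
#'
#' Canonical weekday levels used throughout the package (`"Mon"` .. `"Sun"`).
#'
#' @return Character vector of length 7.
#' @export
weekday_levels <- function() {
  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
}

# Accept abbreviated or full English weekday names; return "Mon".."Sun".
canonical_weekday <- function(x) {
  full <- c(
    "monday", "tuesday", "wednesday", "thursday", "friday",
    "saturday", "sunday"
  )
  lvls <- weekday_levels()
  out <- as.character(x)
  low3 <- substr(tolower(out), 1, 3)
  idx <- match(low3, substr(full, 1, 3))
  res <- ifelse(is.na(idx), NA_character_, lvls[idx])
  res
}

abort_dietmap <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}
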