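#' Normalize free text into a token list
#'
#' Lowercases, replaces every non-alphanumeric character (slashes, hyphens,
#' parentheses, punctuation) by a space, splits on whitespace, and removes
#' stopwords. The result is deterministic and order-preserving.
#'
#' @param s A character scalar (empty text allowed; `NA` is treated as empty).
#' @param stopwords Character vector of tokens to drop after splitting
#'   (already-normalized form). Defaults to none: the matching steps are
#'   deliberately conservative and only drop words the caller names.
#'
#' @return Character vector of tokens (possibly empty).
#' @examples
#' normalize_text("Full fat cheese/yogurt/fromage frais")
#' normalize_text("Hot chips or French fries!", stopwords = "or")
#' @export
normalize_text <- function(s, stopwords = character()) {
  if (length(s) != 1) {
    abort_dietmap("normalize_text() expects a single string, got length %d", length(s))
  }
  if (is.na(s)) s <- ""
  s <- tolower(s)
  s <- gsub("[^a-z0-9]+", " ", s)
  s <- trimws(s)
  if (!nzchar(s)) {
    return(character())
  }
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  toks[!toks %in% stopwords]
}

# Normalized tokens re-joined with single spaces; vectorized over `x`.
normalize_join <- function(x, stopwords = character()) {
  vapply(
    as.character(x),
    function(s) paste(normalize_text(s, stopwords), collapse = " "),
    character(1),
    USE.NAMES = FALSE
  )
}

#' Normalized-Levenshtein string similarity
#'
#' Similarity between two free-text food descriptions, computed on their
#' normalized forms (see [normalize_text()]; tokens re-joined with single
#' spaces):
#' \deqn{sim(a, b) = 1 - \frac{lev(norm(a), norm(b))}{\max(|norm(a)|, |norm(b)|)}}
#' where \eqn{lev} is the Levenshtein edit distance (unit-cost insertions,
#' deletions, substitutions, via [utils::adist()]). Two empty strings are
#' defined to have similarity 1; an empty string against a non-empty one has
#' similarity 0.
#'
#' @param a,b Character scalars.
#' @param stopwords Passed to [normalize_text()].
#'
#' @return A number in `[0, 1]`; symmetric, and `similarity(a, a) == 1`.
#' @examples
#' similarity("hot chips", "hot chps") # 1 - 1/9
#' @export
similarity <- function(a, b, stopwords = character()) {
  na <- normalize_join(a, stopwords)
  nb <- normalize_join(b, stopwords)
  similarity_norm(na, nb)
}

# Similarity on already-normalized strings; `nb` may be a vector.
similarity_norm <- function(na, nb) {
  la <- nchar(na)
  lb <- nchar(nb)
  out <- numeric(length(nb))
  both_empty <- la == 0 & lb == 0
  one_empty <- xor(la == 0, lb == 0)
  out[both_empty] <- 1
  out[one_empty] <- 0
  rest <- !(both_empty | one_empty)
  if (any(rest)) {
    d <- as.numeric(adist(na, nb[rest]))
    out[rest] <- 1 - d / pmax(la, lb[rest])
  }
  out
}
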