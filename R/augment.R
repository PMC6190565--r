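#' Merge the diary with the mapping table into the augmented database
#'
#' Every diary row (one eating occasion) is joined with its food code's
#' mapping verdict. The join is bijective: N rows in, N rows out, in diary
#' order. Each augmented record carries a covered weight equal to its code's
#' `coverage_fraction` and a non-covered weight of `1 - coverage_fraction`;
#' the two always sum to exactly 1. Diary columns beyond the canonical set
#' are passed through untouched.
#'
#' @param diary Diary tibble (see [read_food_diary()]).
#' @param mapping Mapping-entry tibble covering every diary food code.
#' @param force By default a diary code absent from the mapping table is an
#'   error naming the codes (silent classification would corrupt the coverage
#'   statistics downstream). With `force = TRUE` the error is downgraded to a
#'   warning and the offending rows are classified `non_covered` with
#'   `match_step = "none"`.
#'
#' @return Augmented tibble: all diary columns plus `status`, `target_group`,
#'   `coverage_fraction`, `match_step`, `covered_weight`, `noncov_weight`.
#' @export
apply_mapping <- function(diary, mapping, force = FALSE) {
  validate_mapping_entries(mapping)
  if (nrow(diary) == 0) abort_dietmap("diary is empty")
  unmapped <- setdiff(unique(diary$food_code), mapping$food_code)
  if (length(unmapped) > 0) {
    msg <- sprintf(
      "%d diary food code(s) absent from the mapping table: %s",
      length(unmapped), paste(head(unmapped, 20), collapse = ", ")
    )
    if (!force) abort_dietmap("%s", msg)
    warning(paste(msg, "- classifying as non_covered"), call. = FALSE)
    mapping <- dplyr::bind_rows(
      mapping,
      new_mapping_entry(unmapped, "non_covered", NA_character_, 0, "none")
    )
  }
  idx <- match(diary$food_code, mapping$food_code)
  out <- diary
  out$status <- mapping$status[idx]
  out$target_group <- mapping$target_group[idx]
  out$coverage_fraction <- mapping$coverage_fraction[idx]
  out$match_step <- mapping$match_step[idx]
  out$covered_weight <- out$coverage_fraction
  out$noncov_weight <- 1 - out$coverage_fraction
  tibble::as_tibble(out)
}
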