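#' @importFrom rlang .data %||%
#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif rweibull
#'   setNames pnorm pchisq qnorm
#' @importFrom utils head
NULL

# Normalize a drug or PT string for matching: upper case, punctuation to
# spaces, collapsed whitespace. FAERS free-text fields carry salts, dose
# text and inconsistent casing.
normalize_term <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

# Whole-word substring match of `needle` (already normalized) inside each
# normalized element of `haystack`.
match_whole_word <- function(haystack, needle) {
  if (!nzchar(needle)) {
    return(rep(FALSE, length(haystack)))
  }
  pattern <- paste0("(^| )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", needle), "( |$)")
  grepl(pattern, haystack)
}

# Compare FAERS primaryids: numeric when every id parses as a number,
# otherwise zero-padded lexicographic. Returns an order key (character
# sorts correctly after padding; numeric returned as-is).
primaryid_order_key <- function(ids) {
  nums <- suppressWarnings(as.numeric(ids))
  if (!anyNA(nums)) {
    return(list(key = nums, fallback = FALSE))
  }
  width <- max(nchar(ids), 1L)
  list(key = formatC(ids, width = width, flag = "0"), fallback = TRUE)
}

first_na <- function(x) if (length(x)) x[[1L]] else NA_character_

# Percent on the available-value denominator; NA when the denominator is 0.
pct_of <- function(n, denom) {
  if (denom > 0) 100 * n / denom else rep(NA_real_, length(n))
}
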