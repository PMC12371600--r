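#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median setNames aggregate dist hclust cutree kmeans runif
#' @importFrom utils adist head tail
NULL

# Round half away from zero to integer. base::round() rounds half to even,
# which is the wrong convention for reported percentages.
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Integer percentage under the package rounding rule
#'
#' Computes `100 * n / denominator` rounded half away from zero, the rule used
#' for every reported percentage in prevalence tables and summaries.
#'
#' @param n Numerator count(s).
#' @param denominator Positive denominator.
#' @return Integer vector of percentages.
#' @export
#' @examples
#' pct_of(974, 1249) # 78
pct_of <- function(n, denominator) {
  stopifnot(is.numeric(n), is.numeric(denominator), all(denominator > 0))
  as.integer(round_half_away(100 * n / denominator))
}

# Word tokenizer used across rule matching: lowercase word characters,
# keeping internal apostrophes and percent signs attached to numbers.
tokenize_words <- function(text) {
  out <- stringr::str_extract_all(tolower(text), "[a-z0-9']+%?")
  out
}

# Salted polynomial rolling hash over raw bytes, modulo a Mersenne prime.
# Three independent seeds are concatenated to a 12-hex-digit token.
.poly_hash <- function(bytes, seed, mult = 31) {
  m <- 2147483647 # 2^31 - 1
  h <- seed
  for (b in bytes) {
    h <- (h * mult + as.double(b)) %% m
  }
  h
}

.hash_token <- function(x, salt) {
  bytes <- as.double(utf8ToInt(paste0(salt, "", x)))
  # three polynomials with independent multipliers: same-multiplier variants
  # differing only in the additive seed have perfectly correlated collisions
  params <- list(c(17, 31), c(5381, 257), c(104729, 8191))
  parts <- vapply(
    params,
    function(p) sprintf("%04x", .poly_hash(bytes, p[1], p[2]) %% 65536),
    character(1)
  )
  paste0(parts, collapse = "")
}

# All substrings of length k of x (used by the token leakage check).
.substrings_k <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  unique(substring(x, starts, starts + k - 1))
}

# Parse a day-resolution date; month-only strings resolve to day 1.
parse_post_date <- function(x) {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full])
  monthly <- !full & grepl("^\\d{4}-\\d{2}$", x)
  if (any(monthly)) out[monthly] <- as.Date(paste0(x[monthly], "-01"))
  other <- !full & !monthly & !is.na(x) & x != ""
  if (any(other)) {
    suppressWarnings(out[other] <- as.Date(x[other]))
  }
  out
}
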