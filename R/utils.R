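# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-rule rounding used when rendering metrics at two decimal places.
#' Base `round()` rounds half to even, which does not match the convention
#' used in survey-style network reports (0.765 -> 0.77, not 0.76).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-base string hash into [0, 2^31 - 2]; used to derive
# per-network RNG substreams from network labels so that adding a network
# never perturbs the draws of earlier ones.
stable_hash <- function(label) {
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Canonicalize a two-column tie table: character ids, each pair sorted by
# the actor order given in `actor_ids`, duplicates (including reversed
# duplicates) dropped, rows ordered by first then second endpoint.
canonical_ties <- function(pairs, actor_ids) {
  if (is.null(pairs) || NROW(pairs) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  ia <- match(a, actor_ids)
  ib <- match(b, actor_ids)
  swap <- !is.na(ia) & !is.na(ib) & ia > ib
  from <- ifelse(swap, b, a)
  to <- ifelse(swap, a, b)
  out <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  out <- out[order(match(out$from, actor_ids), match(out$to, actor_ids)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
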