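# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero (base round() rounds half to even)
#' @noRd
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Regex fragment matching a synonym as a whole token. The boundary is a
# maximal alphanumeric run, stricter than the tokenizer's letter runs, so a
# drug name fused to a dose ("topamax50") is NOT counted as a mention.
token_pattern <- function(synonyms) {
  stopifnot(length(synonyms) > 0L)
  esc <- gsub("([^[:alnum:]])", "\\\\\\1", synonyms, perl = TRUE)
  paste0("(?<![[:alnum:]])(", paste(esc, collapse = "|"), ")(?![[:alnum:]])")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
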