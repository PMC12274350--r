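# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("%s must be a probability in [0, 1], got: %s",
          what, paste(format(p), collapse = ", "))
  invisible(p)
}

check_count <- function(n, what) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != floor(n))
    stopf("%s must be a single non-negative integer, got: %s",
          what, paste(format(n), collapse = ", "))
  invisible(as.integer(n))
}

#' Derive a deterministic substream seed
#'
#' A fixed affine hash of (master seed, index). Keeps per-patient document
#' generation stable when the cohort grows: new patients get new streams,
#' existing patients keep theirs.
#' @noRd
split_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 +
                as.double(index) * 7919) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Word tokens: lowercase alphanumeric runs, possessives kept with their noun.
token_pattern <- "[a-z0-9]+(?:'[a-z]+)?"

count_words <- function(x) {
  stringr::str_count(stringr::str_to_lower(x), token_pattern)
}

#' Sentence spans of a document
#'
#' Sentences are delimited by runs of `.`, `!`, `?` or newline followed by
#' whitespace. Returns 0-based half-open character spans, the convention used
#' for all spans in this package.
#' @noRd
sentence_spans <- function(text) {
  n <- nchar(text)
  if (is.na(text) || n == 0L)
    return(data.frame(start = integer(), end = integer()))
  br <- stringr::str_locate_all(text, "[.!?\\n]+\\s+")[[1]]
  starts1 <- c(1L, br[, 2L] + 1L)
  ends1 <- c(br[, 2L], n)
  keep <- starts1 <= ends1
  data.frame(start = as.integer(starts1[keep] - 1L),
             end = as.integer(ends1[keep]))
}

# Slice a 0-based half-open span out of text.
slice_span <- function(text, start, end) substr(text, start + 1L, end)

empty_df <- function(proto) proto[0, , drop = FALSE]
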