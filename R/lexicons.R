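#' The six elementary symptom concepts
#'
#' Concept identifiers used throughout the package. Tremor and bradykinesia
#' jointly operationalise parkinsonism; bad dreams and nightmares jointly
#' operationalise (possible) REM sleep behaviour disorder.
#'
#' @return Character vector of the six concept names.
#' @export
#' @examples
#' dlb_concepts()
dlb_concepts <- function() {
  c("visual_hallucinations", "fluctuations", "tremor", "bradykinesia",
    "bad_dreams", "nightmares")
}

#' The four core DLB features
#'
#' @return Character vector of the four core-feature names used in
#'   patient-level profiles.
#' @export
core_features <- function() c("vh", "fluct", "parkinsonism", "rbd")

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dlbtext")
  if (path == "") stopf("packaged data file not found: %s", file)
  path
}

#' Read a concept lexicon
#'
#' A lexicon is a YAML map from concept name to either `patterns` (a list of
#' case-insensitive stem patterns, trailing `*` matching any trailing word
#' characters) or a `proximity` rule (two stems that must co-occur in one
#' sentence within `max_gap` intervening word tokens).
#'
#' @param path Path to a YAML lexicon; `NULL` for the packaged default.
#' @return A named list of class `dlb_lexicon`.
#' @export
read_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("lexicon.yml")
  lex <- yaml::read_yaml(path)
  if (!length(lex) || is.null(names(lex)))
    stopf("lexicon at %s has no named concepts", path)
  for (concept in names(lex)) {
    spec <- lex[[concept]]
    if (is.null(spec$patterns) && is.null(spec$proximity))
      stopf("concept '%s' defines neither patterns nor a proximity rule",
            concept)
    if (!is.null(spec$proximity)) {
      if (length(spec$proximity$stems) != 2L)
        stopf("proximity rule for '%s' needs exactly two stems", concept)
      gap <- spec$proximity$max_gap %||% 5L
      check_count(gap, sprintf("max_gap for '%s'", concept))
      lex[[concept]]$proximity$max_gap <- as.integer(gap)
    }
  }
  structure(lex, class = "dlb_lexicon")
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  if (is.null(.lex_cache$lexicon)) .lex_cache$lexicon <- read_lexicon()
  .lex_cache$lexicon
}

#' Read a cue lexicon for mention classification
#'
#' Cue lists drive the rule-based positive/non-positive call: `negated`
#' (e.g. "no", "denied"), `unknown` (hypothetical/uncertain, e.g.
#' "monitoring to see if"), and `irrelevant` (non-patient experiencers,
#' e.g. "mother"). `max_gap` is the scope in word tokens.
#'
#' @param path Path to a YAML cue file; `NULL` for the packaged default.
#' @return A list of class `dlb_cues` with elements `negated`, `unknown`,
#'   `irrelevant` and `max_gap`.
#' @export
read_cues <- function(path = NULL) {
  path <- path %||% pkg_extdata("cues.yml")
  cues <- yaml::read_yaml(path)
  for (cls in c("negated", "unknown", "irrelevant"))
    cues[[cls]] <- as.character(cues[[cls]] %||% character())
  cues$max_gap <- as.integer(cues$max_gap %||% 6L)
  structure(cues, class = "dlb_cues")
}

#' @rdname read_cues
#' @export
default_cues <- function() {
  if (is.null(.lex_cache$cues)) .lex_cache$cues <- read_cues()
  .lex_cache$cues
}

.lex_cache <- new.env(parent = emptyenv())

# Compile a stem pattern to a regex over lowercased text. `*` expands to
# [a-z]*; internal whitespace matches any whitespace run; a stem without a
# wildcard is matched as a whole word.
stem_regex <- function(stem) {
  stem <- stringr::str_to_lower(stringr::str_trim(stem))
  wild <- stringr::str_detect(stem, "\\*$")
  base <- stringr::str_remove(stem, "\\*$")
  esc <- stringr::str_replace_all(base, "([.\\\\+?^$(){}\\[\\]|*])",
                                  "\\\\\\1")
  esc <- stringr::str_replace_all(esc, "\\s+", "\\\\s+")
  paste0("\\b", esc, if (wild) "[a-z]*" else "\\b")
}

# One alternation regex for a whole cue class ("?" handled separately).
cue_regex <- function(cues) {
  cues <- setdiff(cues, "?")
  if (!length(cues)) return(NA_character_)
  esc <- vapply(cues, function(x) {
    x <- stringr::str_to_lower(stringr::str_trim(x))
    x <- stringr::str_replace_all(x, "([.\\\\+?^$(){}\\[\\]|*])", "\\\\\\1")
    stringr::str_replace_all(x, "\\s+", "\\\\s+")
  }, character(1))
  paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
}
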