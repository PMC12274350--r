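#' Find candidate concept mentions in text
#'
#' Scans one or more documents for the lexicon's concepts using
#' case-insensitive stem matching (regular-expression style). For a proximity
#' concept both stems must fall in the same sentence with at most `max_gap`
#' word tokens between them; the candidate span covers the pair. Overlapping
#' matches of the same concept are merged into one maximal candidate, so no
#' concept yields overlapping duplicates.
#'
#' All spans are 0-based half-open character offsets into the document text.
#' `context` is the sentence containing the span and `context_start` its
#' document offset.
#'
#' @param text Character vector of document texts (may be empty strings).
#' @param lexicon A `dlb_lexicon`, see [read_lexicon()].
#' @param doc_id Optional document identifiers parallel to `text`.
#' @return A data.frame with columns `doc_id`, `concept`, `start`, `end`,
#'   `context`, `context_start`, ordered by document and start offset.
#' @export
#' @examples
#' find_candidates("There was evidence of a tremor when writing.")
find_candidates <- function(text, lexicon = default_lexicon(),
                            doc_id = NULL) {
  if (is.null(doc_id))
    doc_id <- if (length(text)) paste0("doc", seq_along(text)) else character()
  if (length(doc_id) != length(text))
    stopf("doc_id must be parallel to text (%d vs %d)",
          length(doc_id), length(text))
  proto <- data.frame(doc_id = character(), concept = character(),
                      start = integer(), end = integer(),
                      context = character(), context_start = integer(),
                      stringsAsFactors = FALSE)
  if (!length(text)) return(proto)

  lower <- stringr::str_to_lower(text)
  hits <- vector("list", length(lexicon))
  for (k in seq_along(lexicon)) {
    concept <- names(lexicon)[k]
    spec <- lexicon[[concept]]
    h <- if (!is.null(spec$proximity)) {
      locate_proximity(text, lower, spec$proximity)
    } else {
      locate_patterns(lower, spec$patterns)
    }
    if (nrow(h)) h$concept <- concept
    hits[[k]] <- h
  }
  hits <- hits[vapply(hits, nrow, 0L) > 0L]
  if (!length(hits)) return(proto)
  cand <- do.call(rbind, hits)

  # Merge overlapping spans per document x concept, attach sentence contexts.
  out <- vector("list", 64L)
  n_out <- 0L
  for (d in sort(unique(cand$doc_index))) {
    sents <- sentence_spans(text[d])
    for (concept in unique(cand$concept[cand$doc_index == d])) {
      cc <- cand[cand$doc_index == d & cand$concept == concept, , drop = FALSE]
      cc <- cc[order(cc$start, cc$end), , drop = FALSE]
      merged_s <- cc$start[1L]; merged_e <- cc$end[1L]
      starts <- integer(); ends <- integer()
      if (nrow(cc) > 1L) {
        for (i in 2:nrow(cc)) {
          if (cc$start[i] < merged_e) {
            merged_e <- max(merged_e, cc$end[i])
          } else {
            starts <- c(starts, merged_s); ends <- c(ends, merged_e)
            merged_s <- cc$start[i]; merged_e <- cc$end[i]
          }
        }
      }
      starts <- c(starts, merged_s); ends <- c(ends, merged_e)
      si <- findInterval(starts, sents$start)
      si[si < 1L] <- 1L
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        doc_id = doc_id[d], concept = concept,
        start = starts, end = ends,
        context = slice_span(text[d], sents$start[si], sents$end[si]),
        context_start = sents$start[si],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(n_out)])
  res <- res[order(match(res$doc_id, doc_id), res$start, res$concept), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# All stem-pattern matches over the lowercased corpus: doc_index/start/end
# (0-based half-open).
locate_patterns <- function(lower, patterns) {
  out <- list()
  for (p in patterns) {
    loc <- stringr::str_locate_all(lower, stem_regex(p))
    nn <- vapply(loc, nrow, 0L)
    if (!sum(nn)) next
    m <- do.call(rbind, loc)
    out[[length(out) + 1L]] <- data.frame(
      doc_index = rep.int(seq_along(lower), nn),
      start = as.integer(m[, 1L] - 1L), end = as.integer(m[, 2L]))
  }
  if (!length(out))
    return(data.frame(doc_index = integer(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

# Proximity pairs: every pair of the two stems within one sentence and at
# most max_gap word tokens apart yields a candidate spanning both.
locate_proximity <- function(text, lower, prox) {
  r1 <- stem_regex(prox$stems[[1L]])
  r2 <- stem_regex(prox$stems[[2L]])
  loc1 <- stringr::str_locate_all(lower, r1)
  loc2 <- stringr::str_locate_all(lower, r2)
  res <- list()
  for (d in seq_along(lower)) {
    m1 <- loc1[[d]]; m2 <- loc2[[d]]
    if (!nrow(m1) || !nrow(m2)) next
    sents <- sentence_spans(text[d])
    s1 <- findInterval(m1[, 1L] - 1L, sents$start)
    s2 <- findInterval(m2[, 1L] - 1L, sents$start)
    for (i in seq_len(nrow(m1))) {
      for (j in seq_len(nrow(m2))) {
        if (s1[i] != s2[j]) next
        lo_end <- min(m1[i, 2L], m2[j, 2L])
        hi_start <- max(m1[i, 1L], m2[j, 1L])
        if (hi_start <= lo_end) next  # same or nested token
        gap <- count_words(substr(lower[d], lo_end + 1L, hi_start - 1L))
        if (gap > prox$max_gap) next
        res[[length(res) + 1L]] <- c(
          d, min(m1[i, 1L], m2[j, 1L]) - 1L, max(m1[i, 2L], m2[j, 2L]))
      }
    }
  }
  if (!length(res))
    return(data.frame(doc_index = integer(), start = integer(),
                      end = integer()))
  m <- do.call(rbind, res)
  data.frame(doc_index = as.integer(m[, 1L]), start = as.integer(m[, 2L]),
             end = as.integer(m[, 3L]))
}

#' Classify candidate mentions as positive or non-positive
#'
#' Rule-based call in the NegEx tradition: a negation, uncertainty or
#' irrelevant-experiencer cue in the candidate's sentence, within
#' `cues$max_gap` word tokens of the span (either side), makes the mention
#' non-positive with the matching sublabel; the nearest cue wins, ties break
#' conservatively towards negation. With no cue in scope the mention is
#' positive. Negation asserted elsewhere in the record never vetoes a
#' positive mention - non-positive mentions are simply not counted.
#'
#' @param cands Candidate data.frame from [find_candidates()].
#' @param cues A `dlb_cues` list, see [read_cues()].
#' @return A data.frame with columns `label` (`"positive"`/`"non_positive"`)
#'   and `sublabel` (`"none"`, `"negated"`, `"unknown"`, `"irrelevant"`).
#' @export
classify_mentions <- function(cands, cues = default_cues()) {
  n <- nrow(cands)
  if (!n) return(data.frame(label = character(), sublabel = character(),
                            stringsAsFactors = FALSE))
  ctx <- stringr::str_to_lower(cands$context)
  rel_start <- cands$start - cands$context_start
  rel_end <- cands$end - cands$context_start
  prefix <- substr(ctx, 1L, rel_start)
  suffix <- substr(ctx, rel_end + 1L, nchar(ctx))

  dist <- matrix(Inf, nrow = n, ncol = 3L,
                 dimnames = list(NULL, c("negated", "unknown", "irrelevant")))
  for (cls in colnames(dist)) {
    rx <- cue_regex(cues[[cls]])
    if (!is.na(rx)) {
      pre <- stringr::str_locate_all(prefix, rx)
      post <- stringr::str_locate_all(suffix, rx)
      for (i in seq_len(n)) {
        if (nrow(pre[[i]])) {
          cue_end <- max(pre[[i]][, 2L])
          d <- count_words(substr(prefix[i], cue_end + 1L,
                                  nchar(prefix[i])))
          if (d <= cues$max_gap) dist[i, cls] <- min(dist[i, cls], d)
        }
        if (nrow(post[[i]])) {
          cue_start <- min(post[[i]][, 1L])
          d <- count_words(substr(suffix[i], 1L, cue_start - 1L))
          if (d <= cues$max_gap) dist[i, cls] <- min(dist[i, cls], d)
        }
      }
    }
    if ("?" %in% cues[[cls]]) {
      qm <- stringr::str_detect(prefix, "\\?\\s*$")
      dist[qm, cls] <- pmin(dist[qm, cls], 0)
    }
  }
  best <- apply(dist, 1L, min)
  sublabel <- rep("none", n)
  hit <- is.finite(best)
  # which.max on (dist == best) respects column order: negated first on ties
  sublabel[hit] <- colnames(dist)[apply(dist[hit, , drop = FALSE] ==
                                          best[hit], 1L, which.max)]
  data.frame(label = ifelse(hit, "non_positive", "positive"),
             sublabel = sublabel, stringsAsFactors = FALSE)
}

#' @rdname classify_mentions
#' @param cand A single-row candidate data.frame.
#' @export
classify_mention <- function(cand, cues = default_cues()) {
  classify_mentions(cand[1L, , drop = FALSE], cues)
}

#' Extract labelled mentions from documents
#'
#' Composition of [find_candidates()] and [classify_mentions()] (or a trained
#' classifier) over all six concepts. `extract_document()` handles one
#' document; `extract_corpus()` a whole corpus data.frame.
#'
#' @param documents Data.frame with columns `doc_id`, `patient_id`, `text`.
#' @param lexicon A `dlb_lexicon`.
#' @param cues A `dlb_cues` list used by the rule path.
#' @param classifier Optional `mention_classifier` from
#'   [train_mention_classifier()]; `NULL` (default) uses the rule path.
#' @return A data.frame with columns `doc_id`, `concept`, `start`, `end`,
#'   `label`, `sublabel`.
#' @export
#' @examples
#' doc <- data.frame(doc_id = "d1", patient_id = "p1",
#'                   text = "Examination confirmed the presence of bradykinesia.")
#' extract_document(doc)
extract_corpus <- function(documents, lexicon = default_lexicon(),
                           cues = default_cues(), classifier = NULL) {
  cands <- find_candidates(documents$text, lexicon, documents$doc_id)
  labs <- if (is.null(classifier)) {
    classify_mentions(cands, cues)
  } else {
    predict(classifier, cands, cues = cues)
  }
  res <- cbind(cands[, c("doc_id", "concept", "start", "end")], labs)
  rownames(res) <- NULL
  res
}

#' @rdname extract_corpus
#' @param doc A single-row document data.frame (or a list with `doc_id` and
#'   `text`).
#' @export
extract_document <- function(doc, lexicon = default_lexicon(),
                             cues = default_cues(), classifier = NULL) {
  extract_corpus(data.frame(doc_id = doc$doc_id[1L],
                            text = doc$text[1L],
                            stringsAsFactors = FALSE),
                 lexicon, cues, classifier)
}
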