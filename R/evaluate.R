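#' Score extracted mentions against gold annotations
#'
#' Per-concept precision (positive predictive value: the proportion of
#' retrieved entities that are correct) and recall (sensitivity: the
#' proportion of gold entities that are retrieved). Only positive calls
#' count as retrieved entities and only gold `positive` spans count as
#' entities; gold negative/unknown annotations are pooled with other
#' unwanted mentions and enter neither denominator. A prediction matches a
#' gold entity of the same concept in the same document when their spans
#' overlap by at least one character (`match = "overlap"`, the default) or
#' coincide exactly (`match = "exact"`); matching is one-to-one. Undefined
#' ratios (empty denominators) are returned as `NA`, never silently 0.
#'
#' @param mentions Predicted mention data.frame (`doc_id`, `concept`,
#'   `start`, `end`, `label`).
#' @param gold Gold annotation data.frame (`doc_id`, `concept`, `start`,
#'   `end`, `label` in positive/negative/unknown).
#' @param match Span-matching rule.
#' @param concepts Concept universe; unknown concept names in either input
#'   are an error.
#' @return A data.frame with one row per concept: `concept`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`.
#' @export
score_extraction <- function(mentions, gold, match = c("overlap", "exact"),
                             concepts = dlb_concepts()) {
  match <- match.arg(match)
  bad <- setdiff(unique(c(mentions$concept, gold$concept)), concepts)
  if (length(bad)) stopf("unknown concept(s): %s", paste(bad, collapse = ", "))
  pred <- mentions[mentions$label == "positive", , drop = FALSE]
  gpos <- gold[gold$label == "positive", , drop = FALSE]
  out <- data.frame(concept = concepts, tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(concepts)) {
    p <- pred[pred$concept == concepts[i], , drop = FALSE]
    g <- gpos[gpos$concept == concepts[i], , drop = FALSE]
    tp <- 0L
    for (d in unique(c(p$doc_id, g$doc_id))) {
      pd <- p[p$doc_id == d, , drop = FALSE]
      pd <- pd[order(pd$start), , drop = FALSE]
      gd <- g[g$doc_id == d, , drop = FALSE]
      gd <- gd[order(gd$start), , drop = FALSE]
      used <- logical(nrow(gd))
      for (j in seq_len(nrow(pd))) {
        hit <- if (match == "overlap") {
          !used & gd$start < pd$end[j] & gd$end > pd$start[j]
        } else {
          !used & gd$start == pd$start[j] & gd$end == pd$end[j]
        }
        if (any(hit)) {
          used[which(hit)[1L]] <- TRUE
          tp <- tp + 1L
        }
      }
    }
    out$tp[i] <- tp
    out$fp[i] <- nrow(p) - tp
    out$fn[i] <- nrow(g) - tp
  }
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp),
                          NA_real_)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn),
                       NA_real_)
  out
}

#' Document-level extraction metrics
#'
#' Presence/absence agreement per document and concept: a document counts
#' as predicted (gold) positive for a concept when it holds at least one
#' positive predicted mention (gold entity). Provided alongside the default
#' mention-level scoring because a document-level reading of the evaluation
#' unit is also defensible.
#'
#' @inheritParams score_extraction
#' @return Same shape as [score_extraction()].
#' @export
document_metrics <- function(mentions, gold, concepts = dlb_concepts()) {
  bad <- setdiff(unique(c(mentions$concept, gold$concept)), concepts)
  if (length(bad)) stopf("unknown concept(s): %s", paste(bad, collapse = ", "))
  pred <- mentions[mentions$label == "positive", , drop = FALSE]
  gpos <- gold[gold$label == "positive", , drop = FALSE]
  out <- data.frame(concept = concepts, tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(concepts)) {
    pd <- unique(pred$doc_id[pred$concept == concepts[i]])
    gd <- unique(gpos$doc_id[gpos$concept == concepts[i]])
    out$tp[i] <- length(intersect(pd, gd))
    out$fp[i] <- length(setdiff(pd, gd))
    out$fn[i] <- length(setdiff(gd, pd))
  }
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp),
                          NA_real_)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn),
                       NA_real_)
  out
}

#' Sample a test sub-corpus
#'
#' Uniform, seeded, without-replacement sample of documents - the sampling
#' design behind fixed-size (e.g. 100-document) evaluation sets.
#'
#' @param documents Corpus data.frame.
#' @param n_docs Number of documents to draw (`<= nrow(documents)`).
#' @param seed Integer seed.
#' @return The sampled rows of `documents` (original order preserved).
#' @export
sample_test_corpus <- function(documents, n_docs, seed = 1L) {
  n_docs <- check_count(n_docs, "n_docs")
  if (n_docs > nrow(documents))
    stopf("n_docs (%d) exceeds corpus size (%d)", n_docs, nrow(documents))
  idx <- with_seed(seed, sample.int(nrow(documents), n_docs))
  documents[sort(idx), , drop = FALSE]
}
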