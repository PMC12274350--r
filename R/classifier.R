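#' Build a labelled training set from gold annotations
#'
#' Matches extraction candidates to gold spans (any character overlap, same
#' document and concept). Candidates overlapping a gold `positive` span are
#' labelled `positive`; all others (gold negative/unknown, or no gold at all)
#' are `non_positive`, following the coding where negations and other
#' unwanted mentions are pooled on the non-positive side.
#'
#' @param documents Corpus data.frame (`doc_id`, `patient_id`, `text`).
#' @param gold Gold annotation data.frame (`doc_id`, `concept`, `start`,
#'   `end`, `label` in positive/negative/unknown).
#' @param lexicon A `dlb_lexicon`.
#' @return A data.frame with columns `concept`, `context`, `label`.
#' @export
gold_contexts <- function(documents, gold, lexicon = default_lexicon()) {
  cands <- find_candidates(documents$text, lexicon, documents$doc_id)
  lab <- rep("non_positive", nrow(cands))
  gp <- gold[gold$label == "positive", , drop = FALSE]
  if (nrow(gp) && nrow(cands)) {
    for (i in seq_len(nrow(cands))) {
      g <- gp[gp$doc_id == cands$doc_id[i] &
                gp$concept == cands$concept[i], , drop = FALSE]
      if (nrow(g) && any(g$start < cands$end[i] & g$end > cands$start[i]))
        lab[i] <- "positive"
    }
  }
  data.frame(concept = cands$concept, context = cands$context,
             label = lab, stringsAsFactors = FALSE)
}

#' Train a bag-of-words mention classifier
#'
#' A naive Bayes model over binary token-presence features of the candidate's
#' sentence context, binarised to positive vs non-positive. Deterministic
#' given the training set. With a single-class training set the model cannot
#' be fitted; the returned object then falls back to the rule-based path and
#' carries `fallback = TRUE`.
#'
#' The shipped default pipeline is the deterministic rule path; this
#' classifier is an optional supervised alternative trained on synthetic
#' gold annotations.
#'
#' @param training A data.frame with columns `context` and `label`
#'   (`positive`/`non_positive`), e.g. from [gold_contexts()].
#' @return An object of class `mention_classifier`.
#' @export
train_mention_classifier <- function(training) {
  stopifnot(is.data.frame(training),
            all(c("context", "label") %in% names(training)))
  y <- factor(training$label, levels = c("non_positive", "positive"))
  if (any(is.na(y))) stopf("labels must be positive/non_positive")
  if (nrow(training) == 0L || length(unique(y[!is.na(y)])) < 2L) {
    warning("training set has fewer than two classes; ",
            "falling back to rule-based classification")
    return(structure(list(fallback = TRUE), class = "mention_classifier"))
  }
  toks <- stringr::str_extract_all(stringr::str_to_lower(training$context),
                                   token_pattern)
  vocab <- sort(unique(unlist(toks)))
  x <- token_features(toks, vocab)
  model <- e1071::naiveBayes(x, y, laplace = 1)
  structure(list(fallback = FALSE, vocab = vocab, model = model),
            class = "mention_classifier")
}

token_features <- function(toks, vocab) {
  m <- matrix("0", nrow = length(toks), ncol = length(vocab),
              dimnames = list(NULL, paste0("t_", vocab)))
  for (i in seq_along(toks)) m[i, match(intersect(toks[[i]], vocab), vocab)] <- "1"
  as.data.frame(lapply(as.data.frame(m, stringsAsFactors = FALSE),
                       factor, levels = c("0", "1")))
}

#' Predict mention labels with a trained classifier
#'
#' @param object A `mention_classifier`.
#' @param cands Candidate data.frame from [find_candidates()].
#' @param cues Cue lexicon used for the fallback path and to fill in the
#'   sublabel of non-positive calls (the bag-of-words model itself only
#'   makes the binary call).
#' @param ... Unused.
#' @return Same shape as [classify_mentions()].
#' @export
predict.mention_classifier <- function(object, cands,
                                       cues = default_cues(), ...) {
  rule <- classify_mentions(cands, cues)
  if (object$fallback || !nrow(cands)) return(rule)
  toks <- stringr::str_extract_all(stringr::str_to_lower(cands$context),
                                   token_pattern)
  x <- token_features(toks, object$vocab)
  pred <- as.character(predict(object$model, x))
  sublabel <- ifelse(pred == "positive", "none",
                     ifelse(rule$label == "non_positive",
                            rule$sublabel, "unknown"))
  data.frame(label = pred, sublabel = sublabel, stringsAsFactors = FALSE)
}
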