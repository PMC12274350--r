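# Clinical snippet fixtures used across extraction tests: phrase, the
# concept it mentions, and the side of the positive / non-positive split a
# human coder assigns it.
positive_snippets <- function() {
  data.frame(
    text = c("responding to visual hallucinations",
             "experiencing visual hallucinations",
             "history of visual hallucinations",
             "distressed by visual hallucinations",
             "mood has been fluctuating a lot",
             "suicidal thoughts appear to fluctuate",
             "fluctuating attention",
             "fluctuating cognitive impairment",
             "there was evidence of a tremor when writing",
             "with a degree of resting tremor",
             "presence of bradykinesia",
             "motor symptoms - moderate bradykinesia L > R",
             "had a bad dream last night",
             "frequently has bad dreams",
             "unsettled sleep with vivid nightmares"),
    concept = c(rep("visual_hallucinations", 4L), rep("fluctuations", 4L),
                rep("tremor", 2L), rep("bradykinesia", 2L),
                rep("bad_dreams", 2L), "nightmares"),
    stringsAsFactors = FALSE)
}

non_positive_snippets <- function() {
  data.frame(
    text = c("denied any visual hallucinations",
             "not responding to visual hallucinations",
             "not experiencing visual hallucinations",
             "no current visual hallucinations",
             "no visual hallucinations",
             "no evidence of mood fluctuation",
             "does not appear to have significant fluctuations in mental state",
             "monitoring to see if fluctuations deteriorate",
             "his mother's responsibility fluctuated",
             "is the person's risk is likely to fluctuate"),
    concept = c(rep("visual_hallucinations", 5L), rep("fluctuations", 5L)),
    stringsAsFactors = FALSE)
}

# Label the first mention of `concept` in a free-standing phrase.
label_phrase <- function(text, concept) {
  m <- extract_document(list(doc_id = "s1", text = text))
  m <- m[m$concept == concept, , drop = FALSE]
  if (!nrow(m)) return(NA_character_)
  m$label[1L]
}

tiny_mentions <- function(concept, label = "positive", doc = "d1",
                          start = 0L, end = 6L) {
  data.frame(doc_id = doc, concept = concept, start = start, end = end,
             label = label, sublabel = ifelse(label == "positive", "none",
                                              "negated"),
             stringsAsFactors = FALSE)
}
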