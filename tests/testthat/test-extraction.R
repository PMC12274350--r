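# Mention detection and positive / non-positive classification.

test_that("keyword matching finds single-stem candidates with correct spans", {
  cands <- find_candidates("There was evidence of a tremor when writing.")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$concept, "tremor")
  expect_equal(substr("There was evidence of a tremor when writing.",
                      cands$start + 1L, cands$end), "tremor")
  expect_equal(nrow(find_candidates("")), 0L)
  expect_equal(nrow(find_candidates(character())), 0L)
})

test_that("proximity matching for visual hallucinations agrees with a
           brute-force token-pair oracle at every window", {
  sentences <- c(
    "experiencing visual hallucinations at night",
    "visual and auditory hallucinations were reported",
    "visual field testing revealed hallucinations later",
    "visually striking hallucinatory experience",
    "hallucinations that are visual in nature",
    "visual acuity was poor and she described hallucinations of insects",
    "no mention of either term here",
    "visual problems noted; hallucinations denied emphatically today")
  for (w in c(0L, 2L, 5L, 8L)) {
    lex <- default_lexicon()
    lex$visual_hallucinations$proximity$max_gap <- w
    for (s in sentences) {
      got <- any(find_candidates(s, lex)$concept == "visual_hallucinations")
      expect_identical(got, brute_force_vh(s, w),
                       label = sprintf("'%s' @ gap %d", s, w))
    }
  }
})

test_that("matching is case-insensitive and spans are unchanged", {
  s <- "Distressed by VISUAL HALLUCINATIONS and a Tremor."
  a <- find_candidates(s)
  b <- find_candidates(tolower(s))
  expect_equal(a[c("concept", "start", "end")],
               b[c("concept", "start", "end")])
  expect_setequal(a$concept, c("visual_hallucinations", "tremor"))
})

test_that("overlapping matches of one concept merge into one maximal
           candidate", {
  s <- "Complains of visual hallucinations, visual vivid hallucinations."
  cands <- find_candidates(s)
  vh <- cands[cands$concept == "visual_hallucinations", ]
  if (nrow(vh) > 1L) {
    for (i in seq_len(nrow(vh) - 1L))
      expect_gte(vh$start[i + 1L], vh$end[i])
  }
  expect_gte(nrow(vh), 1L)
})

test_that("adding a sentence never removes candidates from the original
           region", {
  base_docs <- c(
    "He reports recurrent nightmares most weeks.",
    "Her mood has been fluctuating a lot recently. No tremor on examination.",
    "Reports experiencing visual hallucinations most evenings.")
  for (txt in base_docs) {
    before <- find_candidates(txt)
    after <- find_candidates(paste(txt, "Seen again in clinic today."))
    merged <- merge(before[c("concept", "start", "end")],
                    after[c("concept", "start", "end")])
    expect_equal(nrow(merged), nrow(before), label = txt)
  }
})

test_that("negation, uncertainty and irrelevant-experiencer cues drive the
           non-positive call with the right sublabel", {
  lab <- function(text) {
    m <- extract_document(list(doc_id = "x", text = text))
    m[1L, c("label", "sublabel")]
  }
  expect_equal(lab("distressed by visual hallucinations")$label, "positive")
  r <- lab("does not appear to have significant fluctuations in mental state")
  expect_equal(r$label, "non_positive")
  expect_equal(r$sublabel, "negated")
  r <- lab("monitoring to see if fluctuations deteriorate")
  expect_equal(r$label, "non_positive")
  expect_equal(r$sublabel, "unknown")
  r <- lab("his mother's responsibility fluctuated")
  expect_equal(r$label, "non_positive")
  expect_equal(r$sublabel, "irrelevant")
  # cue out of scope (> 6 tokens upstream) no longer applies
  far <- paste("not once in the last twelve long months has he described",
               "a tremor")
  expect_equal(lab(far)$label, "positive")
  # cue in the previous sentence does not scope across the boundary
  r <- lab("No concerns were raised. A mild intention tremor was observed.")
  expect_equal(r$label, "positive")
})

test_that("every human-coded snippet lands on its side of the split", {
  pos <- positive_snippets()
  for (i in seq_len(nrow(pos)))
    expect_equal(label_phrase(pos$text[i], pos$concept[i]), "positive",
                 label = pos$text[i])
  neg <- non_positive_snippets()
  for (i in seq_len(nrow(neg)))
    expect_equal(label_phrase(neg$text[i], neg$concept[i]), "non_positive",
                 label = neg$text[i])
})

test_that("extract_document composes detection and classification across
           concepts", {
  m <- extract_document(list(
    doc_id = "d9",
    text = paste("Examination confirmed the presence of bradykinesia.",
                 "Unsettled sleep with vivid nightmares was described.",
                 "She denied any bad dreams recently.")))
  expect_setequal(m$concept[m$label == "positive"],
                  c("bradykinesia", "nightmares"))
  expect_equal(m$label[m$concept == "bad_dreams"], "non_positive")
  none <- extract_document(list(doc_id = "d0",
                                text = "Seen at home; plan unchanged."))
  expect_equal(nrow(none), 0L)
})

test_that("the bag-of-words classifier learns the synthetic gold and beats
           or matches the rule baseline on its training snippets", {
  corp <- generate_corpus(n_ad = 40, n_dlb = 20, seed = 31)
  training <- gold_contexts(corp$documents, corp$gold)
  expect_gte(min(table(training$label)), 2L)
  clf <- train_mention_classifier(training)
  expect_false(clf$fallback)
  cands <- find_candidates(corp$documents$text,
                           doc_id = corp$documents$doc_id)
  truth <- training$label
  ml <- predict(clf, cands)$label
  rule <- classify_mentions(cands)$label
  expect_gte(mean(ml == truth), mean(rule == truth))
})

test_that("disjoint class vocabularies separate perfectly on held-out
           copies", {
  train <- data.frame(
    context = c("alpha beta gamma", "beta gamma delta",
                "omega psi chi", "psi chi phi"),
    label = c("positive", "positive", "non_positive", "non_positive"))
  clf <- train_mention_classifier(train)
  held <- data.frame(doc_id = "h", concept = "tremor", start = 0L,
                     end = 1L, context = c("gamma alpha", "chi omega"),
                     context_start = 0L)
  expect_equal(predict(clf, held)$label, c("positive", "non_positive"))
})

test_that("a single-class training corpus falls back to rules with a
           warning", {
  train <- data.frame(context = c("a b", "b c"),
                      label = c("positive", "positive"))
  expect_warning(clf <- train_mention_classifier(train), "fall")
  expect_true(clf$fallback)
  cands <- find_candidates("She denied any tremor or shaking.")
  expect_equal(predict(clf, cands)$label, "non_positive")
})
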