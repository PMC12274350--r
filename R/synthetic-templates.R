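# Template bank for the synthetic note generator.
#
# Each template is a (prefix, keyword, suffix) triple; the planted gold span
# covers exactly the keyword region, which is what the lexicon matcher
# retrieves. Positive templates contain no classification cues; negative and
# unknown templates carry their cue within rule scope, so the rule-based
# extractor reproduces the gold labels exactly on noise-free text.
# Phrasings follow the wording patterns seen in dementia service notes.

mention_templates <- function() {
  tp <- function(concept, label, prefix, keyword, suffix) {
    data.frame(concept = concept, label = label, prefix = prefix,
               keyword = keyword, suffix = suffix, stringsAsFactors = FALSE)
  }
  rbind(
    # visual hallucinations (proximity concept: keyword carries both stems)
    tp("visual_hallucinations", "positive",
       "She has been responding to ", "visual hallucinations",
       " during the evening."),
    tp("visual_hallucinations", "positive",
       "Reports experiencing ", "visual hallucinations", " most evenings."),
    tp("visual_hallucinations", "positive",
       "There is a history of ", "visual hallucinations",
       " going back several months."),
    tp("visual_hallucinations", "positive",
       "He remains distressed by ", "visual hallucinations",
       " of small animals."),
    tp("visual_hallucinations", "negative",
       "She denied any ", "visual hallucinations", " when asked directly."),
    tp("visual_hallucinations", "negative",
       "He is not experiencing ", "visual hallucinations", " at present."),
    tp("visual_hallucinations", "negative",
       "No current ", "visual hallucinations", " were reported."),
    tp("visual_hallucinations", "unknown",
       "Unclear whether ", "visual hallucinations",
       " are contributing to her distress."),
    # fluctuations
    tp("fluctuations", "positive",
       "Her mood has been ", "fluctuating", " a lot recently."),
    tp("fluctuations", "positive",
       "Suicidal thoughts appear to ", "fluctuate", " from day to day."),
    tp("fluctuations", "positive",
       "", "Fluctuating", " attention was noted on the ward."),
    tp("fluctuations", "positive",
       "Presentation shows ", "fluctuating", " cognitive impairment."),
    tp("fluctuations", "negative",
       "There was no evidence of mood ", "fluctuation", " at review."),
    tp("fluctuations", "negative",
       "He does not appear to have significant ", "fluctuations",
       " in mental state."),
    tp("fluctuations", "unknown",
       "We are monitoring to see if ", "fluctuations", " deteriorate."),
    tp("fluctuations", "unknown",
       "The risk is likely to ", "fluctuate", " over the coming weeks."),
    tp("fluctuations", "unknown",
       "His mother's responsibility ", "fluctuated", " during childhood."),
    # tremor
    tp("tremor", "positive",
       "There was evidence of a ", "tremor", " when writing."),
    tp("tremor", "positive",
       "Examination revealed a degree of resting ", "tremor",
       " in the right hand."),
    tp("tremor", "positive", "A mild intention ", "tremor", " was observed."),
    tp("tremor", "negative", "There was no ", "tremor", " on examination."),
    tp("tremor", "negative", "She denied any ", "tremor", " or shaking."),
    tp("tremor", "unknown",
       "We will monitor to see if the ", "tremor", " progresses."),
    # bradykinesia
    tp("bradykinesia", "positive",
       "Examination confirmed the presence of ", "bradykinesia", " today."),
    tp("bradykinesia", "positive",
       "Motor review showed moderate ", "bradykinesia", " on the left."),
    tp("bradykinesia", "negative",
       "There was no ", "bradykinesia", " or rigidity evident."),
    tp("bradykinesia", "unknown",
       "Unclear whether mild ", "bradykinesia", " is developing."),
    # bad dreams
    tp("bad_dreams", "positive", "She had a ", "bad dream", " last night."),
    tp("bad_dreams", "positive",
       "He frequently has ", "bad dreams", " that wake him."),
    tp("bad_dreams", "negative", "She denied any ", "bad dreams", " recently."),
    tp("bad_dreams", "negative",
       "There were no ", "bad dreams", " reported this week."),
    tp("bad_dreams", "unknown",
       "Unclear whether the ", "bad dreams", " have settled."),
    # nightmares
    tp("nightmares", "positive",
       "Unsettled sleep with vivid ", "nightmares", " was described."),
    tp("nightmares", "positive",
       "He reports recurrent ", "nightmares", " most weeks."),
    tp("nightmares", "negative", "No ", "nightmares", " were reported."),
    tp("nightmares", "unknown",
       "We are monitoring to see if the ", "nightmares", " settle.")
  )
}

# Neutral clinical sentences containing no concept keyword stems.
distractor_sentences <- function() {
  c("Seen at home with the community nurse in attendance.",
    "Medication list reviewed and repeat prescription issued.",
    "Attended the memory clinic accompanied by a family member.",
    "Blood pressure and pulse were within normal limits.",
    "Sleep and appetite were discussed during the review.",
    "Care package remains in place twice daily.",
    "Cognitive testing completed with a stable overall score.",
    "Plans for follow-up in three months were agreed.",
    "Collateral history obtained by telephone earlier today.",
    "Continues to enjoy gardening and short walks.",
    "No concerns were raised about diet this week.",
    "Referral letter copied to the general practitioner.")
}
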