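# Cue lexicon for mention classification. A cue scopes over a candidate in
# the same sentence within max_gap intervening word tokens; the nearest cue
# wins. "?" is special-cased as an immediate-prefix query marker.
negated: ["no", "not", "never", "denied", "denies", "deny", "without", "nil", "free of"]
unknown: ["monitoring to see if", "to see if", "likely to", "unclear whether", "whether", "query", "?"]
irrelevant: ["mother", "father", "wife", "husband", "sister", "brother", "daughter", "son", "carer", "neighbour"]
max_gap: 6
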