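# Concept lexicon for the six elementary DLB-feature concepts.
# Stems use a trailing `*` wildcard meaning "any trailing word characters";
# matching is case-insensitive. visual_hallucinations is the only concept
# matched by a proximity rule (both stems in the same sentence within
# max_gap intervening word tokens).
visual_hallucinations:
  proximity:
    stems: ["visual", "hallucinat*"]
    max_gap: 5
fluctuations:
  patterns: ["fluctuat*"]
tremor:
  patterns: ["tremor*"]
bradykinesia:
  patterns: ["bradykinesi*"]
bad_dreams:
  patterns: ["bad dream*"]
nightmares:
  patterns: ["nightmare*"]
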