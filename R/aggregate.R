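#' Aggregate one patient's mentions to a symptom profile
#'
#' An elementary symptom is flagged if at least one positive mention of it
#' occurs anywhere in the patient's record - the whole record is used, with
#' no time window, so a single positive mention suffices for a lifetime flag
#' and non-positive mentions never veto it. Derived flags:
#' parkinsonism = tremor OR bradykinesia; rbd = bad_dreams OR nightmares;
#' `core_count` counts the true members of {vh, fluct, parkinsonism, rbd}.
#'
#' @param mentions Labelled mention data.frame for a single patient (columns
#'   `concept`, `label`; a `patient_id` column, if present, must be
#'   constant).
#' @return One-row data.frame with the six elementary flags, the four core
#'   flags and `core_count`.
#' @export
#' @examples
#' m <- data.frame(concept = "tremor", label = "positive")
#' aggregate_patient(m)  # parkinsonism TRUE, core_count 1
aggregate_patient <- function(mentions) {
  if ("patient_id" %in% names(mentions) &&
      length(unique(mentions$patient_id)) > 1L)
    stopf("mentions span multiple patients: %s",
          paste(unique(mentions$patient_id), collapse = ", "))
  bad <- setdiff(unique(mentions$concept), dlb_concepts())
  if (length(bad)) stopf("unknown concept(s): %s", paste(bad, collapse = ", "))
  pos <- mentions$concept[mentions$label == "positive"]
  flags <- vapply(dlb_concepts(), function(cc) cc %in% pos, logical(1))
  profile_from_flags(matrix(flags, nrow = 1L,
                            dimnames = list(NULL, dlb_concepts())))
}

# Vectorised: rows of `m` are patients, columns the six elementary flags.
profile_from_flags <- function(m) {
  vh <- m[, "visual_hallucinations"]
  fluct <- m[, "fluctuations"]
  parkinsonism <- m[, "tremor"] | m[, "bradykinesia"]
  rbd <- m[, "bad_dreams"] | m[, "nightmares"]
  data.frame(vh = vh, fluct = fluct, parkinsonism = parkinsonism, rbd = rbd,
             tremor = m[, "tremor"], bradykinesia = m[, "bradykinesia"],
             bad_dreams = m[, "bad_dreams"], nightmares = m[, "nightmares"],
             core_count = as.integer(vh) + as.integer(fluct) +
               as.integer(parkinsonism) + as.integer(rbd),
             row.names = NULL)
}

#' Aggregate a whole corpus of mentions to patient-level profiles
#'
#' @param mentions Labelled mention data.frame (`doc_id`, `concept`,
#'   `label`, ...), e.g. from [extract_corpus()].
#' @param documents Corpus data.frame linking `doc_id` to `patient_id`.
#' @param patients Patient table (`patient_id`, `diagnosis`, ...); every
#'   patient appears in the output, including those with no mentions.
#' @return A data.frame with one row per patient: `patient_id`, `diagnosis`,
#'   flags, `core_count`, `category` and `ad2cs_flag` (see
#'   [classify_criteria()]).
#' @export
aggregate_profiles <- function(mentions, documents, patients) {
  bad <- setdiff(unique(mentions$concept), dlb_concepts())
  if (length(bad)) stopf("unknown concept(s): %s", paste(bad, collapse = ", "))
  pid <- documents$patient_id[match(mentions$doc_id, documents$doc_id)]
  if (nrow(mentions) && anyNA(pid))
    stopf("mentions reference doc_ids missing from the corpus")
  pos <- mentions$label == "positive"
  m <- matrix(FALSE, nrow = nrow(patients), ncol = 6L,
              dimnames = list(NULL, dlb_concepts()))
  if (any(pos)) {
    ri <- match(pid[pos], patients$patient_id)
    if (anyNA(ri)) stopf("mentions reference patients missing from the table")
    m[cbind(ri, match(mentions$concept[pos], dlb_concepts()))] <- TRUE
  }
  prof <- profile_from_flags(m)
  crit <- classify_criteria(patients$diagnosis, prof$core_count)
  cbind(data.frame(patient_id = patients$patient_id,
                   diagnosis = patients$diagnosis,
                   stringsAsFactors = FALSE),
        prof, crit)
}

#' Score core-symptom counts against the DLB criteria categories
#'
#' Zero core features maps to `none`, exactly one to `one_feature` (the
#' criterion for possible DLB), two or more to `two_plus` (the profile that
#' could meet probable-DLB criteria). `ad2cs_flag` marks AD-diagnosed
#' patients with two or more core features (the AD2CS stratum). The category
#' describes the recorded symptom profile; no diagnosis change is asserted.
#'
#' @param diagnosis Character vector, `"AD"` or `"DLB"`.
#' @param core_count Integer vector in 0..4, or a profile data.frame with a
#'   `core_count` column.
#' @return A data.frame with columns `category` and `ad2cs_flag`.
#' @export
#' @examples
#' classify_criteria("AD", 2)  # two_plus, ad2cs_flag TRUE
classify_criteria <- function(diagnosis, core_count) {
  if (is.data.frame(core_count)) core_count <- core_count$core_count
  if (any(core_count < 0 | core_count > 4))
    stopf("core_count must lie in 0..4")
  category <- ifelse(core_count == 0L, "none",
                     ifelse(core_count == 1L, "one_feature", "two_plus"))
  data.frame(category = category,
             ad2cs_flag = diagnosis == "AD" & core_count >= 2L,
             stringsAsFactors = FALSE)
}
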