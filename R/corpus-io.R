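# On-disk corpus formats: JSONL documents (one object per line with keys
# doc_id, patient_id, text), CSV patient table, CSV gold annotations and CSV
# mention/profile/metrics tables. All spans on disk are 0-based half-open
# character offsets. Writers are deterministic: identical inputs give
# byte-identical files.

write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

read_jsonl <- function(path, proto) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0L) return(proto)
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  df[names(proto)]
}

write_csv_ <- function(df, path) {
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) stopf("failed writing %s: %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

read_csv_ <- function(path, classes) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  utils::read.csv(path, colClasses = classes, stringsAsFactors = FALSE)
}

#' Write a synthetic corpus to a directory
#'
#' Emits `documents.jsonl`, `patients.csv`, `gold.csv` and - when planted
#' profiles are present - `true_profiles.csv` (the synthetic ground truth,
#' kept separate from any extraction output). Identifiers must be consistent
#' across the collections. Round-trips losslessly through [read_corpus()].
#'
#' @param corpus A list with `documents`, `patients`, `gold` and optionally
#'   `profiles`, e.g. from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!all(corpus$documents$patient_id %in% corpus$patients$patient_id))
    stopf("documents reference patient_ids missing from the patient table")
  if (!all(corpus$gold$doc_id %in% corpus$documents$doc_id))
    stopf("gold annotations reference doc_ids missing from the documents")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_jsonl(corpus$documents[c("doc_id", "patient_id", "text")],
              file.path(dir, "documents.jsonl"))
  write_csv_(corpus$patients, file.path(dir, "patients.csv"))
  write_csv_(corpus$gold[c("doc_id", "concept", "start", "end", "label")],
             file.path(dir, "gold.csv"))
  if (!is.null(corpus$profiles))
    write_csv_(corpus$profiles, file.path(dir, "true_profiles.csv"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  documents <- read_jsonl(
    file.path(dir, "documents.jsonl"),
    data.frame(doc_id = character(), patient_id = character(),
               text = character(), stringsAsFactors = FALSE))
  patients <- read_csv_(file.path(dir, "patients.csv"),
                        c(patient_id = "character", diagnosis = "character",
                          age_referral = "numeric",
                          age_diagnosis = "numeric", gender = "character",
                          ethnicity = "character", marital = "character"))
  gold <- read_csv_(file.path(dir, "gold.csv"),
                    c(doc_id = "character", concept = "character",
                      start = "integer", end = "integer",
                      label = "character"))
  out <- list(patients = patients, documents = documents, gold = gold)
  pf <- file.path(dir, "true_profiles.csv")
  if (file.exists(pf))
    out$profiles <- read_csv_(pf, c("character", rep("logical", 6L)))
  out
}

#' Read and write mention tables
#'
#' CSV with header `doc_id,concept,start,end,label,sublabel`.
#' @param mentions Mention data.frame from [extract_corpus()].
#' @param path File path.
#' @export
write_mentions <- function(mentions, path) {
  write_csv_(mentions[c("doc_id", "concept", "start", "end", "label",
                        "sublabel")], path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  read_csv_(path, c(doc_id = "character", concept = "character",
                    start = "integer", end = "integer",
                    label = "character", sublabel = "character"))
}

#' Read and write patient-level symptom profiles
#'
#' CSV with header `patient_id,diagnosis,vh,fluct,parkinsonism,rbd,tremor,`
#' `bradykinesia,bad_dreams,nightmares,core_count,category,ad2cs_flag`.
#' @param profiles Profile data.frame from [aggregate_profiles()].
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) write_csv_(profiles, path)

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  read_csv_(path, c(patient_id = "character", diagnosis = "character",
                    vh = "logical", fluct = "logical",
                    parkinsonism = "logical", rbd = "logical",
                    tremor = "logical", bradykinesia = "logical",
                    bad_dreams = "logical", nightmares = "logical",
                    core_count = "integer", category = "character",
                    ad2cs_flag = "logical"))
}

#' Write per-concept evaluation metrics
#'
#' CSV with header `concept,tp,fp,fn,precision,recall`.
#' @param metrics Metrics data.frame from [score_extraction()].
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) write_csv_(metrics, path)
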