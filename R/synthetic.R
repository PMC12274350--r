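#' Prevalence and demographic parameters for the synthetic cohort
#'
#' Defaults encode the study population structure: per-group prevalences of
#' the four core features (DLB / AD: visual hallucinations 83.1/16.7%,
#' fluctuations 74.7/30.3%, parkinsonism 62.1/19.7%, possible RBD 26.6/9.3%),
#' ages at first referral (DLB 76.9 sd 10.2; AD 80.6 sd 8.5), female gender
#' (49.0/64.0%), non-White ethnicity (26.4/27.9%) and married/cohabiting
#' status (42.6/34.8%). Composite features are generated through their
#' elementary components: parkinsonism as tremor OR bradykinesia and RBD as
#' bad dreams OR nightmares, each component sampled independently with
#' p = 1 - sqrt(1 - P) so the composite prevalence equals the configured P.
#' Age at diagnosis is age at referral plus a diagnostic delay, by default
#' one year for AD and two years for DLB and for AD patients carrying 2+
#' core features.
#'
#' @param vh,fluct,parkinsonism,rbd Named numeric `c(dlb = , ad = )` core
#'   feature prevalences (probabilities).
#' @param age_referral List with `dlb` and `ad` elements, each
#'   `c(mean = , sd = )`, in years.
#' @param female,non_white,married Named numeric `c(dlb = , ad = )`
#'   probabilities.
#' @param delay_years Named numeric `c(ad = , ad2cs = , dlb = )` diagnostic
#'   delay in years.
#' @return A list of class `prevalence_config`; `$symptoms` holds the
#'   per-group Bernoulli probabilities of the six elementary symptoms.
#' @export
prevalence_config <- function(vh = c(dlb = 0.831, ad = 0.167),
                              fluct = c(dlb = 0.747, ad = 0.303),
                              parkinsonism = c(dlb = 0.621, ad = 0.197),
                              rbd = c(dlb = 0.266, ad = 0.093),
                              age_referral = list(
                                dlb = c(mean = 76.9, sd = 10.2),
                                ad = c(mean = 80.6, sd = 8.5)),
                              female = c(dlb = 0.490, ad = 0.640),
                              non_white = c(dlb = 0.264, ad = 0.279),
                              married = c(dlb = 0.426, ad = 0.348),
                              delay_years = c(ad = 1, ad2cs = 2, dlb = 2)) {
  for (nm in c("vh", "fluct", "parkinsonism", "rbd",
               "female", "non_white", "married"))
    check_prob(get(nm), nm)
  if (any(delay_years < 0)) stopf("delay_years must be non-negative")
  if (any(vapply(age_referral, function(a) a[["sd"]] < 0, logical(1))))
    stopf("age sd must be non-negative")
  or_split <- function(p) 1 - sqrt(1 - p)  # two iid components OR to p
  symptoms <- rbind(
    visual_hallucinations = vh,
    fluctuations = fluct,
    tremor = or_split(parkinsonism),
    bradykinesia = or_split(parkinsonism),
    bad_dreams = or_split(rbd),
    nightmares = or_split(rbd))
  colnames(symptoms) <- c("dlb", "ad")
  structure(list(symptoms = symptoms, age_referral = age_referral,
                 female = female, non_white = non_white, married = married,
                 delay_years = delay_years),
            class = "prevalence_config")
}

#' Document-noise parameters for the synthetic corpus
#'
#' @param docs_per_patient Integer range `c(min, max)` of documents per
#'   patient (uniform).
#' @param distractors_per_doc Integer range of neutral keyword-free
#'   sentences per document (uniform).
#' @param p_negated,p_unknown Per absent elementary symptom, probability of
#'   planting a negated / an unknown (hypothetical or irrelevant) mention of
#'   it, to exercise the classifier. Set both to 0 for a noise-free corpus.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(docs_per_patient = c(1L, 5L),
                         distractors_per_doc = c(2L, 4L),
                         p_negated = 0.10, p_unknown = 0.05) {
  check_prob(p_negated, "p_negated")
  check_prob(p_unknown, "p_unknown")
  if (length(docs_per_patient) != 2L || docs_per_patient[1L] < 1L ||
      diff(docs_per_patient) < 0)
    stopf("docs_per_patient must be an increasing range with min >= 1")
  if (length(distractors_per_doc) != 2L || distractors_per_doc[1L] < 0L ||
      diff(distractors_per_doc) < 0)
    stopf("distractors_per_doc must be a non-negative increasing range")
  structure(list(docs_per_patient = as.integer(docs_per_patient),
                 distractors_per_doc = as.integer(distractors_per_doc),
                 p_negated = p_negated, p_unknown = p_unknown),
            class = "noise_config")
}

#' Generate a synthetic two-group cohort with planted symptom profiles
#'
#' Samples AD and DLB patients with group-specific demographics and
#' independent Bernoulli elementary symptoms (the planted ground truth kept
#' separately from any extraction output). Each patient draws from its own
#' deterministic RNG substream of the master seed, so regeneration is stable
#' under cohort-size changes and identical seeds give identical cohorts.
#'
#' @param n_ad,n_dlb Number of AD / DLB patients (non-negative).
#' @param params A [prevalence_config()].
#' @param seed Master integer seed.
#' @return A list with `patients` (patient_id, diagnosis, age_referral,
#'   age_diagnosis, gender, ethnicity, marital) and `profiles` (patient_id
#'   plus the six planted elementary flags).
#' @export
#' @examples
#' cohort <- generate_cohort(n_ad = 20, n_dlb = 5, seed = 1)
#' table(cohort$patients$diagnosis)
generate_cohort <- function(n_ad, n_dlb, params = prevalence_config(),
                            seed = 1L) {
  n_ad <- check_count(n_ad, "n_ad")
  n_dlb <- check_count(n_dlb, "n_dlb")
  if (!inherits(params, "prevalence_config"))
    stopf("params must come from prevalence_config()")
  n <- n_ad + n_dlb
  diagnosis <- rep(c("AD", "DLB"), c(n_ad, n_dlb))
  grp <- ifelse(diagnosis == "AD", "ad", "dlb")
  patient_id <- sprintf("P%06d", seq_len(n))

  flags <- matrix(FALSE, nrow = n, ncol = 6L,
                  dimnames = list(NULL, dlb_concepts()))
  age_ref <- numeric(n)
  female <- logical(n); nonwhite <- logical(n); married <- logical(n)
  for (i in seq_len(n)) {
    set.seed(split_seed(seed, i))
    u <- stats::runif(10L)
    g <- grp[i]
    flags[i, ] <- u[1:6] < params$symptoms[, g]
    female[i] <- u[7L] < params$female[[g]]
    nonwhite[i] <- u[8L] < params$non_white[[g]]
    married[i] <- u[9L] < params$married[[g]]
    a <- params$age_referral[[g]]
    age_ref[i] <- stats::qnorm(u[10L], a[["mean"]], a[["sd"]])
  }
  profiles <- cbind(data.frame(patient_id = patient_id,
                               stringsAsFactors = FALSE),
                    as.data.frame(flags))
  core2 <- profile_from_flags(flags)$core_count >= 2L
  delay <- ifelse(diagnosis == "DLB", params$delay_years[["dlb"]],
                  ifelse(core2, params$delay_years[["ad2cs"]],
                         params$delay_years[["ad"]]))
  patients <- data.frame(
    patient_id = patient_id, diagnosis = diagnosis,
    age_referral = round(age_ref, 1L),
    age_diagnosis = round(age_ref, 1L) + delay,
    gender = ifelse(female, "female", "male"),
    ethnicity = ifelse(nonwhite, "non_white", "white"),
    marital = ifelse(married, "married_cohabiting", "other"),
    stringsAsFactors = FALSE)
  list(patients = patients, profiles = profiles)
}

# Render one patient's documents. Returns flat vectors (cheap to concatenate
# across a large cohort).
render_patient <- function(patient_id, flags, noise, seed,
                           templates, distractors) {
  set.seed(seed)
  n_docs <- sample(noise$docs_per_patient[1L]:noise$docs_per_patient[2L], 1L)
  docs <- vector("list", n_docs)
  for (k in seq_len(n_docs)) {
    nd <- sample(noise$distractors_per_doc[1L]:noise$distractors_per_doc[2L],
                 1L)
    idx <- if (nd) sample.int(length(distractors), nd, replace = TRUE)
    docs[[k]] <- data.frame(
      text = distractors[idx], concept = rep(NA_character_, nd),
      label = rep(NA_character_, nd), kw_start = rep(NA_integer_, nd),
      kw_end = rep(NA_integer_, nd), stringsAsFactors = FALSE)
  }
  plant <- function(concept, label) {
    pool <- templates[templates$concept == concept &
                        templates$label == label, , drop = FALSE]
    tpl <- pool[sample.int(nrow(pool), 1L), ]
    k <- sample.int(n_docs, 1L)
    row <- data.frame(
      text = paste0(tpl$prefix, tpl$keyword, tpl$suffix),
      concept = concept, label = label,
      kw_start = nchar(tpl$prefix),
      kw_end = nchar(tpl$prefix) + nchar(tpl$keyword),
      stringsAsFactors = FALSE)
    d <- docs[[k]]
    at <- sample.int(nrow(d) + 1L, 1L)  # insertion point
    docs[[k]] <<- rbind(utils::head(d, at - 1L), row,
                        utils::tail(d, nrow(d) - at + 1L))
  }
  for (concept in dlb_concepts()) {
    if (flags[[concept]]) {
      plant(concept, "positive")
    } else {
      u <- stats::runif(2L)
      if (u[1L] < noise$p_negated) plant(concept, "negative")
      else if (u[2L] < noise$p_unknown) plant(concept, "unknown")
    }
  }
  doc_id <- paste0(patient_id, "-D", seq_len(n_docs))
  texts <- character(n_docs)
  gold <- list()
  for (k in seq_len(n_docs)) {
    d <- docs[[k]]
    if (!nrow(d)) {  # a document must not be empty
      d <- data.frame(text = distractors[1L], concept = NA_character_,
                      label = NA_character_, kw_start = NA_integer_,
                      kw_end = NA_integer_, stringsAsFactors = FALSE)
    }
    offs <- c(0L, cumsum(nchar(d$text) + 1L))[seq_len(nrow(d))]
    texts[k] <- paste(d$text, collapse = " ")
    has <- !is.na(d$concept)
    if (any(has)) {
      gold[[length(gold) + 1L]] <- data.frame(
        doc_id = doc_id[k], concept = d$concept[has],
        start = offs[has] + d$kw_start[has],
        end = offs[has] + d$kw_end[has],
        label = d$label[has], stringsAsFactors = FALSE)
    }
  }
  list(doc_id = doc_id, text = texts,
       gold = if (length(gold)) do.call(rbind, gold))
}

#' Render synthetic clinical documents for one patient
#'
#' Builds the patient's notes from a table-driven template bank: every true
#' planted symptom receives at least one positive-labelled mention; absent
#' symptoms may receive negated or unknown mentions (controlled by `noise`);
#' neutral distractor sentences carry no concept keywords. Gold spans
#' (0-based half-open) exactly cover the planted keyword regions.
#'
#' @param patient One-row patient data.frame (needs `patient_id`).
#' @param profile One-row planted profile (the six elementary flags).
#' @param noise A [noise_config()].
#' @param seed Integer seed for this patient.
#' @return A list with `documents` (doc_id, patient_id, text) and `gold`
#'   (doc_id, concept, start, end, label).
#' @export
render_documents <- function(patient, profile, noise = noise_config(),
                             seed = 1L) {
  r <- render_patient(patient$patient_id[1L],
                      as.list(profile[1L, dlb_concepts()]),
                      noise, seed, mention_templates(),
                      distractor_sentences())
  gold_proto <- data.frame(doc_id = character(), concept = character(),
                           start = integer(), end = integer(),
                           label = character(), stringsAsFactors = FALSE)
  list(documents = data.frame(doc_id = r$doc_id,
                              patient_id = patient$patient_id[1L],
                              text = r$text, stringsAsFactors = FALSE),
       gold = r$gold %||% gold_proto)
}

#' Generate a complete synthetic corpus
#'
#' [generate_cohort()] plus [render_documents()] for every patient, under
#' one master seed (deterministically split per patient). Identical inputs
#' and seed give a byte-identical corpus on disk.
#'
#' @inheritParams generate_cohort
#' @param noise A [noise_config()].
#' @return A list with `patients`, `profiles`, `documents` and `gold`.
#' @export
generate_corpus <- function(n_ad, n_dlb, params = prevalence_config(),
                            noise = noise_config(), seed = 1L) {
  cohort <- generate_cohort(n_ad, n_dlb, params, seed)
  n <- nrow(cohort$patients)
  templates <- mention_templates()
  distractors <- distractor_sentences()
  doc_id <- vector("list", n); text <- vector("list", n)
  pat_of_doc <- vector("list", n); gold <- vector("list", n)
  for (i in seq_len(n)) {
    flags <- as.list(cohort$profiles[i, dlb_concepts()])
    r <- render_patient(cohort$patients$patient_id[i], flags, noise,
                        split_seed(seed, 1000000L + i), templates,
                        distractors)
    doc_id[[i]] <- r$doc_id
    text[[i]] <- r$text
    pat_of_doc[[i]] <- rep(cohort$patients$patient_id[i],
                           length(r$doc_id))
    gold[[i]] <- r$gold
  }
  documents <- data.frame(doc_id = as.character(unlist(doc_id)),
                          patient_id = as.character(unlist(pat_of_doc)),
                          text = as.character(unlist(text)),
                          stringsAsFactors = FALSE)
  gold <- gold[!vapply(gold, is.null, logical(1))]
  gold <- if (length(gold)) do.call(rbind, gold) else
    data.frame(doc_id = character(), concept = character(),
               start = integer(), end = integer(), label = character(),
               stringsAsFactors = FALSE)
  rownames(gold) <- NULL
  c(cohort, list(documents = documents, gold = gold))
}
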