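# Synthetic cohort and corpus generator.

test_that("cohort generation validates inputs and handles the empty case", {
  empty <- generate_cohort(0, 0, seed = 1)
  expect_equal(nrow(empty$patients), 0L)
  expect_equal(nrow(empty$profiles), 0L)
  expect_error(generate_cohort(-1, 5, seed = 1), "non-negative")
  expect_error(prevalence_config(vh = c(dlb = 1.2, ad = 0.1)), "probability")
  expect_error(noise_config(p_negated = -0.1), "probability")
})

test_that("degenerate probabilities plant deterministic symptoms", {
  params <- prevalence_config(vh = c(dlb = 1, ad = 0))
  cohort <- generate_cohort(n_ad = 40, n_dlb = 40, params, seed = 3)
  dlb <- cohort$patients$diagnosis == "DLB"
  expect_true(all(cohort$profiles$visual_hallucinations[dlb]))
  expect_false(any(cohort$profiles$visual_hallucinations[!dlb]))
})

test_that("identical seeds regenerate identical cohorts; patients keep their
           substreams when the cohort grows", {
  a <- generate_cohort(50, 20, seed = 9)
  b <- generate_cohort(50, 20, seed = 9)
  expect_identical(a, b)
  c <- generate_cohort(50, 20, seed = 10)
  expect_false(identical(a$profiles, c$profiles))
  # growing the AD arm appends; the first patients are untouched
  bigger <- generate_cohort(80, 20, seed = 9)
  expect_identical(a$patients[1:50, ], bigger$patients[1:50, ])
})

test_that("planted core-feature prevalences are recovered within exact
           binomial 99% intervals", {
  n <- 800
  cohort <- generate_cohort(n_ad = n, n_dlb = n, seed = 5)
  params <- prevalence_config()
  prof <- cohort$profiles
  prof$parkinsonism <- prof$tremor | prof$bradykinesia
  prof$rbd <- prof$bad_dreams | prof$nightmares
  prof$vh <- prof$visual_hallucinations
  prof$fluct <- prof$fluctuations
  planted <- list(vh = c(0.831, 0.167), fluct = c(0.747, 0.303),
                  parkinsonism = c(0.621, 0.197), rbd = c(0.266, 0.093))
  dlb <- cohort$patients$diagnosis == "DLB"
  for (feat in names(planted)) {
    for (g in 1:2) {
      obs <- mean(prof[[feat]][if (g == 1) dlb else !dlb])
      ci <- exact_binomial_interval(n, planted[[feat]][g], 0.99)
      expect_gte(obs, ci[["lower"]])
      expect_lte(obs, ci[["upper"]])
    }
  }
})

test_that("age at diagnosis never precedes age at referral and delays follow
           the configured strata", {
  cohort <- generate_cohort(300, 100, seed = 21)
  p <- cohort$patients
  expect_true(all(p$age_diagnosis >= p$age_referral))
  delay <- round(p$age_diagnosis - p$age_referral, 6)
  expect_true(all(delay[p$diagnosis == "DLB"] == 2))
  expect_true(all(delay[p$diagnosis == "AD"] %in% c(1, 2)))
})

test_that("a null profile with noise off renders keyword-free documents and
           empty gold", {
  profile <- as.data.frame(as.list(setNames(rep(FALSE, 6), dlb_concepts())))
  r <- render_documents(data.frame(patient_id = "PX"), profile,
                        noise_config(p_negated = 0, p_unknown = 0),
                        seed = 4)
  expect_gt(nrow(r$documents), 0L)
  expect_true(all(nchar(r$documents$text) > 0L))
  expect_equal(nrow(r$gold), 0L)
  expect_equal(nrow(find_candidates(r$documents$text)), 0L)
})

test_that("true symptoms always yield a positive planted mention and gold
           spans slice to the keyword", {
  stems <- c(visual_hallucinations = "visual", fluctuations = "fluctuat",
             tremor = "tremor", bradykinesia = "bradykinesi",
             bad_dreams = "bad dream", nightmares = "nightmare")
  for (s in 1:8) {
    set.seed(100 + s)
    flags <- setNames(as.list(runif(6) < 0.5), dlb_concepts())
    r <- render_documents(data.frame(patient_id = "PY"),
                          as.data.frame(flags), noise_config(), seed = s)
    for (concept in dlb_concepts()) {
      gpos <- r$gold[r$gold$concept == concept &
                       r$gold$label == "positive", , drop = FALSE]
      if (isTRUE(flags[[concept]])) expect_gte(nrow(gpos), 1L)
      else expect_equal(nrow(gpos), 0L)
    }
    # every gold span (any label) contains its concept's keyword stem
    for (i in seq_len(nrow(r$gold))) {
      txt <- r$documents$text[r$documents$doc_id == r$gold$doc_id[i]]
      sl <- tolower(substr(txt, r$gold$start[i] + 1L, r$gold$end[i]))
      expect_match(sl, stems[[r$gold$concept[i]]], fixed = TRUE)
    }
  }
})

test_that("negation noise plants negated mentions for absent symptoms", {
  profile <- as.data.frame(as.list(setNames(rep(FALSE, 6), dlb_concepts())))
  noisy <- noise_config(p_negated = 1, p_unknown = 0)
  r <- render_documents(data.frame(patient_id = "PZ"), profile, noisy,
                        seed = 2)
  expect_equal(sort(unique(r$gold$label)), "negative")
  expect_equal(sort(unique(r$gold$concept)), sort(dlb_concepts()))
})

test_that("the corpus round-trips losslessly and regenerates byte-identically
           under a fixed seed", {
  corp <- generate_corpus(n_ad = 25, n_dlb = 10, seed = 17)
  d1 <- file.path(tempdir(), "corpus_a")
  d2 <- file.path(tempdir(), "corpus_b")
  write_corpus(corp, d1)
  back <- read_corpus(d1)
  expect_equal(back$patients, corp$patients)
  expect_equal(back$documents, corp$documents)
  expect_equal(back$gold, corp$gold)
  expect_equal(back$profiles, corp$profiles)
  # rerun from scratch: byte-identical files
  write_corpus(generate_corpus(n_ad = 25, n_dlb = 10, seed = 17), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty cohort writes valid empty files with headers", {
  corp <- generate_corpus(0, 0, seed = 1)
  d <- file.path(tempdir(), "corpus_empty")
  write_corpus(corp, d)
  expect_equal(readLines(file.path(d, "patients.csv"))[1],
               paste0('"patient_id","diagnosis","age_referral",',
                      '"age_diagnosis","gender","ethnicity","marital"'))
  back <- read_corpus(d)
  expect_equal(nrow(back$patients), 0L)
  expect_equal(nrow(back$documents), 0L)
  expect_equal(nrow(back$gold), 0L)
  unlink(d, recursive = TRUE)
})

test_that("inconsistent identifiers are rejected at write time", {
  corp <- generate_corpus(n_ad = 3, n_dlb = 1, seed = 2)
  corp$documents$patient_id[1] <- "STRANGER"
  expect_error(write_corpus(corp, file.path(tempdir(), "corpus_bad")),
               "patient_ids")
})
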