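#' Percentage rounded half-up to one decimal
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal place
#' (the display convention of the cohort tables; note base R `round()`
#' rounds half to even).
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return Percentage on the 0-100 scale with one decimal.
#' @export
#' @examples
#' derived_percentage(617, 14329)   # 4.3
#' derived_percentage(2563, 13712)  # 18.7
derived_percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stopf("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator))
    stopf("numerator must lie in [0, denominator]")
  x <- 100 * numerator / denominator
  floor(x * 10 + 0.5 + 1e-9) / 10
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, computed from group means, standard deviations and
#' sizes (the form needed when only summaries are available, as in published
#' tables). A pooled-variance option is available via `pooled = TRUE`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries; `n1, n2 >= 2`,
#'   `sd >= 0`.
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return A data.frame row: `test`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_t_test(76.9, 10.2, 617, 80.6, 8.5, 13712)
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stopf("test undefined: both standard deviations are zero")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- (mean1 - mean2) / se
  data.frame(test = if (pooled) "student_t" else "welch_t",
             statistic = stat, df = df,
             p_value = 2 * stats::pt(-abs(stat), df),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction (the large-sample
#' default), df = (r-1)(c-1), upper-tail p-value. Zero margins are rejected
#' with an error naming the degenerate row or column.
#'
#' @param table An r x c matrix of non-negative counts (r, c >= 2).
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return A data.frame row: `test`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared_test(matrix(c(513, 2290, 104, 11422), nrow = 2))
chi_squared_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stopf("need at least a 2x2 table")
  if (any(table < 0) || any(table != floor(table)))
    stopf("counts must be non-negative integers")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stopf("degenerate table: row %d has zero margin", which(rs == 0)[1L])
  if (any(cs == 0))
    stopf("degenerate table: column %d has zero margin", which(cs == 0)[1L])
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  data.frame(test = "chi_squared",
             statistic = unname(res$statistic),
             df = unname(res$parameter),
             p_value = unname(res$p.value), stringsAsFactors = FALSE)
}

#' Exact binomial interval for an observed proportion
#'
#' Central quantile interval of Binomial(n, p)/n, used for planted-parameter
#' recovery checks: with probability `level` the observed frequency of a
#' planted Bernoulli(p) symptom lies inside.
#'
#' @param n Number of trials.
#' @param p Success probability.
#' @param level Coverage level (default 0.99).
#' @return `c(lower, upper)` on the proportion scale.
#' @export
exact_binomial_interval <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(lower = stats::qbinom(a, n, p) / n,
    upper = stats::qbinom(1 - a, n, p) / n)
}

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

# Per-group summaries -------------------------------------------------------

group_summary <- function(d) {
  n <- nrow(d)
  cont <- function(x) {
    if (n == 0L) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(x), sd = stats::sd(x))
  }
  cat_ <- function(flag) {
    cnt <- sum(flag)
    c(count = cnt, pct = if (n > 0L) derived_percentage(cnt, n) else NA_real_)
  }
  cc <- vapply(0:4, function(k) sum(d$core_count == k), 0)
  names(cc) <- paste0("core", 0:4)
  list(n = n,
       age_referral = cont(d$age_referral),
       age_diagnosis = cont(d$age_diagnosis),
       female = cat_(d$gender == "female"),
       non_white = cat_(d$ethnicity == "non_white"),
       married = cat_(d$marital == "married_cohabiting"),
       vh = cat_(d$vh), rbd = cat_(d$rbd), fluct = cat_(d$fluct),
       parkinsonism = cat_(d$parkinsonism),
       core_count = cc,
       core_count_pct = if (n > 0L)
         vapply(cc, derived_percentage, 0, denominator = n)
       else rep(NA_real_, 5L),
       core_mean = cont(d$core_count))
}

#' Group-wise cohort summaries
#'
#' Splits a merged patient/profile table into groups and computes, per
#' group: n, mean (SD) ages, counts and percentages for gender, ethnicity,
#' marital status and the four core features, the 0-4 core-symptom-count
#' distribution and the mean (SD) core count. Empty groups yield n = 0 with
#' undefined (NA) summaries.
#'
#' @param data Data.frame merging the patient table and profiles (columns
#'   `age_referral`, `age_diagnosis`, `gender`, `ethnicity`, `marital`,
#'   `vh`, `fluct`, `parkinsonism`, `rbd`, `core_count`).
#' @param group Factor (or vector) assigning each row to exactly one group.
#' @return Named list of per-group summary lists.
#' @export
summarize_groups <- function(data, group) {
  if (length(group) != nrow(data))
    stopf("group must assign every patient to exactly one group")
  group <- if (is.factor(group)) group else factor(group, unique(group))
  lapply(split(data, group), group_summary)
}

# Two-group comparisons over the standard variable set.
compare_two <- function(d1, d2) {
  rows <- list()
  add <- function(variable, res) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(variable = variable, stringsAsFactors = FALSE), res)
  }
  skip <- nrow(d1) < 2L || nrow(d2) < 2L
  for (v in c("age_referral", "age_diagnosis")) {
    if (!skip)
      add(v, welch_t_test(mean(d1[[v]]), stats::sd(d1[[v]]), nrow(d1),
                          mean(d2[[v]]), stats::sd(d2[[v]]), nrow(d2)))
  }
  cats <- list(female = quote(gender == "female"),
               non_white = quote(ethnicity == "non_white"),
               married = quote(marital == "married_cohabiting"),
               vh = quote(vh), rbd = quote(rbd), fluct = quote(fluct),
               parkinsonism = quote(parkinsonism))
  for (v in names(cats)) {
    if (skip) next
    y1 <- sum(eval(cats[[v]], d1)); y2 <- sum(eval(cats[[v]], d2))
    tab <- matrix(c(y1, y2, nrow(d1) - y1, nrow(d2) - y2), nrow = 2L)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    add(v, chi_squared_test(tab))
  }
  if (!skip) {
    tab <- rbind(vapply(0:4, function(k) sum(d1$core_count == k), 0),
                 vapply(0:4, function(k) sum(d2$core_count == k), 0))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) >= 2L) add("core_count_distribution",
                             chi_squared_test(tab))
    add("core_mean", welch_t_test(
      mean(d1$core_count), stats::sd(d1$core_count), nrow(d1),
      mean(d2$core_count), stats::sd(d2$core_count), nrow(d2)))
  }
  if (!length(rows))
    return(data.frame(variable = character(), test = character(),
                      statistic = numeric(), df = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

merge_cohort <- function(patients, profiles) {
  d <- merge(patients, profiles[, setdiff(names(profiles), "diagnosis")],
             by = "patient_id", sort = FALSE)
  if (nrow(d) != nrow(patients))
    stopf("patients and profiles do not match one-to-one")
  d
}

fmt_cont <- function(s) {
  if (is.na(s[["mean"]])) "" else sprintf("%.1f (%.1f)", s[["mean"]],
                                          s[["sd"]])
}
fmt_pct <- function(s) {
  if (is.na(s[["pct"]])) "" else sprintf("%.1f%%", s[["pct"]])
}

build_table <- function(summaries, comparisons, p_cols) {
  var_rows <- c(n = "n",
                age_referral = "Age at first referral in years (mean, SD)",
                age_diagnosis =
                  "Age at first dementia diagnosis in years (mean, SD)",
                female = "Female gender (%)",
                non_white = "Non-White ethnicity (%)",
                married = "Married or cohabiting (%)",
                vh = "Visual hallucinations (%)",
                rbd = "REM sleep behaviour disorder (%)",
                fluct = "Fluctuations (%)",
                parkinsonism = "Parkinsonism (%)")
  cells <- function(s, key) {
    switch(key,
           n = as.character(s$n),
           age_referral = fmt_cont(s$age_referral),
           age_diagnosis = fmt_cont(s$age_diagnosis),
           core_mean = fmt_cont(s$core_mean),
           core_count_distribution = "",
           female = , non_white = , married = , vh = , rbd = , fluct = ,
           parkinsonism = fmt_pct(s[[key]]),
           if (startsWith(key, "core")) {
             k <- as.integer(sub("core", "", key))
             if (is.na(s$core_count_pct[k + 1L])) ""
             else sprintf("%.1f%%", s$core_count_pct[k + 1L])
           } else "")
  }
  keys <- names(var_rows)
  extra <- attr(comparisons, "extra_rows") %||% character()
  keys <- c(keys, names(extra))
  var_rows <- c(var_rows, extra)
  tab <- data.frame(variable = unname(var_rows), stringsAsFactors = FALSE)
  for (g in names(summaries))
    tab[[g]] <- vapply(keys, cells, "", s = summaries[[g]])
  for (pc in names(p_cols)) {
    cmp <- p_cols[[pc]]
    tab[[pc]] <- vapply(keys, function(k) {
      i <- match(k, cmp$variable)
      if (is.na(i)) "" else format_p(cmp$p_value[i])
    }, "")
  }
  rownames(tab) <- NULL
  tab
}

#' Cohort comparison tables
#'
#' `table1()` compares the full cohort, DLB and AD groups (DLB vs AD
#' p-values); `table2()` compares AD with fewer than two core features, AD
#' with two or more (the AD2CS stratum) and DLB with two or more, with
#' pairwise p-value columns AD2CS vs AD<2 and AD2CS vs DLB2+ (the pairwise
#' design is reproduced as such; no omnibus test is added). Continuous
#' variables use Welch t-tests, categorical variables Pearson chi-squared
#' tests. Displayed p-values below 0.001 are rendered `<0.001`; exact values
#' are kept in `$comparisons`.
#'
#' @param patients Patient table.
#' @param profiles Patient-level profiles from [aggregate_profiles()].
#' @return A list of class `dlb_cohort_table`: `$table` (formatted
#'   character data.frame), `$summaries` (see [summarize_groups()]) and
#'   `$comparisons` (named list of exact test results).
#' @export
table1 <- function(patients, profiles) {
  d <- merge_cohort(patients, profiles)
  group <- factor(ifelse(d$diagnosis == "DLB", "DLB", "AD"),
                  c("DLB", "AD"))
  summaries <- c(list(full = group_summary(d)),
                 summarize_groups(d, group))
  cmp <- compare_two(d[group == "DLB", ], d[group == "AD", ])
  attr(cmp, "extra_rows") <- c(
    core_count_distribution = "Number of core symptoms recorded",
    core0 = "No core symptom", core1 = "1 core symptom",
    core2 = "2 core symptoms", core3 = "3 core symptoms",
    core4 = "4 core symptoms")
  structure(list(table = build_table(summaries, cmp,
                                     list(p_value = cmp)),
                 summaries = summaries,
                 comparisons = list(dlb_vs_ad = cmp)),
            class = "dlb_cohort_table")
}

#' @rdname table1
#' @export
table2 <- function(patients, profiles) {
  d <- merge_cohort(patients, profiles)
  strata <- ifelse(d$diagnosis == "AD" & d$core_count < 2L, "ad_lt2",
                   ifelse(d$diagnosis == "AD", "ad2cs",
                          ifelse(d$core_count >= 2L, "dlb2plus", NA)))
  d <- d[!is.na(strata), ]
  strata <- factor(strata[!is.na(strata)], c("ad_lt2", "ad2cs", "dlb2plus"))
  summaries <- summarize_groups(d, strata)
  cmp1 <- compare_two(d[strata == "ad2cs", ], d[strata == "ad_lt2", ])
  cmp2 <- compare_two(d[strata == "ad2cs", ], d[strata == "dlb2plus", ])
  extra <- c(core_mean = "Number of core symptoms (mean, SD)")
  attr(cmp1, "extra_rows") <- extra
  structure(list(table = build_table(
    summaries, cmp1,
    list(p_ad2cs_vs_ad_lt2 = cmp1, p_ad2cs_vs_dlb2plus = cmp2)),
    summaries = summaries,
    comparisons = list(ad2cs_vs_ad_lt2 = cmp1,
                       ad2cs_vs_dlb2plus = cmp2)),
    class = "dlb_cohort_table")
}

#' @export
print.dlb_cohort_table <- function(x, ...) {
  print(x$table, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Write cohort tables and an exact-statistics sidecar
#'
#' Emits `table1.csv` and `table2.csv` (formatted cells, `<0.001`
#' convention) plus `stats.json` holding the exact test statistics and
#' p-values.
#'
#' @param t1,t2 Results of [table1()] and [table2()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(t1, t2, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_(t1$table, file.path(dir, "table1.csv"))
  write_csv_(t2$table, file.path(dir, "table2.csv"))
  jsonlite::write_json(list(table1 = t1$comparisons,
                            table2 = t2$comparisons),
                       file.path(dir, "stats.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
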