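#' Response-rate table for the primary cohort
#'
#' Computes the trial's response percentages with numerators, overall
#' and by subtype: breast-only pCR (ypT0/is ypN0-3), breast-and-LN pCR,
#' complete eradication (ypT0 ypN0), near-complete response (nCR),
#' combined pCR + nCR, and breast-conserving surgery. Raw fractions are
#' retained alongside percentages rounded to one decimal.
#'
#' @param outcomes Outcomes data.frame (see [generate_cohort()] for the
#'   schema).
#' @return Data.frame: `measure`, `group`, `numerator`, `denominator`,
#'   `fraction`, `percent`.
#' @export
response_rates <- function(outcomes) {
  assert_columns(outcomes, c("patient_id", "subtype", "breast_pcr",
                             "breast_ln_pcr", "yp_category", "ncr", "surgery"),
                 "outcomes")
  known <- c("HER2_amplified", "TNBC", "HR_pos_HER2_neg_RS_ge_25")
  bad <- setdiff(unique(outcomes$subtype), known)
  if (length(bad) > 0) stop("unknown subtype: ", paste(bad, collapse = ", "))
  measures <- list(
    breast_pcr = outcomes$breast_pcr,
    breast_ln_pcr = outcomes$breast_ln_pcr,
    ypt0_ypn0 = outcomes$yp_category == "ypT0_ypN0",
    ncr = outcomes$ncr,
    pcr_or_ncr = outcomes$breast_pcr | outcomes$ncr,
    breast_conserving = outcomes$surgery == "breast_conserving"
  )
  groups <- c(list(overall = rep(TRUE, nrow(outcomes))),
              stats::setNames(lapply(known, function(s) outcomes$subtype == s), known))
  rows <- list()
  for (mn in names(measures)) {
    for (gn in names(groups)) {
      num <- sum(measures[[mn]] & groups[[gn]])
      den <- sum(groups[[gn]])
      rows[[length(rows) + 1]] <- data.frame(
        measure = mn, group = gn, numerator = num, denominator = den,
        fraction = num / den, percent = round(100 * num / den, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

rate_of <- function(rates, measure, group = "overall") {
  rates$percent[rates$measure == measure & rates$group == group]
}

#' Operating characteristics of a single-stage binomial design
#'
#' For a design that declares success when at least `r` responses are
#' seen among `n` patients, the exact type I error is `P[X >= r]` under
#' the null response rate `p0` and the power is `P[X >= r]` under the
#' alternative `p1`, with `X ~ Binomial(n, p)`. The study's design used
#' n = 40, r = 17, p0 = 0.30, p1 = 0.50.
#'
#' @param n Sample size.
#' @param r Success threshold (declare success when responses >= r).
#' @param p0 Null (uninteresting) response rate.
#' @param p1 Alternative response rate.
#' @return List: `type_i_error`, `power` (probabilities).
#' @export
#' @examples
#' design_operating_characteristics()
design_operating_characteristics <- function(n = 40, r = 17, p0 = 0.30, p1 = 0.50) {
  stopifnot(n >= 1, r >= 0, r <= n, p0 > 0, p1 < 1, p0 < p1)
  list(
    type_i_error = stats::pbinom(r - 1, n, p0, lower.tail = FALSE),
    power = stats::pbinom(r - 1, n, p1, lower.tail = FALSE)
  )
}

#' Kaplan-Meier disease-free survival
#'
#' Product-limit estimate of DFS with right censoring, overall or per
#' subtype, via the survival package. The median is the smallest time at
#' which the survivor function drops to 0.5 or below; with too few
#' events it is undefined (`NA`).
#'
#' @param outcomes Outcomes data.frame with `dfs_months` (nonnegative)
#'   and `dfs_event` (logical).
#' @param by_subtype Fit one curve per subtype instead of pooled.
#' @return List: `fit` (a `survfit`), `table` (data.frame: `group`,
#'   `time`, `n_risk`, `n_event`, `survival`), `median` (named vector).
#' @export
km_dfs <- function(outcomes, by_subtype = FALSE) {
  assert_columns(outcomes, c("dfs_months", "dfs_event"), "outcomes")
  if (any(outcomes$dfs_months < 0)) stop("negative DFS time")
  srv <- survival::Surv(outcomes$dfs_months, as.integer(outcomes$dfs_event))
  fit <- if (by_subtype) {
    survival::survfit(srv ~ subtype, data = outcomes)
  } else {
    survival::survfit(srv ~ 1)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) "overall" else sub("^subtype=", "", as.character(s$strata))
  tab <- data.frame(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    survival = s$surv, stringsAsFactors = FALSE
  )
  med <- summary(fit)$table
  medians <- if (is.null(dim(med))) {
    stats::setNames(med[["median"]], "overall")
  } else {
    stats::setNames(med[, "median"], sub("^subtype=", "", rownames(med)))
  }
  list(fit = fit, table = tab, median = medians)
}

#' Relative dose intensity
#'
#' Per-patient RDI (delivered / planned dose) and the cohort fraction at
#' or above a threshold (85% of the scheduled dose by default).
#'
#' @param outcomes Outcomes data.frame with `planned_dose` (> 0) and
#'   `delivered_dose`.
#' @param threshold RDI threshold for the cohort summary.
#' @return List: `per_patient` (data.frame `patient_id`, `rdi`),
#'   `n_at_or_above`, `fraction_at_or_above`, `percent_at_or_above`.
#' @export
dose_intensity <- function(outcomes, threshold = 0.85) {
  assert_columns(outcomes, c("patient_id", "planned_dose", "delivered_dose"),
                 "outcomes")
  if (any(outcomes$planned_dose <= 0)) stop("planned dose must be positive")
  rdi <- outcomes$delivered_dose / outcomes$planned_dose
  n_hi <- sum(rdi >= threshold)
  list(
    per_patient = data.frame(patient_id = outcomes$patient_id, rdi = rdi,
                             stringsAsFactors = FALSE),
    n_at_or_above = n_hi,
    fraction_at_or_above = n_hi / nrow(outcomes),
    percent_at_or_above = round(100 * n_hi / nrow(outcomes))
  )
}

#' Adverse-event summary table
#'
#' Per term: distinct patients with any-grade events and with grade >= 3
#' events (a patient with several events of one term counts once).
#' Rows are reported when the any-grade rate reaches
#' `min_any_grade_fraction` of the cohort or any grade >= 3 event
#' occurred.
#'
#' @param adverse_events Long data.frame: `patient_id`, `term`, `grade`
#'   (1-5).
#' @param n_patients Cohort size (denominator for percentages).
#' @param min_any_grade_fraction Reporting threshold for any-grade rows.
#' @return Data.frame: `term`, `n_any`, `pct_any`, `n_grade3plus`,
#'   `pct_grade3plus`, sorted by term.
#' @export
ae_table <- function(adverse_events, n_patients, min_any_grade_fraction = 0.10) {
  assert_columns(adverse_events, c("patient_id", "term", "grade"),
                 "adverse events")
  if (nrow(adverse_events) == 0) {
    return(data.frame(term = character(0), n_any = integer(0),
                      pct_any = numeric(0), n_grade3plus = integer(0),
                      pct_grade3plus = numeric(0), stringsAsFactors = FALSE))
  }
  if (any(!adverse_events$grade %in% 1:5)) stop("grades must lie in 1..5")
  terms <- sort(unique(adverse_events$term))
  rows <- lapply(terms, function(tm) {
    ev <- adverse_events[adverse_events$term == tm, ]
    n_any <- length(unique(ev$patient_id))
    n_g3 <- length(unique(ev$patient_id[ev$grade >= 3]))
    data.frame(
      term = tm, n_any = n_any, pct_any = round(100 * n_any / n_patients),
      n_grade3plus = n_g3, pct_grade3plus = round(100 * n_g3 / n_patients),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  keep <- out$n_any >= min_any_grade_fraction * n_patients | out$n_grade3plus > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the outcomes CSV
#'
#' Plain CSV with the [generate_cohort()] outcome columns; logical
#' columns are stored as TRUE/FALSE.
#'
#' @param path File path.
#' @return For `read_outcomes`, the outcomes data.frame.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("patient_id", "subtype", "breast_pcr", "breast_ln_pcr",
                       "yp_category", "ncr", "surgery", "dfs_months",
                       "dfs_event", "planned_dose", "delivered_dose"),
                 paste0("'", basename(path), "'"))
  for (cn in c("breast_pcr", "breast_ln_pcr", "ncr", "dfs_event")) {
    df[[cn]] <- as.logical(df[[cn]])
  }
  df
}

#' @param outcomes Outcomes data.frame.
#' @rdname read_outcomes
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
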