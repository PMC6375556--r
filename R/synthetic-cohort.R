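#' Generate a synthetic 40-patient outcomes table
#'
#' Expands requested per-subtype response counts into a patient-level
#' outcomes table for the trial's primary cohort: 15 HER2-amplified, 15
#' triple-negative (TNBC) and 10 hormone-receptor-positive,
#' HER2-non-amplified patients with a high genomic recurrence score. The
#' marginals of the emitted table equal the requested counts exactly; all
#' remaining per-patient detail (which patient within a subtype responds,
#' event times, dose exposure) is deterministic plumbing given the seed.
#'
#' Default arguments reproduce the response, surgery, survival-event and
#' dose-exposure marginals of the study cohort: 22/40 breast pCR (12 HER2,
#' 7 TNBC, 3 HR+), 18/40 breast+LN pCR, 13 ypT0 ypN0, 4 nCR, 19
#' breast-conserving surgeries, 7 DFS events and 35/40 patients at >= 85%
#' relative dose intensity.
#'
#' @param breast_pcr_counts Breast-pCR counts per subtype, in the order
#'   (HER2-amplified, TNBC, HR-positive); each at most the subtype
#'   denominator (15, 15, 10).
#' @param breast_ln_pcr_counts Breast-and-lymph-node pCR counts per
#'   subtype; element-wise at most `breast_pcr_counts`.
#' @param ypt0_ypn0_counts Counts of complete eradication (ypT0 ypN0)
#'   per subtype; at most `breast_ln_pcr_counts`.
#' @param ncr_counts Near-complete response counts per subtype; nCR is
#'   only assigned to patients without breast pCR.
#' @param conserving_counts Breast-conserving surgery counts per subtype.
#' @param dfs_event_counts Disease-free-survival event counts per subtype.
#' @param n_high_rdi Number of patients with relative dose intensity
#'   >= 0.85.
#' @param seed Integer seed for the continuous fillers.
#' @return List with `outcomes` (40-row data.frame) and
#'   `adverse_events` (long data.frame: `patient_id`, `term`, `grade`).
#' @export
generate_cohort <- function(breast_pcr_counts = c(12, 7, 3),
                            breast_ln_pcr_counts = c(12, 5, 1),
                            ypt0_ypn0_counts = c(9, 3, 1),
                            ncr_counts = c(1, 2, 1),
                            conserving_counts = c(8, 7, 4),
                            dfs_event_counts = c(1, 4, 2),
                            n_high_rdi = 35,
                            seed = 1L) {
  denom <- c(15, 15, 10)
  subtypes <- c("HER2_amplified", "TNBC", "HR_pos_HER2_neg_RS_ge_25")
  chk <- function(x, cap, label) {
    stopifnot(length(x) == 3)
    if (any(x < 0) || any(x > cap)) {
      stop(label, " counts must lie within the per-subtype caps (",
           paste(cap, collapse = "/"), ")")
    }
    as.integer(x)
  }
  breast_pcr_counts <- chk(breast_pcr_counts, denom, "breast pCR")
  breast_ln_pcr_counts <- chk(breast_ln_pcr_counts, breast_pcr_counts, "breast+LN pCR")
  ypt0_ypn0_counts <- chk(ypt0_ypn0_counts, breast_ln_pcr_counts, "ypT0 ypN0")
  ncr_counts <- chk(ncr_counts, denom - breast_pcr_counts, "nCR")
  conserving_counts <- chk(conserving_counts, denom, "breast-conserving")
  dfs_event_counts <- chk(dfs_event_counts, denom, "DFS event")
  stopifnot(n_high_rdi >= 0, n_high_rdi <= 40)

  rows <- lapply(1:3, function(s) {
    n <- denom[s]
    pcr <- c(rep(TRUE, breast_pcr_counts[s]), rep(FALSE, n - breast_pcr_counts[s]))
    ln <- c(rep(TRUE, breast_ln_pcr_counts[s]),
            rep(FALSE, n - breast_ln_pcr_counts[s])) & pcr
    ypt0 <- c(rep(TRUE, ypt0_ypn0_counts[s]), rep(FALSE, n - ypt0_ypn0_counts[s])) & ln
    yp <- ifelse(ypt0, "ypT0_ypN0",
                 ifelse(ln, "ypT0is_ypN0",
                        ifelse(pcr, "ypT0is_ypNpos", "residual")))
    ncr <- rep(FALSE, n)
    ncr[which(!pcr)[seq_len(ncr_counts[s])]] <- TRUE
    data.frame(
      subtype = subtypes[s], breast_pcr = pcr, breast_ln_pcr = ln,
      yp_category = yp, ncr = ncr, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- data.frame(patient_id = sprintf("P%02d", 1:40), out, stringsAsFactors = FALSE)

  # surgery: conserving assigned responders-first within each subtype
  out$surgery <- "mastectomy"
  for (s in 1:3) {
    idx <- which(out$subtype == subtypes[s])
    ord <- idx[order(!out$breast_pcr[idx])]
    out$surgery[ord[seq_len(conserving_counts[s])]] <- "breast_conserving"
  }

  # DFS: events non-responders-first within each subtype
  out$dfs_event <- FALSE
  for (s in 1:3) {
    idx <- which(out$subtype == subtypes[s])
    ord <- idx[order(out$breast_pcr[idx])]
    out$dfs_event[ord[seq_len(dfs_event_counts[s])]] <- TRUE
  }

  with_stream(seed, 31L, {
    out$dfs_months <- round(stats::runif(40, 11.5, 31.6), 2)
    out$dfs_months[out$dfs_event] <- round(stats::runif(sum(out$dfs_event), 5, 18), 2)
    # nab-paclitaxel exposure: 125 mg/m2 x 9 planned doses
    out$planned_dose <- 1125
    rdi <- numeric(40)
    hi <- sample(40, n_high_rdi)
    rdi[hi] <- stats::runif(n_high_rdi, 0.86, 1)
    rdi[-hi] <- stats::runif(40 - n_high_rdi, 0.45, 0.80)
    out$delivered_dose <- round(out$planned_dose * rdi, 1)
    rownames(out) <- NULL
    list(outcomes = out, adverse_events = generate_adverse_events(out$patient_id))
  })
}

# Per-term (any-grade, grade>=3) patient counts emulating the study's
# toxicity profile; expanded to one row per affected patient and term.
default_ae_profile <- function() {
  data.frame(
    term = c("alopecia", "anxiety", "bone_pain", "constipation",
             "deranged_transaminases", "diarrhoea", "dysgeusia", "dyspepsia",
             "fatigue", "febrile_neutropenia", "gastro_oesophageal_reflux",
             "headache", "insomnia", "nausea", "neutropenia",
             "sensory_neuropathy", "pneumothorax"),
    n_any = c(38, 6, 6, 9, 2, 8, 6, 4, 27, 3, 8, 6, 7, 25, 23, 22, 1),
    n_grade3plus = c(0, 0, 0, 0, 2, 1, 0, 0, 1, 3, 0, 0, 0, 0, 7, 2, 1),
    stringsAsFactors = FALSE
  )
}

generate_adverse_events <- function(patient_ids, profile = default_ae_profile()) {
  stopifnot(all(profile$n_grade3plus <= profile$n_any),
            all(profile$n_any <= length(patient_ids)))
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    who <- sample(patient_ids, profile$n_any[i])
    grade <- c(rep(3L, profile$n_grade3plus[i]),
               sample(1:2, profile$n_any[i] - profile$n_grade3plus[i], replace = TRUE))
    data.frame(patient_id = who, term = profile$term[i], grade = grade,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
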