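#' Classify variants as high functional impact (HFI)
#'
#' An SNV is HFI when at least three of the six in-silico predictors
#' (SIFT, PolyPhen, PROVEAN, MutationTaster, MutationAssessor, LRT) call
#' it deleterious; "unknown" verdicts count as non-votes, so the
#' denominator is always six. Every INDEL is HFI by rule, regardless of
#' verdicts.
#'
#' @param records Variant data.frame with the six verdict columns.
#' @param min_votes Consensus threshold (default 3 of 6).
#' @return Data.frame: `record_id`, `n_deleterious_votes`, `hfi`,
#'   `basis` (`"consensus_vote"` for SNVs, `"indel_rule"` for INDELs).
#' @export
#' @examples
#' rec <- data.frame(
#'   record_id = "r1", kind = "SNV",
#'   sift = "deleterious", polyphen = "deleterious", provean = "deleterious",
#'   mutation_taster = "tolerated", mutation_assessor = "tolerated",
#'   lrt = "unknown"
#' )
#' classify_hfi(rec)
classify_hfi <- function(records, min_votes = 3) {
  assert_columns(records, c("record_id", "kind", predictor_names()), "records")
  votes <- Reduce(`+`, lapply(predictor_names(), function(pn) {
    as.integer(records[[pn]] == "deleterious")
  }))
  if (nrow(records) == 0) votes <- integer(0)
  indel <- records$kind %in% c("INS", "DEL")
  data.frame(
    record_id = records$record_id,
    n_deleterious_votes = votes,
    hfi = indel | votes >= min_votes,
    basis = ifelse(indel, "indel_rule", "consensus_vote"),
    stringsAsFactors = FALSE
  )
}

#' Select non-synonymous variants
#'
#' Keeps SNVs whose consequence is missense, stop-gained or splice-site,
#' plus all INDELs; this is the variant set used for gene and gene
#' pathway analyses.
#'
#' @param records Variant data.frame.
#' @return Subset of `records`, order preserved.
#' @export
select_nonsynonymous <- function(records) {
  assert_columns(records, c("kind", "consequence"), "records")
  keep <- records$kind %in% c("INS", "DEL") |
    records$consequence %in% c("missense", "stop_gained", "splice_site")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' HFI gene list for one sample
#'
#' Convenience chain: restrict to non-synonymous, drop
#' intronic/intergenic, classify HFI, return the unique uppercased gene
#' symbols of HFI variants.
#'
#' @param records Kept (filtered) variant data.frame for one sample.
#' @return Character vector of gene symbols.
#' @export
hfi_genes <- function(records) {
  r <- restrict_for_gene_analysis(select_nonsynonymous(records))
  if (nrow(r) == 0) return(character(0))
  calls <- classify_hfi(r)
  g <- toupper(r$gene[calls$hfi])
  sort(unique(g[nzchar(g)]))
}
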