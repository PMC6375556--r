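#' Somatic filter thresholds
#'
#' Constructs the threshold set used by [filter_snvs()] and
#' [filter_indels()]. Defaults are the study's published values.
#' Boundary semantics follow the wording each threshold was stated with:
#' "at least"/"minimum" thresholds are inclusive, "less/lower than"
#' thresholds are strict. Concretely a record passes a condition when:
#'
#' * `call_quality >= min_call_quality` (q-value cutoff of 12),
#' * `tumour_depth >= min_tumour_depth_snv` (50x in the tumour),
#' * `germline_depth >= min_germline_depth_snv` (20x in the normal),
#' * `germline_mismatch_fraction < max_germline_mismatch` (lower than 10%),
#' * `vaf >= min_vaf` (VAF less than 10% excluded; a tie at exactly 0.10
#'   is kept),
#' * `indel_support_total >= min_indel_support` (at least 20 reads),
#' * `indel_support_interior >= min_indel_interior_support` (at least 5
#'   reads with the INDEL >= 25 bp from both read ends),
#' * `germline_cover_at_site >= min_germline_cover_indel` with
#'   `germline_indels_within_20bp == 0` (20 covering germline reads, no
#'   germline INDEL at or within 20 bp of the site),
#' * `local_mismatch_rate_10bp < max_local_mismatch_10bp`,
#' * `adjacent_repeat_regions <= max_adjacent_repeats` (more than five
#'   adjacent repetitive regions excluded).
#'
#' @param min_call_quality,min_tumour_depth_snv,min_germline_depth_snv,max_germline_mismatch,min_vaf
#'   SNV thresholds.
#' @param min_indel_support,min_indel_interior_support,indel_interior_margin_bp,min_germline_cover_indel,germline_indel_window_bp,max_local_mismatch_10bp,max_adjacent_repeats
#'   INDEL thresholds. `indel_interior_margin_bp` and
#'   `germline_indel_window_bp` document the geometry under which the
#'   ingested interior-support and germline-window counts were computed.
#' @param drop_consequences_for_gene_analysis Consequence classes removed
#'   by [restrict_for_gene_analysis()].
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_call_quality = 12,
                          min_tumour_depth_snv = 50,
                          min_germline_depth_snv = 20,
                          max_germline_mismatch = 0.10,
                          min_vaf = 0.10,
                          min_indel_support = 20,
                          min_indel_interior_support = 5,
                          indel_interior_margin_bp = 25,
                          min_germline_cover_indel = 20,
                          germline_indel_window_bp = 20,
                          max_local_mismatch_10bp = 0.10,
                          max_adjacent_repeats = 5,
                          drop_consequences_for_gene_analysis = c("intronic", "intergenic")) {
  p <- list(
    min_call_quality = min_call_quality,
    min_tumour_depth_snv = min_tumour_depth_snv,
    min_germline_depth_snv = min_germline_depth_snv,
    max_germline_mismatch = max_germline_mismatch,
    min_vaf = min_vaf,
    min_indel_support = min_indel_support,
    min_indel_interior_support = min_indel_interior_support,
    indel_interior_margin_bp = indel_interior_margin_bp,
    min_germline_cover_indel = min_germline_cover_indel,
    germline_indel_window_bp = germline_indel_window_bp,
    max_local_mismatch_10bp = max_local_mismatch_10bp,
    max_adjacent_repeats = max_adjacent_repeats,
    drop_consequences_for_gene_analysis = drop_consequences_for_gene_analysis
  )
  num <- p[names(p) != "drop_consequences_for_gene_analysis"]
  if (any(unlist(num) <= 0)) stop("all thresholds must be positive")
  if (max_germline_mismatch >= 1 || min_vaf >= 1 || max_local_mismatch_10bp >= 1) {
    stop("fractional thresholds must lie in (0, 1)")
  }
  structure(p, class = "filter_params")
}

new_filter_audit <- function(ids, fail_matrix, params) {
  # fail_matrix: logical, rows = records, cols = reason codes
  failed <- rowSums(fail_matrix) > 0
  rejected <- lapply(which(failed), function(i) colnames(fail_matrix)[fail_matrix[i, ]])
  names(rejected) <- ids[failed]
  structure(
    list(
      kept = ids[!failed],
      rejected = rejected,
      counts = colSums(fail_matrix),
      params = params
    ),
    class = "filter_audit"
  )
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter audit: ", length(x$kept), " kept, ", length(x$rejected),
      " rejected\n", sep = "")
  if (length(x$rejected) > 0) {
    cat("Failures per reason (a record may fail several):\n")
    for (r in names(x$counts)[x$counts > 0]) {
      cat("  ", r, ": ", x$counts[[r]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Filter somatic SNVs
#'
#' Applies the study's five SNV conditions (call quality, tumour depth,
#' germline depth, germline mismatch fraction, VAF; see
#' [filter_params()]) and returns a complete audit: every failing reason
#' is recorded for every rejected record, not just the first.
#'
#' @param records Variant data.frame, all rows `kind == "SNV"`.
#' @param params A [filter_params()].
#' @return A `filter_audit`: list with `kept` (record ids), `rejected`
#'   (named list of reason-code vectors), `counts` (failures per reason)
#'   and `params`.
#' @export
filter_snvs <- function(records, params = filter_params()) {
  assert_columns(records, c("record_id", "kind", "call_quality", "tumour_depth",
                            "germline_depth", "germline_mismatch_fraction", "vaf"),
                 "records")
  if (any(records$kind != "SNV")) stop("filter_snvs received non-SNV records")
  fails <- cbind(
    call_quality = records$call_quality < params$min_call_quality,
    tumour_depth = records$tumour_depth < params$min_tumour_depth_snv,
    germline_depth = records$germline_depth < params$min_germline_depth_snv,
    germline_mismatch = records$germline_mismatch_fraction >= params$max_germline_mismatch,
    vaf = records$vaf < params$min_vaf
  )
  new_filter_audit(records$record_id, fails, params)
}

#' Filter somatic INDELs
#'
#' Applies the study's INDEL conditions — total and interior read
#' support, germline coverage with no germline INDEL in the surrounding
#' window, local mismatch rate, VAF, and repeat adjacency (see
#' [filter_params()]) — and returns a complete audit.
#'
#' @inheritParams filter_snvs
#' @param records Variant data.frame, all rows `kind` INS or DEL.
#' @return A `filter_audit`.
#' @export
filter_indels <- function(records, params = filter_params()) {
  assert_columns(records, c("record_id", "kind", "vaf", "indel_support_total",
                            "indel_support_interior", "germline_cover_at_site",
                            "germline_indels_within_20bp",
                            "local_mismatch_rate_10bp", "adjacent_repeat_regions"),
                 "records")
  if (any(!records$kind %in% c("INS", "DEL"))) {
    stop("filter_indels received non-INDEL records")
  }
  fails <- cbind(
    support_total = records$indel_support_total < params$min_indel_support,
    interior_support = records$indel_support_interior < params$min_indel_interior_support,
    germline_cover = records$germline_cover_at_site < params$min_germline_cover_indel,
    germline_indel_window = records$germline_indels_within_20bp > 0,
    local_mismatch = records$local_mismatch_rate_10bp >= params$max_local_mismatch_10bp,
    vaf = records$vaf < params$min_vaf,
    repeat_adjacency = records$adjacent_repeat_regions > params$max_adjacent_repeats
  )
  new_filter_audit(records$record_id, fails, params)
}

#' Filter a mixed variant table
#'
#' Convenience wrapper dispatching rows to [filter_snvs()] /
#' [filter_indels()] and returning the kept records plus both audits.
#'
#' @param records Variant data.frame.
#' @param params A [filter_params()].
#' @return List: `kept` (data.frame), `snv_audit`, `indel_audit`.
#' @export
filter_variants <- function(records, params = filter_params()) {
  snv <- records[records$kind == "SNV", , drop = FALSE]
  ind <- records[records$kind != "SNV", , drop = FALSE]
  snv_audit <- filter_snvs(snv, params)
  indel_audit <- filter_indels(ind, params)
  kept_ids <- c(snv_audit$kept, indel_audit$kept)
  kept <- records[records$record_id %in% kept_ids, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, snv_audit = snv_audit, indel_audit = indel_audit)
}

#' Drop intronic and intergenic variants before gene-level analysis
#'
#' @param records Variant data.frame.
#' @param drop Consequence classes to remove.
#' @return The records whose consequence is not in `drop`, original order
#'   preserved.
#' @export
restrict_for_gene_analysis <- function(records, drop = c("intronic", "intergenic")) {
  out <- records[!records$consequence %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a filter audit as TSV (one row per record) and JSON summary
#'
#' @param audit A `filter_audit`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_filter_audit <- function(audit, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(audit, "filter_audit"))
  if (!is.null(tsv_path)) {
    df <- rbind(
      data.frame(record_id = audit$kept, fate = "kept", reasons = "",
                 stringsAsFactors = FALSE),
      data.frame(record_id = names(audit$rejected), fate = "rejected",
                 reasons = vapply(audit$rejected, paste, "", collapse = ","),
                 stringsAsFactors = FALSE)
    )
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        n_kept = length(audit$kept), n_rejected = length(audit$rejected),
        counts_per_reason = as.list(audit$counts),
        params = audit$params[names(audit$params) != "drop_consequences_for_gene_analysis"]
      ),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(audit)
}
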