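#' Callable bases of a depth track
#'
#' Number of reference positions with sequencing depth at or above
#' `min_depth` (20 reads by default, the CallableLoci-style criterion
#' used as the mutation-burden denominator).
#'
#' @param track Depth track: either a run-compressed data.frame
#'   (`chrom`, `start`, `end`, `depth`) or a per-base numeric vector.
#' @param min_depth Inclusive depth threshold.
#' @return Base count.
#' @export
callable_bases <- function(track, min_depth = 20) {
  if (is.data.frame(track)) {
    assert_columns(track, c("chrom", "start", "end", "depth"), "depth track")
    if (nrow(track) == 0) stop("empty depth track")
    return(sum((track$end - track$start)[track$depth >= min_depth]))
  }
  if (length(track) == 0) stop("empty depth track")
  sum(track >= min_depth)
}

#' Mutation burden per megabase
#'
#' Computes variants per megabase of callable genome in the study's two
#' counting modes. `mode = "all"` counts every kept SNV — including
#' synonymous, intronic and intergenic — plus all INDELs;
#' `mode = "nonsyn"` counts only missense, stop-gained and splice-site
#' SNVs, plus all INDELs. One megabase is 1e6 bases. The raw rate is
#' returned alongside a 2-significant-figure display value.
#'
#' @param records Kept variant data.frame for one sample.
#' @param callable Callable base count (> 0).
#' @param mode `"all"` or `"nonsyn"`.
#' @param sample_id Optional id stamped on the result.
#' @return One-row data.frame: `sample_id`, `mode`, `n_variants`,
#'   `callable_mb`, `burden_per_mb`, `burden_display`.
#' @export
mutation_burden <- function(records, callable, mode = c("all", "nonsyn"),
                            sample_id = NULL) {
  mode <- match.arg(mode)
  if (callable <= 0) stop("callable bases must be positive")
  assert_columns(records, c("kind", "consequence"), "records")
  n <- if (mode == "all") {
    nrow(records)
  } else {
    nrow(select_nonsynonymous(records))
  }
  rate <- n / (callable / 1e6)
  data.frame(
    sample_id = sample_id %||% (if (nrow(records) > 0) records$sample_id[1] else NA_character_),
    mode = mode,
    n_variants = n,
    callable_mb = callable / 1e6,
    burden_per_mb = rate,
    burden_display = signif(rate, 2),
    stringsAsFactors = FALSE
  )
}

#' Burden summary in both modes
#'
#' @inheritParams mutation_burden
#' @return Two-row data.frame (modes `all` and `nonsyn`).
#' @export
burden_summary <- function(records, callable, sample_id = NULL) {
  rbind(
    mutation_burden(records, callable, "all", sample_id),
    mutation_burden(records, callable, "nonsyn", sample_id)
  )
}
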