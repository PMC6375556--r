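#' EASE score: modified Fisher's exact over-representation p-value
#'
#' One-sided upper-tail Fisher p-value of the 2x2 overlap table with one
#' success removed from the query/pathway cell — the conservative
#' "modified Fisher" statistic used by the DAVID functional annotator.
#' For an overlap of `k` query genes with a pathway of size `K` in a
#' background of `N` genes, with a query list of size `n`, the score is
#' `P[X >= k - 1]` for `X ~ hypergeometric(N, K, n)`. With `k = 1` the
#' decrement removes the only success and the score is 1 by convention.
#'
#' @param k Overlap count (query genes in the pathway).
#' @param n Query list size.
#' @param K Pathway size in the background.
#' @param N Background universe size.
#' @return p-value in (0, 1]; vectorized over its arguments.
#' @export
#' @examples
#' ease_p(3, 10, 5, 1000)
#' ease_p(1, 10, 5, 1000) # == 1
ease_p <- function(k, n, K, N) {
  m <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, m); n <- rep_len(n, m); K <- rep_len(K, m); N <- rep_len(N, m)
  if (any(k < 0 | K > N | n > N | k > pmin(n, K))) {
    stop("inconsistent margins: need 0 <= k <= min(n, K) <= N")
  }
  # P[X >= k - 1] = 1 - P[X <= k - 2]
  p <- stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  p[k <= 1] <- 1
  pmin(p, 1)
}

#' Gene-set over-representation for one sample
#'
#' Scores each gene set against a query gene list (typically the HFI
#' genes of one sample) with [ease_p()]. Only sets overlapping the query
#' (`k >= 1`) are reported, sorted by ascending p-value. Significance is
#' called at `alpha` per pathway with no multiple-testing correction,
#' matching the study's procedure; set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted calls instead.
#'
#' @param genes Character vector of query gene symbols.
#' @param gene_sets A `gene_set_collection` (see [read_gmt()]) or named
#'   list of gene vectors.
#' @param background Background universe size `N`; defaults to the number
#'   of distinct genes in the collection.
#' @param alpha Per-pathway significance level.
#' @param sample_id Optional id stamped on the rows.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame: `sample_id`, `pathway`, `k`, `n`, `K`, `N`,
#'   `p_ease`, `significant`.
#' @export
enrich_sample <- function(genes, gene_sets, background = NULL, alpha = 0.05,
                          sample_id = NA_character_, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(genes) == 0) stop("empty gene list")
  if (!inherits(gene_sets, "gene_set_collection")) {
    gene_sets <- as_gene_sets(gene_sets)
  }
  genes <- unique(toupper(genes))
  universe <- unique(unlist(gene_sets))
  N <- background %||% length(universe)
  if (N <= 0) stop("empty background universe")
  n <- sum(genes %in% universe)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    k <- sum(genes %in% set)
    if (k < 1) return(NULL)
    data.frame(
      sample_id = sample_id, pathway = nm, k = k, n = n,
      K = length(set), N = N, p_ease = ease_p(k, n, length(set), N),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(res)) {
    res <- data.frame(sample_id = character(0), pathway = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_ease = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(res)
  }
  p_used <- if (adjust == "BH") stats::p.adjust(res$p_ease, "BH") else res$p_ease
  res$significant <- p_used < alpha
  res <- res[order(res$p_ease, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare per-sample enrichment calls between groups
#'
#' For each pathway, counts how many samples in each group called it
#' significant (e.g. diagnostic samples from pCR vs non-pCR patients).
#' No pooled statistic is computed: the output is a descriptive
#' contingency of per-sample significance, which is how the study's
#' group comparisons were reported.
#'
#' @param results Data.frame of stacked [enrich_sample()] outputs (one
#'   per sample).
#' @param groups Named character vector mapping `sample_id` to group
#'   label.
#' @return Data.frame: `pathway`, then per group `<group>_significant`
#'   and `<group>_n`.
#' @export
compare_groups <- function(results, groups) {
  assert_columns(results, c("sample_id", "pathway", "significant"), "results")
  unknown <- setdiff(unique(results$sample_id), names(groups))
  if (length(unknown) > 0) {
    stop("samples with no group label: ", paste(unknown, collapse = ", "))
  }
  glev <- unique(unname(groups))
  pathways <- sort(unique(results$pathway))
  out <- data.frame(pathway = pathways, stringsAsFactors = FALSE)
  for (g in glev) {
    members <- names(groups)[groups == g]
    n_g <- length(unique(members))
    sig <- vapply(pathways, function(pw) {
      rows <- results[results$pathway == pw & results$sample_id %in% members, ]
      length(unique(rows$sample_id[rows$significant]))
    }, 1L)
    out[[paste0(g, "_significant")]] <- sig
    out[[paste0(g, "_n")]] <- n_g
  }
  out
}

#' Gene-by-sample alteration grid
#'
#' OncoPrint-style long table: one row per (gene, sample) with the most
#' severe alteration class observed (truncating = stop-gained or INDEL,
#' else missense, else other).
#'
#' @param records_by_sample Named list of kept variant data.frames.
#' @param genes Genes to report (rows).
#' @return Data.frame: `gene`, `sample_id`, `alteration`.
#' @export
alteration_grid <- function(records_by_sample, genes) {
  genes <- unique(toupper(genes))
  rows <- list()
  for (sid in names(records_by_sample)) {
    rec <- records_by_sample[[sid]]
    for (g in genes) {
      hit <- rec[toupper(rec$gene) == g, , drop = FALSE]
      if (nrow(hit) == 0) next
      trunc <- any(hit$kind %in% c("INS", "DEL") | hit$consequence == "stop_gained")
      mis <- any(hit$consequence == "missense")
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, sample_id = sid,
        alteration = if (trunc) "truncating" else if (mis) "missense" else "other",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), sample_id = character(0),
                      alteration = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
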