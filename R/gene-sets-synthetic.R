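#' Synthetic gene-set collection
#'
#' A small Biocarta/KEGG-flavoured gene-set collection over the synthetic
#' generator's gene pool, for exercising the enrichment stage without
#' external pathway files. Includes a DNA-damage/ATM-signalling-like set,
#' an HRD-gene set, a SWI/SNF set, and `n_random` filler sets drawn from
#' the remaining pool. This is a synthetic stand-in, not a curated
#' pathway database.
#'
#' @param n_random Number of filler sets.
#' @param seed Integer seed for the filler sets.
#' @return A `gene_set_collection`.
#' @export
synthetic_gene_sets <- function(n_random = 12, seed = 7L) {
  fixed <- list(
    ATM_SIGNALLING_LIKE = c("ATM", "ATR", "CHEK2", "TP53", "MDM4"),
    HRD_GENES = c("BRCA1", "BRCA2", "PALB2", "CHEK2", "RAD51C", "PTEN", "ATM"),
    SWI_SNF_COMPLEX = c("ARID1A", "ARID1B"),
    ANDROGEN_FOXA1_LIKE = c("FOXA1", "GATA3", "MYC")
  )
  pool <- generator_gene_pool()
  random <- with_stream(seed, 61L, {
    lapply(seq_len(n_random), function(i) sample(pool, sample(5:15, 1)))
  })
  names(random) <- sprintf("RANDOM_SET_%02d", seq_len(n_random))
  as_gene_sets(c(fixed, random),
               descriptions = c(rep("curated-style synthetic set", length(fixed)),
                                rep("random filler set", n_random)))
}
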