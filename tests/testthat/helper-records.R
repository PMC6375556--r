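# Construct minimal valid variant records for tests.
# All filter-relevant fields default to comfortably passing values.
make_record <- function(record_id = "r1", kind = "SNV",
                        call_quality = 30, tumour_depth = 100,
                        tumour_alt_reads = 40, germline_depth = 40,
                        germline_mismatch_fraction = 0.01,
                        consequence = "missense", gene = "TP53",
                        ref = "C", alt = "T", context = "ACA",
                        sift = "unknown", polyphen = "unknown",
                        provean = "unknown", mutation_taster = "unknown",
                        mutation_assessor = "unknown", lrt = "unknown",
                        indel_support_total = 30, indel_support_interior = 10,
                        germline_cover_at_site = 40,
                        germline_indels_within_20bp = 0,
                        local_mismatch_rate_10bp = 0.01,
                        adjacent_repeat_regions = 0,
                        vaf = tumour_alt_reads / tumour_depth,
                        sample_id = "S1", chrom = "chr1", pos = 1000) {
  if (kind != "SNV" && context == "ACA") context <- ""
  if (kind != "SNV" && nchar(ref) == nchar(alt)) {
    ref <- "A"
    alt <- if (kind == "INS") "AT" else "A"
    if (kind == "DEL") { ref <- "AT"; alt <- "A" }
  }
  data.frame(
    record_id = record_id, sample_id = sample_id, chrom = chrom, pos = pos,
    ref = ref, alt = alt, kind = kind, call_quality = call_quality,
    tumour_depth = tumour_depth, tumour_alt_reads = tumour_alt_reads,
    vaf = vaf, germline_depth = germline_depth,
    germline_mismatch_fraction = germline_mismatch_fraction,
    consequence = consequence, gene = gene, context = context,
    sift = sift, polyphen = polyphen, provean = provean,
    mutation_taster = mutation_taster, mutation_assessor = mutation_assessor,
    lrt = lrt,
    indel_support_total = indel_support_total,
    indel_support_interior = indel_support_interior,
    germline_cover_at_site = germline_cover_at_site,
    germline_indels_within_20bp = germline_indels_within_20bp,
    local_mismatch_rate_10bp = local_mismatch_rate_10bp,
    adjacent_repeat_regions = adjacent_repeat_regions,
    stringsAsFactors = FALSE
  )
}

make_records <- function(...) {
  args <- list(...)
  do.call(rbind, args)
}

# random records for property tests: fields straddle the filter thresholds
random_records <- function(n, kind = "SNV", seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      depth <- sample(10:200, 1)
      alt <- sample(0:depth, 1)
      make_record(
        record_id = sprintf("rr%04d", i), kind = kind,
        call_quality = round(runif(1, 0, 40), 1),
        tumour_depth = depth, tumour_alt_reads = alt, vaf = alt / depth,
        germline_depth = sample(5:60, 1),
        germline_mismatch_fraction = round(runif(1, 0, 0.3), 3),
        indel_support_total = sample(5:60, 1),
        indel_support_interior = sample(0:20, 1),
        germline_cover_at_site = sample(5:60, 1),
        germline_indels_within_20bp = sample(0:2, 1),
        local_mismatch_rate_10bp = round(runif(1, 0, 0.3), 3),
        adjacent_repeat_regions = sample(0:8, 1)
      )
    }))
  })
}
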