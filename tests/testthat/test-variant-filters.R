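test_that("SNV thresholds follow the stated boundary semantics", {
  # depth 49 fails, depth 50 passes ("minimum depth of 50x")
  a <- filter_snvs(make_record("r1", tumour_depth = 49, tumour_alt_reads = 20,
                               vaf = 20 / 49))
  expect_equal(names(a$rejected), "r1")
  expect_equal(a$rejected$r1, "tumour_depth")
  # VAF strictly below 0.10 fails; a tie at exactly 0.10 is kept
  b <- filter_snvs(make_record("r2", tumour_depth = 1000, tumour_alt_reads = 99,
                               vaf = 0.099))
  expect_equal(b$rejected$r2, "vaf")
  c <- filter_snvs(make_record("r3", call_quality = 12, tumour_depth = 50,
                               tumour_alt_reads = 5, vaf = 0.10,
                               germline_depth = 20,
                               germline_mismatch_fraction = 0.09))
  expect_equal(c$kept, "r3")
  # germline mismatch of exactly 10% fails ("lower than 10%")
  d <- filter_snvs(make_record("r4", germline_mismatch_fraction = 0.10))
  expect_equal(d$rejected$r4, "germline_mismatch")
})

test_that("all failing reasons are recorded, not just the first", {
  rec <- make_record("multi", call_quality = 5, tumour_depth = 30,
                     tumour_alt_reads = 1, vaf = 1 / 30, germline_depth = 10,
                     germline_mismatch_fraction = 0.2)
  a <- filter_snvs(rec)
  expect_setequal(a$rejected$multi,
                  c("call_quality", "tumour_depth", "germline_depth",
                    "germline_mismatch", "vaf"))
})

test_that("INDEL conditions follow the stated boundaries", {
  base <- function(...) make_record(kind = "DEL", consequence = "other", ...)
  a <- filter_indels(base(record_id = "i1", indel_support_interior = 4))
  expect_equal(a$rejected$i1, "interior_support")
  b <- filter_indels(base(record_id = "i2", adjacent_repeat_regions = 6))
  expect_equal(b$rejected$i2, "repeat_adjacency")
  # all thresholds at their exact boundaries pass
  c <- filter_indels(base(
    record_id = "i3", indel_support_total = 20, indel_support_interior = 5,
    germline_cover_at_site = 20, germline_indels_within_20bp = 0,
    local_mismatch_rate_10bp = 0.09, adjacent_repeat_regions = 5,
    tumour_depth = 100, tumour_alt_reads = 10, vaf = 0.10
  ))
  expect_equal(c$kept, "i3")
  d <- filter_indels(base(record_id = "i4", germline_indels_within_20bp = 1))
  expect_equal(d$rejected$i4, "germline_indel_window")
})

test_that("kind mismatches are errors", {
  expect_error(filter_snvs(make_record(kind = "INS")), "non-SNV")
  expect_error(filter_indels(make_record(kind = "SNV")), "non-INDEL")
})

test_that("audit partition and idempotence hold on randomized records", {
  for (seed in 1:4) {
    recs <- random_records(250, kind = "SNV", seed = seed)
    a <- filter_snvs(recs)
    expect_setequal(c(a$kept, names(a$rejected)), recs$record_id)
    expect_length(intersect(a$kept, names(a$rejected)), 0)
    # filtering the kept set changes nothing
    kept <- recs[recs$record_id %in% a$kept, ]
    a2 <- filter_snvs(kept)
    expect_equal(a2$kept, kept$record_id)
    expect_length(a2$rejected, 0)
  }
  recs <- random_records(250, kind = "DEL", seed = 9)
  a <- filter_indels(recs)
  expect_setequal(c(a$kept, names(a$rejected)), recs$record_id)
  kept <- recs[recs$record_id %in% a$kept, ]
  a2 <- filter_indels(kept)
  expect_length(a2$rejected, 0)
})

test_that("rejected-reason counts equal planted failures on generator output", {
  planted_snv <- c(call_quality = 7, tumour_depth = 6, germline_depth = 5,
                   germline_mismatch = 4, vaf = 3)
  planted_indel <- c(support_total = 4, interior_support = 3,
                     germline_cover = 2, germline_indel_window = 2,
                     local_mismatch = 2, vaf = 2, repeat_adjacency = 2)
  cfg <- simulation_config(seed = 21, n_snvs = 120, n_indels = 60,
                           planted_failures_snv = planted_snv,
                           planted_failures_indel = planted_indel)
  pair <- generate_pair(cfg)
  f <- filter_variants(pair$tumour)
  expect_equal(f$snv_audit$counts[names(planted_snv)], planted_snv)
  expect_equal(f$indel_audit$counts[names(planted_indel)], planted_indel)
  # each planted record is rejected with exactly its planted reason
  truth <- pair$truth
  rejected <- c(f$snv_audit$rejected, f$indel_audit$rejected)
  planted <- truth[truth$intended_fate == "fail", ]
  expect_setequal(names(rejected), planted$record_id)
  for (i in seq_len(nrow(planted))) {
    expect_equal(rejected[[planted$record_id[i]]], planted$reason[i])
  }
})

test_that("intronic and intergenic variants are dropped for gene analysis", {
  recs <- make_records(
    make_record("a", consequence = "missense"),
    make_record("b", consequence = "intronic"),
    make_record("c", consequence = "synonymous"),
    make_record("d", consequence = "intronic"),
    make_record("e", consequence = "stop_gained")
  )
  out <- restrict_for_gene_analysis(recs)
  expect_equal(out$record_id, c("a", "c", "e"))
  allint <- make_records(make_record("x", consequence = "intergenic"),
                         make_record("y", consequence = "intergenic"))
  expect_equal(nrow(restrict_for_gene_analysis(allint)), 0)
})
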