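test_that("planted failures are honoured exactly and everything else passes", {
  cfg <- simulation_config(
    seed = 11, n_snvs = 60, n_indels = 25,
    planted_failures_snv = c(tumour_depth = 5, call_quality = 3, vaf = 2),
    planted_failures_indel = c(interior_support = 4, germline_indel_window = 2)
  )
  pair <- generate_pair(cfg)
  truth <- pair$truth
  expect_equal(sum(truth$reason == "tumour_depth"), 5)
  depth_fails <- pair$tumour[pair$tumour$record_id %in%
                               truth$record_id[truth$reason == "tumour_depth"], ]
  expect_true(all(depth_fails$tumour_depth >= 1 & depth_fails$tumour_depth <= 49))
  # records intended to pass clear every threshold with margin >= 1 unit
  pass <- pair$tumour[pair$tumour$record_id %in%
                        truth$record_id[truth$intended_fate == "pass"], ]
  snv <- pass[pass$kind == "SNV", ]
  expect_true(all(snv$call_quality >= 13 & snv$tumour_depth >= 51 &
                    snv$germline_depth >= 21 & snv$vaf >= 0.11 &
                    snv$germline_mismatch_fraction <= 0.09))
  ind <- pass[pass$kind != "SNV", ]
  expect_true(all(ind$indel_support_total >= 21 & ind$indel_support_interior >= 6 &
                    ind$germline_cover_at_site >= 21 &
                    ind$germline_indels_within_20bp == 0 &
                    ind$local_mismatch_rate_10bp <= 0.09 &
                    ind$adjacent_repeat_regions <= 4 & ind$vaf >= 0.11))
})

test_that("empty configuration yields empty tables and truth", {
  cfg <- simulation_config(seed = 1, n_snvs = 0, n_indels = 0)
  pair <- generate_pair(cfg)
  expect_equal(nrow(pair$tumour), 0)
  expect_equal(nrow(pair$truth), 0)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 42, n_snvs = 50, n_indels = 10,
                           planted_failures_snv = c(vaf = 4))
  a <- generate_pair(cfg)
  b <- generate_pair(cfg)
  expect_identical(a$tumour, b$tumour)
  expect_identical(a$germline, b$germline)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(signature_weights = c(Sig1 = 0.6)), "sum to 1")
  expect_error(
    simulation_config(planted_failures_snv = c(nonsense_code = 2)),
    "unknown SNV reason-code"
  )
  expect_error(
    simulation_config(n_snvs = 3, planted_failures_snv = c(vaf = 5)),
    "exceed"
  )
  expect_error(simulation_config(clone_vafs_diagnostic = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("contexts of a single-signature simulation converge to that signature", {
  S <- synthetic_signatures()
  cfg <- simulation_config(seed = 9, n_snvs = 5000, n_indels = 0,
                           signature_weights = c(Sig1 = 1))
  pair <- generate_pair(cfg, S)
  cat <- build_catalog(pair$tumour)
  cs <- catalog_cosine(cat, S)
  expect_equal(names(which.max(cs)), "Sig1")
  expect_gt(cs[["Sig1"]], 0.99)
})

test_that("depth tracks hit the requested callable fraction", {
  tr <- generate_depth_track(1000, 1.0, seed = 1)
  expect_equal(callable_bases(tr), 1000)
  tr <- generate_depth_track(1000, 0.0, seed = 1)
  expect_equal(callable_bases(tr), 0)
  tr <- generate_depth_track(10000, 0.5, seed = 1)
  expect_lte(abs(callable_bases(tr) - 5000), 1)
  expect_equal(sum(tr$end - tr$start), 10000)
  expect_error(generate_depth_track(0, 0.5), "positive")
})

test_that("cohort marginals equal the requested counts exactly", {
  co <- generate_cohort()
  out <- co$outcomes
  expect_equal(nrow(out), 40)
  expect_equal(sum(out$breast_pcr), 22)
  per_subtype <- vapply(c("HER2_amplified", "TNBC", "HR_pos_HER2_neg_RS_ge_25"),
                        function(s) sum(out$breast_pcr[out$subtype == s]), 1L)
  expect_equal(per_subtype,
               c(HER2_amplified = 12L, TNBC = 7L, HR_pos_HER2_neg_RS_ge_25 = 3L))
  expect_equal(sum(out$breast_ln_pcr), 18)
  expect_equal(sum(out$yp_category == "ypT0_ypN0"), 13)
  expect_equal(sum(out$ncr), 4)
  expect_equal(sum(out$surgery == "breast_conserving"), 19)
  expect_equal(sum(out$dfs_event), 7)
  # structural invariants
  expect_true(all(out$breast_pcr[out$breast_ln_pcr]))
  expect_true(all(!out$breast_pcr[out$ncr]))

  zero <- generate_cohort(breast_pcr_counts = c(0, 0, 0),
                          breast_ln_pcr_counts = c(0, 0, 0),
                          ypt0_ypn0_counts = c(0, 0, 0))
  expect_equal(sum(zero$outcomes$breast_pcr), 0)
  full <- generate_cohort(breast_pcr_counts = c(15, 15, 10),
                          breast_ln_pcr_counts = c(15, 15, 10),
                          ypt0_ypn0_counts = c(13, 0, 0),
                          ncr_counts = c(0, 0, 0))
  expect_equal(sum(full$outcomes$breast_pcr), 40)
  expect_error(generate_cohort(breast_pcr_counts = c(16, 0, 0)), "caps")
})
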