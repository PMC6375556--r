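test_that("a single clonal population yields one cluster", {
  set.seed(1)
  recs <- data.frame(
    record_id = sprintf("v%02d", 1:40), sample_id = "s",
    tumour_depth = 100, tumour_alt_reads = rbinom(40, 100, 0.5),
    stringsAsFactors = FALSE
  )
  recs$vaf <- recs$tumour_alt_reads / recs$tumour_depth
  cl <- cluster_vafs(recs)
  expect_equal(attr(cl, "k"), 1)
  expect_equal(cl[[1]]$size, 40)
  expect_equal(cl[[1]]$mean_vaf, sum(recs$tumour_alt_reads) / sum(recs$tumour_depth))
})

test_that("three identical variants collapse to one cluster at the shared VAF", {
  recs <- data.frame(
    record_id = c("a", "b", "c"), sample_id = "s",
    tumour_depth = 100, tumour_alt_reads = 30, stringsAsFactors = FALSE
  )
  cl <- cluster_vafs(recs)
  expect_equal(attr(cl, "k"), 1)
  expect_equal(cl[[1]]$mean_vaf, 0.3)
  expect_error(cluster_vafs(recs[1, ]), "at least 2")
})

test_that("two planted clones are recovered with accurate means", {
  set.seed(7)
  mk <- function(vaf, n, tag) {
    d <- rep(200, n)
    a <- rbinom(n, d, vaf)
    data.frame(record_id = sprintf("%s%03d", tag, 1:n), sample_id = "s",
               tumour_depth = d, tumour_alt_reads = a, stringsAsFactors = FALSE)
  }
  recs <- rbind(mk(0.45, 50, "hi"), mk(0.10, 50, "lo"))
  cl <- cluster_vafs(recs, seed = 7)
  expect_equal(attr(cl, "k"), 2)
  means <- sort(vapply(cl, `[[`, 0, "mean_vaf"))
  expect_lt(abs(means[1] - 0.10), 0.03)
  expect_lt(abs(means[2] - 0.45), 0.03)
  # memberships match the planted clones
  hi_members <- cl[[which.max(vapply(cl, `[[`, 0, "mean_vaf"))]]$members
  expect_setequal(hi_members, recs$record_id[1:50])
})

test_that("clone tracking classifies identity, emergence and extinction", {
  mkc <- function(ids, vaf) list(sample_id = "s", label = "x", members = ids,
                                 mean_vaf = vaf, size = length(ids))
  d1 <- mkc(sprintf("v%02d", 1:20), 0.5)
  r1 <- mkc(sprintf("v%02d", 1:20), 0.48)
  tr <- track_clones(list(d1), list(r1), patient_id = "p")
  expect_equal(tr$fate, "persistent")

  new <- mkc(sprintf("n%02d", 1:10), 0.2)
  tr2 <- track_clones(list(d1), list(r1, new), patient_id = "p")
  expect_setequal(tr2$fate, c("persistent", "emergent"))

  # disjoint memberships: everything extinct or emergent
  r3 <- mkc(sprintf("z%02d", 1:20), 0.5)
  tr3 <- track_clones(list(d1), list(r3), patient_id = "p")
  expect_setequal(tr3$fate, c("extinct", "emergent"))

  # shared variants within one timepoint are an error
  expect_error(track_clones(list(d1, d1), list(r1)), "share a variant")
})

test_that("every cluster appears in exactly one trajectory", {
  for (seed in 1:10) {
    n_clones <- 2 + seed %% 3
    pat <- simulate_clone_patient(n_clones = n_clones, seed = seed,
                                  patient_id = paste0("p", seed))
    d <- cluster_vafs(pat$diagnostic, seed = seed)
    r <- cluster_vafs(pat$residual, seed = seed)
    tr <- track_clones(d, r, patient_id = paste0("p", seed))
    d_used <- tr$diagnostic_cluster[!is.na(tr$diagnostic_cluster)]
    r_used <- tr$residual_cluster[!is.na(tr$residual_cluster)]
    expect_setequal(d_used, vapply(d, `[[`, "", "label"))
    expect_setequal(r_used, vapply(r, `[[`, "", "label"))
    expect_false(anyDuplicated(d_used) > 0)
    expect_false(anyDuplicated(r_used) > 0)
  }
})

test_that("river table has one row per clone and timepoint", {
  expect_equal(nrow(river_table(track_clones(list(), list()))), 0)
  pat <- simulate_clone_patient(n_clones = 3, seed = 3, patient_id = "p3")
  d <- cluster_vafs(pat$diagnostic, seed = 3)
  r <- cluster_vafs(pat$residual, seed = 3)
  tr <- track_clones(d, r, patient_id = "p3")
  rt <- river_table(tr)
  n_expected <- sum(tr$fate == "persistent") * 2 + sum(tr$fate != "persistent")
  expect_equal(nrow(rt), n_expected)
  expect_true(all(rt$timepoint %in% c("diagnostic", "residual")))
  expect_true(all(rt$fraction > 0 & rt$fraction < 1))
})

test_that("clone fates are recovered accurately on simulated patients", {
  correct <- 0; total <- 0
  for (seed in 1:25) {
    n_clones <- 2 + seed %% 3
    n_extinct <- 1
    pat <- simulate_clone_patient(n_clones = n_clones, n_extinct = n_extinct,
                                  n_emergent = 1, seed = seed,
                                  patient_id = paste0("q", seed))
    d <- cluster_vafs(pat$diagnostic, seed = seed)
    r <- cluster_vafs(pat$residual, seed = seed)
    tr <- track_clones(d, r, patient_id = paste0("q", seed))
    # map each true clone to the trajectory holding most of its variants
    for (ci in seq_len(nrow(pat$truth))) {
      ids <- pat$membership$record_id[pat$membership$clone == pat$truth$clone[ci]]
      overlap <- vapply(tr$defining_variants, function(m) length(intersect(m, ids)), 1L)
      inferred <- tr$fate[which.max(overlap)]
      correct <- correct + (inferred == pat$truth$fate[ci])
      total <- total + 1
    }
  }
  expect_gt(total, 0)
  expect_gte(correct / total, 0.95)
})
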