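test_that("catalogs count qualifying SNVs into single classes", {
  recs <- make_records(
    make_record("a", ref = "C", alt = "T", context = "ACA", call_quality = 30),
    # purine-reference record: G>A at TGT is the reverse complement of A[C>T]A
    make_record("b", ref = "G", alt = "A", context = "TGT", call_quality = 30),
    # excluded: VAF exactly 0.10 (rule is strictly greater)
    make_record("c", tumour_depth = 100, tumour_alt_reads = 10, vaf = 0.10),
    # excluded: quality exactly 20 (rule is strictly greater)
    make_record("d", call_quality = 20),
    # non-SNVs never contribute
    make_record("e", kind = "DEL", consequence = "other")
  )
  cat <- build_catalog(recs)
  expect_equal(sum(cat), 2)
  expect_equal(unname(cat["A[C>T]A"]), 2L)
  expect_equal(attr(cat, "n_mutations"), 2)
})

test_that("an SNV without context is an error", {
  rec <- make_record("a")
  rec$context <- ""
  expect_error(build_catalog(rec), "context")
})

test_that("identity catalogs refit to a single signature with near-zero error", {
  S <- synthetic_signatures()
  catalog <- round(S["Sig5", ] * 100000)
  fit <- fit_signatures(catalog, S)
  expect_gte(unname(fit$weights["Sig5"]), 0.99)
  expect_lt(fit$sse, 1e-5)
  expect_lt(fit$unexplained, 0.01)
})

test_that("an exact 50/50 two-signature mixture is recovered", {
  S <- synthetic_signatures()
  # expected catalog, no sampling noise
  catalog <- (0.5 * S["Sig2", ] + 0.5 * S["Sig7", ]) * 10000
  fit <- fit_signatures(catalog, S)
  expect_equal(unname(fit$weights["Sig2"]), 0.5, tolerance = 0.04)
  expect_equal(unname(fit$weights["Sig7"]), 0.5, tolerance = 0.04)
  expect_true(all(names(fit$weights) %in% c("Sig2", "Sig7")))
})

test_that("no reported weight lies in (0, 0.06) and mass balances", {
  S <- synthetic_signatures()
  set.seed(31)
  for (i in 1:5) {
    w_true <- c(0.85, 0.1, 0.05)
    sigs <- sample(rownames(S), 3)
    p <- as.numeric(w_true %*% S[sigs, ])
    catalog <- as.numeric(stats::rmultinom(1, 1500, p))
    fit <- fit_signatures(catalog, S)
    expect_true(all(fit$weights >= 0.06))
    expect_equal(sum(fit$weights) + fit$unexplained, 1, tolerance = 1e-6)
  }
})

test_that("the refit never does worse than the best single-signature fit", {
  S <- synthetic_signatures()
  set.seed(17)
  for (i in 1:5) {
    p <- as.numeric(c(0.6, 0.4) %*% S[sample(rownames(S), 2), ])
    catalog <- as.numeric(stats::rmultinom(1, 2000, p))
    fit <- fit_signatures(catalog, S)
    pn <- catalog / sum(catalog)
    single_sse <- apply(S, 1, function(s) {
      # best single weight has a closed form on [0,1]
      w <- min(1, max(0, sum(pn * s) / sum(s * s)))
      sum((pn - w * s)^2)
    })
    expect_lte(fit$sse, min(single_sse) + 1e-9)
  }
})

test_that("fit SSE tracks a full-matrix nonnegative least-squares oracle", {
  skip_if_not_installed("pracma")
  S <- synthetic_signatures()
  A <- t(unclass(S))
  set.seed(23)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    w_true <- stats::rgamma(k, 2)
    w_true <- w_true / sum(w_true)
    w_true <- pmax(w_true, 0.08)
    w_true <- w_true / sum(w_true)
    p <- as.numeric(w_true %*% S[sample(rownames(S), k), ])
    # alternate between multinomially sampled and expected catalogs
    catalog <- if (i %% 2) as.numeric(stats::rmultinom(1, 3000, p)) else round(p * 5000)
    pn <- catalog / sum(catalog)
    fit <- fit_signatures(catalog, S)
    nnls <- pracma::lsqnonneg(A, pn)
    oracle_sse <- sum((pn - as.numeric(A %*% nnls$x))^2)
    # the constrained, pruned fit cannot beat the unconstrained oracle and
    # must stay within 5% of it, relative to the catalog's total variance
    expect_gte(fit$sse, oracle_sse - 1e-12)
    expect_lt((fit$sse - oracle_sse) / sum(pn^2), 0.05)
  }
})

test_that("degenerate catalogs are rejected", {
  S <- synthetic_signatures()
  expect_error(fit_signatures(numeric(96), S), "empty catalog")
  expect_error(fit_signatures(numeric(50), S), "96")
})
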