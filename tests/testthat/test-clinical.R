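test_that("response rates reproduce the requested marginals with numerators", {
  co <- generate_cohort()
  rates <- response_rates(co$outcomes)
  get <- function(m, g = "overall") rates[rates$measure == m & rates$group == g, ]
  expect_equal(get("breast_pcr")$percent, 55)
  expect_equal(get("breast_pcr")$numerator, 22)
  expect_equal(get("breast_pcr", "HER2_amplified")$percent, 80)
  expect_equal(get("breast_pcr", "HR_pos_HER2_neg_RS_ge_25")$percent, 30)
  expect_equal(get("breast_pcr", "TNBC")$fraction, 7 / 15)
  expect_equal(get("pcr_or_ncr")$percent, 65)
  # numerators never exceed denominators; subtype numerators sum to overall
  expect_true(all(rates$numerator <= rates$denominator))
  for (m in unique(rates$measure)) {
    sub <- rates[rates$measure == m & rates$group != "overall", ]
    expect_equal(sum(sub$numerator), get(m)$numerator)
  }
})

test_that("all-negative outcomes give zero rates everywhere", {
  co <- generate_cohort(breast_pcr_counts = c(0, 0, 0),
                        breast_ln_pcr_counts = c(0, 0, 0),
                        ypt0_ypn0_counts = c(0, 0, 0),
                        ncr_counts = c(0, 0, 0),
                        conserving_counts = c(0, 0, 0))
  rates <- response_rates(co$outcomes)
  expect_true(all(rates$numerator == 0))
  expect_true(all(rates$percent == 0))
})

test_that("exact binomial operating characteristics match the design", {
  oc <- design_operating_characteristics(n = 40, r = 17, p0 = 0.30, p1 = 0.50)
  expect_equal(round(100 * oc$type_i_error), 6)
  expect_equal(round(100 * oc$power), 87)
  expect_equal(design_operating_characteristics(r = 0)$power, 1)
  expect_equal(design_operating_characteristics(r = 0)$type_i_error, 1)
  expect_error(design_operating_characteristics(p0 = 0.5, p1 = 0.3))
})

test_that("operating characteristics agree with Monte-Carlo simulation", {
  oc <- design_operating_characteristics()
  withr::with_seed(99, {
    mc_alpha <- mean(rbinom(1e6, 40, 0.30) >= 17)
    mc_power <- mean(rbinom(1e6, 40, 0.50) >= 17)
  })
  expect_equal(oc$type_i_error, mc_alpha, tolerance = 0.003 / oc$type_i_error)
  expect_equal(oc$power, mc_power, tolerance = 0.003 / oc$power)
})

test_that("the product-limit estimate matches a hand-computed worked example", {
  # 6 patients: events at 2, 4, 6, 10; censored at 4+ and 8+
  outcomes <- data.frame(
    dfs_months = c(2, 4, 4, 6, 8, 10),
    dfs_event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  km <- km_dfs(outcomes)
  # manual product limit: S(2)=5/6, S(4)=5/6*4/5=2/3, S(6)=2/3*2/3=4/9,
  # S(10)=4/9*0 = 0
  tab <- km$table[km$table$n_event > 0, ]
  expect_equal(tab$time, c(2, 4, 6, 10))
  expect_equal(tab$survival, c(5 / 6, 2 / 3, 4 / 9, 0), tolerance = 1e-12)
  # independent recomputation by direct product over event times
  s <- 1
  at_risk <- function(t) sum(outcomes$dfs_months >= t)
  for (t in c(2, 4, 6, 10)) {
    d <- sum(outcomes$dfs_months == t & outcomes$dfs_event)
    s <- s * (1 - d / at_risk(t))
    expect_equal(tab$survival[tab$time == t], s, tolerance = 1e-12)
  }
  expect_equal(unname(km$median), 6)
})

test_that("with no events the curve stays at 1 and the median is undefined", {
  outcomes <- data.frame(dfs_months = c(12, 18, 24, 30),
                         dfs_event = rep(FALSE, 4))
  km <- km_dfs(outcomes)
  expect_true(all(km$table$survival == 1))
  expect_true(is.na(km$median))
  expect_error(km_dfs(data.frame(dfs_months = -1, dfs_event = TRUE)), "negative")
})

test_that("single event among five patients leaves S = 0.8", {
  outcomes <- data.frame(dfs_months = c(5, 6, 7, 8, 9),
                         dfs_event = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  km <- km_dfs(outcomes)
  expect_equal(km$table$survival[km$table$time == 5], 0.8)
})

test_that("relative dose intensity summarises exposure", {
  out <- data.frame(patient_id = c("a", "b", "c"), planned_dose = 1000,
                    delivered_dose = c(1000, 0, 900))
  di <- dose_intensity(out)
  expect_equal(di$per_patient$rdi, c(1, 0, 0.9))
  expect_equal(di$n_at_or_above, 2)
  expect_error(dose_intensity(data.frame(patient_id = "a", planned_dose = 0,
                                         delivered_dose = 1)), "positive")
  co <- generate_cohort()
  expect_equal(dose_intensity(co$outcomes)$n_at_or_above, 35)
  expect_equal(dose_intensity(co$outcomes)$percent_at_or_above, 88)
})

test_that("adverse events count each patient once per term", {
  aes <- data.frame(
    patient_id = c("a", "a", "b", "c"),
    term = c("nausea", "nausea", "nausea", "neutropenia"),
    grade = c(1, 2, 3, 4), stringsAsFactors = FALSE
  )
  tab <- ae_table(aes, n_patients = 10)
  expect_equal(tab$n_any[tab$term == "nausea"], 2)
  expect_equal(tab$n_grade3plus[tab$term == "nausea"], 1)
  expect_equal(tab$n_grade3plus[tab$term == "neutropenia"], 1)
  expect_equal(nrow(ae_table(aes[0, ], 10)), 0)
  expect_error(ae_table(data.frame(patient_id = "a", term = "x", grade = 6), 10),
               "1..5")
})

test_that("rare any-grade terms are filtered unless grade >= 3", {
  aes <- data.frame(
    patient_id = c("a", "b"), term = c("rare_mild", "rare_severe"),
    grade = c(1, 3), stringsAsFactors = FALSE
  )
  tab <- ae_table(aes, n_patients = 40)
  expect_false("rare_mild" %in% tab$term) # 1/40 < 10%, no grade 3
  expect_true("rare_severe" %in% tab$term)
})

test_that("the generated AE table reproduces the planted toxicity profile", {
  co <- generate_cohort()
  tab <- ae_table(co$adverse_events, n_patients = 40)
  expect_equal(tab$n_any[tab$term == "neutropenia"], 23)
  expect_equal(tab$n_grade3plus[tab$term == "neutropenia"], 7)
  expect_equal(tab$n_any[tab$term == "sensory_neuropathy"], 22)
  expect_equal(tab$n_grade3plus[tab$term == "febrile_neutropenia"], 3)
  # pneumothorax: 1 patient any grade (< 10%) but grade 3, so reported
  expect_true("pneumothorax" %in% tab$term)
  # dyspepsia: 4/40 = 10% any grade, reported at the boundary
  expect_true("dyspepsia" %in% tab$term)
})
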