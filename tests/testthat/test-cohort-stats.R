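mk_results <- function(tiers, reasons = NULL, ids = NULL) {
  n <- length(tiers)
  if (is.null(ids)) ids <- sprintf("P%d", seq_len(n))
  if (is.null(reasons)) {
    reasons <- c(high = "GROUP_A", moderate = "TEST_GHD", low = "NONE")[tiers]
  }
  tibble::tibble(person_id = ids,
                 tier = factor(tiers, levels = c("high", "moderate", "low")),
                 reason = factor(unname(reasons),
                                 levels = aghdscreen:::reason_levels()),
                 excluded_paths = "")
}

test_that("tier proportions sum to one and are order-invariant", {
  r <- mk_results(c("high", "moderate", "low", "low"))
  tp <- tier_proportions(r)
  expect_equal(tp$tiers$proportion, c(0.25, 0.25, 0.50))
  expect_equal(sum(tp$tiers$proportion), 1, tolerance = 1e-12)

  all_low <- tier_proportions(mk_results(rep("low", 5)))
  expect_equal(all_low$tiers$proportion, c(0, 0, 1))

  set.seed(2)
  shuffled <- tier_proportions(r[sample(nrow(r)), ])
  expect_equal(shuffled$tiers, tp$tiers)
  # reason shares sum to one within each occupied tier
  shares <- tapply(tp$reasons$share, tp$reasons$tier, sum)
  expect_true(all(abs(shares[!is.na(shares)] - 1) < 1e-12))

  expect_error(tier_proportions(r[0, ]), class = "aghd_data_error")
})

test_that("age/sex table cells are percentages of the whole cohort", {
  w <- cohort_window()
  p <- mk_person(id = "P1", birth = 1992)  # 25 at index
  r <- mk_results("low", ids = "P1")
  t1 <- age_sex_table(p, r, w)
  expect_equal(t1$low[t1$group == "18-30"], 100)
  expect_equal(t1$cohort[t1$group == "Female"], 100)
  expect_equal(t1$high[t1$group == "All"], 0)

  # multi-band cohort: tier columns sum row-wise to the cohort column,
  # and band rows sum to the All row
  persons <- dplyr::bind_rows(lapply(1:40, function(i) {
    mk_person(id = sprintf("P%d", i), birth = sample(1930:1999, 1),
              sex = sample(c("female", "male"), 1))
  }))
  res <- mk_results(sample(c("high", "moderate", "low"), 40, replace = TRUE),
                    ids = persons$person_id)
  tt <- age_sex_table(persons, res, w)
  expect_equal(tt$cohort, tt$high + tt$moderate + tt$low)
  bands <- tt[!tt$group %in% c("All", "Female", "Male"), ]
  expect_equal(sum(bands$cohort), 100, tolerance = 1e-9)
  expect_equal(tt$cohort[tt$group == "All"], 100, tolerance = 1e-9)

  expect_error(age_sex_table(p, mk_results("low", ids = "NOPE"), w), "NOPE",
               class = "aghd_data_error")
})

test_that("comorbidity incidence counts persons once, within the last observation year", {
  reg <- test_registry()
  w <- cohort_window()
  p <- dplyr::bind_rows(mk_person("P1", birth = 1970),
                        mk_person("P2", birth = 1970))
  r <- mk_results(c("high", "high"), ids = c("P1", "P2"))
  last <- as.Date("2017-12-31")
  ev <- dplyr::bind_rows(
    mk_events("P1", last - 400, "ICD10CM", "I10"),          # outside window
    mk_events("P2", c(last - 10, last - 300), "ICD10CM",
              c("I10", "I101")))                            # twice, counts once
  t2 <- comorbidity_incidence(p, ev, r, reg, w)
  ht <- t2[t2$comorbidity == "hypertensive_disorder", ]
  expect_equal(ht$p_high, 0.5)
  expect_equal(ht$p_low, 0)
  # duplication- and order-invariant
  t2d <- comorbidity_incidence(p, dplyr::bind_rows(ev, ev)[sample(6), ], r,
                               reg, w)
  expect_equal(t2d, t2)
  # negligibility flag tracks |sd| <= 0.1 on every emitted row
  expect_equal(t2$neg_high_low, abs(t2$sd_high_low) <= 0.1)
  expect_equal(t2$neg_high_mod, abs(t2$sd_high_mod) <= 0.1)
  expect_equal(t2$neg_mod_low, abs(t2$sd_mod_low) <= 0.1)
})

test_that("standardized difference matches the pooled closed form and its symmetries", {
  expect_identical(standardized_difference(0.3, 0.3), 0)
  expect_equal(standardized_difference(0.239, 0.025), -0.6663886,
               tolerance = 1e-6)
  expect_identical(standardized_difference(0, 0), 0)
  expect_identical(standardized_difference(1, 1), 0)
  expect_error(standardized_difference(-0.1, 0.5), class = "aghd_data_error")

  set.seed(8)
  a <- runif(100); b <- runif(100)
  expect_equal(standardized_difference(a, b), -standardized_difference(b, a),
               tolerance = 1e-14)
})

test_that("standardized difference agrees with brute-force recomputation from 0/1 vectors", {
  set.seed(21)
  for (i in 1:200) {
    x <- sample(0:1, sample(5:60, 1), replace = TRUE, prob = c(0.4, 0.6))
    y <- sample(0:1, sample(5:60, 1), replace = TRUE)
    # brute force: group means and pooled binomial variance from the raw
    # 0/1 vectors, plugged into the closed form
    p1 <- sum(x) / length(x)
    p2 <- sum(y) / length(y)
    pooled_var <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
    brute <- if (p1 == p2) 0 else (p2 - p1) / sqrt(pooled_var)
    expect_equal(standardized_difference(mean(x), mean(y)), brute,
                 tolerance = 1e-12)
  }
})

test_that("diagnostic-test usage reports labelled tests for high/moderate tiers only", {
  reg <- test_registry()
  p <- dplyr::bind_rows(mk_person("P1", birth = 1970),
                        mk_person("P2", birth = 1970),
                        mk_person("P3", birth = 1970))
  r <- mk_results(c("moderate", "high", "low"), ids = c("P1", "P2", "P3"))
  ev <- dplyr::bind_rows(
    mk_events("P1", "2015-06-01", "CPT", "84305"),  # IGF-I, moderate person
    mk_events("P3", "2015-06-01", "CPT", "84305"))  # low-tier usage not reported
  t3 <- diagnostic_test_usage(p, ev, r, reg)
  expect_setequal(names(t3), c("test", "p_high", "p_moderate"))
  expect_equal(t3$p_moderate[t3$test == "igf1_serum"], 1)
  expect_equal(t3$p_high[t3$test == "igf1_serum"], 0)
  expect_true(all(t3$p_high[t3$test != "igf1_serum"] == 0))

  # an empty tier gives zero rows, not an error
  r2 <- mk_results(c("low", "low", "low"), ids = c("P1", "P2", "P3"))
  t3b <- diagnostic_test_usage(p, ev, r2, reg)
  expect_true(all(t3b$p_high == 0) && all(t3b$p_moderate == 0))
})
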