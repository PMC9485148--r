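test_that("score_table enforces its shape and rejects NaN", {
  m <- matrix(0, 7, 8, dimnames = list(tooth_ids(), stage_levels()))
  expect_s3_class(score_table("male", m), "score_table")
  expect_error(score_table("male", m[1:6, ]), "7 x 8")
  m_nan <- m; m_nan[2, 3] <- NaN
  expect_error(score_table("male", m_nan), "NaN")
})

test_that("lookup_score returns printed cells and errors on absent/missing", {
  tabs <- modified_score_tables()
  expect_equal(lookup_score(tabs$male, "34", "D"), 1.44)
  expect_equal(lookup_score(tabs$female, "37", "H"), 3.30)
  expect_equal(lookup_score(tabs$female, "34", "A"), -1.10)
  expect_equal(lookup_score(tabs$male, "35", "B"), 0.03)
  expect_error(lookup_score(tabs$female, "36", "A"), "absent cell")
  expect_error(lookup_score(tabs$male, "33", "C"), "absent cell")
  expect_error(lookup_score(tabs$male, "34", NA), "missing stage")
  expect_error(lookup_score(tabs$male, "99", "D"), "unknown tooth")
})

test_that("age-sum estimation is the sum of the seven cell scores", {
  tabs <- modified_score_tables()
  all_h <- tibble::tibble(
    id = c("m", "f"), sex = c("male", "female"), age = c(17, 17),
    t31 = "H", t32 = "H", t33 = "H", t34 = "H", t35 = "H", t36 = "H", t37 = "H"
  )
  est_m <- estimate_age_sum(all_h[1, ], tabs$male)
  est_f <- estimate_age_sum(all_h[2, ], tabs$female)
  expect_equal(est_m$dental_age, 15.65) # male column-H sum
  expect_equal(est_f$dental_age, 15.71) # female column-H sum

  zero <- score_table("male", matrix(0, 7, 8), name = "zero")
  expect_equal(estimate_age_sum(all_h[1, ], zero)$dental_age, 0)

  expect_error(estimate_age_sum(all_h, tabs$male), "sex")
})

test_that("age-sum estimation is additive in single-stage changes", {
  tab <- random_full_table(seed = 3)
  coh <- random_cohort(25, seed = 4)
  base <- estimate_age_sum(coh, tab)$dental_age
  for (i in c(1, 9, 20)) {
    coh2 <- coh
    old <- coh2$t34[i]
    new <- setdiff(stage_levels(), old)[1]
    coh2$t34[i] <- new
    shifted <- estimate_age_sum(coh2, tab)$dental_age
    dd <- lookup_score(tab, "34", new) - lookup_score(tab, "34", old)
    expect_equal(shifted[i] - base[i], dd)
    expect_equal(shifted[-i], base[-i])
  }
})

test_that("missing-tooth policy defaults to error, skip flags partial", {
  tab <- random_full_table(seed = 5)
  coh <- random_cohort(10, seed = 6)
  coh$t36[3] <- NA
  expect_error(estimate_age_sum(coh, tab), "missing stage")
  est <- estimate_age_sum(coh, tab, on_missing = "skip")
  expect_true(est$partial[3])
  expect_false(any(est$partial[-3]))
  # skipped tooth contributes nothing
  manual <- sum(vapply(tooth_columns()[-6], function(cl) {
    lookup_score(tab, sub("t", "", cl), coh[[cl]][3])
  }, numeric(1)))
  expect_equal(est$dental_age[3], manual)
})

test_that("maturity conversion interpolates, clamps and flags", {
  conv <- maturity_conversion("male", rbind(c(0, 2), c(100, 16)))
  tab <- score_table("male", matrix(50 / 7, 7, 8), kind = "maturity",
                     name = "flat")
  coh <- random_cohort(3, seed = 8)
  est <- estimate_age_maturity(coh, tab, conv)
  expect_equal(est$maturity_score, rep(50, 3))
  expect_equal(est$dental_age, rep(9, 3)) # linear midpoint
  expect_false(any(est$clamped))

  low <- score_table("male", matrix(-5, 7, 8), kind = "maturity", name = "low")
  est_low <- estimate_age_maturity(coh, low, conv)
  expect_equal(est_low$dental_age, rep(2, 3)) # clamped to first knot age
  expect_true(all(est_low$clamped))

  # maturity score landing exactly on a knot returns the knot age
  conv3 <- maturity_conversion("male", rbind(c(0, 2), c(35, 9.5), c(100, 16)))
  tab35 <- score_table("male", matrix(5, 7, 8), kind = "maturity", name = "k")
  expect_equal(estimate_age_maturity(coh, tab35, conv3)$dental_age, rep(9.5, 3))

  # monotone: higher maturity never lowers the age
  m_lo <- estimate_age_maturity(coh, tab35, conv3)$dental_age
  tab40 <- score_table("male", matrix(40 / 7, 7, 8), kind = "maturity", name = "k2")
  m_hi <- estimate_age_maturity(coh, tab40, conv3)$dental_age
  expect_true(all(m_hi >= m_lo))

  expect_error(maturity_conversion("male", rbind(c(1, 2), c(1, 3))),
               "strictly increasing")
  expect_error(maturity_conversion("male", rbind(c(0, 5), c(10, 4))),
               "nondecreasing")
})

test_that("score-table JSON round-trip is lossless, bad JSON is rejected", {
  tabs <- modified_score_tables()
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(tabs$male, path)
  back <- read_score_table(path)
  expect_equal(back, tabs$male)
  # absent cells stay absent through the trip
  expect_error(lookup_score(back, "33", "A"), "absent cell")

  write_score_table(random_full_table(seed = 10), path)
  expect_equal(read_score_table(path), random_full_table(seed = 10))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","sex":"male","kind":"age_sum","scores":{"31":{}}}', bad)
  expect_error(read_score_table(bad), "missing tooth row|missing stage")

  nan_json <- withr::local_tempfile(fileext = ".json")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  obj$scores[["31"]][["A"]] <- "NaN"
  jsonlite::write_json(obj, nan_json, auto_unbox = TRUE)
  expect_error(read_score_table(nan_json), "non-finite")
})

test_that("tidy() flattens a table to tooth/stage/score rows", {
  tt <- tidy(modified_score_tables()$female)
  expect_equal(nrow(tt), 56)
  expect_equal(tt$score[tt$tooth == "37" & tt$stage == "H"], 3.30)
  expect_true(is.na(tt$score[tt$tooth == "36" & tt$stage == "A"]))
})
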