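test_that("design matrices realize both strategies", {
  tab <- random_full_table(seed = 1)
  coh <- random_cohort(1, seed = 2)
  dm <- build_design_matrix(coh, tab, strategy = "per_tooth")
  expect_equal(dim(dm$x), c(1, 7))
  expect_equal(colnames(dm$x), tooth_ids())
  expect_equal(
    unname(dm$x[1, ]),
    vapply(tooth_columns(), function(cl)
      lookup_score(tab, sub("t", "", cl), coh[[cl]][1]), numeric(1)),
    ignore_attr = TRUE
  )

  two <- random_cohort(2, seed = 3)
  two$t33 <- c("D", "E") # one tooth differing -> two indicator columns
  dm2 <- build_design_matrix(two, strategy = "per_cell")
  expect_true(all(c("33:D", "33:E") %in% colnames(dm2$x)))
  expect_equal(unname(rowSums(dm2$x)), c(7, 7)) # one cell per tooth per record

  # absent base cell propagates with its name
  tabs <- modified_score_tables()
  young <- random_cohort(1, seed = 4)
  young$t33 <- "A"
  expect_error(build_design_matrix(young, tabs$male, "per_tooth"),
               "absent base cell: tooth 33, stage A")

  # missing-stage records are excluded and counted
  miss <- random_cohort(5, seed = 5)
  miss$t31[2] <- NA
  dm3 <- build_design_matrix(miss, tab, "per_tooth")
  expect_equal(nrow(dm3$x), 4)
  expect_equal(dm3$n_excluded, 1)
})

test_that("non-intercept OLS solves the normal equations", {
  expect_equal(unname(fit_nonintercept_ols(cbind(a = c(1, 2, 3)),
                                           c(1, 2, 3))), 1)
  expect_equal(unname(fit_nonintercept_ols(cbind(a = c(2, 4, 6)),
                                           c(1, 2, 3))), 0.5)
  # hand oracle: b = sum(x*y) / sum(x^2) = 31/14
  expect_equal(unname(fit_nonintercept_ols(cbind(a = c(1, 2, 3)),
                                           c(2, 4, 7))), 31 / 14)

  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_error(fit_nonintercept_ols(x, c(1, 2, 3)),
               "singular design.*b")

  # minimum-norm agrees with QR on full-rank designs
  set.seed(1)
  xf <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- rnorm(20)
  expect_equal(fit_nonintercept_ols(xf, y, "minimum-norm"),
               fit_nonintercept_ols(xf, y, "qr"), tolerance = 1e-10)
})

test_that("derive_modified_table maps coefficients to cells", {
  tab <- random_full_table(seed = 6)
  b1 <- setNames(rep(1, 7), tooth_ids())
  expect_equal(derive_modified_table(b1, tab, "per_tooth")$scores, tab$scores)

  b2 <- b1; b2["34"] <- 2
  tabs <- modified_score_tables()
  out <- derive_modified_table(b2, tabs$male, "per_tooth")
  expect_equal(out$scores["34", "D"], 2 * 1.44)

  cells <- c("31:C" = 1.5, "34:D" = -0.2)
  pc <- derive_modified_table(cells, strategy = "per_cell", sex = "female")
  expect_equal(pc$scores["31", "C"], 1.5)
  expect_equal(pc$scores["34", "D"], -0.2)
  expect_true(is.na(pc$scores["37", "H"])) # unobserved cells stay absent
})

test_that("per-tooth refit recovers known scale factors on noise-free data", {
  base <- random_full_table(seed = 7)
  scale <- setNames(c(1.2, 0.8, 1.5, 1.0, 0.5, 2.0, 0.9), tooth_ids())
  scaled <- score_table(base$sex, base$scores * scale, name = "scaled")
  spec <- cohort_spec(counts = dplyr::mutate(
    table1_counts(), female = 0, male = pmin(male, 40)))
  coh <- generate_from_score_table(scaled, spec, noise_sd = 0, seed = 8)
  fit <- refit_score_table(coh, base = base, strategy = "per_tooth")
  expect_equal(fit$coefficients, scale, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("per-cell refit reproduces ages exactly and is idempotent", {
  tab <- random_full_table(sex = "female", seed = 9)
  spec <- cohort_spec(counts = dplyr::mutate(
    table1_counts(), male = 0, female = pmin(female, 40)))
  coh <- generate_from_score_table(tab, spec, noise_sd = 0, seed = 10)

  fit1 <- refit_score_table(coh, sex = "female", strategy = "per_cell")
  expect_lt(fit1$residual_sd, 1e-8)
  est1 <- estimate_age_sum(coh, fit1$modified_table, on_missing = "error")
  expect_equal(est1$dental_age, coh$age, tolerance = 1e-8)

  # a table already produced by the refit is recovered cell-for-cell
  coh2 <- coh
  est_on_stages <- estimate_age_sum(coh, fit1$modified_table)
  coh2$age <- est_on_stages$dental_age
  fit2 <- refit_score_table(coh2, sex = "female", strategy = "per_cell")
  seen <- !is.na(fit1$modified_table$scores)
  expect_equal(fit2$modified_table$scores[seen],
               fit1$modified_table$scores[seen], tolerance = 1e-8)
})

test_that("residuals are orthogonal to the design on every fit", {
  tabs <- modified_score_tables()
  coh <- generate_cohort(seed = 12)$cohort
  for (s in c("female", "male")) {
    sub <- coh[coh$sex == s, ]
    for (strat in c("per_cell", "per_tooth")) {
      dm <- build_design_matrix(sub, tabs[[s]], strat)
      b <- fit_nonintercept_ols(dm$x, dm$y,
                                if (strat == "per_cell") "minimum-norm" else "qr")
      r <- dm$y - drop(dm$x %*% b)
      expect_lt(max(abs(crossprod(dm$x, r))) / length(dm$y), 1e-8)
    }
  }
})

test_that("refit on noisy score-model data reports the noise scale", {
  tab <- random_full_table(seed = 13)
  spec <- cohort_spec(counts = dplyr::mutate(
    table1_counts(), female = 0,
    male = round(male * 1000 / sum(male))))
  coh <- generate_from_score_table(tab, spec, noise_sd = 1, seed = 14)
  fit <- refit_score_table(coh, sex = "male", strategy = "per_cell")
  expect_gt(fit$residual_sd, 0.8)
  expect_lt(fit$residual_sd, 1.2)
})

test_that("reweighting shrinks the mean age deviation of a biased base table", {
  coh <- generate_cohort(seed = 15)$cohort
  tabs <- modified_score_tables()
  for (s in c("female", "male")) {
    sub <- coh[coh$sex == s, ]
    base_est <- estimate_age_sum(sub, tabs[[s]])
    fit <- refit_score_table(sub, base = tabs[[s]], strategy = "per_cell")
    mod_est <- estimate_age_sum(sub, fit$modified_table)
    ad_base <- mean(base_est$dental_age - sub$age)
    ad_mod <- mean(mod_est$dental_age - sub$age)
    expect_lte(abs(ad_mod), abs(ad_base))
  }
})

test_that("tidy and glance expose the fitted coefficients", {
  tabs <- modified_score_tables()
  coh <- generate_cohort(seed = 16)$cohort
  sub <- coh[coh$sex == "male", ]
  fit <- refit_score_table(sub, base = tabs$male, strategy = "per_tooth")
  td <- tidy(fit)
  expect_equal(td$term, tooth_ids())
  gl <- glance(fit)
  expect_equal(gl$n, nrow(sub))
  expect_equal(gl$strategy, "per_tooth")
})
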