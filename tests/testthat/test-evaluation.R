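pairs_of <- function(ca, da, sex = "female") {
  tibble::tibble(id = sprintf("p%d", seq_along(ca)), sex = sex,
                 age = ca, dental_age = da, method = "toy")
}

test_that("age deviation is DA - CA with sign meaning over/underestimation", {
  p <- pairs_of(c(10, 12), c(10, 12))
  expect_equal(age_deviation(p)$summary$mean_ad, 0)
  expect_equal(age_deviation(pairs_of(10, 9.5))$summary$mean_ad, -0.5)
  ad <- age_deviation(pairs_of(c(10, 11), c(11.5, 11)))
  expect_equal(ad$per_subject$ad, c(1.5, 0))
})

test_that("MAE distinguishes absolute from signed error and honours caps", {
  p <- pairs_of(c(10, 10), c(11, 9))
  expect_equal(mae(p), 1)
  expect_equal(age_deviation(p)$summary$mean_ad, 0)

  capped <- pairs_of(c(15, 16.5, 17), c(15.5, 18.5, 18))
  expect_equal(mae(capped, 18), mean(c(0.5, 2, 1)))
  expect_equal(mae(capped, 16), 0.5) # only CA < 16 retained
  expect_equal(mae(pairs_of(c(3, 4), c(3, 4))), 0)
  expect_error(mae(pairs_of(17, 18), age_cap = 16), "no subjects")

  # cohort entirely under 16: both caps agree
  young <- pairs_of(runif(50, 2, 15.9), runif(50, 2, 16))
  expect_equal(mae(young, 18), mae(young, 16))
})

test_that("regression metrics match their closed forms", {
  perfect <- pairs_of(c(3, 7, 11), c(3, 7, 11))
  m <- regression_metrics(perfect)
  expect_equal(unlist(m[c("mse", "rmse", "mae", "r2")]),
               c(mse = 0, rmse = 0, mae = 0, r2 = 1))

  ones <- pairs_of(c(4, 6, 8, 10), c(5, 7, 9, 11))
  m1 <- regression_metrics(ones)
  expect_equal(c(m1$mse, m1$rmse, m1$mae), c(1, 1, 1))

  # hand-computed 4-point example
  hand <- pairs_of(c(4, 6, 8, 10), c(5, 5, 9, 9))
  mh <- regression_metrics(hand)
  expect_equal(mh$mse, 1)
  expect_equal(mh$r2, 1 - 4 / 20) # ss_tot = 9+1+1+9
  expect_error(regression_metrics(pairs_of(c(5, 5), c(4, 6))), "zero variance")
})

test_that("RMSE >= MAE and MSE = RMSE^2 on random inputs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    p <- pairs_of(runif(n, 2, 18), runif(n, 2, 18))
    m <- regression_metrics(p)
    expect_gte(m$rmse, m$mae)
    expect_equal(m$mse, m$rmse^2, tolerance = 1e-12)
  }
})

test_that("paired t-test matches its closed form and the reference routine", {
  sym <- pairs_of(c(10, 10), c(10.7, 9.3))
  tt <- paired_t_test(sym)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  # AD = {1,2,3}: t = 2*sqrt(3), p ~ 0.0742
  p3 <- pairs_of(c(5, 5, 5), c(6, 7, 8))
  t3 <- paired_t_test(p3)
  expect_equal(t3$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(t3$p, 0.0742, tolerance = 1e-3)
  expect_equal(t3$signif, "")

  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:100, 1)
    p <- pairs_of(runif(n, 2, 18), runif(n, 2, 18))
    mine <- paired_t_test(p)
    ref <- stats::t.test(p$dental_age, p$age, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }

  expect_error(paired_t_test(pairs_of(c(4, 5), c(5, 6))), "degenerate")
})

test_that("a persistent mean shift at cohort scale is significant", {
  set.seed(11)
  ca <- runif(833, 2, 18)
  p <- pairs_of(ca, ca + rnorm(833, mean = 0.3, sd = 1.15))
  expect_lt(paired_t_test(p)$p, 0.001)
  expect_equal(paired_t_test(p)$signif, "***")
})

test_that("Cohen's kappa: identity, chance and a hand-computed table", {
  a <- rep(c("A", "B", "C"), 10)
  expect_equal(cohens_kappa(a, a), 1)

  # 2x2 with po = 0.9, pe = 0.5 -> kappa = 0.8
  r1 <- c(rep("X", 45), rep("X", 5), rep("Y", 5), rep("Y", 45))
  r2 <- c(rep("X", 45), rep("Y", 5), rep("X", 5), rep("Y", 45))
  expect_equal(cohens_kappa(r1, r2), 0.8)

  set.seed(3)
  u <- sample(stage_levels(), 10000, replace = TRUE)
  v <- sample(stage_levels(), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(u, v)), 0.05)

  # weighted kappa credits adjacent-category disagreement
  w1 <- c("A", "B", "C", "D", "E", "F", "G", "H")
  w2 <- c("B", "C", "D", "E", "F", "G", "H", "A")
  kw <- cohens_kappa(w1, w2, weighted = TRUE, levels = stage_levels())
  ku <- cohens_kappa(w1, w2, levels = stage_levels())
  expect_gt(kw, ku)

  expect_error(cohens_kappa(c("A", "B"), c("A")), "equal length")
  expect_error(cohens_kappa(rep("A", 5), rep("A", 5)), "degenerate")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  for (i in 1:20) {
    n <- 200
    a <- sample(stage_levels()[1:4], n, replace = TRUE)
    b <- ifelse(runif(n) < 0.6, a, sample(stage_levels()[1:4], n, replace = TRUE))
    lev <- stage_levels()[1:4]
    ref <- e1071::classAgreement(table(factor(a, lev), factor(b, lev)))$kappa
    expect_equal(cohens_kappa(a, b, levels = lev), ref, tolerance = 1e-10)
  }
})

test_that("per-group MAE matches a brute-force group-by", {
  coh <- generate_cohort(seed = 19)$cohort
  est <- estimate_with_tables(coh, modified_score_tables())
  p <- paired_ages(coh, est)
  got <- per_group_mae(p)

  brute <- sapply(split(abs(p$dental_age - p$age), floor(p$age)), mean)
  expect_equal(got$mae, unname(brute), tolerance = 1e-12)
  expect_equal(sum(got$n), nrow(p))

  single <- p[p$age >= 9 & p$age < 10, ]
  g1 <- per_group_mae(single)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$mae, mae(single))
})

test_that("report builders are pure and shaped like the study tables", {
  coh <- generate_cohort(seed = 20)$cohort
  est <- estimate_with_tables(coh, modified_score_tables(), method = "modified")
  p <- paired_ages(coh, est)
  r1 <- fit_report(p)
  r2 <- fit_report(p)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2) # one method x two sexes
  expect_named(r1, c("method", "sex", "n", "ca_mean", "ca_sd", "da_mean",
                     "da_sd", "ad_mean", "ad_sd", "p", "signif",
                     "mae_under_18", "mae_under_16"))
  # summary statistics recompute from the pairs
  fem <- p[p$sex == "female", ]
  expect_equal(r1$ca_mean[r1$sex == "female"], mean(fem$age))
  expect_equal(r1$ad_sd[r1$sex == "female"],
               sd(fem$dental_age - fem$age))

  lp <- dplyr::mutate(p, split = "testing")
  lr <- learner_report(lp)
  expect_named(lr, c("method", "sex", "split", "mse", "rmse", "mae", "r2", "n"))
  expect_equal(nrow(lr), 2)
})
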