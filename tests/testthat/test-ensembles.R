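test_that("GBDT training MSE is nonincreasing over rounds", {
  coh <- learner_fixture(400)
  fit <- fit_gbdt(encode_features(coh), coh$age, n_trees = 40)
  expect_length(fit$train_mse, 40)
  expect_true(all(diff(fit$train_mse) <= 1e-12))
})

test_that("single-round ensembles reduce to the base CART", {
  coh <- learner_fixture(200)
  x <- encode_features(coh); y <- coh$age
  ctrl <- tree_control() # identical config for base tree and ensembles
  base <- predict(fit_regression_tree(x, y, control = ctrl), x)

  g1 <- fit_gbdt(x, y, n_trees = 1, learning_rate = 1, control = ctrl)
  expect_equal(predict(g1, x), base, tolerance = 1e-12)

  f1 <- fit_forest(x, y, n_trees = 1, variant = "random_forest",
                   bootstrap = FALSE, control = ctrl, seed = 1)
  expect_equal(predict(f1, x), base, tolerance = 1e-12)

  a1 <- fit_adaboost_r2(x, y, n_estimators = 1, control = ctrl, seed = 1)
  expect_equal(predict(a1, x), base, tolerance = 1e-12)
})

test_that("forests are deterministic per seed and average their trees", {
  coh <- learner_fixture(300)
  x <- encode_features(coh); y <- coh$age
  f1 <- fit_forest(x, y, n_trees = 10, seed = 5)
  f2 <- fit_forest(x, y, n_trees = 10, seed = 5)
  expect_identical(predict(f1, x), predict(f2, x))
  f3 <- fit_forest(x, y, n_trees = 10, seed = 6)
  expect_false(identical(predict(f1, x), predict(f3, x)))

  manual <- rowMeans(vapply(f1$trees, function(tr) predict(tr, x),
                            numeric(nrow(x))))
  expect_equal(predict(f1, x), manual)

  const <- fit_forest(x, rep(7, nrow(x)), n_trees = 3, seed = 1)
  expect_equal(predict(const, x), rep(7, nrow(x)))

  e1 <- fit_forest(x, y, n_trees = 10, variant = "extra_trees", seed = 5)
  e2 <- fit_forest(x, y, n_trees = 10, variant = "extra_trees", seed = 5)
  expect_identical(predict(e1, x), predict(e2, x))
  expect_false(e1$bootstrap)
})

test_that("AdaBoost.R2 stops on a perfect round and stays deterministic", {
  # perfectly fittable: few distinct patterns, constant response per pattern
  x <- cbind(a = rep(c(1, 2, 3, 4), each = 5))
  y <- rep(c(2, 4, 6, 8), each = 5)
  fit <- fit_adaboost_r2(x, y, n_estimators = 10, seed = 1)
  expect_true(fit$stopped_early)
  expect_length(fit$trees, 1)
  expect_equal(predict(fit, x), y)

  coh <- learner_fixture(300)
  xm <- encode_features(coh)
  a1 <- fit_adaboost_r2(xm, coh$age, n_estimators = 15, seed = 2)
  a2 <- fit_adaboost_r2(xm, coh$age, n_estimators = 15, seed = 2)
  expect_identical(predict(a1, xm), predict(a2, xm))
})

test_that("AdaBoost.R2 test error tracks a reference implementation", {
  # scikit-learn's AdaBoostRegressor is the reference; it reweights
  # rather than resamples, so agreement is checked at the error level
  skip_if(Sys.which("python") == "", "python not on PATH")
  coh <- learner_fixture(600, seed = 9)
  sp <- split_train_test(coh, 0.75, seed = 9)
  xtr <- encode_features(sp$train); xte <- encode_features(sp$test)
  fit <- fit_adaboost_r2(xtr, sp$train$age, n_estimators = 100, seed = 9)
  mae_native <- mean(abs(predict(fit, xte) - sp$test$age))

  tr_csv <- withr::local_tempfile(fileext = ".csv")
  te_csv <- withr::local_tempfile(fileext = ".csv")
  out_txt <- withr::local_tempfile(fileext = ".txt")
  utils::write.csv(data.frame(y = sp$train$age, xtr), tr_csv, row.names = FALSE)
  utils::write.csv(data.frame(xte), te_csv, row.names = FALSE)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import pandas as pd, numpy as np, sys",
    "from sklearn.ensemble import AdaBoostRegressor",
    "from sklearn.tree import DecisionTreeRegressor",
    sprintf("tr = pd.read_csv('%s'); te = pd.read_csv('%s')", tr_csv, te_csv),
    "base = DecisionTreeRegressor(max_depth=10, max_leaf_nodes=50,",
    "    min_samples_split=2, min_samples_leaf=2)",
    "m = AdaBoostRegressor(estimator=base, n_estimators=100,",
    "    learning_rate=1.0, loss='linear', random_state=9)",
    "m.fit(tr.iloc[:, 1:], tr.y)",
    sprintf("np.savetxt('%s', m.predict(te))", out_txt)
  ), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  skip_if(status != 0, "reference python run failed")
  ref <- scan(out_txt, quiet = TRUE)
  mae_ref <- mean(abs(ref - sp$test$age))
  expect_lt(abs(mae_native - mae_ref), 0.20 * mae_ref)
})

test_that("ensembles serialize to JSON and reload with identical predictions", {
  coh <- learner_fixture(150)
  x <- encode_features(coh); y <- coh$age
  models <- list(
    fit_gbdt(x, y, n_trees = 5),
    fit_forest(x, y, n_trees = 5, seed = 3),
    fit_adaboost_r2(x, y, n_estimators = 5, seed = 3),
    fit_knn(x, y, k = 5)
  )
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    expect_identical(predict(load_model(path), x), predict(m, x))
  }
})
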