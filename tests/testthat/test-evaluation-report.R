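## Brute-force metric oracles, written independently of the implementation.
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}
mae_brute <- function(a, b) sum(abs(a - b)) / length(a)

test_that("pearson matches hand values and a brute-force oracle to 1e-12", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 2, 5)), 0.8660254, tolerance = 1e-6)
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(50, sd = runif(1, 0.1, 40))
    y <- rnorm(50, sd = runif(1, 0.1, 40)) + runif(1, -1, 1) * x
    expect_equal(pearson(x, y), pearson_brute(x, y), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:4, 1:5), "length mismatch")
})

test_that("mae matches hand values and a brute-force oracle to 1e-12", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1.0)
  expect_equal(mae(c(-50, 50), c(-44, 58)), 7.0)
  set.seed(32)
  for (i in 1:25) {
    a <- rnorm(40, sd = 20); b <- rnorm(40, sd = 20)
    expect_equal(mae(a, b), mae_brute(a, b), tolerance = 1e-12)
  }
  expect_error(mae(1:3, 1:4), "length mismatch")
})

test_that("residual_by_angle groups by nominal angle with sample SD", {
  ## perfect predictions
  out <- residual_by_angle(c(1, 2, 3), c(1, 2, 3), c(0, 0, 10))
  expect_equal(out$mean_residual_deg, c(0, 0))
  expect_equal(out$sd_residual_deg, c(0, 0))
  ## two-point group: residuals {1, -1} -> mean 0, sample SD sqrt(2)
  out <- residual_by_angle(c(11, 9), c(10, 10), c(10, 10))
  expect_equal(out$mean_residual_deg, 0)
  expect_equal(out$sd_residual_deg, sqrt(2), tolerance = 1e-12)
  ## singletons flagged with SD 0; counts conserved; angles ascending
  set.seed(33)
  truth <- rnorm(101, sd = 30)
  pred <- truth + rnorm(101, sd = 3)
  nominal <- c(sample(seq(-50, 50, 10), 100, replace = TRUE), 77)
  out <- residual_by_angle(truth, pred, nominal)
  expect_equal(sum(out$n), 101L)
  expect_false(is.unsorted(out$nominal_angle_deg))
  expect_true(out$singleton[out$nominal_angle_deg == 77])
  expect_equal(out$sd_residual_deg[out$nominal_angle_deg == 77], 0)
  ## conservation: weighted mean of group means = overall mean residual
  expect_equal(sum(out$mean_residual_deg * out$n) / sum(out$n),
               mean(truth - pred), tolerance = 1e-12)
})

test_that("feature correlation matrix is symmetric with unit diagonal", {
  run <- default_noisy_run()
  cm <- feature_correlation_matrix(run$features)
  expect_equal(dim(cm), c(8L, 8L))
  expect_equal(diag(cm), setNames(rep(1, 8), c(FEATURE_NAMES, "true_angle_deg")))
  expect_equal(cm, t(cm))
  ## the signed parallelogram feature tracks the angle far better than the
  ## trunk angle does
  expect_gt(abs(cm["norm_elbow_size", "true_angle_deg"]),
            abs(cm["trunk_angle", "true_angle_deg"]))
  ## constant column flagged
  rows <- linear_feature_rows(30L)
  rows$trunk_angle <- 90
  expect_warning(cm2 <- feature_correlation_matrix(rows), "trunk_angle")
  expect_true(all(is.na(cm2["trunk_angle", -which(colnames(cm2) == "trunk_angle")])))
})

test_that("tree importance uses per-tree gain shares and sums to 1", {
  ## single-stump ensemble can only split on the one informative feature
  rows <- linear_feature_rows(n = 80L)
  rows[, setdiff(FEATURE_NAMES, "norm_elbow_size")] <- 0
  m1 <- fit_model(model_spec("gbt", list(n_rounds = 1L, max_depth = 1L),
                             seed = 1L), rows)
  imp1 <- tree_feature_importance(m1)
  expect_equal(unname(imp1["norm_elbow_size"]), 1)
  expect_equal(unname(imp1[setdiff(FEATURE_NAMES, "norm_elbow_size")]),
               rep(0, 6L))

  run <- default_noisy_run()
  for (m in list(run$gbt,
                 fit_model(model_spec("rf", seed = 1L),
                           run$split$train[1:800, ]))) {
    imp <- tree_feature_importance(m)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
  }
  expect_error(tree_feature_importance(run$ols), "tree ensembles only")
})

test_that("per-tree importance shares agree with a direct recomputation", {
  run <- default_noisy_run()
  fo <- run$gbt$forest
  ## independent aggregation: loop over trees, normalize gains within each
  by_tree <- split(data.frame(f = fo$feature, g = fo$gain), fo$tree)
  acc <- setNames(rep(0, 7L), FEATURE_NAMES)
  for (tr in by_tree) {
    tr <- tr[tr$f >= 0L, ]
    if (nrow(tr) == 0L) next
    shares <- tapply(tr$g, FEATURE_NAMES[tr$f + 1L], sum) / sum(tr$g)
    acc[names(shares)] <- acc[names(shares)] + shares
  }
  acc <- acc / length(by_tree)
  expect_equal(tree_feature_importance(run$gbt), acc / sum(acc),
               tolerance = 1e-12)
})

test_that("boosted-tree Shapley attributions satisfy local accuracy and match the booster", {
  run <- default_noisy_run()
  rows <- run$split$test[1:200, ]
  sh <- shap_attributions(run$gbt, rows)
  expect_equal(sh$base_value + rowSums(sh$contributions), sh$prediction,
               tolerance = 1e-6)
  expect_equal(sh$prediction, predict(run$gbt, rows), tolerance = 1e-12)
  ## independent oracle: the booster's own float32 path-attribution
  cb <- predict(run$gbt$fit, as.matrix(rows[, FEATURE_NAMES]),
                type = "contrib")
  expect_equal(unname(sh$contributions), unname(cb[, 1:7]), tolerance = 1e-3)
  expect_equal(sh$base_value, unname(cb[1, 8]), tolerance = 1e-4)
})

test_that("extreme signed-area rows get same-signed attributions", {
  run <- default_noisy_run()
  test <- run$split$test
  hi <- test[which.max(test$norm_elbow_size), ]
  lo <- test[which.min(test$norm_elbow_size), ]
  sh <- shap_attributions(run$gbt, rbind(hi, lo))
  expect_gt(sh$contributions[1, "norm_elbow_size"], 0)
  expect_lt(sh$contributions[2, "norm_elbow_size"], 0)
})

test_that("a constant model attributes nothing and predicts its base value", {
  rows <- linear_feature_rows(30L)
  rows$true_angle_deg <- 5
  m <- suppressWarnings(fit_model(model_spec("gbt", seed = 1L), rows))
  sh <- shap_attributions(m, rows[1:4, ])
  expect_equal(max(abs(sh$contributions)), 0)
  expect_equal(sh$prediction, rep(sh$base_value, 4L), tolerance = 1e-9)
  expect_equal(sh$base_value, 5, tolerance = 1e-6)
})

test_that("the sampling Shapley estimator for forests satisfies local accuracy", {
  tab <- small_table(seed = 19L, frames = 10L)
  ft <- extract_feature_table(tab)
  m <- fit_model(model_spec("rf", seed = 2L), ft)
  sh <- shap_attributions(m, ft[1:3, ], background = ft[1:40, ],
                          n_permutations = 60L)
  expect_equal(sh$base_value + rowSums(sh$contributions), sh$prediction,
               tolerance = 1e-9)
  expect_error(shap_attributions(fit_model(model_spec("ols"), ft), ft[1:2, ]),
               "tree ensembles only")
})

test_that("eval_report assembles the full battery and writes its artifacts", {
  run <- default_noisy_run()
  rep <- eval_report(run$gbt, run$split$test[1:300, ])
  expect_s3_class(rep, "eval_report")
  expect_true(rep$pearson_r > 0 && rep$pearson_r <= 1)
  expect_gte(rep$mae_deg, 0)
  expect_equal(length(rep$residuals), 300L)
  expect_equal(sum(rep$per_angle_summary$n), 300L)
  expect_equal(sum(rep$importance), 1, tolerance = 1e-9)
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  for (f in c("report.json", "residuals_by_angle.csv", "correlations.csv",
              "importance.csv", "shap_summary.csv")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  payload <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(payload$mae_deg, rep$mae_deg, tolerance = 1e-9)
})
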