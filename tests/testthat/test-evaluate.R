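test_that("regression metrics follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5), c(6, 6)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
  # rmse^2 * n recovers the residual sum of squares
  set.seed(40)
  y <- rnorm(17); yh <- rnorm(17)
  expect_equal(rmse(y, yh)^2 * 17, sum((y - yh)^2))
})

test_that("classification metrics come from the confusion counts", {
  labels <- c(rep(1, 5), rep(0, 8))
  preds  <- c(rep(1, 4), 0,  rep(0, 7), 1)   # tp=4 fn=1 tn=7 fp=1
  m <- classification_metrics(labels, preds)
  expect_equal(unname(m$counts), c(4, 7, 1, 1))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.875)
  expect_equal(m$precision, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 11 / 13, tolerance = 1e-12)
  all_right <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  for (nm in c("sensitivity", "specificity", "precision", "f1", "accuracy"))
    expect_equal(all_right[[nm]], 1)
  expect_warning(m0 <- classification_metrics(c(1, 1, 0), c(0, 0, 0)),
                 "precision undefined")
  expect_equal(m0$sensitivity, 0)
  expect_true(is.nan(m0$precision))
  expect_error(classification_metrics(c(1, 0), 1), "equal length")
})

test_that("F1 equals the harmonic mean of precision and sensitivity", {
  set.seed(41)
  for (i in 1:25) {
    l <- rbinom(30, 1, 0.4); p <- rbinom(30, 1, 0.5)
    m <- suppressWarnings(classification_metrics(l, p))
    if (is.nan(m$precision) || is.nan(m$sensitivity) ||
        (m$precision + m$sensitivity) == 0) next
    expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                   (m$precision + m$sensitivity))
  }
})

test_that("rollout chains predictions and reduces to the remission rule", {
  sim <- generate_cohort(sim_config(n_patients = 25,
                                    feature_sizes = tiny_schema(),
                                    missing_rate = 0, seed = 31))
  feats <- sim$features
  # oracle predictor: looks up the true next score -> labels must match
  lookup <- sim$visits
  oracle <- function(ex, feats_) {
    lookup$hamd[lookup$patient_id == ex$patient_id &
                  lookup$visit_index == ex$from_visit + 1L]
  }
  ro <- rollout_remission(oracle, sim$visits, feats)
  expect_identical(ro$label_pred, ro$label)
  truth <- remission_cases(sim$visits)
  expect_identical(ro$label, truth$label)
  # an always-zero predictor labels every patient remitted
  zero <- rollout_remission(function(ex, f) 0, sim$visits, feats)
  expect_true(all(zero$label_pred == 1L))
})

test_that("a two-step hand rollout matches the chained linear predictor", {
  v <- tiny_visits()[tiny_visits()$patient_id == "A", ][1:3, ]
  feats <- tiny_features()
  # linear toy rule: next = 0.8 * current - 0.5 * interval
  f <- function(ex, feats_) 0.8 * ex$hamd_now - 0.5 * ex$interval
  ro <- rollout_remission(f, v, feats)
  h2 <- 0.8 * 20 - 0.5 * 1
  h3 <- 0.8 * h2 - 0.5 * 3
  expect_equal(ro$hamd_final_pred, h3)
  expect_equal(ro$label_pred, as.integer(h3 / 20 <= 0.5))
})

test_that("model evaluation bundles both tasks", {
  sim <- generate_cohort(sim_config(n_patients = 20,
                                    feature_sizes = tiny_schema(),
                                    missing_rate = 0, seed = 32))
  ex <- build_pairs(sim$visits)
  fit <- adrnet(ex, sim$features, sim$vocabulary, d = 3, d_prime = 2,
                epochs = 40, seed = 1)
  # a briefly-trained model may predict no remissions at all, which flags
  # the undefined precision ratio; that path is expected here
  rep_ <- suppressWarnings(
    evaluate_model(fit, ex, sim$features, visits = sim$visits))
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$rmse, rmse(ex$hamd_next, predict(fit, ex, sim$features)))
  expect_equal(rep_$n_cases, 20L)
  expect_true(all(unlist(rep_$classification[c("sensitivity", "specificity",
                                               "accuracy")]) >= 0,
                  na.rm = TRUE))
})

test_that("baseline harness evaluates generic regressors on the shared design", {
  sim <- generate_cohort(sim_config(n_patients = 40,
                                    feature_sizes = tiny_schema(),
                                    missing_rate = 0, seed = 33))
  ex <- build_pairs(sim$visits)
  sp <- split_dataset(ex, 0.25, seed = 2)
  feats <- sim$features
  # mean predictor: out-of-sample R-squared hovers around zero
  suite <- list(mean = list(fit = function(X, y) mean(y),
                            predict = function(fit, X) rep(fit, nrow(X))))
  out <- run_baselines(sp$train, sp$test, feats, sim$vocabulary, suite)
  expect_equal(out$model, "mean")
  expect_lt(abs(out$r_squared), 0.35)
  # ridge on (nearly) linear synthetic data tracks the signal
  skip_if_not_installed("glmnet")
  out2 <- run_baselines(sp$train, sp$test, feats, sim$vocabulary,
                        baseline_suite("ridge"), visits = sim$visits)
  expect_gt(out2$r_squared, 0.5)
  expect_true(out2$accuracy >= 0 && out2$accuracy <= 1)
  # empty suite -> empty report; failing member is recorded, not fatal
  expect_equal(nrow(run_baselines(sp$train, sp$test, feats, sim$vocabulary,
                                  list())), 0L)
  boom <- list(bad = list(fit = function(X, y) stop("nope"),
                          predict = function(fit, X) 0))
  expect_warning(outb <- run_baselines(sp$train, sp$test, feats,
                                       sim$vocabulary, boom), "failed to fit")
  expect_true(is.na(outb$rmse))
})
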