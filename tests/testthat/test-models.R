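# Planted-signal design matrices built directly (no chemistry) so the
# expected behaviour is known exactly.
planted_design <- function(n, p, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p,
              dimnames = list(NULL, paste0("b", seq_len(p))))
  X[, k] <- rep(c(0L, 1L), length.out = n)
  X
}

test_that("regressor recovers a planted single-bit effect", {
  X <- planted_design(200, 64, k = 7, seed = 2)
  set.seed(3)
  y <- 5 + 3 * X[, 7] + rnorm(200, 0, 0.1)
  reg <- train_regressor(X, y, test_regressor_space(seed = 2, n_trials = 3))
  expect_lte(mean(reg$cv_metrics$rmse), 0.3)
  gi <- gain_importance(reg)
  expect_equal(gi$bit[1], 7)
  expect_true(all(diff(gi$gain) <= 1e-12))   # non-increasing
  expect_identical(gi$rank, seq_len(nrow(gi)))
})

test_that("constant targets reduce to the mean fit with empty importance", {
  X <- planted_design(50, 16, k = 3, seed = 4)
  reg <- train_regressor(X, rep(6, 50), test_regressor_space(seed = 4, n_trials = 2))
  expect_true(all(abs(predict(reg, X) - 6) < 1e-3))
  expect_equal(nrow(gain_importance(reg)), 0)
})

test_that("search-space contracts are enforced", {
  expect_error(regressor_search_space(n_estimators = c(10, 100)),
               class = "gpcrscreen_config_error")
  expect_error(regressor_search_space(n_estimators = c(50, 60000)),
               class = "gpcrscreen_config_error")
  expect_error(gain_importance(lm(y ~ x, data.frame(x = 1:5, y = 1:5))),
               class = "gpcrscreen_unsupported_model")
})

test_that("partial dependence recovers the planted effect within 20%", {
  X <- planted_design(1000, 32, k = 5, seed = 6)
  set.seed(7)
  beta <- 3
  y <- 5 + beta * X[, 5] + rnorm(1000, 0, 0.1)
  reg <- train_regressor(X, y, test_regressor_space(seed = 6, n_trials = 3))
  X1 <- X; X1[, 5] <- 1L
  X0 <- X; X0[, 5] <- 0L
  est <- mean(predict(reg, X1) - predict(reg, X0))
  expect_lt(abs(est - beta) / beta, 0.2)
})

test_that("classifier separates a noise-free planted embedding", {
  X <- planted_design(150, 32, k = 1, seed = 8)
  X[, 2] <- rep(c(0L, 0L, 1L), length.out = 150)
  y <- ifelse(X[, 1] == 1, 5L, ifelse(X[, 2] == 1, 3L, 0L))
  cls <- train_classifier(X, y, test_classifier_space(seed = 8, n_trials = 4))
  expect_gte(mean(cls$cv_metrics$accuracy), 0.95)
  # softmax contract and label range
  P <- predict(cls, X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
  expect_true(all((max.col(P) - 1L) %in% 0:5))
  # beats the majority baseline by a clear margin
  expect_gte(mean(cls$cv_metrics$accuracy),
             max(table(y)) / length(y) + 0.2)
})

test_that("degenerate labels and shape mismatches are rejected", {
  X <- planted_design(30, 16, k = 1, seed = 9)
  expect_error(train_classifier(X, rep(2L, 30)),
               class = "gpcrscreen_degenerate_labels")
  y <- rep(c(0L, 4L), 15)
  cls <- train_classifier(X, y, test_classifier_space(seed = 9, n_trials = 2))
  expect_error(predict(cls, X[, 1:8]), class = "gpcrscreen_shape_error")
})

test_that("training is reproducible from the seed", {
  X <- planted_design(60, 16, k = 2, seed = 10)
  set.seed(11); y <- 5 + 2 * X[, 2] + rnorm(60, 0, 0.2)
  r1 <- train_regressor(X, y, test_regressor_space(seed = 10, n_trials = 3))
  r2 <- train_regressor(X, y, test_regressor_space(seed = 10, n_trials = 3))
  expect_identical(r1$best_params, r2$best_params)
  expect_identical(r1$cv_metrics, r2$cv_metrics)
  yc <- ifelse(X[, 2] == 1, 4L, 1L)
  c1 <- train_classifier(X, yc, test_classifier_space(seed = 10, n_trials = 2))
  c2 <- train_classifier(X, yc, test_classifier_space(seed = 10, n_trials = 2))
  expect_identical(c1$best_params, c2$best_params)
  expect_identical(c1$cv_metrics, c2$cv_metrics)
})

test_that("each record sits in exactly one validation fold over the 10-fold CV", {
  folds <- gpcrscreen:::cv_fold_ids(97, 10, seed = 12)
  expect_length(folds, 97)
  expect_setequal(unique(folds), 1:10)
  # each record: 1 validation appearance, 9 training appearances
  val_counts <- vapply(seq_along(folds), function(i)
    sum(vapply(1:10, function(k) folds[i] == k, logical(1))), numeric(1))
  expect_true(all(val_counts == 1))
})

test_that("fragment importance reports decode the planted pharmacophore", {
  lib <- fixture_small_amide_lib()
  reg <- train_regressor(lib$X, lib$activities$pchembl,
                         test_regressor_space(seed = 21, n_trials = 2))
  rep5 <- suppressMessages(
    importance_report(reg, lib$compounds, fp_spec(), top_k = 5))
  expect_identical(rep5$rank, seq_len(nrow(rep5)))
  # the top fragment is an image of the planted pharmacophore: it occurs in
  # every carrier and in no non-carrier
  hits <- count_substructure(lib$compounds$smiles, rep5$fragment_smiles[1])
  expect_true(all(hits[lib$compounds$is_carrier] > 0))
  expect_true(all(hits[!lib$compounds$is_carrier] == 0))
  # and the amide motif itself surfaces among the leading fragments
  expect_true(any(vapply(rep5$fragment_smiles, function(f)
    count_substructure(f, "C(=O)N") > 0, logical(1))))
  rep2 <- suppressMessages(
    importance_report(reg, lib$compounds, fp_spec(), top_k = 2))
  expect_lte(nrow(rep2), 2)
  # no compounds to decode from -> unresolved
  rep0 <- importance_report(reg, lib$compounds[0, ], fp_spec(), top_k = 2)
  expect_true(all(rep0$fragment_smiles == "unresolved"))
})

test_that("profile legs share one fingerprint and reject mismatched specs", {
  lib <- fixture_small_amide_lib()
  scheme <- activity_class_scheme()
  bundles <- train_receptor_models(
    lib$activities, lib$compounds,
    classifier_space = test_classifier_space(seed = 21, n_trials = 2),
    regressor_space = test_regressor_space(seed = 21, n_trials = 2))
  b <- bundles[[1]]
  leg1 <- predict_profile_leg(b, lib$compounds[1, ])
  leg2 <- predict_profile_leg(b, lib$compounds[1, ])
  expect_identical(leg1, leg2)
  expect_equal(sum(leg1$class_probs), 1, tolerance = 1e-6)
  expect_true(leg1$predicted_class %in% 0:5)
  expect_error(predict_profile_leg(b, lib$compounds[1, ],
                                   spec = fp_spec(n_bits = 512)),
               class = "gpcrscreen_config_error")
  # peptide-derived records go through the identical path
  pep <- peptide_record("HAEGTFTSDVSS", "pep")
  legp <- predict_profile_leg(b, pep)
  expect_equal(sum(legp$class_probs), 1, tolerance = 1e-6)
  # broom accessors
  expect_equal(nrow(tidy(b)), 20)
  expect_equal(nrow(glance(b)), 1)
})
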