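# The two machine-learning legs, trained per (receptor, site mode):
# a feed-forward six-class activity classifier and a gradient-boosted
# decision-tree pChEMBL regressor, each tuned by randomized hyperparameter
# search under 10-fold cross-validation, plus gain-based feature importance
# decoded back to chemical fragments.

#' Search space for the multiclass activity classifier
#'
#' Random search draws each trial's architecture from these ranges: depth
#' (number of hidden layers), layer width (powers of two), activation, and
#' Adam learning rate (log-uniform).  The loss is fixed to categorical
#' cross-entropy with a softmax head.
#'
#' @param n_hidden_layers Integer range, default `c(5, 20)`.
#' @param units_per_layer Width range over powers of two, default `c(16, 2048)`.
#' @param activation Candidate activations.
#' @param learning_rate Adam learning-rate range (log-uniform sampling).
#' @param epochs,patience Training budget and early-stopping patience.
#' @param n_trials Number of random-search trials (default 25).
#' @param seed Integer seed controlling sampling, fold assignment and weights.
#' @return `classifier_search_space` object.
#' @export
classifier_search_space <- function(n_hidden_layers = c(5, 20),
                                    units_per_layer = c(16, 2048),
                                    activation = c("relu", "tanh", "sigmoid"),
                                    learning_rate = c(3e-4, 3e-2),
                                    epochs = 200, patience = 20,
                                    n_trials = 25, seed = 1L) {
  stopifnot(length(n_hidden_layers) == 2, n_hidden_layers[1] >= 1,
            diff(n_hidden_layers) >= 0,
            length(units_per_layer) == 2, units_per_layer[1] >= 1,
            all(activation %in% c("relu", "tanh", "sigmoid")),
            learning_rate[1] > 0, n_trials >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units_per_layer = as.integer(units_per_layer),
                 activation = activation, learning_rate = learning_rate,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "classifier_search_space")
}

#' Search space for the gradient-boosted pChEMBL regressor
#'
#' @param n_estimators Tree-count range; must lie within `[50, 50000]`.
#' @param learning_rate Shrinkage range (log-uniform sampling).
#' @param max_depth Tree-depth range.
#' @param subsample,colsample Row/column subsampling ranges.
#' @param n_trials Number of random-search trials (default 25).
#' @param seed Integer seed.
#' @return `regressor_search_space` object.
#' @export
regressor_search_space <- function(n_estimators = c(50, 2000),
                                   learning_rate = c(0.01, 0.3),
                                   max_depth = c(3, 10),
                                   subsample = c(0.6, 1),
                                   colsample = c(0.5, 1),
                                   n_trials = 25, seed = 1L) {
  if (n_estimators[1] < 50 || n_estimators[2] > 50000) {
    abort("`n_estimators` must lie within [50, 50000].",
          class = "gpcrscreen_config_error")
  }
  stopifnot(diff(n_estimators) >= 0, learning_rate[1] > 0, n_trials >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 subsample = subsample, colsample = colsample,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "regressor_search_space")
}

cv_fold_ids <- function(n, n_folds = 10L, seed = 1L) {
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

# Restrict the design matrix to informative (non-constant) columns; the
# selection is stored with the model so prediction sees the same columns.
active_columns <- function(X) {
  cs <- colSums(X)
  which(cs > 0 & cs < nrow(X))
}

#' Train the six-class activity classifier
#'
#' Runs randomized architecture search: each trial is scored by mean accuracy
#' under 10-fold cross-validation and the best architecture is refit on the
#' full input.  Deterministic given the seed in `space`.
#'
#' @param X Binary feature matrix (rows = compounds, columns = fingerprint
#'   bits).
#' @param y Integer class labels in `0..5`.
#' @param space Search space from [classifier_search_space()].
#' @param n_classes Number of classes (default 6).
#' @return A `gpcr_classifier` object with elements `model`, `cv_metrics`
#'   (10-row tibble for the selected trial), `best_params` and `trials`.
#' @export
train_classifier <- function(X, y, space = classifier_search_space(),
                             n_classes = 6L) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 10) abort("Need at least 10 samples.")
  y <- as.integer(y)
  if (any(y < 0 | y >= n_classes)) {
    abort(sprintf("Class labels must lie in 0..%d.", n_classes - 1))
  }
  if (length(unique(y)) < 2) {
    abort("Labels contain a single class; nothing to classify.",
          class = "gpcrscreen_degenerate_labels")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  cols <- active_columns(X)
  if (length(cols) == 0) cols <- 1L  # constant input: fit on a dummy column
  Xa <- X[, cols, drop = FALSE]
  Y <- matrix(0, nrow(X), n_classes)
  Y[cbind(seq_along(y), y + 1L)] <- 1

  set.seed(space$seed)
  pow2 <- 2^(ceiling(log2(space$units_per_layer[1])):
             floor(log2(space$units_per_layer[2])))
  trials <- tibble(
    trial = seq_len(space$n_trials),
    n_layers = sample(seq(space$n_hidden_layers[1], space$n_hidden_layers[2]),
                      space$n_trials, replace = TRUE),
    units = sample(pow2, space$n_trials, replace = TRUE),
    activation = sample(space$activation, space$n_trials, replace = TRUE),
    lr = exp(runif(space$n_trials, log(space$learning_rate[1]),
                   log(space$learning_rate[2])))
  )
  folds <- cv_fold_ids(nrow(X), 10L, space$seed)

  eval_trial <- function(tr) {
    accs <- vapply(seq_len(10L), function(k) {
      tr_idx <- folds != k
      fit <- mlp_train(Xa[tr_idx, , drop = FALSE], Y[tr_idx, , drop = FALSE],
                       hidden = rep(tr$units, tr$n_layers),
                       activation = tr$activation, lr = tr$lr,
                       epochs = space$epochs, patience = space$patience,
                       seed = space$seed + 1000L * tr$trial + k)
      P <- mlp_predict(fit, Xa[!tr_idx, , drop = FALSE])
      mean(max.col(P) - 1L == y[!tr_idx])
    }, numeric(1))
    accs
  }
  cv_all <- map(seq_len(space$n_trials), function(i) eval_trial(trials[i, ]))
  trials$mean_cv_accuracy <- map_dbl(cv_all, mean)
  best_i <- which.max(trials$mean_cv_accuracy)
  best <- trials[best_i, ]

  final <- mlp_train(Xa, Y, hidden = rep(best$units, best$n_layers),
                     activation = best$activation, lr = best$lr,
                     epochs = space$epochs, patience = space$patience,
                     seed = space$seed)
  structure(list(
    model = final,
    feature_columns = cols,
    n_features = ncol(X),
    n_classes = n_classes,
    cv_metrics = tibble(fold = 1:10, accuracy = cv_all[[best_i]]),
    best_params = as.list(best[c("n_layers", "units", "activation", "lr")]),
    trials = trials,
    space = space
  ), class = "gpcr_classifier")
}

#' @export
predict.gpcr_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Feature width %d does not match the %d bits this classifier was trained on.",
                  ncol(X), object$n_features),
          class = "gpcrscreen_shape_error")
  }
  P <- mlp_predict(object$model, X[, object$feature_columns, drop = FALSE])
  colnames(P) <- paste0("class", seq_len(object$n_classes) - 1L)
  P
}

#' @export
print.gpcr_classifier <- function(x, ...) {
  cat(sprintf("gpcr_classifier: %d layers x %d units (%s), mean CV accuracy %.3f\n",
              x$best_params$n_layers, x$best_params$units,
              x$best_params$activation, mean(x$cv_metrics$accuracy)))
  invisible(x)
}

#' Train the gradient-boosted pChEMBL regressor
#'
#' Gradient-boosted decision trees on fingerprint bits, tuned by randomized
#' search under 10-fold cross-validation (selection by mean RMSE) and refit
#' on the full input.  Split-gain importance of the fitted ensemble drives
#' the fragment reports.
#'
#' @param X Binary feature matrix.
#' @param y pChEMBL values.
#' @param space Search space from [regressor_search_space()].
#' @return A `gpcr_regressor` object with `model` (an xgboost booster),
#'   `cv_metrics` (10-row RMSE tibble for the selected trial), `best_params`
#'   and `trials`.
#' @export
train_regressor <- function(X, y, space = regressor_search_space()) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 10) abort("Need at least 10 samples.")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  if (length(active_columns(X)) == 0) {
    warn("Design matrix is constant; the model reduces to the mean and feature importance is undefined.")
  }
  set.seed(space$seed)
  trials <- tibble(
    trial = seq_len(space$n_trials),
    nrounds = round(exp(runif(space$n_trials, log(space$n_estimators[1]),
                              log(space$n_estimators[2])))),
    eta = exp(runif(space$n_trials, log(space$learning_rate[1]),
                    log(space$learning_rate[2]))),
    max_depth = sample(seq(space$max_depth[1], space$max_depth[2]),
                       space$n_trials, replace = TRUE),
    subsample = runif(space$n_trials, space$subsample[1], space$subsample[2]),
    colsample = runif(space$n_trials, space$colsample[1], space$colsample[2])
  )
  folds <- cv_fold_ids(nrow(X), 10L, space$seed)
  fit_one <- function(tr, X1, y1) {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = tr$eta,
                    max_depth = tr$max_depth, subsample = tr$subsample,
                    colsample_bytree = tr$colsample, nthread = 1,
                    seed = space$seed),
      data = xgboost::xgb.DMatrix(X1, label = y1, nthread = 1),
      nrounds = tr$nrounds, verbose = 0
    )
  }
  cv_all <- map(seq_len(space$n_trials), function(i) {
    tr <- trials[i, ]
    vapply(seq_len(10L), function(k) {
      tr_idx <- folds != k
      set.seed(space$seed + 1000L * i + k)
      fit <- fit_one(tr, X[tr_idx, , drop = FALSE], y[tr_idx])
      pred <- predict(fit, xgboost::xgb.DMatrix(X[!tr_idx, , drop = FALSE],
                                                nthread = 1))
      sqrt(mean((pred - y[!tr_idx])^2))
    }, numeric(1))
  })
  trials$mean_cv_rmse <- map_dbl(cv_all, mean)
  best_i <- which.min(trials$mean_cv_rmse)
  best <- trials[best_i, ]
  set.seed(space$seed)
  final <- fit_one(best, X, y)
  structure(list(
    model = final,
    n_features = ncol(X),
    cv_metrics = tibble(fold = 1:10, rmse = cv_all[[best_i]]),
    best_params = as.list(best[c("nrounds", "eta", "max_depth",
                                 "subsample", "colsample")]),
    trials = trials,
    space = space
  ), class = "gpcr_regressor")
}

#' @export
predict.gpcr_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Feature width %d does not match the %d bits this regressor was trained on.",
                  ncol(X), object$n_features),
          class = "gpcrscreen_shape_error")
  }
  as.numeric(predict(object$model, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' @export
print.gpcr_regressor <- function(x, ...) {
  cat(sprintf("gpcr_regressor: %d trees, depth %d, eta %.3f, mean CV RMSE %.3f\n",
              x$best_params$nrounds, x$best_params$max_depth,
              x$best_params$eta, mean(x$cv_metrics$rmse)))
  invisible(x)
}

#' Split-gain feature importance of the regressor
#'
#' Total loss reduction attributed to splits on each fingerprint bit, sorted
#' descending; bits never used in a split are excluded, so the list may be
#' shorter than `top_k`.
#'
#' @param regressor A `gpcr_regressor`.
#' @param top_k Maximum number of bits to return (default all).
#' @return Tibble with `bit` (1-based index), `gain`, `rank`.
#' @export
gain_importance <- function(regressor, top_k = Inf) {
  if (!inherits(regressor, "gpcr_regressor")) {
    abort("Gain importance requires a tree-ensemble regressor.",
          class = "gpcrscreen_unsupported_model")
  }
  imp <- tryCatch(xgboost::xgb.importance(model = regressor$model),
                  error = function(e) NULL)
  if (is.null(imp) || nrow(imp) == 0) {
    return(tibble(bit = integer(), gain = numeric(), rank = integer()))
  }
  out <- tibble(
    bit = as.integer(sub("^b", "", imp$Feature)),
    gain = as.numeric(imp$Gain)
  ) |>
    arrange(desc(.data$gain)) |>
    mutate(rank = row_number())
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Fragment-level importance report
#'
#' Joins the top gain-ranked bits with their chemical fragments, decoded
#' from the first provided compound whose fingerprint sets each bit
#' (attachment points marked `*`).  Bits carried by none of the provided
#' compounds are reported as `"unresolved"`.
#'
#' @param regressor A trained `gpcr_regressor`.
#' @param compounds Compound tibble, normally the training set.
#' @param spec Fingerprint spec used in training.
#' @param top_k Number of bits to report (default 2, the headline fragments).
#' @return Tibble with `bit`, `gain`, `rank`, `fragment_smiles`,
#'   `example_compound`.
#' @export
importance_report <- function(regressor, compounds, spec = fp_spec(),
                              top_k = 2) {
  imp <- gain_importance(regressor, top_k)
  if (nrow(imp) == 0) {
    return(mutate(imp, fragment_smiles = character(), example_compound = character()))
  }
  fps <- if (nrow(compounds) > 0) map(compounds$smiles, ecfp4, spec = spec) else list()
  resolve <- function(bit) {
    for (j in seq_along(fps)) {
      if (bit %in% fps[[j]]$on_bits) {
        frag <- tryCatch(fragment_for_bit(fps[[j]], bit, spec),
                         error = function(e) NA_character_)
        if (!is.na(frag)) {
          return(list(fragment = frag, compound = compounds$compound_id[j]))
        }
      }
    }
    list(fragment = "unresolved", compound = NA_character_)
  }
  res <- map(imp$bit, resolve)
  imp$fragment_smiles <- map_chr(res, "fragment")
  imp$example_compound <- map_chr(res, "compound")
  imp
}

#' Train the two ML legs for every (receptor, site-mode) training set
#'
#' Builds one model bundle per receptor and binding-site mode present in the
#' activity table: fingerprint featurization, six-class labels from the
#' class scheme, classifier and regressor training.  Receptors with fewer
#' than `min_records` curated records are skipped with a warning.
#'
#' @param activities Curated activity tibble.
#' @param compounds Compound tibble supplying SMILES.
#' @param spec Fingerprint spec shared by both legs.
#' @param scheme Activity class scheme.
#' @param classifier_space,regressor_space Search spaces.
#' @param min_records Minimum training-set size per bundle (default 10).
#' @return Named list (`"<receptor>:<site_mode>"`) of `gpcr_model_bundle`
#'   objects.
#' @export
train_receptor_models <- function(activities, compounds,
                                  spec = fp_spec(),
                                  scheme = activity_class_scheme(),
                                  classifier_space = classifier_search_space(),
                                  regressor_space = regressor_search_space(),
                                  min_records = 10L) {
  groups <- activities |>
    distinct(.data$receptor_id, .data$site_mode) |>
    arrange(.data$receptor_id, .data$site_mode)
  bundles <- list()
  for (g in seq_len(nrow(groups))) {
    rid <- groups$receptor_id[g]; sm <- groups$site_mode[g]
    sub <- activities |>
      filter(.data$receptor_id == rid, .data$site_mode == sm)
    cmp <- compounds[match(sub$compound_id, compounds$compound_id), ]
    if (nrow(sub) < min_records) {
      warn(sprintf("Skipping %s:%s - only %d record(s), need %d.",
                   rid, sm, nrow(sub), min_records))
      next
    }
    X <- featurize_set(cmp, spec)
    y_class <- assign_class(sub$pchembl, scheme)
    classifier <- train_classifier(X, y_class, classifier_space,
                                   n_classes = nrow(scheme))
    regressor <- train_regressor(X, sub$pchembl, regressor_space)
    bundle <- structure(list(
      receptor_id = rid, site_mode = sm,
      classifier = classifier, regressor = regressor,
      spec = spec, class_scheme = scheme,
      n_train = nrow(sub), seed = classifier_space$seed
    ), class = "gpcr_model_bundle")
    bundles[[paste(rid, sm, sep = ":")]] <- bundle
  }
  if (length(bundles) == 0) warn("No bundle had enough records to train.")
  bundles
}

#' @export
print.gpcr_model_bundle <- function(x, ...) {
  cat(sprintf("gpcr_model_bundle %s (%s): %d training records\n",
              x$receptor_id, x$site_mode, x$n_train))
  cat(sprintf("  classifier mean CV accuracy %.3f | regressor mean CV RMSE %.3f\n",
              mean(x$classifier$cv_metrics$accuracy),
              mean(x$regressor$cv_metrics$rmse)))
  invisible(x)
}

#' Predict both ML legs for one compound
#'
#' Both legs score the identical fingerprint, so class probabilities and the
#' pChEMBL estimate are directly comparable; peptide-derived and
#' small-molecule records are treated identically.
#'
#' @param bundle A `gpcr_model_bundle`.
#' @param compound One-row compound tibble or SMILES string.
#' @param spec Fingerprint spec; must match the bundle's.
#' @return List with `class_probs` (length-6 named vector summing to 1),
#'   `predicted_class`, `predicted_pchembl`.
#' @export
predict_profile_leg <- function(bundle, compound, spec = bundle$spec) {
  if (!identical(unclass(spec), unclass(bundle$spec))) {
    abort("Fingerprint spec does not match the one this bundle was trained with.",
          class = "gpcrscreen_config_error")
  }
  cmp <- if (is.data.frame(compound)) compound else compound_records(compound)
  X <- featurize_set(cmp[1, , drop = FALSE], spec)
  P <- predict(bundle$classifier, X)
  list(
    class_probs = P[1, ],
    predicted_class = which.max(P[1, ]) - 1L,
    predicted_pchembl = predict(bundle$regressor, X)[1]
  )
}

# --- broom-style accessors -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gpcr_classifier
#' @export
tidy.gpcr_classifier <- function(x, ...) x$cv_metrics

#' @method glance gpcr_classifier
#' @export
glance.gpcr_classifier <- function(x, ...) {
  tibble(mean_cv_accuracy = mean(x$cv_metrics$accuracy),
         sd_cv_accuracy = sd(x$cv_metrics$accuracy),
         n_layers = x$best_params$n_layers,
         units = x$best_params$units,
         activation = x$best_params$activation,
         learning_rate = x$best_params$lr,
         n_trials = nrow(x$trials))
}

#' @method tidy gpcr_regressor
#' @export
tidy.gpcr_regressor <- function(x, ...) x$cv_metrics

#' @method glance gpcr_regressor
#' @export
glance.gpcr_regressor <- function(x, ...) {
  tibble(mean_cv_rmse = mean(x$cv_metrics$rmse),
         sd_cv_rmse = sd(x$cv_metrics$rmse),
         nrounds = x$best_params$nrounds,
         eta = x$best_params$eta,
         max_depth = x$best_params$max_depth,
         n_trials = nrow(x$trials))
}

#' @method tidy gpcr_model_bundle
#' @export
tidy.gpcr_model_bundle <- function(x, ...) {
  bind_rows(
    mutate(x$classifier$cv_metrics, leg = "classifier",
           metric = "accuracy", value = .data$accuracy, accuracy = NULL),
    mutate(x$regressor$cv_metrics, leg = "regressor",
           metric = "rmse", value = .data$rmse, rmse = NULL)
  ) |>
    mutate(receptor_id = x$receptor_id, site_mode = x$site_mode) |>
    select("receptor_id", "site_mode", "leg", "fold", "metric", "value")
}

#' @method glance gpcr_model_bundle
#' @export
glance.gpcr_model_bundle <- function(x, ...) {
  tibble(receptor_id = x$receptor_id, site_mode = x$site_mode,
         n_train = x$n_train,
         classifier_cv_accuracy = mean(x$classifier$cv_metrics$accuracy),
         regressor_cv_rmse = mean(x$regressor$cv_metrics$rmse))
}
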