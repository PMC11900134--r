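# End-to-end orchestration: curate -> featurize -> train -> profile ->
# evaluate, with every seed and setting recorded next to the outputs so a
# run can be reproduced from its directory alone.

#' Assemble a run configuration
#'
#' @param spec Fingerprint spec.
#' @param scheme Activity class scheme.
#' @param classifier_space,regressor_space Search spaces.
#' @param backend Docking backend (`"stub"` or `"vina"`).
#' @param registry Receptor class registry tibble.
#' @param seed Master seed; propagated into both search spaces.
#' @return `run_config` object.
#' @export
run_config <- function(spec = fp_spec(),
                       scheme = activity_class_scheme(),
                       classifier_space = classifier_search_space(),
                       regressor_space = regressor_search_space(),
                       backend = "stub",
                       registry = default_receptor_registry(),
                       seed = 1L) {
  classifier_space$seed <- as.integer(seed)
  regressor_space$seed <- as.integer(seed)
  structure(list(spec = spec, scheme = scheme,
                 classifier_space = classifier_space,
                 regressor_space = regressor_space,
                 backend = backend, registry = registry,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_metadata <- function(config) {
  list(
    seed = config$seed,
    fingerprint = unclass(config$spec),
    class_scheme = as.list(config$scheme),
    classifier_space = unclass(config$classifier_space),
    regressor_space = unclass(config$regressor_space),
    backend = config$backend
  )
}

#' Train all receptor models from raw inputs
#'
#' Curates the activity table, trains one model bundle per (receptor,
#' site-mode) with at least `min_records` curated records (others are
#' skipped with a warning), and computes held-out test metrics on the 20%
#' split.  If `out_dir` is given, bundles, metrics, the curation report and
#' the full configuration (seeds included) are written there.
#'
#' @param compounds Compound tibble.
#' @param activities Raw activity tibble.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param min_records Minimum records per bundle.
#' @return List: `bundles`, `metrics` (per-bundle CV and held-out test
#'   metrics), `curation` report.
#' @export
run_train <- function(compounds, activities, config = run_config(),
                      out_dir = NULL, min_records = 10L) {
  curated <- curate_activities(activities, compounds)
  report <- curation_report(curated)

  groups <- curated |> distinct(.data$receptor_id, .data$site_mode)
  bundles <- list()
  metrics <- list()
  for (g in seq_len(nrow(groups))) {
    rid <- groups$receptor_id[g]; sm <- groups$site_mode[g]
    sub <- curated |> filter(.data$receptor_id == rid, .data$site_mode == sm)
    if (nrow(sub) < min_records) {
      warn(sprintf("Skipping %s:%s - only %d curated record(s).",
                   rid, sm, nrow(sub)))
      next
    }
    split <- split_dataset(nrow(sub), seed = config$seed)
    train <- sub[split$train_indices, ]
    test <- sub[split$test_indices, ]
    b <- train_receptor_models(
      train, compounds, spec = config$spec, scheme = config$scheme,
      classifier_space = config$classifier_space,
      regressor_space = config$regressor_space,
      min_records = min_records)
    if (length(b) == 0) next
    bundle <- b[[1]]
    # held-out 20% metrics
    Xt <- featurize_set(
      compounds[match(test$compound_id, compounds$compound_id), ], config$spec)
    yhat <- predict(bundle$regressor, Xt)
    chat <- max.col(predict(bundle$classifier, Xt)) - 1L
    ytrue <- test$pchembl
    ctrue <- assign_class(ytrue, config$scheme)
    metrics[[paste(rid, sm, sep = ":")]] <- glance(bundle) |>
      mutate(test_rmse = sqrt(mean((yhat - ytrue)^2)),
             test_accuracy = mean(chat == ctrue),
             n_test = nrow(test))
    bundles[[paste(rid, sm, sep = ":")]] <- bundle
  }
  metrics <- bind_rows(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config_metadata(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    if (!is.null(report)) {
      jsonlite::write_json(report, file.path(out_dir, "curation_report.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    saveRDS(bundles, file.path(out_dir, "bundles.rds"))
  }
  list(bundles = bundles, metrics = metrics, curation = report)
}

#' Profile and vote query compounds against trained models
#'
#' For each query compound: fingerprint once, score all (receptor, site)
#' bundles with both ML legs, dock into the configured sites (stub backend
#' by default), and assign per-leg targets plus the k-of-3 consensus.
#' Unparseable queries become per-compound error entries; the run continues.
#'
#' @param bundles Bundle list from [run_train()] / [train_receptor_models()].
#' @param query_compounds Compound tibble.
#' @param config A [run_config()]; its fingerprint spec must match the
#'   bundles'.
#' @param sites Optional list of [binding_site()]s for the docking leg; when
#'   `NULL` with the stub backend, stub sites matching the bundles are used.
#' @param reference_compounds Optional known actives; when given, each query
#'   gains a [compare_to_known()] ranking.
#' @param out_dir Optional output directory (profiles and decisions JSON).
#' @return List: `profiles` (tibble), `decisions` (tibble), `failures`
#'   (tibble of unparseable queries), `comparison` (tibble or NULL).
#' @export
run_predict <- function(bundles, query_compounds, config = run_config(),
                        sites = NULL, reference_compounds = NULL,
                        out_dir = NULL) {
  if (length(bundles) == 0) {
    abort("No bundles.", class = "gpcrscreen_config_error")
  }
  if (!identical(unclass(bundles[[1]]$spec), unclass(config$spec))) {
    abort("Fingerprint spec in config does not match the trained bundles.",
          class = "gpcrscreen_config_error")
  }
  if (is.null(sites) && config$backend == "stub") {
    sites <- map(bundles, function(b)
      binding_site(b$receptor_id, b$site_mode, rbind(c(0, 0, 0))))
  }
  profile_one <- function(cmp) {
    dr <- if (!is.null(sites))
      dock_all(cmp, sites, backend = config$backend) else NULL
    build_profile(cmp, bundles, dr)
  }
  results <- map(seq_len(nrow(query_compounds)), function(i) {
    tryCatch(profile_one(query_compounds[i, ]), error = function(e) e)
  })
  ok <- !map_lgl(results, inherits, "error")
  failures <- tibble(
    compound_id = query_compounds$compound_id[!ok],
    error = map_chr(results[!ok], conditionMessage))
  profiles <- bind_rows(results[ok])
  decisions <- bind_rows(map(results[ok], assign_targets,
                             registry = config$registry))
  comparison <- NULL
  if (!is.null(reference_compounds) && nrow(profiles) > 0) {
    ref_profiles <- map(seq_len(nrow(reference_compounds)), function(i)
      build_profile(reference_compounds[i, ], bundles))
    comparison <- bind_rows(map(results[ok], compare_to_known,
                                reference_profiles = ref_profiles))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config_metadata(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(profiles, file.path(out_dir, "profiles.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    jsonlite::write_json(decisions, file.path(out_dir, "decisions.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  list(profiles = profiles, decisions = decisions, failures = failures,
       comparison = comparison)
}
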