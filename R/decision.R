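# Consensus engine: assemble per-receptor compound profiles from the three
# legs, assign one predicted target per leg, vote (k-of-3), and evaluate
# precision = TP / (TP + FP) with target / target-class stratification.

#' Default receptor-to-class registry
#'
#' Static table mapping each receptor of the screening panel to its GPCR
#' class (A or B): chemokine CC/CXC receptors are class A; the secretin-like
#' peptide receptors are class B.  Extend or replace for custom panels.
#'
#' @return Tibble with `receptor_id`, `gpcr_class`.
#' @export
default_receptor_registry <- function() {
  path <- system.file("extdata", "receptor_classes.csv", package = "gpcrscreen")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Build a compound profile across all trained receptor models
#'
#' One row per (receptor, site-mode) bundle: six class probabilities, the
#' argmax class, the regressor's pChEMBL estimate, and - where provided -
#' the docking score for that site.
#'
#' @param compound One-row compound tibble or SMILES.
#' @param bundles Named list of `gpcr_model_bundle` objects (see
#'   [train_receptor_models()]).
#' @param docking_results Optional docking tibble from [dock_all()].
#' @return A `gpcr_profile` tibble.
#' @export
build_profile <- function(compound, bundles, docking_results = NULL) {
  if (length(bundles) == 0) {
    abort("No model bundles supplied.", class = "gpcrscreen_config_error")
  }
  keys <- map_chr(bundles, ~ paste(.x$receptor_id, .x$site_mode, sep = ":"))
  if (anyDuplicated(keys)) {
    abort("Duplicate bundle for the same (receptor, site mode).",
          class = "gpcrscreen_config_error")
  }
  cmp <- if (is.data.frame(compound)) compound[1, , drop = FALSE]
         else compound_records(compound)
  rows <- map(bundles, function(b) {
    leg <- predict_profile_leg(b, cmp)
    out <- tibble(compound_id = cmp$compound_id,
                  receptor_id = b$receptor_id, site_mode = b$site_mode,
                  predicted_class = leg$predicted_class,
                  predicted_pchembl = leg$predicted_pchembl,
                  docking_score = NA_real_)
    probs <- as_tibble(as.list(leg$class_probs))
    bind_cols(out, probs)
  })
  prof <- bind_rows(rows)
  if (!is.null(docking_results)) {
    prof <- prof |>
      rows_update(
        docking_results |>
          transmute(.data$receptor_id, .data$site_mode,
                    docking_score = .data$best_score),
        by = c("receptor_id", "site_mode"), unmatched = "ignore")
  }
  class(prof) <- c("gpcr_profile", class(prof))
  prof
}

# Collapse a profile to one representative row per receptor: the more
# active of its orthosteric/allosteric entries per leg.
collapse_sites <- function(profile) {
  prob_cols <- grep("^class[0-9]+$", names(profile), value = TRUE)
  act_cols <- setdiff(prob_cols, "class0")
  profile |>
    mutate(active_mass = rowSums(across(all_of(act_cols)))) |>
    group_by(.data$receptor_id) |>
    summarise(
      predicted_class = max(.data$predicted_class),
      active_mass = max(.data$active_mass),
      predicted_pchembl = max(.data$predicted_pchembl),
      docking_score = if (all(is.na(.data$docking_score))) NA_real_
                      else min(.data$docking_score, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Assign per-leg targets and the k-of-3 consensus
#'
#' Each leg names one receptor: the classifier leg the receptor with the
#' highest predicted activity class (ties broken by the probability mass
#' above the inactive class, then lexicographically), the regressor leg the
#' receptor with the highest predicted pChEMBL, the docking leg the receptor
#' with the lowest (best) score.  A receptor with both site modes is
#' represented by its more active entry.  `agreement_k` is the size of the
#' largest set of legs naming the same receptor; the consensus target is
#' that receptor when `agreement_k >= 2`, otherwise none (`NA`).
#'
#' @param profile A [build_profile()] tibble.
#' @param registry Receptor class registry tibble.
#' @return One-row tibble: per-leg targets and classes, `consensus_target`,
#'   `agreement_k`.
#' @export
assign_targets <- function(profile, registry = default_receptor_registry()) {
  stopifnot(nrow(profile) > 0)
  rec <- collapse_sites(profile) |> arrange(.data$receptor_id)
  cls_target <- rec |>
    arrange(desc(.data$predicted_class), desc(.data$active_mass),
            .data$receptor_id) |>
    slice(1) |> pull("receptor_id")
  reg_target <- rec |>
    arrange(desc(.data$predicted_pchembl), .data$receptor_id) |>
    slice(1) |> pull("receptor_id")
  dock_target <- if (all(is.na(rec$docking_score))) NA_character_ else
    rec |>
      filter(!is.na(.data$docking_score)) |>
      arrange(.data$docking_score, .data$receptor_id) |>
      slice(1) |> pull("receptor_id")
  legs <- c(classifier = cls_target, regressor = reg_target,
            docking = dock_target)
  votes <- table(legs[!is.na(legs)])
  k <- max(votes)
  top <- sort(names(votes)[votes == k])
  consensus <- if (k >= 2) top[1] else NA_character_
  cls_of <- function(r) {
    if (is.na(r)) return(NA_character_)
    hit <- registry$gpcr_class[registry$receptor_id == r]
    if (length(hit)) hit[1] else NA_character_
  }
  tibble(
    compound_id = profile$compound_id[1],
    classifier_target = cls_target,
    regressor_target = reg_target,
    docking_target = dock_target,
    classifier_class = cls_of(cls_target),
    regressor_class = cls_of(reg_target),
    docking_class = cls_of(dock_target),
    consensus_target = consensus,
    agreement_k = as.integer(k)
  )
}

#' Evaluate target and target-class precision
#'
#' Scores a set of consensus decisions against the known truth under the
#' voting rules: `all3` (every leg must name the truth), `atleast2`,
#' `atleast1`, and the three per-leg rules.  Precision is
#' TP / (TP + FP) where a true positive is a compound whose target (or
#' target class) was assigned correctly under the rule; it is `NaN` when no
#' call was made.  Results are stratified by the truth's binding-site mode
#' when a `site_mode` column is present.
#'
#' @param decisions Tibble of [assign_targets()] rows.
#' @param truth Tibble with `compound_id`, `true_target`, `true_class`, and
#'   optionally `site_mode`.  Non-selective compounds may have several truth
#'   rows; a leg is then correct if it names any of the acceptable targets.
#' @param rules Character vector of rules to score.
#' @return Tibble with one row per (rule, measure, stratum): `tp`, `fp`,
#'   `precision`.
#' @export
evaluate_decisions <- function(decisions, truth,
                               rules = c("all3", "atleast2", "atleast1",
                                         "classifier", "regressor", "docking")) {
  stopifnot(nrow(decisions) > 0)
  if (!all(decisions$compound_id %in% truth$compound_id)) {
    abort("Every decision needs a truth row.", class = "gpcrscreen_truth_error")
  }
  if (!"true_class" %in% names(truth)) truth$true_class <- NA_character_
  if (!"site_mode" %in% names(truth)) truth$site_mode <- "all"
  tset <- truth |>
    group_by(.data$compound_id) |>
    summarise(targets = list(unique(.data$true_target)),
              classes = list(unique(.data$true_class)),
              site_mode = first(.data$site_mode), .groups = "drop")
  d <- left_join(decisions, tset, by = "compound_id")
  leg_cols <- c("classifier_target", "regressor_target", "docking_target")
  cls_cols <- c("classifier_class", "regressor_class", "docking_class")

  n_correct <- function(cols, setcol) {
    hits <- map(cols, function(cl)
      map2_lgl(d[[cl]], d[[setcol]], function(x, ok) !is.na(x) && x %in% ok))
    Reduce(`+`, hits)
  }
  target_hits <- n_correct(leg_cols, "targets")
  class_hits <- n_correct(cls_cols, "classes")

  score_rule <- function(rule, hits, cols, setcol) {
    correct <- switch(rule,
      all3 = hits == 3,
      atleast2 = hits >= 2,
      atleast1 = hits >= 1,
      classifier = ,
      regressor = ,
      docking = {
        cl <- grep(paste0("^", rule), cols, value = TRUE)
        map2_lgl(d[[cl]], d[[setcol]], function(x, ok) !is.na(x) && x %in% ok)
      })
    tibble(site_mode = d$site_mode, correct = correct) |>
      group_by(.data$site_mode) |>
      summarise(tp = sum(.data$correct), fp = sum(!.data$correct),
                .groups = "drop") |>
      mutate(rule = rule,
             precision = ifelse(.data$tp + .data$fp > 0,
                                .data$tp / (.data$tp + .data$fp), NaN))
  }
  out <- bind_rows(
    map(rules, function(r) mutate(
      score_rule(r, target_hits, leg_cols, "targets"), measure = "target")),
    map(rules, function(r) mutate(
      score_rule(r, class_hits, cls_cols, "classes"), measure = "target_class"))
  )
  select(out, "rule", "measure", "site_mode", "tp", "fp", "precision")
}

#' Rank a query compound against known active ligands
#'
#' For every receptor in the query profile, the query's predicted pChEMBL is
#' placed within the distribution of reference (known-active) predictions:
#' percentile and z-score.  Receptors with no reference predictions are
#' omitted with a warning.
#'
#' @param profile Query [build_profile()] tibble.
#' @param reference_profiles Profile tibble(s) of known actives,
#'   precomputed with the same bundles.
#' @return Tibble with `receptor_id`, `site_mode`, `predicted_pchembl`,
#'   `predicted_class`, `n_reference`, `percentile`, `z_score`.
#' @export
compare_to_known <- function(profile, reference_profiles) {
  refs <- bind_rows(reference_profiles)
  if (nrow(refs) == 0) {
    warn("No reference profiles; returning an empty comparison.")
    return(tibble(receptor_id = character(), site_mode = character(),
                  predicted_pchembl = numeric(), predicted_class = integer(),
                  n_reference = integer(), percentile = numeric(),
                  z_score = numeric()))
  }
  out <- profile |>
    select("receptor_id", "site_mode", "predicted_pchembl", "predicted_class") |>
    pmap(function(receptor_id, site_mode, predicted_pchembl, predicted_class) {
      r <- refs |>
        filter(.data$receptor_id == !!receptor_id,
               .data$site_mode == !!site_mode)
      if (nrow(r) == 0) return(NULL)
      tibble(receptor_id, site_mode, predicted_pchembl, predicted_class,
             n_reference = nrow(r),
             percentile = 100 * mean(r$predicted_pchembl <= predicted_pchembl),
             z_score = if (nrow(r) > 1 && sd(r$predicted_pchembl) > 0)
               (predicted_pchembl - mean(r$predicted_pchembl)) / sd(r$predicted_pchembl)
             else NA_real_)
    })
  dropped <- sum(map_lgl(out, is.null))
  if (dropped > 0) {
    warn(sprintf("%d receptor-site entr(ies) had no reference predictions and were omitted.",
                 dropped))
  }
  bind_rows(out)
}
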