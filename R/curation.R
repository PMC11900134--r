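# Dataset curation: the three admission rules (functional assay, parseable
# SMILES, chemical uniqueness), pChEMBL conversion, six-class binning, and
# the 80/20 split with 10-fold cross-validation partitions.

#' Convert a potency to pChEMBL
#'
#' pChEMBL is \eqn{-\log_{10}} of the molar potency (IC50/EC50/Ki and
#' relatives), clipped below at 0 so that 0 marks the inactive boundary.
#'
#' @param value Positive potency value(s).
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return pChEMBL value(s).
#' @examples
#' pchembl_from_potency(10, "nM")   # 8
#' pchembl_from_potency(1, "uM")    # 6
#' @export
pchembl_from_potency <- function(value, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  if (any(!is.finite(value) | value <= 0)) {
    abort("Potency values must be positive.", class = "gpcrscreen_invalid_potency")
  }
  factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  pmax(0, -log10(value * factor))
}

#' Six-bin activity class scheme
#'
#' Class 0 holds exactly pChEMBL = 0 (the negative data points); the active
#' range is covered by lower-exclusive/upper-inclusive bins.  The default
#' scheme is \{0\}, (0,5], (5,6], (6,7], (7,8], (8,Inf): unit bins across the
#' pharmacologically standard 5-8 potency range.
#'
#' @param breaks Increasing interior break points between class 1 and the top
#'   class; `length(breaks) + 2` classes result.
#' @return A tibble with columns `label`, `lower` (exclusive), `upper`
#'   (inclusive).
#' @export
activity_class_scheme <- function(breaks = c(5, 6, 7, 8)) {
  stopifnot(all(diff(breaks) > 0), all(breaks > 0))
  lower <- c(-Inf, 0, breaks)
  upper <- c(0, breaks, Inf)
  tibble(label = seq_along(lower) - 1L, lower = lower, upper = upper)
}

#' Assign pChEMBL values to activity classes
#'
#' Every value in \eqn{[0, \infty)} maps to exactly one class; 0 maps to the
#' negative class 0.
#'
#' @param pchembl Non-negative value(s).
#' @param scheme Class scheme from [activity_class_scheme()].
#' @return Integer class labels.
#' @examples
#' assign_class(c(0, 8, 8.0001))  # 0, 4, 5
#' @export
assign_class <- function(pchembl, scheme = activity_class_scheme()) {
  if (any(pchembl < 0, na.rm = TRUE)) {
    abort("pChEMBL values must be non-negative.")
  }
  labs <- rep(NA_integer_, length(pchembl))
  for (k in seq_len(nrow(scheme))) {
    hit <- pchembl > scheme$lower[k] & pchembl <= scheme$upper[k]
    labs[hit] <- scheme$label[k]
  }
  if (anyNA(labs[!is.na(pchembl)])) {
    abort("Class scheme does not cover all values.",
          class = "gpcrscreen_scheme_gap")
  }
  labs
}

#' Curate an activity table
#'
#' Applies the three admission rules in order: assay-type compatibility
#' (only functional assays, `assay_type == "F"`), SMILES correctness (the
#' compound must parse to a molecule), and uniqueness (first occurrence of
#' each (canonical SMILES, receptor, site-mode) triple wins; later
#' duplicates with a conflicting pChEMBL are logged).  Idempotent.
#'
#' @param activities Activity tibble (see [activity_records()]).
#' @param compounds Compound tibble providing the SMILES for each
#'   `compound_id`.
#' @return The curated activity tibble, with the per-rule removal counts in
#'   `attr(, "curation_report")` (also retrievable with [curation_report()]).
#' @export
curate_activities <- function(activities, compounds) {
  n0 <- nrow(activities)
  act <- activities
  # rule 1: functional assays only
  keep <- act$assay_type == "F"
  n_assay <- sum(!keep)
  act <- act[keep, , drop = FALSE]
  # rule 2: SMILES correctness
  smi <- compounds$smiles[match(act$compound_id, compounds$compound_id)]
  can <- ob_convert_smiles(smi, "CAN")
  keep <- !is.na(can)
  n_smiles <- sum(!keep)
  act <- act[keep, , drop = FALSE]
  can <- can[keep]
  # rule 3: uniqueness on (canonical SMILES, receptor, site mode)
  key <- paste(can, act$receptor_id, act$site_mode, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    first_p <- act$pchembl[match(key[dup], key)]
    conflict <- abs(first_p - act$pchembl[dup]) > 1e-9
    if (any(conflict)) {
      inform(sprintf("%d duplicate record(s) had conflicting pChEMBL; first occurrence kept.",
                     sum(conflict)))
    }
  }
  act <- act[!dup, , drop = FALSE]
  report <- tibble(
    rule = c("assay", "smiles", "duplicate"),
    removed = c(n_assay, n_smiles, n_dup)
  )
  if (nrow(act) == 0) warn("Curation removed every record.")
  inform(sprintf("Curation: %d -> %d records (assay %d, smiles %d, duplicate %d).",
                 n0, nrow(act), n_assay, n_smiles, n_dup))
  attr(act, "curation_report") <- report
  act
}

#' @rdname curate_activities
#' @param curated A tibble returned by [curate_activities()].
#' @export
curation_report <- function(curated) {
  attr(curated, "curation_report")
}

#' Random 80/20 split with 10-fold CV partitions
#'
#' Records are split at the record level: `floor(0.8 n)` go to training, the
#' rest to the held-out test set, and the training indices are partitioned
#' into `n_folds` cross-validation folds whose sizes differ by at most one.
#' Fully reproducible from `seed`.
#'
#' @param n Number of records, or a data frame whose rows are split.
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.8).
#' @param n_folds Number of CV folds (default 10).
#' @return An object of class `dataset_split` with `train_indices`,
#'   `test_indices`, `folds` (list of disjoint index vectors over the
#'   training set) and `seed`.
#' @export
split_dataset <- function(n, seed = 1L, train_frac = 0.8, n_folds = 10L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < n_folds) {
    abort(sprintf("Need at least %d records to build %d folds.", n_folds, n_folds),
          class = "gpcrscreen_too_few_records")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- floor(train_frac * n)
  train <- sort(perm[seq_len(n_train)])
  test <- sort(perm[-seq_len(n_train)])
  fold_id <- rep(seq_len(n_folds), length.out = n_train)
  fold_id <- sample(fold_id)
  folds <- split(train, fold_id)
  names(folds) <- paste0("fold", seq_len(n_folds))
  structure(list(train_indices = train, test_indices = test,
                 folds = folds, seed = as.integer(seed),
                 n = n, train_frac = train_frac),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d test (seed %d), %d CV folds\n",
              length(x$train_indices), length(x$test_indices),
              x$seed, length(x$folds)))
  invisible(x)
}

# Save/restore the RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
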