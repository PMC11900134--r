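# Planted structure-activity generator.  Every pipeline stage is exercised
# on libraries built here: carrier molecules are random drug-like scaffolds
# with a receptor-specific pharmacophore grafted on, non-carriers lack it,
# and pChEMBL follows baseline + effect * carrier + Gaussian noise (clipped
# at 0).  Nothing here attempts to mimic real ChEMBL chemistry; the point is
# a controlled signal whose recovery can be asserted exactly.

# Twenty small drug-like cores, each written so that appending further
# SMILES tokens extends the molecule from a free valence.
SCAFFOLD_CORES <- c(
  "CCCC", "CC(C)C", "CCCCC", "CCOCC", "CCNCC",
  "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "C1CCNC1",
  "c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccc2ccccc2c1", "c1ccoc1",
  "c1ccsc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccc(cc1)C", "C1COCCN1"
)
DECOY_TAILS <- c("C", "CC", "CCO", "CO", "C(C)O", "CCN", "C#N", "C=C", "CCl",
                 "COC", "CF", "CCC")
SCAFFOLD_PREFIXES <- c("", "C", "CC", "CCC", "CCCC")
SPACERS <- c("", "C", "CC", "CCC", "C(C)", "CO", "COC")

#' Planted structure-activity specification
#'
#' @param receptor_id Receptor the signal belongs to.
#' @param site_mode Binding-site mode of the generated records.
#' @param pharmacophore SMILES/SMARTS of the activity-defining substructure;
#'   must itself be a valid appendable SMILES fragment.
#' @param effect_size pChEMBL lift for carriers (> 0, default 3).
#' @param baseline Baseline pChEMBL (default 5).
#' @param noise_sd Gaussian noise SD (default 0.1).
#' @param n_actives,n_inactives Carrier / non-carrier counts.
#' @param seed Integer seed.
#' @return `planted_sar` object.
#' @export
planted_sar <- function(receptor_id, site_mode = "orthosteric",
                        pharmacophore = "CC(=O)NO",
                        effect_size = 3, baseline = 5, noise_sd = 0.1,
                        n_actives = 100, n_inactives = 100, seed = 1L) {
  stopifnot(effect_size > 0, noise_sd >= 0, n_actives >= 0, n_inactives >= 0)
  if (is.na(ob_convert_smiles(pharmacophore, "CAN"))) {
    abort(sprintf("Invalid pharmacophore SMILES: %s", pharmacophore),
          class = "gpcrscreen_invalid_smiles")
  }
  structure(list(receptor_id = receptor_id, site_mode = site_mode,
                 pharmacophore = pharmacophore, effect_size = effect_size,
                 baseline = baseline, noise_sd = noise_sd,
                 n_actives = n_actives, n_inactives = n_inactives,
                 seed = as.integer(seed)),
            class = "planted_sar")
}

# Enumerate unique decorated molecules; carriers end with the pharmacophore.
build_molecules <- function(n, carrier, pharmacophore, rng_offset = 0L,
                            seed = 1L) {
  set.seed(seed + rng_offset)
  out <- character(0)
  guard <- 0
  while (length(out) < n && guard < 50) {
    guard <- guard + 1
    cand <- vapply(seq_len(2 * n), function(i) {
      prefix <- sample(SCAFFOLD_PREFIXES, 1)
      core <- sample(SCAFFOLD_CORES, 1)
      spacer <- sample(SPACERS, 1)
      extra <- if (runif(1) < 0.5) sample(SPACERS, 1) else ""
      tail <- if (carrier) pharmacophore else sample(DECOY_TAILS, 1)
      paste0(prefix, core, spacer, extra, tail)
    }, character(1))
    can <- ob_convert_smiles(cand, "CAN")
    out <- unique(c(out, can[!is.na(can)]))
  }
  if (length(out) < n) {
    abort("Could not generate enough unique molecules; widen the scaffold space.")
  }
  out[seq_len(n)]
}

#' Generate a planted single-receptor library
#'
#' Carriers are scaffold molecules with the pharmacophore grafted on;
#' non-carriers draw decoy tails instead.  pChEMBL is
#' `baseline + effect_size * carrier + N(0, noise_sd)`, clipped at 0, and
#' every record is a functional-assay (`"F"`) measurement.  Deterministic
#' given the seed.  Carrier status is re-checked against the substructure
#' oracle; molecules violating the planted design are dropped.
#'
#' @param sar A [planted_sar()].
#' @param id_prefix Prefix for compound ids.
#' @return List with `compounds` (compound tibble plus `is_carrier`) and
#'   `activities` (activity tibble).
#' @export
generate_library <- function(sar, id_prefix = sar$receptor_id) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  act_smi <- build_molecules(sar$n_actives, TRUE, sar$pharmacophore,
                             rng_offset = 0L, seed = sar$seed)
  inact_smi <- build_molecules(sar$n_inactives, FALSE, sar$pharmacophore,
                               rng_offset = 7919L, seed = sar$seed)
  smi <- c(act_smi, inact_smi)
  carrier <- rep(c(TRUE, FALSE), c(length(act_smi), length(inact_smi)))
  # oracle check: the planted substructure must separate the two groups
  hits <- count_substructure(smi, sar$pharmacophore)
  keep <- (carrier & hits > 0) | (!carrier & hits == 0)
  smi <- smi[keep]; carrier <- carrier[keep]
  compounds <- compound_records(
    smi, compound_id = paste0(id_prefix, "_", seq_along(smi)))
  compounds$is_carrier <- carrier
  set.seed(sar$seed + 104729L)
  pchembl <- pmax(0, sar$baseline + sar$effect_size * carrier +
                    rnorm(length(smi), 0, sar$noise_sd))
  activities <- activity_records(
    compound_id = compounds$compound_id,
    receptor_id = sar$receptor_id,
    site_mode = sar$site_mode,
    assay_type = "F",
    pchembl = pmin(pchembl, 14)
  )
  list(compounds = compounds, activities = activities)
}

#' Generate random peptide sequences
#'
#' Uniform sequences over the 20-letter alphabet, with lengths drawn
#' uniformly from `length_range` - including lengths straddling the
#' 6-residue truncation boundary up to roughly 30-mers.
#'
#' @param n Number of sequences.
#' @param length_range Integer range of sequence lengths, default `c(4, 30)`.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
generate_peptide_library <- function(n, length_range = c(4, 30), seed = 1L) {
  stopifnot(length_range[1] >= 1, n >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a multi-receptor benchmark with selective and dual ligands
#'
#' Each receptor gets a library of selective carriers; `n_dual` additional
#' compounds carry two pharmacophores at once (non-selective ligands) and
#' appear with high activity for both receptors.  The truth table lists the
#' true target(s), target class (from the registry) and site mode per
#' compound.  Pharmacophores must not be substructures of one another.
#'
#' @param sars List of [planted_sar()] objects with distinct pharmacophores.
#' @param n_dual Number of dual-pharmacophore compounds (default 10).
#' @param registry Receptor class registry.
#' @return List: `compounds`, `activities`, `truth` (one row per
#'   compound-target pair), `registry`.
#' @export
generate_multireceptor_benchmark <- function(sars, n_dual = 10,
                                             registry = default_receptor_registry()) {
  stopifnot(length(sars) >= 2)
  phs <- map_chr(sars, "pharmacophore")
  for (i in seq_along(phs)) for (j in seq_along(phs)) {
    if (i != j && count_substructure(phs[i], phs[j]) > 0) {
      abort(sprintf("Pharmacophores overlap: '%s' contains '%s'.", phs[i], phs[j]),
            class = "gpcrscreen_config_error")
    }
  }
  libs <- map(sars, generate_library)
  compounds <- bind_rows(map(libs, "compounds"))
  activities <- bind_rows(map(libs, "activities"))

  # cross-receptor negatives: selective carriers of receptor i are
  # non-carriers (baseline activity) for receptor j
  base_seed <- sars[[1]]$seed
  set.seed(base_seed + 15485863L)
  cross <- list()
  for (j in seq_along(sars)) {
    other <- compounds |>
      filter(!startsWith(.data$compound_id, paste0(sars[[j]]$receptor_id, "_")))
    cross[[j]] <- activity_records(
      compound_id = other$compound_id,
      receptor_id = sars[[j]]$receptor_id,
      site_mode = sars[[j]]$site_mode,
      assay_type = "F",
      pchembl = pmin(14, pmax(0, sars[[j]]$baseline +
                                rnorm(nrow(other), 0, sars[[j]]$noise_sd)))
    )
  }
  activities <- bind_rows(activities, bind_rows(cross))

  truth <- compounds |>
    mutate(true_target = sub("_[0-9]+$", "", .data$compound_id)) |>
    select("compound_id", "true_target")

  if (n_dual > 0) {
    du <- build_molecules(n_dual, TRUE, paste0(phs[1], phs[2]),
                          rng_offset = 32452843L, seed = base_seed)
    ok <- count_substructure(du, phs[1]) > 0 & count_substructure(du, phs[2]) > 0
    du <- du[ok]
    dual_cmp <- compound_records(du, compound_id = paste0("DUAL_", seq_along(du)))
    dual_cmp$is_carrier <- TRUE
    set.seed(base_seed + 49979687L)
    dual_act <- map(sars[1:2], function(s) activity_records(
      compound_id = dual_cmp$compound_id, receptor_id = s$receptor_id,
      site_mode = s$site_mode, assay_type = "F",
      pchembl = pmin(14, pmax(0, s$baseline + s$effect_size +
                                rnorm(nrow(dual_cmp), 0, s$noise_sd)))))
    compounds <- bind_rows(compounds, dual_cmp)
    activities <- bind_rows(activities, bind_rows(dual_act))
    truth <- bind_rows(truth, bind_rows(map(sars[1:2], function(s)
      tibble(compound_id = dual_cmp$compound_id, true_target = s$receptor_id))))
  }
  site_of <- setNames(map_chr(sars, "site_mode"), map_chr(sars, "receptor_id"))
  truth <- truth |>
    left_join(registry, by = c(true_target = "receptor_id")) |>
    rename(true_class = "gpcr_class") |>
    mutate(site_mode = unname(site_of[.data$true_target]))
  list(compounds = compounds, activities = activities, truth = truth,
       registry = registry)
}
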