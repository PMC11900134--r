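#' Canonicalize SMILES strings
#'
#' Converts SMILES to the OpenBabel canonical form, keeping stereochemistry.
#' Canonicalization is the package-wide identity: two spellings of the same
#' molecule map to the same string, and every stored compound record holds
#' the canonical form.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), any unparseable SMILES raises an error
#'   naming the offending strings; if `FALSE`, they yield `NA`.
#' @return Character vector of canonical SMILES, aligned with the input.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))   # identical output
#' canonicalize_smiles("C1=CC=CC=C1") == canonicalize_smiles("c1ccccc1")
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  out <- ob_convert_smiles(smiles, "CAN")
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    abort(c("Unparseable SMILES:", setNames(bad, rep("x", length(bad)))),
          class = "gpcrscreen_invalid_smiles")
  }
  out
}

#' Build a compound record table
#'
#' The compound table is the package's central ligand container: one row per
#' compound, with canonical SMILES.  Rows whose SMILES contain disconnected
#' fragments (a `.` in the SMILES) are kept verbatim and flagged in
#' `has_mixture`; no salt stripping is attempted.
#'
#' @param smiles Character vector of SMILES (canonicalized on entry).
#' @param compound_id Optional character ids; defaults to `CPD1`, `CPD2`, ...
#' @param is_peptide_derived Logical flag per row.
#' @param source_sequence One-letter residue string for peptide-derived rows
#'   (`NA` otherwise).  Must be present exactly when `is_peptide_derived`.
#' @return A tibble with columns `compound_id`, `smiles`,
#'   `is_peptide_derived`, `source_sequence`, `has_mixture`.
#' @export
compound_records <- function(smiles,
                             compound_id = NULL,
                             is_peptide_derived = FALSE,
                             source_sequence = NA_character_) {
  n <- length(smiles)
  compound_id <- compound_id %||% paste0("CPD", seq_len(n))
  res <- tibble(
    compound_id = as.character(compound_id),
    smiles = canonicalize_smiles(smiles),
    is_peptide_derived = rep_len(is_peptide_derived, n),
    source_sequence = rep_len(as.character(source_sequence), n)
  )
  bad <- xor(res$is_peptide_derived, !is.na(res$source_sequence))
  if (any(bad)) {
    abort("`source_sequence` must be set exactly for peptide-derived records.")
  }
  res$has_mixture <- grepl(".", res$smiles, fixed = TRUE)
  if (any(res$has_mixture)) {
    inform(sprintf("%d record(s) contain disconnected fragments ('.'); kept and flagged.",
                   sum(res$has_mixture)))
  }
  res
}

#' Read compound records from SMI, CSV or SDF files
#'
#' Unparseable entries are skipped with a message giving their line or record
#' number; the skipped entries are attached as the `"skipped"` attribute.
#' A `sequence` column in CSV input routes those rows through the peptide
#' builder ([peptide_record()]): the sequence is truncated to its 6-residue
#' activation fragment and converted to SMILES.
#'
#' @param path File path.
#' @param format `"smi"` (whitespace-separated SMILES + id), `"csv"` (named
#'   columns `smiles` and/or `sequence`, optional `compound_id`), `"sdf"`
#'   (V2000), or `"auto"` to infer from the extension.
#' @return Compound record tibble (see [compound_records()]).
#' @export
read_compounds <- function(path, format = c("auto", "smi", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gpcrscreen_io_error")
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smi", csv = "csv", sdf = "sdf",
                     abort(sprintf("Cannot infer format from '%s'.", path)))
  }
  raw <- switch(format,
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      toks <- strsplit(trimws(lines), "\\s+")
      tibble(
        smiles = map_chr(toks, 1),
        compound_id = map_chr(toks, ~ if (length(.x) > 1)
          paste(.x[-1], collapse = " ") else NA_character_),
        sequence = NA_character_
      )
    },
    csv = {
      df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      if (!any(c("smiles", "sequence") %in% names(df))) {
        abort("CSV must contain a `smiles` and/or `sequence` column.")
      }
      tibble(
        smiles = if ("smiles" %in% names(df)) as.character(df$smiles) else NA_character_,
        compound_id = if ("compound_id" %in% names(df))
          as.character(df$compound_id) else NA_character_,
        sequence = if ("sequence" %in% names(df))
          as.character(df$sequence) else NA_character_
      )
    },
    sdf = {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
      smis <- ob_convert_smiles_from_sdf(path)
      ids <- map_chr(ChemmineR::SDFset2SDF(sdfset), function(s) {
        nm <- ChemmineR::header(s)[["Molecule_Name"]]
        if (is.null(nm) || !nzchar(nm)) NA_character_ else nm
      })
      n <- max(length(smis), length(ids))
      tibble(smiles = smis[seq_len(n)], compound_id = ids[seq_len(n)],
             sequence = NA_character_)
    }
  )
  if (nrow(raw) == 0) {
    abort("No records in input.", class = "gpcrscreen_empty_input")
  }

  is_pep <- !is.na(raw$sequence) & nzchar(raw$sequence)
  can <- rep(NA_character_, nrow(raw))
  idx_smi <- which(!is_pep & !is.na(raw$smiles))
  can[idx_smi] <- ob_convert_smiles(raw$smiles[idx_smi], "CAN")
  pep_smi <- map_chr(raw$sequence[is_pep], function(s)
    tryCatch(peptide_to_smiles(truncate_peptide(s)), error = function(e) NA_character_))
  can[is_pep] <- pep_smi

  ok <- !is.na(can)
  if (!any(ok)) {
    abort("No parseable records in input.", class = "gpcrscreen_empty_input")
  }
  if (any(!ok)) {
    inform(sprintf("Skipped %d unparseable record(s) at position(s): %s",
                   sum(!ok), paste(which(!ok), collapse = ", ")))
  }
  ids <- raw$compound_id
  ids[is.na(ids)] <- paste0("CPD", which(is.na(ids)))
  res <- tibble(
    compound_id = ids[ok],
    smiles = can[ok],
    is_peptide_derived = is_pep[ok],
    source_sequence = ifelse(is_pep[ok], raw$sequence[ok], NA_character_),
    has_mixture = grepl(".", can[ok], fixed = TRUE)
  )
  attr(res, "skipped") <- tibble(
    position = which(!ok),
    smiles = raw$smiles[!ok],
    sequence = raw$sequence[!ok]
  )
  res
}

# SDF file -> canonical SMILES vector, via OpenBabel.
ob_convert_smiles_from_sdf <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", source = paste0(txt, "\n")),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  map_chr(strsplit(lines, "\t", fixed = TRUE), 1)
}

#' Write compound records to CSV
#'
#' @param compounds Compound record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  readr::write_csv(compounds, path)
  invisible(path)
}

#' Drop chemical duplicates from a compound table
#'
#' The duplicate key is the canonical SMILES alone (chemical identity, not
#' the id); the first occurrence wins and the input order is preserved.
#' Idempotent.
#'
#' @param compounds Compound record tibble (canonical SMILES).
#' @return The deduplicated tibble.
#' @export
deduplicate_compounds <- function(compounds) {
  compounds[!duplicated(compounds$smiles), , drop = FALSE]
}

#' Build an activity record table
#'
#' One row per (compound, receptor, site-mode) measurement.  `pchembl` is the
#' ChEMBL-style normalized potency, \eqn{-\log_{10}} of the molar activity
#' measure; 0 denotes a negative (inactive) data point.
#'
#' @param compound_id,receptor_id Character vectors.
#' @param site_mode `"orthosteric"` or `"allosteric"`.
#' @param assay_type Single uppercase assay-type letter (ChEMBL convention;
#'   `"F"` = functional).
#' @param pchembl Non-negative reals, bounded by 14.
#' @return Activity tibble.
#' @export
activity_records <- function(compound_id, receptor_id,
                             site_mode = "orthosteric",
                             assay_type = "F", pchembl) {
  n <- length(compound_id)
  res <- tibble(
    compound_id = as.character(compound_id),
    receptor_id = as.character(receptor_id),
    site_mode = rep_len(as.character(site_mode), n),
    assay_type = rep_len(as.character(assay_type), n),
    pchembl = as.numeric(pchembl)
  )
  if (!all(res$site_mode %in% c("orthosteric", "allosteric"))) {
    abort("`site_mode` must be 'orthosteric' or 'allosteric'.")
  }
  if (!all(grepl("^[A-Z]$", res$assay_type))) {
    abort("`assay_type` must be a single uppercase character.")
  }
  if (any(res$pchembl < 0 | res$pchembl > 14, na.rm = TRUE)) {
    abort("`pchembl` must lie in [0, 14].")
  }
  res
}

#' Read an activity table from CSV
#'
#' Expects the column layout written by [write_activities()]: `compound_id`,
#' `smiles` (optional), `receptor_id`, `site_mode`, `assay_type`, `pchembl`.
#'
#' @param path CSV path.
#' @return Activity tibble (plus a `smiles` column if present in the file).
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gpcrscreen_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("compound_id", "receptor_id", "site_mode", "assay_type", "pchembl")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("Activity CSV lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  out <- activity_records(df$compound_id, df$receptor_id, df$site_mode,
                          df$assay_type, df$pchembl)
  if ("smiles" %in% names(df)) out$smiles <- as.character(df$smiles)
  out
}

#' @rdname read_activities
#' @param activities Activity tibble.
#' @export
write_activities <- function(activities, path) {
  readr::write_csv(activities, path)
  invisible(path)
}
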