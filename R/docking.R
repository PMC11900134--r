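# Docking leg: ligand-centered cubic search boxes, ligand preparation, a
# pluggable docking backend and score parsing.  The external engine
# (AutoDock Vina) is optional at runtime; a deterministic stub backend keeps
# the rest of the pipeline testable without any binary.

#' Describe a receptor binding site
#'
#' @param receptor_id Receptor identifier.
#' @param site_mode `"orthosteric"` or `"allosteric"`.
#' @param ref_coords Numeric matrix (n x 3) of reference-ligand coordinates
#'   in Angstrom; the search box is centred on their centroid.
#' @param receptor_file Optional path to the prepared receptor PDBQT (needed
#'   only by the external backend).
#' @return `binding_site` object.
#' @export
binding_site <- function(receptor_id,
                         site_mode = c("orthosteric", "allosteric"),
                         ref_coords, receptor_file = NA_character_) {
  site_mode <- match.arg(site_mode)
  ref_coords <- matrix(as.numeric(ref_coords), ncol = 3)
  if (nrow(ref_coords) < 1 || any(!is.finite(ref_coords))) {
    abort("Need at least one finite reference coordinate.",
          class = "gpcrscreen_invalid_site")
  }
  structure(list(receptor_id = receptor_id, site_mode = site_mode,
                 ref_coords = ref_coords, receptor_file = receptor_file),
            class = "binding_site")
}

#' Read a binding-site registry from JSON
#'
#' The registry is a JSON array of objects with `receptor_id`, `site_mode`,
#' `receptor_file` (PDBQT) and `ref_ligand_file` (PDB); the reference
#' ligand's heavy-atom coordinates define each site's box centre.
#'
#' @param path JSON file path.
#' @return List of [binding_site()] objects.
#' @export
read_sites_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gpcrscreen_io_error")
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading reference-ligand PDB files requires the bio3d package.")
  }
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  map(entries, function(e) {
    pdb <- bio3d::read.pdb(e$ref_ligand_file)
    coords <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
    sym <- pdb$atom$elesy
    if (!is.null(sym)) coords <- coords[is.na(sym) | sym != "H", , drop = FALSE]
    binding_site(e$receptor_id, e$site_mode, coords,
                 receptor_file = e$receptor_file %||% NA_character_)
  })
}

#' Build the cubic search box for a binding site
#'
#' The box is centred on the arithmetic centroid of the reference-ligand
#' coordinates, with a 30 Angstrom edge by default.
#'
#' @param site A [binding_site()].
#' @param edge Cube edge length in Angstrom (default 30).
#' @return `docking_box` object with `center` (length-3) and `edge`.
#' @examples
#' s <- binding_site("GLP1R", "orthosteric", rbind(c(0, 0, 0), c(2, 4, 6)))
#' make_box(s)$center   # c(1, 2, 3)
#' @export
make_box <- function(site, edge = 30) {
  stopifnot(inherits(site, "binding_site"), edge > 0)
  structure(list(center = colMeans(site$ref_coords), edge = edge),
            class = "docking_box")
}

#' Prepare a ligand PDBQT from SMILES
#'
#' Embeds a 3D conformer, assigns Gasteiger partial charges and annotates
#' rotatable bonds through Open Babel.  Nonpolar hydrogens are merged
#' (AutoDock united-atom convention).  Failures are per-compound errors, not
#' fatal to a batch caller.
#'
#' @param compound One-row compound tibble or SMILES string.
#' @param outfile Output PDBQT path.
#' @return `outfile` invisibly, or an error of class
#'   `gpcrscreen_prep_error` describing the failing compound.
#' @export
prepare_ligand <- function(compound, outfile = tempfile(fileext = ".pdbqt")) {
  smi <- if (is.data.frame(compound)) compound$smiles[[1]] else compound
  chk <- ob_convert_smiles(smi, "CAN")
  if (is.na(chk)) {
    abort(sprintf("Cannot prepare ligand: unparseable SMILES '%s'.", smi),
          class = "gpcrscreen_prep_error")
  }
  ob <- Sys.which("obabel")
  if (!nzchar(ob)) {
    abort("Open Babel binary `obabel` not found on PATH.",
          class = "gpcrscreen_backend_unavailable")
  }
  status <- suppressWarnings(system2(
    ob, c(paste0("-:", shQuote(smi)), "-opdbqt", "--gen3d",
          "--partialcharge", "gasteiger", "-O", shQuote(outfile)),
    stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(outfile) ||
      !any(grepl("^ATOM", readLines(outfile, warn = FALSE)))) {
    abort(sprintf("3D coordinate generation failed for '%s'.", smi),
          class = "gpcrscreen_prep_error")
  }
  invisible(outfile)
}

# Deterministic stub score: hash of (canonical SMILES, receptor, site mode)
# mapped into the plausible Vina score range [-12, -2] kcal/mol.
stub_dock_score <- function(smiles, receptor_id, site_mode) {
  h <- hash_ints(utf8ToInt(paste(smiles, receptor_id, site_mode, sep = "|")))
  -12 + 10 * (h / HASH_MOD)
}

#' Parse an AutoDock Vina result table
#'
#' Reads the `mode | affinity | rmsd` table printed by the engine (or saved
#' in its log file) into a tibble sorted by affinity.
#'
#' @param text Character vector of log lines, or a single string.
#' @return Tibble with `mode`, `affinity` (kcal/mol), `rmsd_lb`, `rmsd_ub`.
#' @export
parse_vina_log <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  hit <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s+\\d+(\\.\\d+)?\\s+\\d+(\\.\\d+)?\\s*$",
              lines, value = TRUE)
  if (length(hit) == 0) {
    abort("No result table found in the docking log.",
          class = "gpcrscreen_parse_error")
  }
  fields <- map(strsplit(trimws(hit), "\\s+"), as.numeric)
  tibble(
    mode = map_dbl(fields, 1),
    affinity = map_dbl(fields, 2),
    rmsd_lb = map_dbl(fields, 3),
    rmsd_ub = map_dbl(fields, 4)
  ) |>
    arrange(.data$affinity)
}

#' Dock one compound into one binding site
#'
#' The `"vina"` backend shells out to the AutoDock Vina binary with the
#' box written as engine configuration and parses its score table.  The
#' `"stub"` backend (the test-time default) returns a deterministic score
#' computed from a hash of (canonical SMILES, receptor, site mode), mapped
#' into \eqn{[-12, -2]} kcal/mol - no binary needed.
#'
#' @param compound One-row compound tibble or SMILES.
#' @param site A [binding_site()].
#' @param box A [make_box()] result; defaults to the site's 30 Angstrom box.
#' @param backend `"stub"` or `"vina"`.
#' @param exhaustiveness,seed Engine settings (vina backend).
#' @param vina_path Path to the engine binary.
#' @return One-row tibble: `receptor_id`, `site_mode`, `best_score`,
#'   `n_poses`, `backend`.
#' @export
dock <- function(compound, site, box = make_box(site),
                 backend = c("stub", "vina"),
                 exhaustiveness = 8, seed = 42,
                 vina_path = Sys.which("vina")) {
  backend <- match.arg(backend)
  smi <- if (is.data.frame(compound)) compound$smiles[[1]] else compound
  cid <- if (is.data.frame(compound)) compound$compound_id[[1]] else NA_character_
  smi <- canonicalize_smiles(smi)
  if (backend == "stub") {
    score <- stub_dock_score(smi, site$receptor_id, site$site_mode)
    return(tibble(compound_id = cid, receptor_id = site$receptor_id,
                  site_mode = site$site_mode, best_score = score,
                  n_poses = 1L, backend = "stub"))
  }
  if (!nzchar(vina_path)) {
    abort("Docking engine binary not found; use backend = 'stub' or install AutoDock Vina.",
          class = "gpcrscreen_backend_unavailable")
  }
  lig <- prepare_ligand(smi)
  cfg <- tempfile(fileext = ".txt")
  writeLines(c(
    sprintf("receptor = %s", site$receptor_file),
    sprintf("ligand = %s", lig),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.1f", box$edge),
    sprintf("size_y = %.1f", box$edge),
    sprintf("size_z = %.1f", box$edge),
    sprintf("exhaustiveness = %d", as.integer(exhaustiveness)),
    sprintf("seed = %d", as.integer(seed))
  ), cfg)
  out <- suppressWarnings(system2(vina_path, c("--config", shQuote(cfg)),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    abort(c("Docking engine exited with an error.", paste(out, collapse = "\n")),
          class = "gpcrscreen_backend_error")
  }
  poses <- parse_vina_log(out)
  tibble(compound_id = cid, receptor_id = site$receptor_id,
         site_mode = site$site_mode, best_score = poses$affinity[1],
         n_poses = nrow(poses), backend = "vina")
}

#' Dock one compound into every binding site of a panel
#'
#' Per-site failures are recorded (in the `"failures"` attribute) rather
#' than aborting the batch; an error is raised only if every site fails.
#'
#' @param compound One-row compound tibble or SMILES.
#' @param sites List of [binding_site()] objects.
#' @param backend,... Passed to [dock()].
#' @return Tibble of docking results, one row per successful site.
#' @export
dock_all <- function(compound, sites, backend = "stub", ...) {
  stopifnot(length(sites) >= 1)
  res <- map(sites, function(s)
    tryCatch(dock(compound, s, backend = backend, ...),
             error = function(e) e))
  ok <- !map_lgl(res, inherits, "error")
  if (!any(ok)) {
    abort("Docking failed for every site.", class = "gpcrscreen_backend_error")
  }
  out <- bind_rows(res[ok])
  fails <- res[!ok]
  if (length(fails)) {
    inform(sprintf("Docking failed for %d site(s).", length(fails)))
  }
  attr(out, "failures") <- map_chr(fails, conditionMessage)
  out
}
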