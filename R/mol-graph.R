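# Internal molecular-graph layer.
#
# All chemistry I/O goes through OpenBabel (ChemmineOB) and ChemmineR; this
# file only turns a parsed SDF block into the light heavy-atom graph the
# fingerprinting code consumes: atoms (element, charge, attached hydrogens,
# degree, ring/aromatic flags) and bonds (order, aromatic flag).

# Batch-convert SMILES between OpenBabel formats, keeping track of which
# inputs survived.  Returns a character vector aligned with `smiles`, NA for
# entries OpenBabel could not parse.
ob_convert_smiles <- function(smiles, to = "CAN") {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("gsmi", seq_along(smiles))
  src <- paste0(paste(smiles, ids), "\n", collapse = "")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, source = src),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else NA_character_)
  val <- map_chr(parts, 1)
  res <- rep(NA_character_, length(smiles))
  hit <- match(got, ids)
  res[hit[!is.na(hit)]] <- val[!is.na(hit)]
  # The SMI reader stops at the first unparseable line, so records after a
  # bad one go missing from the batch; retry those one at a time.
  for (i in which(is.na(res))) {
    one <- tryCatch(
      ChemmineOB::convertFormat("SMI", to, paste0(smiles[i], " x\n")),
      error = function(e) "")
    tok <- strsplit(one, "[\t\n]")[[1]]
    if (length(tok) >= 1 && nzchar(tok[1])) res[i] <- tok[1]
  }
  res
}

# SMILES -> one SDFset with explicit hydrogens (one molecule per input).
# Unparseable inputs are dropped; the "gsmi<i>" titles recover alignment.
# Because the SMI reader aborts its stream at the first bad line, a batch
# that comes back incomplete is rerun on the individually-validated subset.
ob_smiles_to_sdfset <- function(smiles, .validated = FALSE) {
  ids <- paste0("gsmi", seq_along(smiles))
  src <- paste0(paste(smiles, ids), "\n", collapse = "")
  sdfstr <- tryCatch(ChemmineOB::convertFormat(
    "SMI", "SDF", source = src,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  ), error = function(e) "")
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  sdfset <- if (length(lines) >= 4) ChemmineR::read.SDFset(lines) else NULL
  idx <- if (is.null(sdfset)) integer(0) else
    match(map_chr(ChemmineR::SDFset2SDF(sdfset), function(s)
      ChemmineR::header(s)[["Molecule_Name"]]), ids)
  if (length(idx) == length(smiles) || .validated) {
    if (is.null(sdfset)) return(NULL)
    return(list(sdfset = sdfset, input_index = idx))
  }
  valid <- which(!is.na(ob_convert_smiles(smiles, "CAN")))
  if (length(valid) == 0) return(NULL)
  sub <- ob_smiles_to_sdfset(smiles[valid], .validated = TRUE)
  if (is.null(sub)) return(NULL)
  list(sdfset = sub$sdfset, input_index = valid[sub$input_index])
}

# Formal charges from an SDF record: OpenBabel emits old-style charge codes
# in the atom block (3 = +1, 5 = -1, ...); "M  CHG" lines, when present,
# override them.
CHARGE_FROM_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
CODE_FROM_CHARGE <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

sdf_charges <- function(sdf, n_atoms) {
  chg <- rep(0L, n_atoms)
  txt <- as.character(ChemmineR::sdf2str(sdf))
  counts <- txt[4]
  na <- as.integer(substr(counts, 1, 3))
  atom_lines <- txt[5:(4 + na)]
  codes <- vapply(strsplit(trimws(atom_lines), "\\s+"), function(t)
    if (length(t) >= 6) t[6] else "0", character(1))
  code_chg <- CHARGE_FROM_CODE[codes]
  code_chg[is.na(code_chg)] <- 0L
  chg[seq_len(min(na, n_atoms))] <- code_chg[seq_len(min(na, n_atoms))]
  mlines <- grep("^M  CHG", txt, value = TRUE)
  if (length(mlines)) chg[] <- 0L
  for (ln in mlines) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- toks[1]
    for (j in seq_len(k)) {
      chg[toks[2 * j]] <- toks[2 * j + 1]
    }
  }
  chg
}

# Heavy-atom graph from one ChemmineR SDF object (explicit hydrogens).
mol_graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- gsub("_.*", "", rownames(ab))
  n_all <- length(sym)
  Z <- ChemmineR::atomprop$Number[match(sym, ChemmineR::atomprop$Symbol)]
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
  chg <- sdf_charges(sdf, n_all)

  nH <- vapply(seq_len(n_all), function(i) {
    nb <- c(b2[b1 == i], b1[b2 == i])
    sum(sym[nb] == "H")
  }, integer(1))

  keep <- sym != "H"
  idx <- cumsum(keep)
  hb <- which(keep[b1] & keep[b2])
  atoms <- tibble(
    Z = as.integer(Z[keep]), nH = nH[keep], charge = chg[keep]
  )
  bonds <- tibble(a1 = idx[b1[hb]], a2 = idx[b2[hb]], order = bo[hb])
  n <- nrow(atoms)
  atoms$degree <- vapply(seq_len(n), function(i)
    sum(bonds$a1 == i | bonds$a2 == i), integer(1))

  in_ring <- rep(FALSE, n); aromatic <- rep(FALSE, n)
  ring_bond <- rep(FALSE, nrow(bonds)); arom_bond <- rep(FALSE, nrow(bonds))
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(rr) && length(rr$RINGS) > 0) {
    for (k in seq_along(rr$RINGS)) {
      ai <- idx[as.integer(gsub(".*_", "", rr$RINGS[[k]]))]
      in_ring[ai] <- TRUE
      inb <- bonds$a1 %in% ai & bonds$a2 %in% ai
      ring_bond[inb] <- TRUE
      if (isTRUE(rr$AROMATIC[[k]])) {
        aromatic[ai] <- TRUE
        arom_bond[inb] <- TRUE
      }
    }
  }
  atoms$in_ring <- in_ring
  atoms$aromatic <- aromatic
  bonds$code <- ifelse(arom_bond & aromatic[bonds$a1] & aromatic[bonds$a2],
                       4L, bonds$order)
  list(atoms = atoms, bonds = bonds)
}

# Graphs for a vector of (canonical) SMILES; returns a list aligned with the
# input, NULL where parsing failed.
mol_graphs <- function(smiles) {
  out <- vector("list", length(smiles))
  if (length(smiles) == 0) return(out)
  conv <- ob_smiles_to_sdfset(smiles)
  if (is.null(conv)) return(out)
  sdfs <- ChemmineR::SDFset2SDF(conv$sdfset)
  for (j in seq_along(sdfs)) {
    i <- conv$input_index[j]
    if (is.na(i)) next
    out[[i]] <- tryCatch(mol_graph_from_sdf(sdfs[[j]]), error = function(e) NULL)
  }
  out
}

# Deterministic polynomial hash of a non-negative integer vector, exact in
# double precision (values stay < 2^53), reduced mod 2^31 - 1.
HASH_MOD <- 2147483647
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (as.numeric(x) %% HASH_MOD)) %% HASH_MOD
  h
}

# Molecular formula string via OpenBabel, e.g. "C12H20N6O7".
molecular_formula <- function(smiles) {
  conv <- ob_smiles_to_sdfset(smiles)
  res <- rep(NA_character_, length(smiles))
  if (is.null(conv)) return(res)
  p <- ChemmineR::propOB(conv$sdfset)
  ok <- !is.na(conv$input_index)
  res[conv$input_index[ok]] <- p$formula[ok]
  res
}

# Count SMARTS matches per molecule (0 when the pattern is absent).
#' Count occurrences of a SMARTS substructure
#'
#' Thin wrapper over the OpenBabel SMARTS matcher used throughout the package
#' as the substructure oracle (planted-pharmacophore bookkeeping, fragment
#' checks).
#'
#' @param smiles Character vector of SMILES.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of match counts, aligned with `smiles`; `NA` for
#'   unparseable molecules.
#' @export
count_substructure <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  res <- rep(NA_integer_, length(smiles))
  if (length(smiles) == 0) return(res)
  conv <- ob_smiles_to_sdfset(smiles)
  if (is.null(conv)) return(res)
  hits <- ChemmineR::smartsSearchOB(conv$sdfset, smarts, uniqueMatches = FALSE)
  ok <- !is.na(conv$input_index)
  res[conv$input_index[ok]] <- as.integer(hits)[ok]
  res
}
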