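# Peptide handling: truncation to the receptor-activating fragment and
# assembly of a SMILES string by amide condensation of residue blocks.
#
# Peptide GPCR agonists carry their activation "message" in a short terminal
# fragment while the remainder ("address") mainly drives binding orientation.
# Truncating to six residues puts peptides into the same small-molecule
# feature space used for fingerprinting and docking.

# Side-chain fragments attached to the alpha carbon.  The backbone for a
# chiral residue is "N[C@@H](<side>)C(=O)" (L configuration); glycine and
# proline have their own backbone spellings.
AA_SIDE_CHAINS <- c(
  A = "C",
  R = "CCCNC(=N)N",
  N = "CC(N)=O",
  D = "CC(=O)O",
  C = "CS",
  E = "CCC(=O)O",
  Q = "CCC(N)=O",
  H = "Cc1c[nH]cn1",
  I = "[C@@H](C)CC",
  K = "CCCCN",
  L = "CC(C)C",
  M = "CCSC",
  F = "Cc1ccccc1",
  S = "CO",
  T = "[C@H](O)C",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)
AA_ALPHABET <- c(names(AA_SIDE_CHAINS), "G", "P")

residue_block <- function(code, stereo = TRUE) {
  if (code == "G") return("NCC(=O)")
  if (code == "P") {
    return(if (stereo) "N1CCC[C@H]1C(=O)" else "N1CCCC1C(=O)")
  }
  side <- AA_SIDE_CHAINS[[code]]
  if (!stereo) side <- gsub("\\[C@@?H\\]", "C", side)
  alpha <- if (stereo) "[C@@H]" else "C"
  paste0("N", alpha, "(", side, ")C(=O)")
}

validate_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (is.na(sequence) || !nzchar(sequence)) {
    abort("Peptide sequence must be non-empty.",
          class = "gpcrscreen_invalid_sequence")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% AA_ALPHABET)
  if (length(bad)) {
    abort(sprintf("Non-standard residue code '%s' at position %d.",
                  res[bad[1]], bad[1]),
          class = "gpcrscreen_invalid_sequence")
  }
  paste(res, collapse = "")
}

#' Truncate a peptide to its activation fragment
#'
#' Keeps the first `n` residues under the N-terminal rule (the default for
#' opioid, chemokine and class B receptor ligands) or the last `n` under the
#' C-terminal rule (for receptor families whose activating fragment is
#' C-terminal).  Sequences of length at most `n` pass through unchanged;
#' the operation is idempotent at fixed `n`.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param n Fragment length; default 6.
#' @param terminus `"N_terminal"` (default) or `"C_terminal"`.
#' @return The truncated sequence string.
#' @examples
#' truncate_peptide("HAEGTFTSDVSS")            # "HAEGTF"
#' truncate_peptide("YGGFL")                   # unchanged
#' @export
truncate_peptide <- function(sequence, n = 6,
                             terminus = c("N_terminal", "C_terminal")) {
  terminus <- match.arg(terminus)
  stopifnot(n >= 1)
  sequence <- validate_sequence(sequence)
  len <- nchar(sequence)
  if (len <= n) return(sequence)
  if (terminus == "N_terminal") substr(sequence, 1, n)
  else substr(sequence, len - n + 1, len)
}

#' Assemble a peptide SMILES by amide condensation
#'
#' Builds the linear peptide from residue blocks: free amine N-terminus,
#' carboxylic-acid C-terminus (an amide cap is available for fragments whose
#' new C-terminus was created by truncation), one water removed per peptide
#' bond.  L-alpha stereocentres are encoded by default.  The returned SMILES
#' is canonical.
#'
#' @param sequence One-letter amino-acid string.
#' @param stereo Encode L-configuration stereocentres (default `TRUE`).
#' @param cterm `"acid"` (default) or `"amide"` C-terminal cap.
#' @return A canonical SMILES string.
#' @examples
#' peptide_to_smiles("G")    # glycine, NCC(=O)O
#' @export
peptide_to_smiles <- function(sequence, stereo = TRUE,
                              cterm = c("acid", "amide")) {
  cterm <- match.arg(cterm)
  sequence <- validate_sequence(sequence)
  res <- strsplit(sequence, "")[[1]]
  body <- paste(vapply(res, residue_block, character(1), stereo = stereo),
                collapse = "")
  smi <- paste0(body, if (cterm == "acid") "O" else "N")
  canonicalize_smiles(smi)
}

#' Turn a peptide sequence into a compound record
#'
#' Truncates to the `n`-residue activation fragment, converts to SMILES and
#' returns a one-row compound table with `is_peptide_derived = TRUE` and the
#' original (untruncated) sequence in `source_sequence`.
#'
#' @inheritParams truncate_peptide
#' @inheritParams peptide_to_smiles
#' @param compound_id Record id.
#' @return One-row compound record tibble.
#' @export
peptide_record <- function(sequence, compound_id, n = 6,
                           terminus = "N_terminal",
                           stereo = TRUE, cterm = "acid") {
  sequence <- validate_sequence(sequence)
  frag <- truncate_peptide(sequence, n = n, terminus = terminus)
  smi <- peptide_to_smiles(frag, stereo = stereo, cterm = cterm)
  compound_records(smi, compound_id = compound_id,
                   is_peptide_derived = TRUE, source_sequence = sequence)
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file of one-letter amino-acid sequences.
#' @return Tibble with `compound_id` (FASTA header) and `sequence`.
#' @export
read_peptides_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gpcrscreen_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("Not a FASTA file (no '>' headers).")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(x)
    gsub("\\s", "", paste(x, collapse = "")), character(1))
  tibble(compound_id = ids, sequence = unname(seqs))
}
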