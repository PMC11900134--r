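# ECFP4 (Morgan) fingerprints with bit -> atom-environment decoding.
#
# The fingerprint is computed on the heavy-atom graph: each atom starts from
# a hashed invariant (element, heavy degree, attached hydrogens, formal
# charge, ring and aromatic flags) and is iteratively updated from its
# neighbours' identifiers and bond orders, radius 0..2 (bond diameter 4).
# Environments whose bond set duplicates an already-emitted environment are
# discarded, mirroring the canonical ECFP duplicate-removal rule, and the
# surviving identifiers are folded into a fixed-length bit vector.  Keeping
# the (atom, radius) provenance of every identifier is what allows a bit to
# be decoded back into its chemical fragment for importance reporting.

#' Fingerprint specification
#'
#' @param radius Morgan radius (2 = ECFP4, bond diameter 4).
#' @param n_bits Folded length; must be a power of two (default 2048).
#' @param use_chirality Reserved flag; only `FALSE` (classic ECFP, topology
#'   without stereo) is currently implemented.
#' @return An object of class `fp_spec`.
#' @export
fp_spec <- function(radius = 2, n_bits = 2048, use_chirality = FALSE) {
  stopifnot(radius >= 0, n_bits >= 2)
  if (bitwAnd(n_bits, n_bits - 1L) != 0) {
    abort("`n_bits` must be a power of two.")
  }
  if (isTRUE(use_chirality)) {
    abort("Chirality-aware fingerprints are not implemented; use_chirality must be FALSE.")
  }
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits),
                 use_chirality = FALSE),
            class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat(sprintf("ECFP%d fingerprint spec: radius %d, %d bits\n",
              2 * x$radius, x$radius, x$n_bits))
  invisible(x)
}

# Enumerate Morgan atom environments of one molecular graph.
# Returns a tibble: atom, radius, hash, and the bond set as a list-column.
morgan_environments <- function(graph, radius = 2) {
  atoms <- graph$atoms; bonds <- graph$bonds
  n <- nrow(atoms)
  if (n == 0) return(tibble(atom = integer(), radius = integer(),
                            hash = numeric(), bond_set = list()))
  adj <- lapply(seq_len(n), function(i) {
    r1 <- which(bonds$a1 == i); r2 <- which(bonds$a2 == i)
    list(nbr = c(bonds$a2[r1], bonds$a1[r2]), bond = c(r1, r2),
         code = bonds$code[c(r1, r2)])
  })
  inv <- vapply(seq_len(n), function(i) {
    a <- atoms[i, ]
    hash_ints(c(a$Z, a$degree, a$nH, a$charge + 8L, a$in_ring, a$aromatic))
  }, numeric(1))

  out_atom <- seq_len(n); out_radius <- rep(0L, n); out_hash <- inv
  out_bonds <- rep(list(integer(0)), n)
  bondsets <- rep(list(integer(0)), n)
  seen <- character(0)
  curinv <- inv
  for (r in seq_len(radius)) {
    newinv <- curinv
    newsets <- bondsets
    for (i in seq_len(n)) {
      a <- adj[[i]]
      if (length(a$nbr) == 0) next
      ord <- order(a$code, curinv[a$nbr])
      newinv[i] <- hash_ints(c(r, curinv[i],
                               rbind(a$code[ord], curinv[a$nbr[ord]])))
      newsets[[i]] <- sort(unique(c(bondsets[[i]], a$bond,
                                    unlist(bondsets[a$nbr]))))
    }
    for (i in seq_len(n)) {
      if (length(adj[[i]]$nbr) == 0) next
      if (length(newsets[[i]]) <= length(bondsets[[i]])) next  # env stopped growing
      key <- paste(newsets[[i]], collapse = ",")
      if (key %in% seen) next                                  # duplicate substructure
      seen <- c(seen, key)
      out_atom <- c(out_atom, i); out_radius <- c(out_radius, r)
      out_hash <- c(out_hash, newinv[i]); out_bonds <- c(out_bonds, list(newsets[[i]]))
    }
    bondsets <- newsets; curinv <- newinv
  }
  tibble(atom = out_atom, radius = out_radius, hash = out_hash,
         bond_set = out_bonds)
}

# Full fingerprint for one canonical SMILES (internal; graph may be supplied).
ecfp_one <- function(smiles, spec, graph = NULL) {
  graph <- graph %||% mol_graphs(smiles)[[1]]
  if (is.null(graph)) {
    abort(sprintf("Unparseable SMILES: %s", smiles),
          class = "gpcrscreen_invalid_smiles")
  }
  envs <- morgan_environments(graph, spec$radius)
  envs$bit <- as.integer(envs$hash %% spec$n_bits) + 1L
  structure(list(
    smiles = smiles,
    spec = spec,
    on_bits = sort(unique(envs$bit)),
    environments = envs,
    graph = graph
  ), class = "ecfp")
}

#' Compute an ECFP4 fingerprint
#'
#' @param compound A one-row compound record tibble (see
#'   [compound_records()]) or a single SMILES string.
#' @param spec Fingerprint specification from [fp_spec()].
#' @return An `ecfp` object: `on_bits` (sorted 1-based set-bit indices),
#'   `environments` (tibble mapping each bit to its (atom, radius)
#'   provenance), and the underlying graph.
#' @examples
#' fp <- ecfp4("CCO", fp_spec(n_bits = 1024))
#' fp$on_bits
#' @export
ecfp4 <- function(compound, spec = fp_spec()) {
  smiles <- if (is.data.frame(compound)) compound$smiles[[1]] else compound
  smiles <- canonicalize_smiles(smiles)
  ecfp_one(smiles, spec)
}

#' @export
print.ecfp <- function(x, ...) {
  cat(sprintf("ECFP%d fingerprint (%d bits): %d bits set\n",
              2 * x$spec$radius, x$spec$n_bits, length(x$on_bits)))
  invisible(x)
}

#' Fingerprint a compound table into a binary feature matrix
#'
#' @param compounds Compound record tibble.
#' @param spec Fingerprint specification.
#' @return A binary matrix, one row per compound (rownames = `compound_id`),
#'   `n_bits` columns named `b1..b<n_bits>`.
#' @export
featurize_set <- function(compounds, spec = fp_spec()) {
  n <- nrow(compounds)
  X <- matrix(0L, nrow = n, ncol = spec$n_bits,
              dimnames = list(compounds$compound_id,
                              paste0("b", seq_len(spec$n_bits))))
  if (n == 0) return(X)
  graphs <- mol_graphs(compounds$smiles)
  bad <- which(vapply(graphs, is.null, logical(1)))
  if (length(bad)) {
    abort(sprintf("Unparseable compound record(s): %s",
                  paste(compounds$compound_id[bad], collapse = ", ")),
          class = "gpcrscreen_invalid_smiles")
  }
  for (i in seq_len(n)) {
    envs <- morgan_environments(graphs[[i]], spec$radius)
    bits <- unique(as.integer(envs$hash %% spec$n_bits) + 1L)
    X[i, bits] <- 1L
  }
  X
}

#' Decode a fingerprint bit into its chemical fragment
#'
#' Extracts the atom environment behind a set bit (centre atom plus all
#' atoms within its radius) and renders it as a fragment SMILES in which
#' attachment points - bonds continuing into the rest of the molecule - are
#' marked with `*`.  When several distinct environment identifiers fold onto
#' the same bit (a folding collision) the smallest-radius environment is
#' returned and the collision is reported.
#'
#' @param compound Compound record row or SMILES whose fingerprint sets `bit`.
#' @param bit 1-based bit index.
#' @param spec Fingerprint specification.
#' @return Fragment SMILES string with `*` attachment markers.
#' @export
fragment_for_bit <- function(compound, bit, spec = fp_spec()) {
  fp <- if (inherits(compound, "ecfp")) compound else ecfp4(compound, spec)
  envs <- fp$environments[fp$environments$bit == bit, , drop = FALSE]
  if (nrow(envs) == 0) {
    abort(sprintf("Bit %d is not set for this molecule.", bit),
          class = "gpcrscreen_bit_not_set")
  }
  if (length(unique(envs$hash)) > 1) {
    inform(sprintf("Bit %d carries %d distinct environments (folding collision); using the smallest.",
                   bit, length(unique(envs$hash))))
  }
  env <- envs[order(envs$radius, envs$atom), ][1, ]
  environment_fragment(fp$graph, env$atom, env$radius)
}

# Subgraph of atoms within `radius` bonds of `centre`, rendered as SMILES
# with '*' dummies for outgoing bonds.
environment_fragment <- function(graph, centre, radius) {
  atoms <- graph$atoms; bonds <- graph$bonds
  # BFS out to `radius`
  dist <- rep(Inf, nrow(atoms)); dist[centre] <- 0
  frontier <- centre
  d <- 0
  while (length(frontier) && d < radius) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
      new <- nb[dist[nb] > d + 1]
      dist[new] <- d + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
    d <- d + 1
  }
  inside <- which(is.finite(dist))
  # bonds fully inside; bonds leaving the environment become '*' attachments
  sel <- bonds$a1 %in% inside & bonds$a2 %in% inside
  sym <- element_symbols(atoms$Z)
  frag_atoms <- sym[inside]
  remap <- match(seq_len(nrow(atoms)), inside)
  fb <- cbind(remap[bonds$a1[sel]], remap[bonds$a2[sel]],
              pmin(bonds$order[sel], 3L))
  cross <- which(xor(bonds$a1 %in% inside, bonds$a2 %in% inside))
  for (bi in cross) {
    inner <- if (bonds$a1[bi] %in% inside) bonds$a1[bi] else bonds$a2[bi]
    frag_atoms <- c(frag_atoms, "*")
    fb <- rbind(fb, c(remap[inner], length(frag_atoms),
                      pmin(bonds$order[bi], 3L)))
  }
  frag_codes <- rep(0L, length(frag_atoms))
  known <- seq_along(inside)
  frag_codes[known] <- dplyr::coalesce(
    CODE_FROM_CHARGE[as.character(atoms$charge[inside])], 0L)
  sdf_block <- c(
    "fragment", "  gpcrscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(frag_atoms), nrow(fb)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, frag_atoms, frag_codes),
    sprintf("%3d%3d%3d  0  0  0  0", fb[, 1], fb[, 2], fb[, 3]),
    "M  END", "$$$$"
  )
  out <- ChemmineOB::convertFormat("SDF", "SMI",
                                   paste0(paste(sdf_block, collapse = "\n"), "\n"))
  frag <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(frag) || !nzchar(frag)) {
    abort("Fragment rendering failed.", class = "gpcrscreen_fragment_error")
  }
  frag
}

element_symbols <- function(Z) {
  as.character(ChemmineR::atomprop$Symbol)[match(Z, ChemmineR::atomprop$Number)]
}
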