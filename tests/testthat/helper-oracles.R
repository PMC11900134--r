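# Shared fixtures and independent oracles for the test suite.

# Memoise expensive fixtures across test files (files share one R session).
.fixture_env <- new.env(parent = emptyenv())
cached_fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Alternative SMILES spellings of the same molecule, produced by permuting
# the atom order of the parsed structure and re-emitting SMILES through
# OpenBabel.  Independent of the fingerprint code path.
smiles_reorderings <- function(smiles, n = 3, seed = 1) {
  g <- gpcrscreen:::mol_graphs(smiles)[[1]]
  stopifnot(!is.null(g))
  sym <- gpcrscreen:::element_symbols(g$atoms$Z)
  set.seed(seed)
  out <- character(0)
  for (k in seq_len(n)) {
    perm <- sample(nrow(g$atoms))
    inv <- order(perm)
    codes <- gpcrscreen:::CODE_FROM_CHARGE[as.character(g$atoms$charge[perm])]
    codes[is.na(codes)] <- 0L
    sdf <- c("reordered", "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(g$atoms), nrow(g$bonds)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                     0, 0, 0, sym[perm], codes),
             sprintf("%3d%3d%3d  0  0  0  0",
                     inv[g$bonds$a1], inv[g$bonds$a2], g$bonds$order),
             "M  END", "$$$$")
    smi <- ChemmineOB::convertFormat("SDF", "SMI",
                                     paste0(paste(sdf, collapse = "\n"), "\n"))
    out <- c(out, strsplit(smi, "[\t\n]")[[1]][1])
  }
  unique(out)
}

# Reference Morgan implementation (RDKit, radius 2, unfolded): number of
# distinct atom environments per molecule.
rdkit_available <- function() nzchar(Sys.which("python"))
rdkit_env_counts <- function(smiles) {
  script <- paste(
    "import sys, warnings",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem import AllChem",
    "RDLogger.DisableLog('rdApp.*')",
    "warnings.filterwarnings('ignore')",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    bi = {}",
    "    AllChem.GetMorganFingerprint(m, 2, bitInfo=bi)",
    "    print(len(bi))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)),
                 input = smiles, stdout = TRUE, stderr = FALSE)
  as.integer(out)
}

# A small set of drug-like molecules (no stereocentres) used for
# fingerprint invariance and reference-agreement checks.
druglike_smiles <- function() c(
  "CCO", "CCN", "CCCC", "CC(C)O", "CC(=O)O", "CC(=O)NC", "CCOC(=O)C",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "c1cc[nH]c1",
  "c1ccoc1", "c1ccsc1", "c1cnc[nH]1", "c1ccc2ccccc2c1",
  "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "NCC(=O)O", "NC(CC(=O)O)C(=O)O",
  "OC(=O)CCC(=O)O", "CCN(CC)CC", "CSCC", "N#Cc1ccccc1", "FC(F)(F)c1ccccc1",
  "ClC(Cl)Cl", "O=C(O)c1ccccc1O", "COc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "O=[N+]([O-])c1ccccc1", "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "C1CCNC1",
  "CC(C)(C)c1ccccc1", "CC(=O)c1ccccc1", "OCCO", "OCCN", "SCC(N)C(=O)O",
  "O=C(N)c1ccccc1", "CC#N", "CC=C", "C=CC=C", "CCOCC", "CC(=O)CC(=O)C",
  "O=S(=O)(N)c1ccccc1", "NC(=O)NC(=O)N"
)

# Toy activity table violating each curation rule exactly once.
toy_curation_fixture <- function() {
  compounds <- tibble::tibble(
    compound_id = c("c1", "c2", "c3", "c4", "c5"),
    smiles = c("CCO", "OCC", "CCN", "not_a_smiles", "CCCC")
  )
  activities <- tibble::tibble(
    compound_id = c("c1", "c2", "c3", "c4", "c5"),
    receptor_id = "R1",
    site_mode = "orthosteric",
    assay_type = c("F", "F", "B", "F", "F"),
    pchembl = c(7, 6.5, 7, 5, 8)
  )
  list(compounds = compounds, activities = activities)
}

# Planted library at the standard study conditions, memoised (used by the
# model tests and the acceptance checks).
fixture_sar_library <- function(noise_sd, n_side = 500, seed = 11) {
  key <- sprintf("sar_%s_%d_%d", format(noise_sd), n_side, seed)
  cached_fixture(key, function() {
    sar <- planted_sar("GLP1R", pharmacophore = "CC(=O)NO",
                       baseline = 5, effect_size = 3, noise_sd = noise_sd,
                       n_actives = n_side, n_inactives = n_side, seed = seed)
    lib <- generate_library(sar)
    lib$X <- featurize_set(lib$compounds, fp_spec())
    lib
  })
}

# Small planted amide-pharmacophore library shared by the model tests.
fixture_small_amide_lib <- function() {
  cached_fixture("small_amide_lib", function() {
    sar <- planted_sar("CCR1", pharmacophore = "CC(=O)NO", noise_sd = 0.1,
                       n_actives = 40, n_inactives = 40, seed = 21)
    out <- generate_library(sar)
    out$X <- featurize_set(out$compounds, fp_spec())
    out
  })
}

# Bits that perfectly indicate carrier status (the planted signal's
# fingerprint image): set in every carrier, absent from every non-carrier.
carrier_indicator_bits <- function(X, carrier) {
  hit <- colSums(X[carrier, , drop = FALSE]) == sum(carrier)
  miss <- colSums(X[!carrier, , drop = FALSE]) == 0
  which(hit & miss)
}

# Desk-scale search spaces used throughout the tests: the model contracts
# (random search, 10-fold CV, selection metric) are identical to the
# defaults, only the architecture ranges and trial counts are reduced.
test_classifier_space <- function(seed = 1L, n_trials = 5L) {
  classifier_search_space(n_hidden_layers = c(5, 8),
                          units_per_layer = c(16, 64),
                          n_trials = n_trials, epochs = 150, patience = 15,
                          seed = seed)
}
test_regressor_space <- function(seed = 1L, n_trials = 5L) {
  regressor_search_space(n_estimators = c(50, 500), n_trials = n_trials,
                         seed = seed)
}
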