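test_that("noise-free libraries place carriers and non-carriers exactly", {
  sar <- planted_sar("CCR2", pharmacophore = "CC(=O)NO", noise_sd = 0,
                     n_actives = 15, n_inactives = 15, seed = 5)
  lib <- generate_library(sar)
  expect_true(all(lib$activities$pchembl[lib$compounds$is_carrier] == 8))
  expect_true(all(lib$activities$pchembl[!lib$compounds$is_carrier] == 5))
  expect_true(all(lib$activities$assay_type == "F"))
})

test_that("generation is byte-identical under a fixed seed", {
  sar <- planted_sar("CCR2", pharmacophore = "CC(=O)NO",
                     n_actives = 10, n_inactives = 10, seed = 6)
  a <- generate_library(sar)
  b <- generate_library(sar)
  expect_identical(a, b)
  sar2 <- planted_sar("CCR2", pharmacophore = "CC(=O)NO",
                      n_actives = 10, n_inactives = 10, seed = 7)
  expect_false(identical(generate_library(sar2)$compounds$smiles,
                         a$compounds$smiles))
})

test_that("the substructure oracle separates carriers from non-carriers", {
  lib <- fixture_small_amide_lib()
  hits <- count_substructure(lib$compounds$smiles, "CC(=O)NO")
  expect_true(all(hits[lib$compounds$is_carrier] > 0))
  expect_true(all(hits[!lib$compounds$is_carrier] == 0))
})

test_that("invalid pharmacophores are rejected", {
  expect_error(planted_sar("R", pharmacophore = "XX(("),
               class = "gpcrscreen_invalid_smiles")
})

test_that("peptide libraries honour their length range and seed", {
  seqs <- generate_peptide_library(25, c(4, 10), seed = 3)
  expect_length(seqs, 25)
  expect_true(all(nchar(seqs) >= 4 & nchar(seqs) <= 10))
  expect_identical(seqs, generate_peptide_library(25, c(4, 10), seed = 3))
  expect_length(generate_peptide_library(0, c(4, 10), seed = 3), 0)
})

test_that("truncation keeps N-terminal pharmacophores and drops distal ones", {
  # tryptophan indole as the motif: in the first six residues vs beyond
  indole <- "c1cc2c(cc1)c(c[nH]2)"
  near <- "GWGAGAGAGA"    # W at position 2 (within the 6-mer)
  far <- "GAGAGAGAWG"     # W at position 9 (beyond the 6-mer)
  near_frag <- peptide_to_smiles(truncate_peptide(near))
  far_frag <- peptide_to_smiles(truncate_peptide(far))
  expect_gt(count_substructure(near_frag, indole), 0)
  expect_equal(count_substructure(far_frag, indole), 0)
  # untruncated, both carry it
  expect_gt(count_substructure(peptide_to_smiles(far), indole), 0)
})

test_that("the multi-receptor benchmark plants selective and dual ligands", {
  bench <- cached_fixture("bench_small", function() {
    sars <- list(
      planted_sar("CCR1", pharmacophore = "CC(=O)NO", noise_sd = 0.2,
                  n_actives = 20, n_inactives = 20, seed = 31),
      planted_sar("GLP1R", pharmacophore = "CS(=O)(=O)N", noise_sd = 0.2,
                  n_actives = 20, n_inactives = 20, seed = 32))
    generate_multireceptor_benchmark(sars, n_dual = 5)
  })
  expect_equal(nrow(bench$compounds), 85)       # 2 x 40 + 5 dual
  duals <- grepl("^DUAL", bench$truth$compound_id)
  expect_equal(sum(duals), 10)                  # two truth rows per dual
  expect_setequal(unique(bench$truth$true_class), c("A", "B"))
  # every compound has one activity row per receptor
  expect_equal(nrow(bench$activities), 2 * nrow(bench$compounds))
  # dual carriers hold both motifs
  dual_smis <- bench$compounds$smiles[grepl("^DUAL", bench$compounds$compound_id)]
  expect_true(all(count_substructure(dual_smis, "CC(=O)NO") > 0))
  expect_true(all(count_substructure(dual_smis, "CS(=O)(=O)N") > 0))
})

test_that("overlapping pharmacophores are refused", {
  sars <- list(
    planted_sar("R1", pharmacophore = "CC(=O)NO", n_actives = 5,
                n_inactives = 5, seed = 1),
    planted_sar("R2", pharmacophore = "C(=O)N", n_actives = 5,
                n_inactives = 5, seed = 2))
  expect_error(generate_multireceptor_benchmark(sars),
               class = "gpcrscreen_config_error")
})

test_that("a noise-free planted regression problem is exactly solvable", {
  sar <- planted_sar("CCR2", pharmacophore = "CC(=O)NO", noise_sd = 0,
                     n_actives = 30, n_inactives = 30, seed = 8)
  lib <- generate_library(sar)
  X <- featurize_set(lib$compounds, fp_spec(n_bits = 1024))
  reg <- train_regressor(X, lib$activities$pchembl,
                         test_regressor_space(seed = 8, n_trials = 3))
  expect_lte(mean(reg$cv_metrics$rmse), 0.1)
})
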