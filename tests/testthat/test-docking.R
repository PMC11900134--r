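test_that("the search box is centred on the reference ligand with a 30 A edge", {
  s1 <- binding_site("R1", "orthosteric", rbind(c(1, 2, 3)))
  b1 <- make_box(s1)
  expect_equal(b1$center, c(1, 2, 3))
  expect_equal(b1$edge, 30)
  s2 <- binding_site("R1", "orthosteric", rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(make_box(s2)$center, c(0, 0, 0))
  s3 <- binding_site("R1", "orthosteric", rbind(c(0, 0, 0), c(2, 4, 6)))
  expect_equal(make_box(s3)$center, c(1, 2, 3))
})

test_that("box construction is translation-equivariant", {
  set.seed(31)
  coords <- matrix(rnorm(30), ncol = 3)
  v <- c(5, -3, 11)
  c0 <- make_box(binding_site("R", "allosteric", coords))$center
  c1 <- make_box(binding_site("R", "allosteric", sweep(coords, 2, v, "+")))$center
  expect_equal(c1, c0 + v)
})

test_that("sites demand at least one finite coordinate", {
  expect_error(binding_site("R", "orthosteric", matrix(numeric(0), ncol = 3)),
               class = "gpcrscreen_invalid_site")
  expect_error(binding_site("R", "orthosteric", rbind(c(1, NA, 3))),
               class = "gpcrscreen_invalid_site")
})

test_that("the stub backend is deterministic, bounded and non-degenerate", {
  site <- binding_site("CCR1", "orthosteric", rbind(c(0, 0, 0)))
  d1 <- dock(compound_records("CCO"), site)
  d2 <- dock(compound_records("CCO"), site)
  expect_identical(d1$best_score, d2$best_score)
  expect_identical(d1$backend, "stub")
  lib <- fixture_small_amide_lib()
  scores <- vapply(lib$compounds$smiles, function(s)
    gpcrscreen:::stub_dock_score(s, "CCR1", "orthosteric"), numeric(1))
  expect_true(all(scores >= -12 & scores <= -2))
  expect_gt(length(unique(round(scores, 3))), length(scores) * 0.9)
  expect_gt(sd(scores), 0.5)
})

test_that("engine result tables parse into sorted pose lists", {
  log <- c("mode |   affinity | dist from best mode",
           "-----+------------+----------",
           "   1       -7.1      0.000      0.000",
           "   2       -6.5      2.213      4.199",
           "   3       -6.9      1.220      2.104")
  poses <- parse_vina_log(log)
  expect_equal(nrow(poses), 3)
  expect_equal(poses$affinity, c(-7.1, -6.9, -6.5))
  expect_error(parse_vina_log("no table here"),
               class = "gpcrscreen_parse_error")
})

test_that("panel docking tolerates per-site failures but not total failure", {
  sites <- list(
    binding_site("R1", "orthosteric", rbind(c(0, 0, 0))),
    binding_site("R2", "orthosteric", rbind(c(1, 1, 1))),
    binding_site("R3", "allosteric", rbind(c(2, 2, 2)))
  )
  res <- dock_all(compound_records("CCO"), sites)
  expect_equal(nrow(res), 3)
  # results do not depend on site ordering
  res_rev <- dock_all(compound_records("CCO"), rev(sites))
  expect_equal(dplyr::arrange(res, receptor_id),
               dplyr::arrange(res_rev, receptor_id))
  # missing engine binary: every site fails -> aggregate error
  expect_error(
    suppressMessages(dock_all(compound_records("CCO"), sites,
                              backend = "vina", vina_path = "")),
    class = "gpcrscreen_backend_error")
})

test_that("a 39-site stub panel scores in well under a second", {
  sites <- lapply(1:39, function(i)
    binding_site(paste0("R", i), "orthosteric", rbind(c(i, 0, 0))))
  t0 <- Sys.time()
  res <- dock_all(compound_records("CCO"), sites)
  expect_equal(nrow(res), 39)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})

test_that("a JSON site registry resolves reference-ligand centroids", {
  lig <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("HETATM    1  C1  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            0, 0, 0),
    sprintf("HETATM    2  C2  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2, 4, 6),
    "END"), lig)
  reg <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(receptor_id = "GLP1R",
                                 site_mode = "orthosteric",
                                 ref_ligand_file = lig)),
                       reg, auto_unbox = TRUE)
  sites <- read_sites_json(reg)
  expect_length(sites, 1)
  expect_equal(make_box(sites[[1]])$center, c(1, 2, 3))
})

test_that("ligand preparation yields a united-atom PDBQT with torsions", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  prepare_ligand(compound_records("CCO"), f)
  lines <- readLines(f)
  atoms <- grep("^ATOM", lines, value = TRUE)
  # nonpolar hydrogens merged: 2 C + polar H + O
  expect_equal(length(atoms), 4)
  expect_true(any(grepl("OA", atoms)))
  tors <- grep("TORSDOF", lines, value = TRUE)
  expect_gte(as.integer(sub(".*TORSDOF\\s+", "", tors[1])), 1)
  # a truncated peptide prepares as a flexible small molecule
  f2 <- withr::local_tempfile(fileext = ".pdbqt")
  prepare_ligand(peptide_record("YGG", "pep"), f2)
  expect_gt(length(grep("^ATOM", readLines(f2))), 10)
  expect_error(prepare_ligand("XX(("), class = "gpcrscreen_prep_error")
})
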