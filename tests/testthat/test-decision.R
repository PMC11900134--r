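# Hand-built profiles: the voting logic is tested independently of any
# trained model.
fake_profile <- function(compound_id, receptors, classes, pchembls, docks,
                         site_mode = "orthosteric") {
  n <- length(receptors)
  probs <- matrix(0, n, 6, dimnames = list(NULL, paste0("class", 0:5)))
  probs[cbind(seq_len(n), classes + 1)] <- 1
  dplyr::bind_cols(
    tibble::tibble(compound_id = compound_id, receptor_id = receptors,
                   site_mode = rep_len(site_mode, n),
                   predicted_class = classes,
                   predicted_pchembl = pchembls, docking_score = docks),
    tibble::as_tibble(probs)
  )
}
registry3 <- tibble::tibble(receptor_id = c("R", "S", "T"),
                            gpcr_class = c("A", "B", "B"))

test_that("unanimous, majority and split votes produce k = 3, 2, 1", {
  p3 <- fake_profile("c", c("R", "S"), c(5L, 1L), c(8, 5), c(-9, -4))
  d3 <- assign_targets(p3, registry3)
  expect_identical(d3$classifier_target, "R")
  expect_identical(d3$regressor_target, "R")
  expect_identical(d3$docking_target, "R")
  expect_identical(d3$consensus_target, "R")
  expect_equal(d3$agreement_k, 3L)
  expect_identical(d3$classifier_class, "A")

  p2 <- fake_profile("c", c("R", "S"), c(5L, 1L), c(8, 5), c(-4, -9))
  d2 <- assign_targets(p2, registry3)
  expect_identical(d2$consensus_target, "R")
  expect_equal(d2$agreement_k, 2L)

  p1 <- fake_profile("c", c("R", "S", "T"), c(5L, 1L, 1L), c(6, 8, 5),
                     c(-4, -5, -9))
  d1 <- assign_targets(p1, registry3)
  expect_identical(d1$consensus_target, NA_character_)
  expect_equal(d1$agreement_k, 1L)
})

test_that("classifier ties break by active probability mass, then name", {
  p <- fake_profile("c", c("S", "R"), c(4L, 4L), c(6, 7), c(-5, -6))
  # equal class and mass -> lexicographic
  d <- assign_targets(p, registry3)
  expect_identical(d$classifier_target, "R")
  # higher active mass wins over name order
  p$class4 <- c(0.9, 0.8); p$class0 <- c(0.1, 0.2)
  expect_identical(assign_targets(p, registry3)$classifier_target, "S")
})

test_that("missing docking makes the docking leg a no-call with k over 2 legs", {
  p <- fake_profile("c", c("R", "S"), c(5L, 1L), c(8, 5),
                    c(NA_real_, NA_real_))
  d <- assign_targets(p, registry3)
  expect_true(is.na(d$docking_target))
  expect_equal(d$agreement_k, 2L)
  expect_identical(d$consensus_target, "R")
})

test_that("a receptor is represented by its more active site entry", {
  p <- dplyr::bind_rows(
    fake_profile("c", "R", 2L, 6.0, -5, site_mode = "orthosteric"),
    fake_profile("c", "R", 5L, 8.5, -10, site_mode = "allosteric"),
    fake_profile("c", "S", 4L, 7.0, -7, site_mode = "orthosteric"))
  d <- assign_targets(p, registry3)
  expect_identical(d$classifier_target, "R")
  expect_identical(d$regressor_target, "R")
  expect_identical(d$docking_target, "R")
})

test_that("profiles join model legs with docking results", {
  lib <- fixture_small_amide_lib()
  bundles <- train_receptor_models(
    lib$activities, lib$compounds,
    classifier_space = test_classifier_space(seed = 21, n_trials = 2),
    regressor_space = test_regressor_space(seed = 21, n_trials = 2))
  site <- binding_site("CCR1", "orthosteric", rbind(c(0, 0, 0)))
  dr <- dock_all(lib$compounds[1, ], list(site))
  prof <- build_profile(lib$compounds[1, ], bundles, dr)
  expect_equal(nrow(prof), 1)
  expect_false(is.na(prof$docking_score))
  prof2 <- build_profile(lib$compounds[1, ], bundles)
  expect_true(is.na(prof2$docking_score))
  expect_error(build_profile(lib$compounds[1, ], c(bundles, bundles)),
               class = "gpcrscreen_config_error")
  expect_error(build_profile(lib$compounds[1, ], list()),
               class = "gpcrscreen_config_error")
})

test_that("precision follows TP / (TP + FP)", {
  # 9 correct, 11 wrong single-leg calls
  n <- 20
  truth <- tibble::tibble(compound_id = paste0("c", 1:n),
                          true_target = "R", true_class = "A")
  dec <- tibble::tibble(
    compound_id = paste0("c", 1:n),
    classifier_target = c(rep("R", 9), rep("S", 11)),
    regressor_target = "R", docking_target = "R",
    classifier_class = c(rep("A", 9), rep("B", 11)),
    regressor_class = "A", docking_class = "A",
    consensus_target = "R", agreement_k = 2L)
  ev <- evaluate_decisions(dec, truth, rules = "classifier")
  tgt <- ev[ev$measure == "target", ]
  expect_equal(tgt$tp, 9)
  expect_equal(tgt$fp, 11)
  expect_equal(tgt$precision, 0.45)
  # all correct under atleast1 -> precision 1
  ev1 <- evaluate_decisions(dec, truth, rules = "atleast1")
  expect_true(all(ev1$precision == 1))
  expect_error(evaluate_decisions(dec[1:2, ], truth[3:4, ]),
               class = "gpcrscreen_truth_error")
})

test_that("TP counts nest across voting rules (vs brute force), any order", {
  brute_tp <- function(dec, truth, need) {
    tp <- 0
    for (i in seq_len(nrow(dec))) {
      tt <- truth$true_target[truth$compound_id == dec$compound_id[i]]
      hits <- sum(c(dec$classifier_target[i], dec$regressor_target[i],
                    dec$docking_target[i]) %in% tt)
      if (hits >= need) tp <- tp + 1
    }
    tp
  }
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    recs <- c("R", "S", "T")
    dec <- tibble::tibble(
      compound_id = paste0("c", 1:n),
      classifier_target = sample(recs, n, TRUE),
      regressor_target = sample(recs, n, TRUE),
      docking_target = sample(recs, n, TRUE),
      classifier_class = "A", regressor_class = "A", docking_class = "A",
      consensus_target = NA_character_, agreement_k = 1L)
    truth <- tibble::tibble(compound_id = paste0("c", 1:n),
                            true_target = sample(recs, n, TRUE),
                            true_class = "A")
    ev <- evaluate_decisions(dec, truth,
                             rules = c("all3", "atleast2", "atleast1"))
    tgt <- ev[ev$measure == "target", ]
    tp <- setNames(tgt$tp, tgt$rule)
    expect_lte(tp[["all3"]], tp[["atleast2"]])
    expect_lte(tp[["atleast2"]], tp[["atleast1"]])
    expect_equal(tp[["all3"]], brute_tp(dec, truth, 3))
    expect_equal(tp[["atleast2"]], brute_tp(dec, truth, 2))
    expect_equal(tp[["atleast1"]], brute_tp(dec, truth, 1))
    # permutation invariance of the decision list
    perm <- sample(n)
    ev_p <- evaluate_decisions(dec[perm, ], truth,
                               rules = c("all3", "atleast2", "atleast1"))
    expect_equal(dplyr::arrange(ev_p, rule, measure),
                 dplyr::arrange(ev, rule, measure))
  }
})

test_that("queries rank against known actives by percentile and z-score", {
  refs <- fake_profile(paste0("ref", 1:5), rep("R", 5), rep(3L, 5),
                       c(5, 6, 7, 8, 9), rep(NA_real_, 5))
  q_top <- fake_profile("q", "R", 4L, 9.5, NA_real_)
  cmp <- compare_to_known(q_top, refs)
  expect_equal(cmp$percentile, 100)
  q_mid <- fake_profile("q", "R", 4L, 7, NA_real_)
  cmp_mid <- compare_to_known(q_mid, refs)
  expect_equal(cmp_mid$percentile, 60)   # 3 of 5 references at or below
  expect_equal(cmp_mid$z_score,
               (7 - mean(c(5, 6, 7, 8, 9))) / sd(c(5, 6, 7, 8, 9)))
  # no references at all -> empty table with a warning
  expect_warning(out <- compare_to_known(q_top, refs[0, ]), "reference")
  expect_equal(nrow(out), 0)
})
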