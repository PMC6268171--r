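test_that("library generation is a pure function of its arguments", {
  a <- synth_library(30, seed = 8)
  b <- synth_library(30, seed = 8)
  expect_identical(attr(a, "labels"), attr(b, "labels"))
  fa <- withr::local_tempfile(fileext = ".smi")
  fb <- withr::local_tempfile(fileext = ".smi")
  write_molecules(a, fa); write_molecules(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(attr(synth_library(30, seed = 9), "labels"),
                         attr(a, "labels")))
  expect_length(synth_library(0), 0)
})

test_that("ground-truth labels agree with the detectors they feed", {
  lib <- synth_library(120, seed = 21, zbg_fraction = 0.5,
                       excluded_fraction = 0.1, violation_fraction = 0.15)
  lab <- attr(lib, "labels")
  ids <- vapply(lib, function(m) m$id, character(1))
  expect_equal(ids, lab$id)
  for (i in seq_along(lib)) {
    classes <- vapply(detect_zbg(lib[[i]]), `[[`, character(1), "class")
    if (!is.na(lab$zbg_class[i]))
      expect_true(lab$zbg_class[i] %in% classes, label = lab$smiles[i])
    if (!is.na(lab$excluded_group[i]))
      expect_length(classes, 0)
  }
  # every engineered violator fails strict Lipinski/Veber
  desc <- compute_descriptors(lib[lab$violates])
  lv <- filter_library(desc, "lipinski_veber")
  expect_true(all(!lv$verdict))
})

test_that("all eight ZBG classes are cycled through", {
  lib <- synth_library(64, seed = 3, zbg_fraction = 1, excluded_fraction = 0,
                       violation_fraction = 0)
  expect_setequal(unique(attr(lib, "labels")$zbg_class),
                  c("carboxyl", "phosphate", "imidazole", "triazole-123",
                    "triazole-124", "tetrazole", "thiadiazole",
                    "hydroxy-oxo-12"))
})

test_that("toy conformers satisfy exactly the intended feature subset", {
  m <- glo1()
  full <- toy_conformer(m, 7, jitter = 0)
  r <- ph_match_points(perceive_ligand_features(full), m)
  expect_equal(r$fit, 7, tolerance = 1e-9)
  expect_null(ph_match_points(perceive_ligand_features(toy_conformer(m, 3)), m))
  toy5 <- toy_conformer(m, 5, jitter = 0.5, seed = 6)
  r5 <- ph_match_points(perceive_ligand_features(toy5), m)
  expect_equal(r5$mapped_count, 5L)
  expect_gte(r5$fit, 5 * (1 - 0.5 / 1.6) - 1e-6)
  expect_true(all(m$mandatory %in% attr(toy5, "intended")))
})

test_that("score tables cover six functions per candidate deterministically", {
  tab <- synth_score_table(paste0("x", 1:10), seed = 2)
  st <- load_scores(tab)
  expect_equal(nrow(st$best), 10)
  expect_equal(sum(!is.na(as.matrix(st$best[, names(SCORE_DIRECTIONS)]))), 60)
  expect_identical(tab, synth_score_table(paste0("x", 1:10), seed = 2))
  expect_error(synth_score_table(character(0)), "non-empty")
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_library(5, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})
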