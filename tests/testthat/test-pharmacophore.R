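test_that("the packaged Glo-1 model has the published composition", {
  m <- glo1()
  expect_length(m$features, 7)
  kinds <- table(vapply(m$features, function(f) f$kind, character(1)))
  expect_equal(kinds[["ZB"]], 1)
  expect_equal(kinds[["HY"]], 2)
  expect_equal(kinds[["HBD"]], 2)
  expect_equal(kinds[["HBA"]], 1)
  expect_equal(kinds[["NI"]], 1)
  expect_equal(m$min_required, 4L)
  expect_length(m$mandatory, 2)
  # mandatory = ZB plus the HY nearest to it
  ids <- feature_ids(m); kindv <- feature_kinds(m)
  zb <- which(kindv == "ZB")
  hy <- which(kindv == "HY")
  d_hy <- vapply(hy, function(i)
    sqrt(sum((m$features[[i]]$center - m$features[[zb]]$center)^2)), numeric(1))
  expect_setequal(m$mandatory, c(ids[zb], ids[hy[which.min(d_hy)]]))
  ann <- paste(vapply(m$features, function(f) f$annotation, character(1)),
               collapse = " ")
  for (res in c("Asn103", "Thr101", "Lys156", "Arg122", "Zn"))
    expect_match(ann, res, fixed = TRUE)
})

test_that("model files round-trip and corrupt files are refused", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ph_model(glo1(), f)
  back <- read_ph_model(f)
  expect_equal(feature_kinds(back), feature_kinds(glo1()))
  expect_equal(back$min_required, glo1()$min_required)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nothing: here", bad)
  expect_error(read_ph_model(bad), "corrupt")
})

test_that("model invariants are enforced at construction", {
  f1 <- ph_feature("A", "ZB", c(0, 0, 0))
  f2 <- ph_feature("B", "ZB", c(3, 0, 0))
  expect_error(ph_model(list(f1, f2), 1), "at most one ZB")
  expect_error(ph_model(list(f1), 2), "min_required")
  expect_error(ph_model(list(f1), 1, mandatory = "nope"), "mandatory")
  expect_error(ph_feature("X", "HY", c(0, 0, 0), tolerance = 0), "tolerance")
  expect_error(ph_feature("X", "HY", c(0, 0, 0),
                          projection = list(target = c(1, 0, 0))),
               "directional")
})

test_that("customize_zb re-types the zinc-oriented donor exactly once", {
  zn <- c(1, 1, 1)
  feats <- list(
    ph_feature("D1", "HBD", zn + c(0, 0, 2.0),
               projection = list(target = zn, angle_tol = 45)),
    ph_feature("D2", "HBD", zn + c(8, 0, 0),
               projection = list(target = zn + c(10, 0, 0), angle_tol = 45)),
    ph_feature("H1", "HY", zn + c(4, 4, 0)))
  m <- ph_model(feats, 3)
  cz <- customize_zb(m, zn)
  expect_equal(feature_kinds(cz), c("ZB", "HBD", "HY"))
  expect_equal(cz$features[[1]]$center, feats[[1]]$center)
  expect_identical(customize_zb(cz, zn), cz)   # idempotent
  far <- ph_model(feats[2:3], 2)
  expect_error(customize_zb(far, zn), "no feature orients")
})

test_that("ligand feature perception applies its documented rules", {
  benzene <- mol1("c1ccccc1", "benz")
  benzene$coords <- cbind(cos(pi * (0:5) / 3), sin(pi * (0:5) / 3), 0)
  pts <- perceive_ligand_features(benzene)
  kinds <- vapply(pts, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "RA"), 1)
  expect_equal(sum(kinds == "HY"), 1)
  expect_false(any(kinds %in% c("HBA", "HBD", "NI", "PI", "ZB")))

  acet <- mol1("CC(=O)[O-]", "acetate")
  acet$coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0),
                       c(2.2, -1.1, 0))
  pts <- perceive_ligand_features(acet)
  kinds <- vapply(pts, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "NI"), 1)
  expect_equal(sum(kinds == "ZB"), 1)
  ni <- pts[[which(kinds == "NI")]]; zb <- pts[[which(kinds == "ZB")]]
  expect_equal(zb$position, colMeans(acet$coords[3:4, ]))
  expect_equal(zb$zbg$class, "carboxyl")

  methane <- mol1("C", "methane")
  methane$coords <- matrix(0, 1, 3)
  expect_length(perceive_ligand_features(methane), 0)
  expect_error(perceive_ligand_features(mol1("CC", "dry")), "coordinates")
})

test_that("a perfect five-point placement scores fit = 5 exactly", {
  m <- glo1()
  toy <- toy_conformer(m, 5)
  r <- ph_match_points(perceive_ligand_features(toy), m)
  expect_false(is.null(r))
  expect_equal(r$fit, 5.0, tolerance = 1e-9)
  expect_equal(r$mapped_count, 5L)
  expect_setequal(attr(toy, "intended"), names(r$assignment))
})

test_that("three satisfied features are below the minimum of four", {
  m <- glo1()
  toy <- toy_conformer(m, 3)
  expect_null(ph_match_points(perceive_ligand_features(toy), m))
})

test_that("jittered placements stay within the displacement bound", {
  m <- glo1()
  for (sd in 1:3) {
    toy <- toy_conformer(m, 5, jitter = 0.5, seed = sd)
    r <- ph_match_points(perceive_ligand_features(toy), m)
    expect_false(is.null(r))
    expect_equal(r$mapped_count, 5L)
    expect_gte(r$fit, 5 * (1 - 0.5 / 1.6) - 1e-6)
  }
})

test_that("matches re-verify their own invariants", {
  m <- glo1()
  for (k in c(4, 5, 7)) {
    toy <- toy_conformer(m, k, jitter = 0.3, seed = k)
    pts <- perceive_ligand_features(toy)
    r <- ph_match_points(pts, m)
    expect_true(verify_match(r, pts, m))
    expect_gte(r$fit, 0)
    expect_lte(r$fit, r$mapped_count)
    expect_lte(r$mapped_count, length(m$features))
    expect_true(all(model_tols <- vapply(names(r$assignment), function(id)
      r$displacements[[id]] <=
        m$features[[which(feature_ids(m) == id)]]$tolerance + 1e-9,
      logical(1))))
    expect_true(all(m$mandatory %in% names(r$assignment)))
  }
})

test_that("the best fit is invariant under rigid motion of the conformer", {
  m <- glo1()
  toy <- toy_conformer(m, 5, jitter = 0.4, seed = 2)
  pts <- perceive_ligand_features(toy)
  r0 <- ph_match_points(pts, m)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  toy2 <- toy
  toy2$coords <- sweep(t(R %*% t(toy$coords)), 2, c(4, -7, 2), `+`)
  r1 <- ph_match_points(perceive_ligand_features(toy2), m)
  expect_equal(r1$fit, r0$fit, tolerance = 1e-6)
})

test_that("the optimized matcher agrees with the exhaustive transform oracle", {
  m <- glo1()
  sets <- list(c("ZB1", "HY1", "HY2", "HBD1"),
               c("ZB1", "HY1", "HBD1", "HBD2", "NI1"),
               c("ZB1", "HY1", "HY2", "HBD2", "HBA1", "NI1"))
  for (sd in seq_along(sets)) {
    pts <- make_points(m, sets[[sd]], jitter = 0.3, seed = sd + 10)
    expect_lte(length(pts), 6)
    got <- ph_match_points(pts, m)
    want <- oracle_match_fit(pts, m)
    expect_false(is.null(got))
    expect_false(is.null(want))
    expect_equal(got$fit, want, tolerance = 1e-3)
  }
})

test_that("conformer ensembles respect the cap and the energy window", {
  c20 <- mol1(paste(rep("C", 20), collapse = ""), "c20")
  ens <- embed_conformers(c20, max_confs = 255, energy_window = Inf, seed = 3)
  expect_equal(ens$generated, 255)
  expect_equal(length(ens$conformers), 255)
  ens2 <- embed_conformers(c20, max_confs = 40, energy_window = 20, seed = 3)
  expect_equal(ens2$generated, 40)
  expect_lte(length(ens2$conformers), 40)
  expect_true(all(ens2$energies <= min(ens2$energies) + 20))
  # determinism under the seed
  a <- embed_conformers(c20, 10, 20, seed = 9)
  b <- embed_conformers(c20, 10, 20, seed = 9)
  expect_identical(a, b)
})

test_that("screening finds the planted binder and reports funnel counts", {
  m <- glo1()
  binder <- toy_conformer(m, 5, jitter = 0.2, seed = 4)
  binder$id <- "binder"
  decoys <- small_db()[1:6]
  scr <- ph_screen(c(list(binder), decoys), m, max_confs = 4, seed = 1)
  expect_true("binder" %in% scr$hits$id)
  expect_gte(scr$hits$mapped[scr$hits$id == "binder"], 4)
  expect_equal(scr$counts$input, 7)
  expect_gte(scr$counts$matched, 1)
  empty <- ph_screen(list(), m)
  expect_equal(nrow(empty$hits), 0)
  expect_equal(empty$counts$input, 0)
})
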