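test_that("every allowed class exemplar is detected exactly once", {
  panel <- zbg_panel()
  for (m in panel) {
    hits <- detect_zbg(m)
    expect_length(hits, 1)
    expect_equal(hits[[1]]$class, m$id)
  }
})

test_that("hydroxamates and thiols are never reported", {
  for (m in zbg_exclusion_panel())
    expect_length(detect_zbg(m), 0)
})

test_that("an allowed class is still reported next to an excluded group", {
  both <- mol1("OC(=O)CCS", "mercaptoacid")          # carboxyl + thiol
  hits <- detect_zbg(both)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$class, "carboxyl")
  hx <- mol1("OC(=O)CCC(=O)NO", "succinate_hydroxamate")
  classes <- vapply(detect_zbg(hx), `[[`, character(1), "class")
  expect_equal(classes, "carboxyl")
})

test_that("matched and coordinating atoms are valid and lone-pair bearing", {
  for (m in c(zbg_panel(), list(mol1("OC(=O)c1ccc(cc1)c1nnn[nH]1", "multi")))) {
    for (hit in detect_zbg(m)) {
      expect_true(all(hit$atoms >= 1 & hit$atoms <= n_atoms(m)))
      expect_true(all(hit$coordinating %in% hit$atoms))
      expect_true(all(m$atoms$element[hit$coordinating] %in% c("N", "O")))
    }
  }
})

test_that("detection is invariant under atom reordering", {
  m <- mol1("CC(=O)O", "acet")
  perm <- c(4, 2, 1, 3); inv <- order(perm)
  m2 <- mol_record("acet2", m$atoms[perm, ],
                   data.frame(a1 = inv[m$bonds$a1], a2 = inv[m$bonds$a2],
                              order = m$bonds$order))
  h1 <- detect_zbg(m); h2 <- detect_zbg(m2)
  expect_equal(h1[[1]]$class, h2[[1]]$class)
  expect_equal(m$atoms$element[h1[[1]]$coordinating],
               m2$atoms$element[h2[[1]]$coordinating])
})

test_that("azole detection is tautomer-drawing invariant", {
  a <- mol1("c1cnc[nH]1", "imid_a")     # NH drawn on one nitrogen
  b <- mol1("C1=CN=CN1", "imid_b")      # kekulized, NH on the other
  expect_equal(detect_zbg(a)[[1]]$class, "imidazole")
  expect_equal(detect_zbg(b)[[1]]$class, "imidazole")
})

test_that("deprotonated forms match their parent class", {
  for (smi in c("CC(=O)[O-]", "[O-]C(=O)c1ccccc1")) {
    hits <- detect_zbg(mol1(smi, "anion"))
    expect_length(hits, 1)
    expect_equal(hits[[1]]$class, "carboxyl")
  }
})

test_that("flavonoid-style keto-hydroxyl cores are the hydroxy-oxo class", {
  chromone <- mol1("Oc1cccc2OC=CC(=O)c12", "hydroxychromone")
  hits <- detect_zbg(chromone)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$class, "hydroxy-oxo-12")
  coord_el <- chromone$atoms$element[hits[[1]]$coordinating]
  expect_equal(sort(coord_el), c("O", "O"))
  # catechol: two hydroxyls, no carbonyl -> intentionally not covered
  expect_length(detect_zbg(mol1("Oc1ccccc1O", "catechol")), 0)
  expect_length(detect_zbg(mol1("C1CCCCC1", "cyclohexane")), 0)
})

test_that("the chelation window is [2.0, 3.0] with midpoint 2.5", {
  expect_true(chelation_geometry_ok(c(0, 0, 0), c(2.5, 0, 0)))
  expect_false(chelation_geometry_ok(c(0, 0, 0), c(1.9, 0, 0)))
  dists <- seq(1, 4, by = 0.01)
  ok <- vapply(dists, function(d)
    chelation_geometry_ok(c(0, 0, 0), c(d, 0, 0)), logical(1))
  accepted <- dists[ok]
  expect_equal(min(accepted), 2.00, tolerance = 1e-9)
  expect_equal(max(accepted), 3.00, tolerance = 1e-9)
  expect_equal(mean(range(accepted)), 2.50, tolerance = 1e-9)
})
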