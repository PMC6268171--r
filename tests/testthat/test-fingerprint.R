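test_that("fingerprints are deterministic and atom-order invariant", {
  m <- mol1("c1ccccc1", "benzene")
  f1 <- fingerprint(m, "atom-type")
  f2 <- fingerprint(m, "atom-type")
  expect_identical(f1$entries, f2$entries)
  perm <- c(3, 1, 2, 6, 4, 5); inv <- order(perm)
  m2 <- mol_record("benzene_d", m$atoms[perm, ],
                   data.frame(a1 = inv[m$bonds$a1], a2 = inv[m$bonds$a2],
                              order = m$bonds$order))
  f3 <- fingerprint(m2, "atom-type")
  expect_identical(f1$entries[order(names(f1$entries))],
                   f3$entries[order(names(f3$entries))])
})

test_that("related molecules share and distinguish environments", {
  fps <- lapply(parse_smiles(c("CCO", "CCCO"), c("eth", "prop")),
                fingerprint, scheme = "atom-type")
  comp <- fp_components(fps[[1]], fps[[2]])
  expect_gt(comp$SA, 0)
  expect_gt(comp$SB, 0)
  expect_gt(comp$SC, 0)
})

test_that("components agree with an explicit multiset oracle", {
  t1 <- structure(list(entries = c(a = 1, b = 1, c = 1), scheme = "atom-type",
                       max_distance = 6L, mode = "bit"), class = "sparse_fp")
  r1 <- structure(list(entries = c(b = 1, c = 1, d = 1), scheme = "atom-type",
                       max_distance = 6L, mode = "bit"), class = "sparse_fp")
  cb <- fp_components(t1, r1, "bit")
  expect_equal(cb[c("SA", "SB", "SC")], list(SA = 2, SB = 1, SC = 1))
  t2 <- structure(list(entries = c(a = 3), scheme = "atom-type",
                       max_distance = 6L, mode = "count"), class = "sparse_fp")
  r2 <- structure(list(entries = c(a = 1), scheme = "atom-type",
                       max_distance = 6L, mode = "count"), class = "sparse_fp")
  cc <- fp_components(t2, r2, "count")
  expect_equal(cc[c("SA", "SB", "SC")], list(SA = 1, SB = 2, SC = 0))
  set.seed(7)
  for (i in 1:20) {
    a <- random_sparse_fp(sample(3:20, 1))
    b <- random_sparse_fp(sample(3:20, 1))
    for (mode in c("bit", "count")) {
      got <- fp_components(a, b, mode)
      want <- oracle_components(a$entries, b$entries, mode)
      expect_equal(got[c("SA", "SB", "SC")], want)
    }
  }
})

test_that("scheme mismatches are refused", {
  a <- fingerprint(mol1("CCO"), "atom-type")
  b <- fingerprint(mol1("CCO"), "functional-class")
  expect_error(fp_components(a, b), "mismatch")
})

test_that("the three measures evaluate their printed formulas", {
  comp <- list(SA = 2, SB = 1, SC = 1, mode = "bit")
  expect_equal(fp_similarity(comp, "tanimoto"), 0.5)
  expect_equal(fp_similarity(comp, "dice"), 0.6667, tolerance = 1e-4)
  expect_equal(fp_similarity(comp, "cosine"), 0.6667, tolerance = 1e-4)
  f <- fingerprint(mol1("CC(=O)O"), "atom-type")
  for (ms in c("tanimoto", "dice", "cosine"))
    expect_equal(fp_similarity(fp_components(f, f), ms), 1.0)
  g <- list(SA = 0, SB = 5, SC = 7, mode = "bit")
  for (ms in c("tanimoto", "dice", "cosine"))
    expect_equal(fp_similarity(g, ms), 0)
  expect_warning(z <- fp_similarity(list(SA = 0, SB = 0, SC = 0), "tanimoto"),
                 "convention")
  expect_equal(z, 0)
  expect_error(fp_similarity(list(SA = -1, SB = 0, SC = 0), "dice"),
               "negative")
})

test_that("similarity laws hold on randomized components", {
  set.seed(11)
  for (i in 1:200) {
    sa <- sample(1:30, 1); sb <- sample(0:30, 1); sc <- sample(0:30, 1)
    comp <- list(SA = sa, SB = sb, SC = sc)
    t <- fp_similarity(comp, "tanimoto")
    d <- fp_similarity(comp, "dice")
    co <- fp_similarity(comp, "cosine")
    for (v in c(t, d, co)) { expect_gte(v, 0); expect_lte(v, 1) }
    expect_gte(d, t)                       # dice = 2T/(1+T) >= T
    expect_equal(d, 2 * t / (1 + t), tolerance = 1e-12)
    expect_gte(co + 1e-12, t)              # AM-GM
    # symmetry: swapping target and reference swaps SB and SC only
    rev_comp <- list(SA = sa, SB = sc, SC = sb)
    for (ms in c("tanimoto", "dice", "cosine"))
      expect_equal(fp_similarity(comp, ms), fp_similarity(rev_comp, ms))
  }
})

test_that("top-k search equals an exhaustive scan oracle", {
  db <- small_db()
  ids <- vapply(db, function(m) m$id, character(1))
  for (scheme in c("atom-type", "functional-class")) {
    db_fps <- lapply(db, fingerprint, scheme = scheme)
    names(db_fps) <- ids
    ref <- fingerprint(db[[7]], scheme)
    for (measure in c("tanimoto", "dice", "cosine")) {
      got <- top_k_similar(ref, db_fps, 10, measure, scheme)
      want <- oracle_top_k(ref, db_fps, 10, measure)
      expect_equal(got$target_id, want$target_id)
      expect_equal(got$similarity, want$similarity)
      expect_false(is.unsorted(-got$similarity))
    }
  }
})

test_that("a reference contained in the database ranks first at 1.0", {
  db <- small_db()
  hl <- top_k_similar(db[[3]], db, 5, "tanimoto", "atom-type")
  expect_equal(hl$target_id[1], db[[3]]$id)
  expect_equal(hl$similarity[1], 1.0)
})

test_that("k larger than the database returns everything", {
  db <- small_db()[1:3]
  hl <- top_k_similar(db[[1]], db, 500, "dice", "atom-type")
  expect_equal(nrow(hl), 3)
  expect_warning(empty <- top_k_similar(db[[1]], list(), 5), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the battery emits one run per reference x measure x scheme", {
  db <- small_db()
  refs <- db[c(2, 9)]
  hl <- run_similarity_battery(refs, db, k = 10)
  expect_equal(nrow(hl), 2 * 3 * 2 * 10)
  expect_equal(length(unique(hl$run_id)), 12)
  hl1 <- run_similarity_battery(db[1], db[1:7], k = 500,
                                measures = "tanimoto", schemes = "atom-type")
  expect_equal(nrow(hl1), 7)
  expect_error(run_similarity_battery(list(), db, 5), "non-empty")
})
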