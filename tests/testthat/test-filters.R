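desc_row <- function(mw = 300, clogp = 2, hbd = 1, hba = 4, rotb = 3,
                     tpsa = 60, id = "d") {
  data.frame(id = id, mw = mw, clogp = clogp, hbd = hbd, hba = hba,
             rotb = rotb, tpsa = tpsa)
}

test_that("compliant descriptors pass with zero violations", {
  r <- lipinski_veber(desc_row())
  expect_true(r$verdict)
  expect_equal(r$violations, 0)
  expect_equal(nrow(r$rules), 6)
})

test_that("the molecular weight rule is strictly below 500", {
  r <- lipinski_veber(desc_row(mw = 500))
  expect_false(r$verdict)
  expect_equal(r$violations, 1)
  expect_true(lipinski_veber(desc_row(mw = 500), max_violations = 1)$verdict)
  expect_true(lipinski_veber(desc_row(mw = 499.999))$verdict)
})

test_that("every rule flips exactly at its documented boundary", {
  eps <- 1e-9
  cases <- list(
    list(field = "hbd", limit = 5, strict = FALSE),
    list(field = "hba", limit = 10, strict = FALSE),
    list(field = "clogp", limit = 5, strict = FALSE),
    list(field = "mw", limit = 500, strict = TRUE),
    list(field = "rotb", limit = 10, strict = FALSE),
    list(field = "tpsa", limit = 140, strict = FALSE))
  for (cs in cases) {
    at <- desc_row(); at[[cs$field]] <- cs$limit
    above <- desc_row(); above[[cs$field]] <- cs$limit + eps
    below <- desc_row(); below[[cs$field]] <- cs$limit - eps
    expect_equal(lipinski_veber(at)$verdict, !cs$strict, label = cs$field)
    expect_false(lipinski_veber(above)$verdict, label = cs$field)
    expect_true(lipinski_veber(below)$verdict, label = cs$field)
  }
})

test_that("worsening any descriptor never turns a fail into a pass", {
  set.seed(5)
  fields <- c("mw", "clogp", "hbd", "hba", "rotb", "tpsa")
  for (i in 1:100) {
    d <- desc_row(mw = runif(1, 100, 700), clogp = runif(1, -2, 8),
                  hbd = sample(0:8, 1), hba = sample(0:14, 1),
                  rotb = sample(0:14, 1), tpsa = runif(1, 0, 200))
    before <- lipinski_veber(d)
    f <- sample(fields, 1)
    d2 <- d; d2[[f]] <- d2[[f]] + runif(1, 0, 100)
    after <- lipinski_veber(d2)
    if (!before$verdict) expect_false(after$verdict)
    expect_gte(after$violations, before$violations)
    # verdict/violation consistency on both draws
    expect_equal(before$verdict, before$violations <= 0)
    expect_equal(after$verdict, after$violations <= 0)
  }
})

test_that("ADMET proxies implement their documented windows", {
  ok <- admet_proxy(desc_row(clogp = 2, tpsa = 60))
  expect_true(ok$verdict)
  expect_true(all(ok$rules$pass))
  poor_abs <- admet_proxy(desc_row(tpsa = 200))
  expect_false(poor_abs$rules$pass[poor_abs$rules$rule == "absorption"])
  expect_false(poor_abs$verdict)
  insol <- admet_proxy(desc_row(clogp = 7, tpsa = 50))
  expect_false(insol$rules$pass[insol$rules$rule == "solubility"])
  # BBB is a reported flag, not an exclusion, unless requested
  cns_neg <- desc_row(clogp = 0.5, tpsa = 60)
  expect_true(admet_proxy(cns_neg)$verdict)
  expect_false(admet_proxy(cns_neg)$rules$pass[3])
  expect_false(admet_proxy(cns_neg, bbb_required = TRUE)$verdict)
})

test_that("filter_library summarizes verdicts per molecule", {
  d <- rbind(desc_row(id = "ok"), desc_row(id = "heavy", mw = 650))
  lv <- filter_library(d, "lipinski_veber")
  expect_equal(lv$verdict, c(TRUE, FALSE))
  rows <- filter_report_rows(list(lipinski_veber(d[1, ]), admet_proxy(d[1, ])))
  expect_equal(nrow(rows), 9)
})
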