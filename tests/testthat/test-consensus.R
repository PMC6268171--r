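score_fixture <- function() {
  # three candidates, hand-computable: best-pose values below
  rows <- expand.grid(candidate_id = c("cA", "cB", "cC"),
                      score_name = names(SCORE_DIRECTIONS),
                      stringsAsFactors = FALSE)
  vals <- c(
    cA = 0, cB = 0, cC = 0)
  base <- list(
    cA = c(GoldScore = 60, ChemScore = 50, ASP = 40, CHEMPLP = 55,
           CDOCKER = -40, LibDock = 120),
    cB = c(GoldScore = 50, ChemScore = 45, ASP = 35, CHEMPLP = 50,
           CDOCKER = -30, LibDock = 100),
    cC = c(GoldScore = 55, ChemScore = 60, ASP = 30, CHEMPLP = 45,
           CDOCKER = -50, LibDock = 90))
  do.call(rbind, lapply(names(base), function(cid)
    data.frame(candidate_id = cid, pose_id = "pose1",
               score_name = names(base[[cid]]), value = unname(base[[cid]]))))
}

test_that("score tables load, validate, and select the direction-best pose", {
  df <- score_fixture()
  st <- load_scores(df)
  expect_equal(nrow(st$best), 3)
  expect_length(st$incomplete, 0)
  # second pose per candidate per score: keep max for higher-better,
  # min for lower-better
  df2 <- df
  df2$pose_id <- "pose2"
  df2$value <- df2$value + 5
  st2 <- load_scores(rbind(df, df2))
  expect_equal(st2$best$GoldScore[st2$best$candidate_id == "cA"], 65)
  expect_equal(st2$best$CDOCKER[st2$best$candidate_id == "cA"], -40)
  # a candidate missing one score is flagged incomplete and excluded
  df3 <- df[!(df$candidate_id == "cB" & df$score_name == "LibDock"), ]
  st3 <- load_scores(df3)
  expect_equal(st3$incomplete, "cB")
  expect_equal(nrow(st3$best), 2)
  dfbad <- df; dfbad$score_name[1] <- "Vina"
  expect_error(load_scores(dfbad), "unknown score name")
})

test_that("raw_sum consensus equals hand-computed sign-corrected sums", {
  st <- load_scores(score_fixture())
  cr <- consensus_rank(st, "raw_sum")
  # hand sums: cA 60+50+40+55+40+120 = 365; cB 50+45+35+50+30+100 = 310;
  #            cC 55+60+30+45+50+90 = 330 (CDOCKER negated)
  expect_equal(cr$consensus[cr$candidate_id == "cA"], 365)
  expect_equal(cr$consensus[cr$candidate_id == "cB"], 310)
  expect_equal(cr$consensus[cr$candidate_id == "cC"], 330)
  expect_equal(cr$candidate_id, c("cA", "cC", "cB"))
  expect_equal(cr$rank, 1:3)
  single <- load_scores(score_fixture()[score_fixture()$candidate_id == "cA", ])
  expect_equal(consensus_rank(single)$rank, 1)
})

test_that("a candidate dominating on all six scores ranks first both ways", {
  tab <- synth_score_table(paste0("m", 1:8), seed = 13)
  st <- load_scores(tab)
  for (method in c("raw_sum", "rank_sum"))
    expect_equal(consensus_rank(st, method)$candidate_id[1], attr(tab, "plant"))
})

test_that("raw_sum ranking is invariant to constant shifts of one score", {
  st <- load_scores(score_fixture())
  shifted <- st
  shifted$best$ASP <- shifted$best$ASP + 1000
  expect_equal(consensus_rank(shifted, "raw_sum")$candidate_id,
               consensus_rank(st, "raw_sum")$candidate_id)
})

test_that("rank_sum is invariant under monotone transforms of one score", {
  st <- load_scores(score_fixture())
  tr <- st
  tr$best$GoldScore <- exp(tr$best$GoldScore / 20)   # strictly increasing
  expect_equal(consensus_rank(tr, "rank_sum")$candidate_id,
               consensus_rank(st, "rank_sum")$candidate_id)
})

test_that("final selection joins consensus with fit values", {
  st <- load_scores(score_fixture())
  cr <- consensus_rank(st)
  hits <- data.frame(id = c("cA", "cC", "cZ"), fit = c(4.3, 5.1, 6.0))
  rep9 <- select_candidates(cr, hits, top_n = 9)
  expect_equal(nrow(rep9), 2)           # whole join when top_n exceeds it
  expect_equal(names(rep9), c("candidate_id", "consensus", "rank", "fit"))
  expect_equal(rep9$candidate_id, c("cA", "cC"))
  one <- select_candidates(cr, hits, top_n = 1)
  expect_equal(nrow(one), 1)
  expect_warning(none <- select_candidates(cr, data.frame(id = "q", fit = 1)),
                 "no overlap")
  expect_equal(nrow(none), 0)
})
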