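# Consensus aggregation of external docking scores. Docking itself is out
# of scope: the module ingests score tables produced by external programs
# (or the synthetic generator). The direction map is explicit, versioned
# configuration: the four GOLD fitness functions and LibDock are
# higher-better, CDOCKER interaction energies are lower-better and are
# negated before raw summation.

#' Default direction map for the six docking score functions
#'
#' +1 = higher is better (GoldScore, ChemScore, ASP, CHEMPLP, LibDock),
#' -1 = lower is better (CDOCKER interaction energy).
#' @export
SCORE_DIRECTIONS <- c(GoldScore = 1, ChemScore = 1, ASP = 1, CHEMPLP = 1,
                      CDOCKER = -1, LibDock = 1)

#' Load and validate a docking score table
#'
#' Expects columns candidate_id, pose_id, score_name, value. Per candidate
#' and score the direction-best pose is retained. Candidates missing any of
#' the six score functions are flagged incomplete and excluded from
#' consensus by default.
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @param directions named direction map (+1 higher-better, -1 lower-better).
#' @return `score_table`: list with `best` (wide data.frame, one row per
#'   complete candidate), `incomplete` (ids), `directions`.
#' @export
load_scores <- function(path, directions = SCORE_DIRECTIONS) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("candidate_id", "pose_id", "score_name", "value")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(df$score_name), names(directions))
  if (length(unknown))
    stop("unknown score name(s): ", paste(unknown, collapse = ", "))
  cands <- unique(df$candidate_id)
  wide <- data.frame(candidate_id = cands)
  for (sn in names(directions)) {
    sub <- df[df$score_name == sn, ]
    agg <- if (nrow(sub)) {
      f <- if (directions[[sn]] > 0) max else min
      tapply(sub$value, sub$candidate_id, f)
    } else numeric(0)
    wide[[sn]] <- as.numeric(agg[match(cands, names(agg))])
  }
  complete <- stats::complete.cases(wide[, names(directions)])
  structure(list(best = wide[complete, , drop = FALSE],
                 incomplete = cands[!complete],
                 directions = directions),
            class = "score_table")
}

#' Consensus ranking of docking scores
#'
#' `raw_sum`: every score is sign-normalized to higher-better (lower-better
#' scores negated) and summed across the six functions. `rank_sum`:
#' per-score direction-aware ranks (best = 1) are summed, lower sum better.
#' Ranking is deterministic; ties are broken by candidate id.
#'
#' @param table a `score_table` from [load_scores()].
#' @param method `"raw_sum"` or `"rank_sum"`.
#' @return data.frame (candidate_id, consensus, rank), best first.
#' @export
consensus_rank <- function(table, method = c("raw_sum", "rank_sum")) {
  method <- match.arg(method)
  best <- table$best
  if (!nrow(best)) stop("no complete candidates for consensus")
  dirs <- table$directions
  sc <- as.matrix(best[, names(dirs)])
  if (method == "raw_sum") {
    val <- as.numeric(sc %*% unname(dirs))
    ord <- order(-val, best$candidate_id)
  } else {
    rk <- apply(sweep(sc, 2, unname(dirs), `*`), 2,
                function(col) rank(-col, ties.method = "average"))
    val <- rowSums(rk)
    ord <- order(val, best$candidate_id)
  }
  data.frame(candidate_id = best$candidate_id[ord], consensus = val[ord],
             rank = seq_along(ord))
}

#' Join consensus ranking with pharmacophore fit values
#'
#' Inner join keyed by candidate id; the report carries both columns so the
#' consensus-vs-fit comparison is explicit. Candidates are ordered by
#' consensus rank and truncated to `top_n`.
#'
#' @param consensus data.frame from [consensus_rank()].
#' @param hits pharmacophore hit data.frame with columns `id` and `fit`.
#' @param top_n rows to keep (default 9).
#' @return data.frame (candidate_id, consensus, rank, fit).
#' @export
select_candidates <- function(consensus, hits, top_n = 9L) {
  joined <- merge(consensus, hits[, c("id", "fit")],
                  by.x = "candidate_id", by.y = "id")
  if (!nrow(joined)) {
    warning("no overlap between consensus ranking and pharmacophore hits",
            call. = FALSE)
    return(data.frame(candidate_id = character(0), consensus = numeric(0),
                      rank = integer(0), fit = numeric(0)))
  }
  joined <- joined[order(joined$rank), , drop = FALSE]
  rownames(joined) <- NULL
  utils::head(joined, top_n)
}
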