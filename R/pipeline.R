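# End-to-end screening funnel: similarity battery -> merge -> deduplicate
# -> Lipinski/Veber -> ADMET -> ligand enumeration -> pharmacophore screen
# -> consensus. Stage order is fixed; record counts are non-increasing at
# every stage except enumeration. Every stage's artifact is persisted and
# the whole run is a pure function of the config (seeds included).

#' Run the full screening funnel
#'
#' @param config a list or path to a YAML file with entries:
#'   \describe{
#'     \item{run_dir}{output directory for stage artifacts.}
#'     \item{seed}{master seed; all stage randomness derives from it.}
#'     \item{references}{character vector of SMILES, or a `.smi` path.}
#'     \item{library}{a `.smi`/`.sdf` path, or a list
#'       `(n, zbg_fraction, violation_fraction)` for a synthetic library.}
#'     \item{k}{hits per similarity run (default 500).}
#'     \item{measures,schemes}{similarity battery settings.}
#'     \item{max_violations}{Lipinski/Veber tolerance (default 0).}
#'     \item{admet}{logical, run the ADMET proxies (default TRUE).}
#'     \item{enumerate}{logical, run ligand enumeration (default TRUE).}
#'     \item{model}{pharmacophore model path, or `"glo1"` (default).}
#'     \item{max_confs,energy_window}{conformer settings (default 32 / 20).}
#'     \item{scores}{optional docking score CSV, or `"synthetic"`.}
#'     \item{top_n}{final candidates reported (default 9).}
#'   }
#' @return a `funnel_report` list: per-stage counts and parameters, seed
#'   registry, paths of stage artifacts; also written as JSON to the run
#'   directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    # YAML 1.1 parses a bare `n:` mapping key as boolean FALSE; restore it
    if (is.list(config$library)) {
      nm <- names(config$library)
      names(config$library)[nm %in% c("FALSE", "no")] <- "n"
    }
  }
  cfg <- config
  if (is.list(cfg$library) && is.null(cfg$library$n))
    cfg$library$n <- cfg$library$size
  run_dir <- cfg$run_dir %||% tempfile("zbrun")
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  k <- as.integer(cfg$k %||% 500L)
  measures <- cfg$measures %||% c("tanimoto", "dice", "cosine")
  schemes <- cfg$schemes %||% c("functional-class", "atom-type")
  max_violations <- as.integer(cfg$max_violations %||% 0L)
  stages <- list()
  t_all <- list()
  tick <- function(name, n_in, n_out, params = list()) {
    stages[[length(stages) + 1]] <<- list(stage = name, n_in = n_in,
                                          n_out = n_out, params = params)
    message(sprintf("[%s] %d -> %d", name, n_in, n_out))
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    t_all[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- inputs -----------------------------------------------------------
  refs <- if (length(cfg$references) == 1 && file.exists(cfg$references[1]))
    read_molecules(cfg$references[1])
  else parse_smiles(unlist(cfg$references),
                    paste0("ref", seq_along(unlist(cfg$references))))
  library_mols <- if (is.list(cfg$library))
    synth_library(cfg$library$n %||% 1000L, derive_seed(seed, "library"),
                  cfg$library$zbg_fraction %||% 0.35,
                  cfg$library$violation_fraction %||% 0.1)
  else read_molecules(cfg$library)

  if (!length(library_mols)) {
    empty_stages <- c("similarity_battery", "merge", "deduplicate",
                      "lipinski_veber", "admet", "enumerate_forms",
                      "pharmacophore_screen")
    for (s in empty_stages) tick(s, 0L, 0L)
    report <- funnel_report(stages, seed, run_dir, t_all, complete = TRUE)
    write_funnel_report(report, file.path(run_dir, "funnel_report.json"))
    return(report)
  }

  # --- 1. similarity battery -------------------------------------------
  hitlist <- timed("similarity_battery",
    run_similarity_battery(refs, library_mols, k, measures, schemes))
  utils::write.csv(hitlist, file.path(run_dir, "01_hitlist.csv"),
                   row.names = FALSE)
  tick("similarity_battery", length(library_mols), nrow(hitlist),
       list(k = k, n_ref = length(refs), measures = measures,
            schemes = schemes))

  # --- 2. merge ---------------------------------------------------------
  merged_ids <- unique(hitlist$target_id)
  by_id <- stats::setNames(library_mols,
                           vapply(library_mols, function(m) m$id, character(1)))
  cands <- unname(by_id[merged_ids])
  tick("merge", nrow(hitlist), length(cands))

  # --- 3. deduplicate ---------------------------------------------------
  cands <- timed("deduplicate", deduplicate(cands))
  write_molecules(cands, file.path(run_dir, "03_deduplicated.smi"))
  tick("deduplicate", length(merged_ids), length(cands))

  # --- 4. Lipinski/Veber ------------------------------------------------
  desc <- timed("lipinski_veber", compute_descriptors(cands))
  lv <- filter_library(desc, "lipinski_veber", max_violations = max_violations)
  keep <- lv$id[lv$verdict]
  n_in <- length(cands)
  cands <- cands[vapply(cands, function(m) m$id %in% keep, logical(1))]
  utils::write.csv(lv, file.path(run_dir, "04_lipinski_veber.csv"),
                   row.names = FALSE)
  tick("lipinski_veber", n_in, length(cands),
       list(max_violations = max_violations))

  # --- 5. ADMET ---------------------------------------------------------
  if (isTRUE(cfg$admet %||% TRUE)) {
    desc2 <- desc[desc$id %in% vapply(cands, function(m) m$id, character(1)), ]
    ad <- filter_library(desc2, "admet")
    keep <- ad$id[ad$verdict]
    n_in <- length(cands)
    cands <- cands[vapply(cands, function(m) m$id %in% keep, logical(1))]
    utils::write.csv(ad, file.path(run_dir, "05_admet.csv"), row.names = FALSE)
    tick("admet", n_in, length(cands))
  }

  # --- 6. ligand enumeration -------------------------------------------
  if (isTRUE(cfg$enumerate %||% TRUE)) {
    n_in <- length(cands)
    enum <- timed("enumerate_forms", {
      out <- list()
      for (m in cands)
        for (f in enumerate_forms(m, max_forms = cfg$max_forms %||% 8L))
          out[[length(out) + 1]] <- f
      out
    })
    enum <- deduplicate(enum)
    write_molecules(enum, file.path(run_dir, "06_enumerated.smi"))
    tick("enumerate_forms", n_in, length(enum),
         list(max_forms = cfg$max_forms %||% 8L))
    cands <- enum
  }

  # --- 7. pharmacophore screen -----------------------------------------
  model <- if (is.null(cfg$model) || identical(cfg$model, "glo1")) glo1_model()
           else read_ph_model(cfg$model)
  scr <- timed("pharmacophore_screen",
    ph_screen(cands, model, as.integer(cfg$max_confs %||% 32L),
              cfg$energy_window %||% 20, derive_seed(seed, "screen")))
  utils::write.csv(scr$hits, file.path(run_dir, "07_pharmacophore_hits.csv"),
                   row.names = FALSE)
  tick("pharmacophore_screen", length(cands), nrow(scr$hits),
       list(max_confs = as.integer(cfg$max_confs %||% 32L),
            energy_window = cfg$energy_window %||% 20,
            min_required = model$min_required))

  # --- 8. consensus -----------------------------------------------------
  if (!is.null(cfg$scores)) {
    st <- if (identical(cfg$scores, "synthetic")) {
      ids <- unique(sub("_f\\d+$", "", scr$hits$id))
      if (length(ids))
        load_scores(synth_score_table(ids, derive_seed(seed, "scores")))
      else NULL
    } else load_scores(cfg$scores)
    if (!is.null(st) && nrow(st$best)) {
      cons <- consensus_rank(st, cfg$consensus_method %||% "raw_sum")
      hits_parent <- scr$hits
      hits_parent$id <- sub("_f\\d+$", "", hits_parent$id)
      hits_parent <- hits_parent[!duplicated(hits_parent$id), ]
      final <- select_candidates(cons, hits_parent,
                                 as.integer(cfg$top_n %||% 9L))
      utils::write.csv(final, file.path(run_dir, "08_final_candidates.csv"),
                       row.names = FALSE)
      tick("consensus", nrow(scr$hits), nrow(final),
           list(method = cfg$consensus_method %||% "raw_sum",
                top_n = as.integer(cfg$top_n %||% 9L)))
    }
  }

  report <- funnel_report(stages, seed, run_dir, t_all, complete = TRUE)
  write_funnel_report(report, file.path(run_dir, "funnel_report.json"))
  report
}

funnel_report <- function(stages, seed, run_dir, timings, complete) {
  structure(list(stages = stages, seed = seed, run_dir = run_dir,
                 complete = complete, wall_clock = timings),
            class = "funnel_report")
}

#' Write a funnel report as JSON
#'
#' The `stages`, `seed` and `complete` fields are deterministic for a fixed
#' config; wall-clock timings live in a separate `wall_clock` field so that
#' reports can be compared net of timing noise.
#'
#' @param report `funnel_report`.
#' @param path output JSON path.
#' @export
write_funnel_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  for (s in x$stages)
    cat(sprintf("  %-22s %6d -> %6d\n", s$stage, s$n_in, s$n_out))
  invisible(x)
}
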