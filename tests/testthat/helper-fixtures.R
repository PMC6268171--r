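# Shared fixtures, built in code. Parsing goes through Open Babel once per
# helper call; anything expensive is memoised for the session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) assign(key, force(expr), fixture_env)
  get(key, envir = fixture_env)
}

mol1 <- function(smiles, id = "m") parse_smiles(smiles, id)[[1]]

pipeline_cfg <- function(run_dir, n = 60, seed = 7) {
  list(run_dir = run_dir, seed = seed,
       references = c("CC(=O)O", "Cn1cnnn1", "Oc1cccc2OC=CC(=O)c12"),
       library = list(n = n), k = 10, max_confs = 3, max_forms = 4,
       scores = "synthetic", top_n = 5)
}

cached_run <- function() {
  memo("pipeline_run", {
    dir <- file.path(tempdir(), "zb_pipe_a")
    list(report = suppressWarnings(run_pipeline(pipeline_cfg(dir))), dir = dir)
  })
}

glo1 <- function() memo("glo1", glo1_model())

small_db <- function() memo("small_db", synth_library(60, seed = 42))

# allowed-class exemplar panel: one canonical molecule per ZBG class
zbg_panel <- function() memo("zbg_panel", {
  smi <- c(carboxyl = "CC(=O)O", phosphate = "COP(=O)(O)O",
           imidazole = "c1cnc[nH]1", `triazole-123` = "c1c[nH]nn1",
           `triazole-124` = "c1nc[nH]n1", tetrazole = "c1nnn[nH]1",
           thiadiazole = "c1nncs1", `hydroxy-oxo-12` = "Oc1cccc2OC=CC(=O)c12")
  parse_smiles(unname(smi), names(smi))
})

# exclusion panel: hydroxamate, reverse hydroxamate, two thiols
zbg_exclusion_panel <- function() memo("zbg_excl", parse_smiles(
  c("CC(=O)NO", "ON(C(N)=O)c1ccccc1", "CCS", "Sc1ccccc1"),
  c("acetohydroxamic", "reverse_hydroxamate", "ethanethiol", "thiophenol")))

# an independent exhaustive top-k scan used as the search oracle
oracle_top_k <- function(ref_fp, db_fps, k, measure) {
  sims <- numeric(length(db_fps))
  for (i in seq_along(db_fps))
    sims[i] <- fp_similarity(fp_components(db_fps[[i]], ref_fp), measure)
  ord <- order(-sims, seq_along(sims))
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(target_id = names(db_fps)[top], similarity = unname(sims[top]),
             rank = seq_along(top))
}

# independent bit-set components oracle over explicit feature multisets
oracle_components <- function(t_entries, r_entries, mode) {
  if (mode == "bit") { t_entries[] <- pmin(t_entries, 1); r_entries[] <- pmin(r_entries, 1) }
  keys <- union(names(t_entries), names(r_entries))
  tv <- ifelse(keys %in% names(t_entries), t_entries[keys], 0)
  rv <- ifelse(keys %in% names(r_entries), r_entries[keys], 0)
  tv[is.na(tv)] <- 0; rv[is.na(rv)] <- 0
  list(SA = sum(pmin(tv, rv)), SB = sum(tv - pmin(tv, rv)),
       SC = sum(rv - pmin(tv, rv)))
}

# bare feature-point toys: one point per requested feature id, displaced by
# `jitter` in a seeded random direction
make_points <- function(model, ids, jitter = 0, seed = 1) {
  feats <- model$features[match(ids, vapply(model$features, `[[`, "", "id"))]
  with_local_seed <- get("with_local_seed", asNamespace("zbscreen"))
  with_local_seed(seed, lapply(feats, function(f) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    list(kind = f$kind, position = f$center + d * jitter, atoms = integer(0))
  }))
}

random_sparse_fp <- function(n_feat, scheme = "atom-type", mode = "count") {
  ids <- as.character(sample(1e6, n_feat))
  entries <- stats::setNames(sample(1:4, n_feat, replace = TRUE), ids)
  structure(list(entries = entries, scheme = scheme, max_distance = 6L,
                 mode = mode), class = "sparse_fp")
}

# Independent matcher oracle: exhaustive assignment enumeration plus a
# rotation-grid + Nelder-Mead superposition search (no Kabsch), scoring
# fit identically. Suitable for toys with <= 6 points.
oracle_match_fit <- function(points, model) {
  ids <- vapply(model$features, function(f) f$id, character(1))
  kinds <- vapply(model$features, function(f) f$kind, character(1))
  mand <- match(model$mandatory, ids)
  need <- max(model$min_required, 3L)
  nf <- length(ids)
  best_fit <- NULL
  rot <- function(a, b, g) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  eval_assign <- function(fsub, psub) {
    P <- t(vapply(psub, function(j) points[[j]]$position, numeric(3)))
    Q <- t(vapply(fsub, function(i) model$features[[i]]$center, numeric(3)))
    tol <- vapply(fsub, function(i) model$features[[i]]$tolerance, numeric(1))
    obj <- function(par) {
      Rm <- rot(par[1], par[2], par[3])
      moved <- sweep(t(Rm %*% t(P)), 2, par[4:6], `+`)
      sum((moved - Q)^2)
    }
    best <- NULL
    grid <- seq(0, 2 * pi, length.out = 5)[-5]
    for (a in grid) for (b in grid[1:2]) {
      start <- c(a, b, 0, colMeans(Q) - colMeans(P))
      o <- stats::optim(start, obj, control = list(maxit = 1000, reltol = 1e-14))
      o <- stats::optim(o$par, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    Rm <- rot(best$par[1], best$par[2], best$par[3])
    moved <- sweep(t(Rm %*% t(P)), 2, best$par[4:6], `+`)
    d <- sqrt(rowSums((moved - Q)^2))
    if (all(d <= tol + 1e-9)) sum(1 - d / tol) else NULL
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  subsets <- unlist(lapply(need:nf, function(k)
    utils::combn(nf, k, simplify = FALSE)), recursive = FALSE)
  for (fsub in subsets) {
    if (!all(mand %in% fsub)) next
    cand <- lapply(fsub, function(i)
      which(vapply(points, function(p) p$kind == kinds[i], logical(1))))
    if (any(vapply(cand, length, 1L) == 0)) next
    pool <- unique(unlist(cand))
    if (length(pool) < length(fsub)) next
    for (sel in utils::combn(pool, length(fsub), simplify = FALSE)) {
      for (pp in perms(sel)) {
        ok <- all(vapply(seq_along(fsub), function(t) pp[t] %in% cand[[t]],
                         logical(1)))
        if (!ok) next
        f <- eval_assign(fsub, pp)
        if (!is.null(f) && (is.null(best_fit) || f > best_fit)) best_fit <- f
      }
    }
  }
  best_fit
}
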