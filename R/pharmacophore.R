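# 3D pharmacophore models and the partial-matching engine.
#
# A pharmacophore feature is a typed, toleranced sphere (optionally with a
# directional projection) annotated with the receptor environment it
# represents. Matching assigns kind-compatible ligand feature points to
# model features, superposes them rigidly (least-squares, Kabsch) and
# accepts an assignment when every mapped displacement stays within its
# feature's tolerance. The fit value of an accepted assignment is
#     fit = sum over mapped features of (1 - displacement / tolerance),
# a transparent surrogate spanning 0..mapped-count (a perfect five-feature
# map scores exactly 5).

PH_KINDS <- c("HBA", "HBD", "HY", "NI", "PI", "RA", "ZB")
DIRECTIONAL_KINDS <- c("HBA", "HBD", "ZB")

#' Construct a pharmacophore feature
#'
#' @param id feature id.
#' @param kind one of HBA, HBD, HY, NI, PI, RA, ZB.
#' @param center numeric xyz (Angstrom).
#' @param tolerance sphere radius in Angstrom (> 0).
#' @param projection optional list `(target = xyz, angle_tol = degrees)`;
#'   only directional kinds (HBA/HBD/ZB) may carry one.
#' @param annotation free-text receptor annotation (e.g. `"Lys156"`, `"Zn"`).
#' @return list of class `ph_feature`.
#' @export
ph_feature <- function(id, kind, center, tolerance = 1.6, projection = NULL,
                       annotation = "") {
  kind <- match.arg(kind, PH_KINDS)
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (!is.null(projection) && !(kind %in% DIRECTIONAL_KINDS))
    stop("projection is only allowed on directional kinds (HBA/HBD/ZB)")
  structure(list(id = as.character(id), kind = kind,
                 center = as.numeric(center), tolerance = tolerance,
                 projection = projection, annotation = annotation),
            class = "ph_feature")
}

#' Construct a pharmacophore model
#'
#' @param features list of [ph_feature()].
#' @param min_required minimum number of mapped features for a match.
#' @param mandatory character vector of feature ids that every match must map.
#' @param metadata list (source structure, zinc position, provenance notes).
#' @param name model name.
#' @return list of class `ph_model`.
#' @export
ph_model <- function(features, min_required, mandatory = character(0),
                     metadata = list(), name = "model") {
  ids <- vapply(features, function(f) f$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids")
  if (min_required > length(features))
    stop("min_required exceeds feature count")
  if (!all(mandatory %in% ids)) stop("mandatory ids must exist in the model")
  if (sum(vapply(features, function(f) f$kind, character(1)) == "ZB") > 1)
    stop("at most one ZB feature is allowed")
  structure(list(name = name, features = features,
                 min_required = as.integer(min_required),
                 mandatory = mandatory, metadata = metadata),
            class = "ph_model")
}

#' @export
print.ph_model <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, character(1))
  cat(sprintf("<ph_model %s: %d features [%s], min %d, mandatory {%s}>\n",
              x$name, length(x$features), paste(kinds, collapse = ","),
              x$min_required, paste(x$mandatory, collapse = ",")))
  invisible(x)
}

#' Feature ids of a pharmacophore model
#' @param model `ph_model`.
#' @return character vector.
#' @export
feature_ids <- function(model) vapply(model$features, function(f) f$id, character(1))

#' Feature kinds of a pharmacophore model
#' @param model `ph_model`.
#' @return character vector.
#' @export
feature_kinds <- function(model) vapply(model$features, function(f) f$kind, character(1))

#' Read a pharmacophore model from YAML
#' @param path model file.
#' @return `ph_model`.
#' @export
read_ph_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model) || is.null(y$features))
    stop("corrupt model file (missing 'model' or 'features' section): ", path)
  feats <- lapply(y$features, function(f) {
    proj <- if (!is.null(f$projection))
      list(target = as.numeric(unlist(f$projection$target)),
           angle_tol = as.numeric(f$projection$angle_tol %||% 45))
    ph_feature(f$id, f$kind, as.numeric(unlist(f$center)),
               f$tolerance %||% 1.6, proj, f$annotation %||% "")
  })
  meta <- y$model[setdiff(names(y$model), c("min_required", "mandatory", "name"))]
  if (!is.null(meta$zinc)) meta$zinc <- as.numeric(unlist(meta$zinc))
  ph_model(feats, y$model$min_required %||% length(feats),
           unlist(y$model$mandatory) %||% character(0), meta,
           y$model$name %||% basename(path))
}

#' Write a pharmacophore model to YAML
#' @param model `ph_model`.
#' @param path output file.
#' @export
write_ph_model <- function(model, path) {
  y <- list(model = c(list(name = model$name), model$metadata,
                      list(min_required = model$min_required,
                           mandatory = as.list(model$mandatory))),
            features = lapply(model$features, function(f) {
              o <- list(id = f$id, kind = f$kind, center = as.list(f$center),
                        tolerance = f$tolerance)
              if (!is.null(f$projection))
                o$projection <- list(target = as.list(f$projection$target),
                                     angle_tol = f$projection$angle_tol)
              o$annotation <- f$annotation
              o
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The packaged seven-feature Glo-1 model
#'
#' Loads the versioned model file shipped with the package: one zinc binder
#' (ZB) pointing to the catalytic zinc, two hydrophobics (HY) filling the
#' pocket, two donors (HBD) toward Asn103/Thr101, one acceptor (HBA) toward
#' Lys156 and one negative ionizable (NI) complementary to Arg122/Arg37;
#' minimum match four of seven, ZB and its adjacent HY mandatory.
#' Coordinates are synthetic fixture data (see the file header).
#'
#' @return `ph_model`.
#' @export
glo1_model <- function() {
  read_ph_model(system.file("extdata", "glo1_model_synthetic.yaml",
                            package = "zbscreen"))
}

#' Replace the zinc-oriented donor feature by a zinc-binder feature
#'
#' The single HBD feature nearest the zinc position (its projection target
#' or, failing that, its center must lie within 2.8 A of the zinc) is
#' re-typed to ZB with position and tolerance retained. Idempotent: a model
#' whose zinc-proximal feature is already ZB is returned unchanged.
#'
#' @param model `ph_model`.
#' @param zn numeric xyz of the zinc atom.
#' @return modified `ph_model`.
#' @export
customize_zb <- function(model, zn) {
  zn <- as.numeric(zn)
  prox_dist <- vapply(model$features, function(f) {
    p <- if (!is.null(f$projection)) f$projection$target else f$center
    min(vnorm(p - zn), vnorm(f$center - zn))
  }, numeric(1))
  kinds <- feature_kinds(model)
  prox <- which(prox_dist <= 2.8)
  if (!length(prox)) stop("no feature orients to the zinc position")
  if (any(kinds[prox] == "ZB")) return(model)   # already customized
  cand <- prox[kinds[prox] == "HBD"]
  if (!length(cand)) stop("no feature orients to the zinc position")
  i <- cand[which.min(prox_dist[cand])]
  model$features[[i]]$kind <- "ZB"
  model$features[[i]]$annotation <- "Zn"
  model$metadata$zinc <- zn
  model
}

# ---- ligand-side feature perception -------------------------------------

#' Perceive pharmacophoric feature points of a 3D conformer
#'
#' Rule-based perception: HBD = N/O bearing hydrogen; HBA = O (not
#' positively charged) and N without hydrogen; HY = centroids of all-carbon
#' rings and of acyclic apolar carbon chains of three or more atoms; NI =
#' centroids of deprotonatable acid groups (carboxyl(ate), sulfon(ate),
#' phosphate, acidic tetrazole); PI = protonatable or protonated amine
#' nitrogens; RA = aromatic ring centroids; ZB = coordinating-atom centroid
#' of every [detect_zbg()] match. N-H nitrogens are treated as donor-only.
#'
#' @param mol a `mol_record` with 3D coordinates.
#' @return list of points: `kind`, `position`, `atoms`, optional `zbg`.
#' @export
perceive_ligand_features <- function(mol) {
  if (is.null(mol$coords)) stop("missing 3D coordinates for '", mol$id, "'")
  xyz <- mol$coords
  el <- mol$atoms$element; ch <- mol$atoms$charge
  h <- implicit_h(mol)
  adj <- mol_adj(mol)
  deg <- heavy_degree(mol)
  rings <- mol_rings(mol)
  arom <- aromatic_rings(mol)
  pts <- list()
  add <- function(kind, atoms, extra = NULL) {
    pos <- colMeans(xyz[atoms, , drop = FALSE])
    pts[[length(pts) + 1]] <<- c(list(kind = kind, position = pos,
                                      atoms = atoms), extra)
  }
  # donors / acceptors
  for (i in seq_len(n_atoms(mol))) {
    if (el[i] %in% c("N", "O") && h[i] > 0) add("HBD", i)
    if (el[i] == "O" && ch[i] <= 0) add("HBA", i)
    if (el[i] == "N" && h[i] == 0 && ch[i] <= 0) add("HBA", i)
  }
  # hydrophobics: all-carbon rings
  for (r in rings) if (all(el[r] == "C")) add("HY", r)
  # hydrophobics: acyclic apolar chains >= 3 C
  in_ring <- seq_len(n_atoms(mol)) %in% unlist(rings)
  apolar <- vapply(seq_len(n_atoms(mol)), function(i)
    el[i] == "C" && !in_ring[i] && ch[i] == 0 &&
      all(el[adj[[i]]$nbr] == "C"), logical(1))
  comp <- rep(NA_integer_, n_atoms(mol)); cid <- 0L
  for (i in which(apolar)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L; q <- i
    while (length(q)) {
      a <- q[1]; q <- q[-1]
      if (!is.na(comp[a])) next
      comp[a] <- cid
      q <- c(q, intersect(adj[[a]]$nbr, which(apolar)))
    }
  }
  if (cid > 0) for (k in seq_len(cid)) {
    chain <- which(comp == k)
    if (length(chain) >= 3) add("HY", chain)
  }
  # aromatic ring centroids
  for (r in arom) add("RA", r, list(normal = ring_normal(xyz[r, , drop = FALSE])))
  # negative ionizable acid groups
  ctx <- list(adj = adj, h = h, el = el, ch = ch, deg = deg,
              rings = rings, arom = arom)
  ni_atoms <- list()
  for (m in zbg_carboxyl(mol, ctx)) ni_atoms[[length(ni_atoms) + 1]] <- m$coordinating
  for (m in zbg_phosphate(mol, ctx)) ni_atoms[[length(ni_atoms) + 1]] <- m$coordinating
  for (m in zbg_ring(mol, ctx, list(c("N", "N", "N", "N", "C"))))
    ni_atoms[[length(ni_atoms) + 1]] <- m$atoms
  for (i in seq_len(n_atoms(mol))) {   # sulfonate / sulfonic
    if (el[i] != "S") next
    o_nb <- adj[[i]]$nbr[el[adj[[i]]$nbr] == "O"]
    if (sum(adj[[i]]$order == 2 & el[adj[[i]]$nbr] == "O") >= 2 &&
        any(vapply(o_nb, function(o) deg[o] == 1 && (h[o] > 0 || ch[o] < 0),
                   logical(1))))
      ni_atoms[[length(ni_atoms) + 1]] <- c(i, o_nb)
  }
  for (a in ni_atoms) add("NI", a)
  # positive ionizable
  for (i in which(el == "N" & ch > 0)) add("PI", i)
  rules <- pka_rules()
  for (s in find_ionizable_sites(mol, rules))
    if (s$group == "aliphatic_amine") add("PI", s$atom)
  # zinc binders
  for (zm in detect_zbg(mol)) add("ZB", zm$coordinating, list(zbg = zm))
  # drop exact duplicates (same kind, same atom set)
  keys <- vapply(pts, function(p)
    paste(p$kind, paste(sort(p$atoms), collapse = ","), sep = "@"), character(1))
  pts[!duplicated(keys)]
}

ring_normal <- function(m) {
  c0 <- colMeans(m)
  sv <- svd(sweep(m, 2, c0))
  sv$v[, 3]
}

# ---- rigid superposition and matching -----------------------------------

# Least-squares rigid superposition of ligand points P onto feature centers
# Q (Kabsch). Returns R, t with x' = R x + t.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

apply_transform <- function(xyz, tr) {
  sweep(t(tr$R %*% t(xyz)), 2, tr$t, `+`)
}

#' Match ligand feature points against a pharmacophore model
#'
#' Searches kind-compatible assignments of ligand points to model features
#' (ZB features accept only ZB points, every other kind its own), requiring
#' all mandatory features plus at least `min_required` mapped features
#' (never fewer than three, the minimum for a determined rigid
#' superposition). Each candidate assignment is superposed by least squares;
#' it is accepted when every mapped displacement is within its feature's
#' tolerance. Returns the accepted match maximizing
#' `fit = sum(1 - d/tol)`, ties broken by larger mapped count then
#' lexicographically; `NULL` when no assignment is acceptable.
#'
#' @param points output of [perceive_ligand_features()].
#' @param model `ph_model`.
#' @param conformer_id id recorded on the result.
#' @return `ph_match` or `NULL`.
#' @export
ph_match_points <- function(points, model, conformer_id = "conf1") {
  n_feat <- length(model$features)
  ids <- feature_ids(model)
  kinds <- feature_kinds(model)
  mand_idx <- match(model$mandatory, ids)
  need <- max(model$min_required, 3L)
  cand <- lapply(seq_len(n_feat), function(i)
    which(vapply(points, function(p) p$kind == kinds[i], logical(1))))
  feasible <- which(vapply(cand, length, 1L) > 0)
  if (length(intersect(mand_idx, feasible)) < length(mand_idx)) return(NULL)
  opt <- setdiff(feasible, mand_idx)
  best <- NULL
  consider <- function(sub) {
    res <- best_assignment(sub, cand, points, model)
    if (is.null(res)) return()
    if (is.null(best) || res$fit > best$fit + 1e-12 ||
        (abs(res$fit - best$fit) <= 1e-12 &&
         (res$mapped_count > best$mapped_count ||
          (res$mapped_count == best$mapped_count &&
           res$assign_key < best$assign_key)))) best <<- res
  }
  for (k in seq(from = max(need - length(mand_idx), 0), to = length(opt))) {
    if (length(mand_idx) + k < need) next
    combos <- if (k == 0) list(integer(0))
              else utils::combn(opt, k, simplify = FALSE)
    for (cmb in combos) consider(sort(c(mand_idx, cmb)))
  }
  if (is.null(best)) return(NULL)
  best$conformer <- conformer_id
  best$assign_key <- NULL
  structure(best, class = "ph_match")
}

# exhaustive injective assignment of the feature subset to candidate points
best_assignment <- function(sub, cand, points, model) {
  best <- NULL
  k <- length(sub)
  Q <- t(vapply(sub, function(i) model$features[[i]]$center, numeric(3)))
  tol <- vapply(sub, function(i) model$features[[i]]$tolerance, numeric(1))
  ids <- vapply(sub, function(i) model$features[[i]]$id, character(1))
  assign_rec <- function(pos, chosen) {
    if (pos > k) {
      P <- t(vapply(chosen, function(j) points[[j]]$position, numeric(3)))
      tr <- kabsch(P, Q)
      moved <- apply_transform(P, tr)
      d <- sqrt(rowSums((moved - Q)^2))
      if (all(d <= tol + 1e-9)) {
        fit <- sum(1 - d / tol)
        key <- paste(ids, chosen, sep = ":", collapse = ";")
        res <- list(assignment = stats::setNames(chosen, ids),
                    displacements = stats::setNames(d, ids), fit = fit,
                    transform = tr, mapped_count = k, assign_key = key)
        if (is.null(best) || fit > best$fit + 1e-12 ||
            (abs(fit - best$fit) <= 1e-12 && key < best$assign_key))
          best <<- res
      }
      return()
    }
    for (j in setdiff(cand[[sub[pos]]], chosen))
      assign_rec(pos + 1, c(chosen, j))
  }
  assign_rec(1, integer(0))
  best
}

#' @export
print.ph_match <- function(x, ...) {
  cat(sprintf("<ph_match %s: %d features mapped, fit %.3f>\n",
              x$conformer, x$mapped_count, x$fit))
  invisible(x)
}

#' Re-verify a match result
#'
#' Re-applies the stored transform to the mapped points, recomputes
#' displacements and the fit value, and checks every invariant
#' (displacement within tolerance, fit consistent to 1e-9, mandatory
#' features mapped, mapped count >= min_required).
#'
#' @param match `ph_match`.
#' @param points the ligand points the match was computed from.
#' @param model the model.
#' @return TRUE (invisibly); stops on any violated invariant.
#' @export
verify_match <- function(match, points, model) {
  ids <- feature_ids(model)
  sub <- match(names(match$assignment), ids)
  P <- t(vapply(match$assignment, function(j) points[[j]]$position, numeric(3)))
  Q <- t(vapply(sub, function(i) model$features[[i]]$center, numeric(3)))
  tol <- vapply(sub, function(i) model$features[[i]]$tolerance, numeric(1))
  moved <- apply_transform(P, match$transform)
  d <- sqrt(rowSums((moved - Q)^2))
  if (!all(d <= tol + 1e-6)) stop("displacement exceeds tolerance on re-check")
  if (abs(sum(1 - d / tol) - match$fit) > 1e-9)
    stop("fit does not recompute within 1e-9")
  if (!all(model$mandatory %in% names(match$assignment)))
    stop("mandatory feature missing from match")
  if (match$mapped_count < model$min_required)
    stop("mapped count below min_required")
  invisible(TRUE)
}
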